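test_that("Pearson association: exact lines, stars and errors", {
  x <- 1:20
  a <- pearson_association(x, 2 * x + 1)
  expect_equal(a$r, 1)
  expect_equal(pearson_association(x, -x)$r, -1)
  expect_error(pearson_association(x, rep(3, 20)),
               class = "undefined_correlation_error")
  expect_error(pearson_association(1:2, 2:1), class = "domain_error")
  # stars are a pure function of p
  expect_equal(rotifd:::significance_stars(c(0.2, 0.04, 0.004)),
               c("", "*", "**"))
})

test_that("independent normal samples rarely cross the critical value", {
  # Monte-Carlo at n = 118: |r| below the t-based 5% critical value in >= 90%
  crit <- sqrt(qt(0.975, 116)^2 / (qt(0.975, 116)^2 + 116))
  set.seed(1)
  hits <- sum(replicate(100, {
    abs(pearson_association(rnorm(118), rnorm(118))$r) < crit
  }))
  expect_gte(hits, 90)
})

test_that("simple regression matches the normal-equations oracle", {
  expect_error(simple_regression(c(1, 2), c(1, 2)), class = "domain_error")
  expect_error(simple_regression(rep(1, 5), rnorm(5)), class = "design_error")
  x <- 1:10
  fit <- suppressWarnings(simple_regression(x, 3 * x - 2))  # perfect-fit warning
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, 3)
  expect_lt(max(abs(fit$band$fit - (3 * x - 2))), 1e-10)
  set.seed(1)
  x <- rnorm(500)
  y <- 0.5 * x + rnorm(500)
  fit <- simple_regression(x, y)
  ora <- oracle_lm_coefs(x, y)
  expect_equal(c(fit$intercept, fit$slope), unname(ora), tolerance = 1e-9)
  # R^2 equals squared Pearson r
  expect_equal(fit$r2, pearson_association(x, y)$r^2, tolerance = 1e-12)
  # band brackets the fitted line
  expect_true(all(fit$band$lwr <= fit$band$fit & fit$band$fit <= fit$band$upr))
})

test_that("one-way ANOVA with Tukey HSD behaves at the boundaries", {
  expect_error(anova_tukey(rnorm(10), rep("a", 10)), class = "validation_error")
  expect_error(anova_tukey(c(1, 2, 3), c("a", "a", "b")), class = "validation_error")
  # all groups one constant: F = 0, p = 1, one shared letter
  res <- anova_tukey(rep(5, 12), rep(c("a", "b", "c"), each = 4))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_equal(unname(res$letters), rep("a", 3))
  # two groups 10 pooled SDs apart: overwhelming evidence
  set.seed(2)
  v <- c(rnorm(20, 0, 1), rnorm(20, 10, 1))
  g <- rep(c("lo", "hi"), each = 20)
  res <- anova_tukey(v, g)
  expect_lt(res$p, 1e-3)
  expect_false(res$letters[["lo"]] == res$letters[["hi"]])
  # closed-form F for the two-group case equals t^2
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  # hand-computed F from the sums of squares
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  expect_equal(res$F, (ssb / 1) / (ssw / 38), tolerance = 1e-9)
})

test_that("seasonal grouping maps months to meteorological seasons", {
  expect_equal(season_of_month(c(3, 6, 9, 12, 2)),
               c("spring", "summer", "autumn", "winter", "winter"))
  seas <- season_of_month(1:12)
  expect_equal(unname(table(seas)[c("spring", "summer", "autumn", "winter")]),
               rep(3L, 4), ignore_attr = TRUE)
})

test_that("report bundle is complete and its tables deterministic", {
  ds <- simulate_dataset(sim_config(master_seed = 1L, n_sites = 4L, n_months = 6L,
                                    n_species = 18L, missing_sample_rate = 0))
  tli <- composite_tli(ds$environment)
  space <- trait_pcoa(trait_distance(ds$traits))
  fd <- fd_indices(ds$community, space)
  beta <- decompose_beta(ds$community)
  out1 <- tempfile("rep1"); out2 <- tempfile("rep2")
  man <- render_report(ds, tli, fd, beta, out1)
  expect_equal(sum(man$kind == "figure"), 6)
  expect_equal(sum(man$kind == "table"), 7)
  expect_true(all(file.exists(file.path(out1, man$file))))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  # rerun: CSV tables byte-identical
  render_report(ds, tli, fd, beta, out2)
  for (f in man$file[man$kind == "table"]) {
    expect_identical(readBin(file.path(out1, f), "raw", file.size(file.path(out1, f))),
                     readBin(file.path(out2, f), "raw", file.size(file.path(out2, f))),
                     label = f)
  }
  expect_error(render_report(ds, NULL, fd, beta, out1), class = "dependency_error")
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("CLI runs the pipeline end to end", {
  out <- tempfile("cli")
  expect_invisible(rotifd_cli(c("simulate", "--seed", "3", "--outdir", out,
                                "--log-level", "quiet")))
  expect_true(file.exists(file.path(out, "community.csv")))
  rotifd_cli(c("tli", "--seed", "3", "--outdir", out, "--log-level", "quiet"))
  tl <- read.csv(file.path(out, "tli_result.csv"))
  expect_true(all(c("tlic", "class") %in% names(tl)))
  rotifd_cli(c("beta", "--seed", "3", "--outdir", out, "--log-level", "quiet",
               "--beta-family", "podani-ruzicka"))
  expect_true(file.exists(file.path(out, "dendrogram.nwk")))
  tri <- read.csv(file.path(out, "beta_triads.csv"))
  expect_true(all(abs(tri$sim + tri$repl + tri$rich - 1) < 1e-12))
  expect_error(rotifd_cli(c("frobnicate")), class = "configuration_error")
  unlink(out, recursive = TRUE)
})
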