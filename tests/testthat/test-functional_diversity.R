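square_space <- function() {
  xy <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c", "d"), c("axis1", "axis2")))
  as_space(xy)
}

test_that("trait distances: mean categorical mismatch in [0, 1]", {
  tr <- validate_trait_table(data.frame(
    taxon = c("A", "B", "C"),
    trophi = c("malleate", "malleate", "virgate"),
    size = c("<150um", "<150um", ">300um"),
    feeding = c("filter_feeding", "filter_feeding", "sucking"),
    swimming = c("planktonic", "benthic", "benthic")))
  d <- trait_distance(tr, "gower")
  expect_equal(d["A", "A"], 0)
  expect_equal(d["A", "B"], 0.25)   # one of four categories differs
  expect_equal(d["A", "C"], 1)      # all four differ
  expect_true(isSymmetric(d))
  # one-hot Bray-Curtis coincides for single-modality categorical traits
  d2 <- trait_distance(tr, "braycurtis_indicator")
  expect_equal(d2, d)
  expect_error(trait_distance(tr[1, , drop = FALSE]), class = "domain_error")
})

test_that("PCoA: two-point geometry and Euclidean round-trip", {
  d <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sp <- trait_pcoa(d, k_max = 2)
  expect_equal(sp$k, 1)
  expect_equal(sort(sp$coords[, 1]), c(-0.4, 0.4), ignore_attr = TRUE)
  # planar Euclidean distances are reproduced exactly on 2 axes
  set.seed(3)
  pts <- matrix(runif(10), 5, 2)
  de <- as.matrix(dist(pts))
  sp2 <- trait_pcoa(de, k_max = 4)
  expect_false(sp2$correction_applied)
  expect_equal(as.matrix(dist(sp2$coords)), de, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(sp2$quality, 1, tolerance = 1e-9)
  # eigenvalues nonincreasing
  expect_true(all(diff(sp2$eigenvalues) <= 1e-12))
})

test_that("PCoA applies the additive correction only when needed", {
  ds <- simulate_dataset(sim_config(master_seed = 4L, n_species = 15L))
  d <- trait_distance(ds$traits)
  sp <- trait_pcoa(d)
  expect_true(sp$correction_applied)       # categorical distances: non-Euclidean
  expect_gt(sp$additive_constant, 0)
  expect_true(all(sp$eigenvalues > -1e-8)) # corrected space has no negatives
  sp_raw <- trait_pcoa(d, correction = "none")
  expect_lt(min(sp_raw$eigenvalues), 0)
  expect_error(trait_pcoa(matrix(c(0, 1, 2, 0), 2, 2)), class = "validation_error")
})

test_that("FRic: unit square, degeneracy and insufficiency rules", {
  sp <- square_space()
  expect_equal(as.numeric(fric(sp, c("a", "b", "c", "d"))), 1)
  # collinear points: zero volume, degenerate flag
  col <- as_space(matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE,
                         dimnames = list(c("a", "b", "c"), NULL)))
  v <- fric(col, c("a", "b", "c"))
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "flag"), "degenerate hull")
  # S <= axes: undefined
  v2 <- fric(sp, c("a", "b"))
  expect_true(is.na(v2))
  expect_match(attr(v2, "flag"), "S <= axes")
  # 1-axis space: volume is the range
  sp1 <- as_space(matrix(c(0, 2, 5), 3, 1, dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(as.numeric(fric(sp1, c("a", "b", "c"))), 5)
})

test_that("FRic monotonicity: outside point grows the hull, inside leaves it", {
  set.seed(12)
  for (i in 1:20) {
    cm <- random_planar_community(8)
    sp <- as_space(cm$xy)
    base <- as.numeric(fric(sp, rownames(cm$xy)[1:7]))
    full <- as.numeric(fric(sp, rownames(cm$xy)))
    expect_gte(full, base - 1e-12)
    # adding the hull centroid (interior) leaves the volume unchanged
    xy2 <- rbind(cm$xy, inner = colMeans(oracle_hull(cm$xy)))
    expect_equal(as.numeric(fric(as_space(xy2), rownames(xy2))), full,
                 tolerance = 1e-12)
  }
})

test_that("FEve: evenness on the unit square and bounds", {
  sp <- square_space()
  ab <- setNames(rep(1, 4), c("a", "b", "c", "d"))
  expect_equal(as.numeric(feve(sp, ab)), 1)   # 3 unit MST edges, equal weights
  ab97 <- setNames(c(0.97, 0.01, 0.01, 0.01), c("a", "b", "c", "d"))
  v <- as.numeric(feve(sp, ab97))
  expect_lt(v, 1)
  expect_gte(v, 0)
  expect_equal(v, oracle_feve(sp$coords, ab97))
  expect_true(is.na(feve(sp, setNames(c(1, 1, 0, 0), c("a", "b", "c", "d")))))
})

test_that("FDiv: symmetric square is 1, centre-heavy community below 1", {
  sp <- square_space()
  ab <- setNames(rep(1, 4), c("a", "b", "c", "d"))
  expect_equal(as.numeric(fdiv(sp, ab)), 1)   # all d_i equal
  xy5 <- rbind(sp$coords, e = c(0.5, 0.5))
  sp5 <- as_space(xy5)
  ab5 <- setNames(c(rep(0.0025, 4), 0.99), rownames(xy5))
  v <- as.numeric(fdiv(sp5, ab5))
  expect_lt(v, 1)
  expect_gte(v, 0)
  expect_equal(v, oracle_fdiv(xy5, ab5))
  expect_true(is.na(fdiv(sp, setNames(c(1, 1, 0, 0), c("a", "b", "c", "d")))))
})

test_that("FEve and FDiv are invariant to the abundance scale", {
  set.seed(21)
  for (i in 1:10) {
    cm <- random_planar_community(7)
    sp <- as_space(cm$xy)
    k <- runif(1, 0.01, 1000)
    expect_equal(as.numeric(feve(sp, cm$ab)), as.numeric(feve(sp, k * cm$ab)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(fdiv(sp, cm$ab)), as.numeric(fdiv(sp, k * cm$ab)),
                 tolerance = 1e-12)
  }
})

test_that("indices agree with brute-force oracles on random communities", {
  set.seed(99)
  for (i in 1:30) {
    cm <- random_planar_community(sample(5:10, 1))
    sp <- as_space(cm$xy)
    expect_equal(as.numeric(fric(sp, rownames(cm$xy))), oracle_hull_area(cm$xy),
                 tolerance = 1e-9)
    expect_equal(as.numeric(feve(sp, cm$ab)), oracle_feve(cm$xy, cm$ab),
                 tolerance = 1e-9)
    expect_equal(as.numeric(fdiv(sp, cm$ab)), oracle_fdiv(cm$xy, cm$ab),
                 tolerance = 1e-9)
  }
})

test_that("per-sample table flags undefined indices with reasons", {
  ds <- simulate_dataset(sim_config(master_seed = 8L, n_sites = 2L, n_months = 3L,
                                    n_species = 12L, missing_sample_rate = 0))
  space <- trait_pcoa(trait_distance(ds$traits))
  fd <- fd_indices(ds$community, space)
  expect_equal(nrow(fd), 6)
  expect_true(all(fd$feve >= 0 & fd$feve <= 1, na.rm = TRUE))
  expect_true(all(fd$fdiv >= 0 & fd$fdiv <= 1, na.rm = TRUE))
  expect_true(all(fd$fric >= 0, na.rm = TRUE))
  expect_true(all(!is.na(fd$feve) | grepl("S <", fd$feve_flag)))
})
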