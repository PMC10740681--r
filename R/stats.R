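# Association and group-comparison statistics used by the report layer.

significance_stars <- function(p, thresholds = c(0.05, 0.01)) {
  ifelse(p < thresholds[2], "**", ifelse(p < thresholds[1], "*", ""))
}

#' Pearson correlation with significance stars
#'
#' @param x,y numeric vectors of equal length (n >= 3), both nonconstant.
#' @param names optional pair of variable names for the report.
#' @return list of class `association_result`: names, `r`, `p`, `stars`,
#'   `n`.
#' @export
pearson_association <- function(x, y, names = c("x", "y")) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) rfd_stop("domain_error", "need n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    rfd_stop("undefined_correlation_error", "constant vector: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(names = names, r = unname(ct$estimate), p = ct$p.value,
                 stars = significance_stars(ct$p.value), n = length(x)),
            class = "association_result")
}

#' Simple linear regression with a 95% mean-response band
#'
#' @param x,y numeric vectors (n >= 3, x nonconstant).
#' @return list of class `regression_result`: `slope`, `intercept`, `r2`,
#'   `p` (slope, two-sided), `n`, and `band` (data.frame x, fit, lwr, upr
#'   at the observed x).
#' @export
simple_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) rfd_stop("domain_error", "need n >= 3 (insufficient df)")
  if (sd(x) == 0) rfd_stop("design_error", "constant x: slope undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  ci <- predict(fit, interval = "confidence", level = 0.95)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 n = length(x),
                 band = data.frame(x = x, fit = ci[, "fit"], lwr = ci[, "lwr"],
                                   upr = ci[, "upr"])),
            class = "regression_result")
}

# compact letter display by insert-and-absorb on the pairwise p matrix
grouping_letters <- function(levels, pairs_p, alpha = 0.05) {
  k <- length(levels)
  cols <- list(rep(TRUE, k))   # start: everyone shares letter a
  for (pr in seq_len(nrow(pairs_p))) {
    i <- pairs_p$i[pr]; j <- pairs_p$j[pr]
    if (pairs_p$p[pr] >= alpha) next
    for (ci in seq_along(cols)) {
      if (cols[[ci]][i] && cols[[ci]][j]) {
        a <- cols[[ci]]; b <- cols[[ci]]
        a[i] <- FALSE; b[j] <- FALSE
        cols[[ci]] <- a
        cols <- c(cols, list(b))
      }
    }
    # absorb duplicated/contained columns
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] && all(cols[[ci]] <= cols[[cj]]))
        keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  letters_out <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""), "")
  setNames(letters_out, levels)
}

#' One-way ANOVA with Tukey honest significant differences
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @param alpha significance level for the compact letter display.
#' @return list of class `anova_result`: `F`, `p`, `df`, `tukey`
#'   (data.frame pair, diff, lwr, upr, p_adj), `letters`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  ok <- complete.cases(values, groups)
  values <- values[ok]; groups <- factor(groups[ok])
  sizes <- table(groups)
  if (length(sizes) < 2L) rfd_stop("validation_error", "need >= 2 groups")
  if (any(sizes < 2L))
    rfd_stop("validation_error", "group(s) with < 2 observations: %s",
             paste(names(sizes)[sizes < 2], collapse = ", "))
  if (sd(values) == 0) {
    # zero total variance: no evidence of any difference (F -> 0, p -> 1)
    lv <- levels(groups)
    cmb <- utils::combn(lv, 2)
    return(structure(list(F = 0, p = 1, df = c(length(lv) - 1L, length(values) - length(lv)),
                          tukey = data.frame(pair = paste(cmb[2, ], cmb[1, ], sep = "-"),
                                             diff = 0, lwr = 0, upr = 0, p_adj = 1),
                          letters = setNames(rep("a", length(lv)), lv)),
                     class = "anova_result"))
  }
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  Fv <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
  tk <- TukeyHSD(fit)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  lv <- levels(groups)
  pairs_p <- data.frame(i = match(pairs[, 1], lv), j = match(pairs[, 2], lv),
                        p = tk[, "p adj"])
  structure(list(F = Fv, p = p, df = tab[["Df"]],
                 tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                                    p_adj = tk[, "p adj"], row.names = NULL),
                 letters = grouping_letters(lv, pairs_p, alpha)),
            class = "anova_result")
}

#' Meteorological-season label for a calendar month
#'
#' Spring = Mar-May, summer = Jun-Aug, autumn = Sep-Nov, winter = Dec-Feb.
#'
#' @param month integer 1-12.
#' @return character vector of season names.
#' @export
season_of_month <- function(month) {
  stopifnot(all(month %in% 1:12))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[month]
}
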