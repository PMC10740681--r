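#' Trophic level index coefficient sets
#'
#' Per-parameter intercepts and slopes for the lake trophic level index
#' TLI_j = 10 * (a_j + b_j * ln x_j), plus the reference correlations r_j of
#' each parameter with chlorophyll-a used to derive the composite weights.
#' The parameter order is fixed: chla (mg/m3), tp (mg/L), tn (mg/L),
#' sd (m, transparency), cod (mg/L, permanganate COD).
#'
#' Two sets are shipped. `"canonical"` is the standard Chinese lake-survey
#' coefficient set, in which transparency enters with a negative slope (clear
#' water scores low). `"as_printed"` reproduces a corrupted published variant
#' in which the SD line duplicates the TP coefficients and the COD line
#' carries the canonical SD constants; it is retained so results computed
#' against that text can be reproduced exactly.
#'
#' @param set `"canonical"` or `"as_printed"`.
#' @param r reference correlation vector (length 5, chla first); defaults to
#'   the national 26-lake survey values.
#' @return Object of class `tli_coefficients`: list with `a`, `b`, `r`,
#'   `set`, all named by parameter.
#' @export
#' @examples
#' tli_coefficients()$b  # sd slope is negative in the canonical set
tli_coefficients <- function(set = c("canonical", "as_printed"),
                             r = c(chla = 1, tp = 0.84, tn = 0.82,
                                   sd = 0.83, cod = 0.83)) {
  set <- match.arg(set)
  params <- c("chla", "tp", "tn", "sd", "cod")
  ab <- switch(set,
    canonical = list(
      a = c(chla = 2.5, tp = 9.436, tn = 5.453, sd = 5.118, cod = 0.109),
      b = c(chla = 1.086, tp = 1.624, tn = 1.694, sd = -1.94, cod = 2.661)),
    as_printed = list(
      a = c(chla = 2.5, tp = 9.436, tn = 5.453, sd = 9.436, cod = 5.118),
      b = c(chla = 1.086, tp = 1.624, tn = 1.694, sd = 1.624, cod = 1.94)))
  r <- setNames(as.numeric(r), params)
  if (any(!is.finite(r))) rfd_stop("configuration_error", "non-finite reference correlation")
  structure(list(a = ab$a, b = ab$b, r = r, set = set, params = params),
            class = "tli_coefficients")
}

#' Single-parameter trophic level index
#'
#' TLI_j = 10 * (a_j + b_j * ln x_j), natural logarithm, on the 0-100 index
#' scale.
#'
#' @param parameter one of `"chla"`, `"tp"`, `"tn"`, `"sd"`, `"cod"`.
#' @param value strictly positive concentration (or transparency in m).
#' @param coefficients a [tli_coefficients()] object.
#' @return numeric index values, same length as `value`.
#' @export
#' @examples
#' tli_parameter("chla", 1)   # 25: ln(1) = 0
tli_parameter <- function(parameter, value, coefficients = tli_coefficients()) {
  if (!parameter %in% coefficients$params)
    rfd_stop("configuration_error", "unknown parameter '%s' (expected one of %s)",
             parameter, paste(coefficients$params, collapse = ", "))
  bad <- which(!is.finite(value) | value <= 0)
  if (length(bad))
    rfd_stop("domain_error", "non-positive %s value at position(s) %s: logarithm undefined",
             parameter, paste(head(bad, 5), collapse = ", "))
  10 * (coefficients$a[[parameter]] + coefficients$b[[parameter]] * log(value))
}

#' Correlation-derived composite weights
#'
#' W_j = r_j^2 / sum(r^2). Sign-invariant in each r_j; weights sum to 1.
#'
#' @param r numeric vector of reference correlations (not all zero).
#' @return numeric weights, same names/length as `r`.
#' @export
weights_from_correlations <- function(r) {
  if (length(r) == 0L) rfd_stop("degenerate_weights_error", "empty correlation vector")
  if (any(!is.finite(r))) rfd_stop("degenerate_weights_error", "non-finite correlation")
  s <- sum(r^2)
  if (s == 0) rfd_stop("degenerate_weights_error", "all reference correlations are zero")
  r^2 / s
}

#' Classify trophic state from a composite index value
#'
#' Below 30: oligotrophic; 30 to 50 inclusive: mesotrophic; above 50:
#' eutrophic. The published thresholds use strict inequalities on both sides,
#' leaving the boundaries unassigned; here both boundary values fall in the
#' mesotrophic class.
#'
#' @param tlic finite numeric composite index values.
#' @return character vector of classes.
#' @export
#' @examples
#' classify_trophic_state(c(25, 40, 54.93))
classify_trophic_state <- function(tlic) {
  if (any(!is.finite(tlic))) rfd_stop("domain_error", "non-finite TLIc value")
  ifelse(tlic < 30, "oligotrophic", ifelse(tlic <= 50, "mesotrophic", "eutrophic"))
}

#' Composite trophic level index for an environment table
#'
#' Scores each sample as the correlation-weighted sum of the five
#' per-parameter indices and attaches the trophic class. Samples with a
#' missing or non-positive parameter are skipped with a warning, or scored
#' with weights renormalized over the available parameters when
#' `na_action = "renormalize"`.
#'
#' @param env data.frame with at least `sample_id` and columns `chla`, `tp`,
#'   `tn`, `sd`, `cod` (strictly positive where present).
#' @param coefficients a [tli_coefficients()] object.
#' @param na_action `"skip"` (default) or `"renormalize"`.
#' @return data.frame of class `tli_result`: `sample_id`, `tli_chla` ..
#'   `tli_cod`, `tlic`, `class`, with the weight vector, parameter count `m`
#'   and coefficient-set label as attributes.
#' @export
composite_tli <- function(env, coefficients = tli_coefficients(),
                          na_action = c("skip", "renormalize")) {
  na_action <- match.arg(na_action)
  params <- coefficients$params
  missing_cols <- setdiff(c("sample_id", params), names(env))
  if (length(missing_cols))
    rfd_stop("validation_error", "environment table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  W <- weights_from_correlations(coefficients$r)
  x <- as.matrix(env[params])
  usable <- is.finite(x) & x > 0
  sub <- matrix(NA_real_, nrow(env), length(params),
                dimnames = list(NULL, paste0("tli_", params)))
  for (j in seq_along(params))
    sub[usable[, j], j] <- tli_parameter(params[j], x[usable[, j], j], coefficients)
  complete <- rowSums(usable) == length(params)
  tlic <- rep(NA_real_, nrow(env))
  tlic[complete] <- drop(sub[complete, , drop = FALSE] %*% W)
  if (na_action == "renormalize") {
    partial <- which(!complete & rowSums(usable) > 0)
    for (i in partial) {
      ok <- usable[i, ]
      tlic[i] <- sum(sub[i, ok] * W[ok] / sum(W[ok]))
    }
    dropped <- which(rowSums(usable) == 0)
  } else {
    dropped <- which(!complete)
  }
  if (length(dropped))
    rfd_warn("skipping %d sample(s) with missing/non-positive chemistry: %s",
             length(dropped), paste(head(env$sample_id[dropped], 5), collapse = ", "))
  scored <- !is.na(tlic)
  if (!any(scored)) rfd_stop("empty_result_error", "no scorable samples")
  cls <- rep(NA_character_, nrow(env))
  cls[scored] <- classify_trophic_state(tlic[scored])
  out <- data.frame(sample_id = env$sample_id, sub, tlic = tlic, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "weights") <- W
  attr(out, "m") <- length(params)
  attr(out, "coefficient_set") <- coefficients$set
  class(out) <- c("tli_result", "data.frame")
  out
}
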