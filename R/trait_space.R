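#' Pairwise trait distances between taxa
#'
#' For purely categorical traits with one modality per category, the Gower
#' distance is the mean per-category mismatch (0/1), giving each of the four
#' traits equal weight. The `braycurtis_indicator` variant computes
#' Bray-Curtis on the per-category one-hot indicator coding; for
#' single-modality categoricals the two coincide exactly.
#'
#' @param traits validated trait table (>= 2 taxa).
#' @param method `"gower"` or `"braycurtis_indicator"`.
#' @return symmetric distance matrix in \[0, 1\] with taxa as dimnames.
#' @export
trait_distance <- function(traits, method = c("gower", "braycurtis_indicator")) {
  method <- match.arg(method)
  if (nrow(traits) < 2L) rfd_stop("domain_error", "need at least 2 taxa")
  n <- nrow(traits)
  if (method == "gower") {
    d <- matrix(0, n, n)
    for (cat in TRAIT_CATEGORIES)
      d <- d + outer(traits[[cat]], traits[[cat]], "!=")
    d <- d / length(TRAIT_CATEGORIES)
  } else {
    onehot <- do.call(cbind, lapply(TRAIT_CATEGORIES, function(cat) {
      lv <- unique(traits[[cat]])
      outer(traits[[cat]], lv, "==") * 1
    }))
    d <- as.matrix(vegan::vegdist(onehot, method = "bray"))
  }
  dimnames(d) <- list(traits$taxon, traits$taxon)
  d
}

#' Principal coordinate analysis of a trait distance matrix
#'
#' Double-centered eigendecomposition of the squared distances. Categorical
#' distances are generally non-Euclidean; when negative eigenvalues occur and
#' `correction = "additive"`, the Cailliez additive constant is applied to
#' the off-diagonal distances and the decomposition recomputed, after which
#' all eigenvalues are nonnegative. Retains at most `k_max` axes with
#' positive eigenvalues.
#'
#' @param distances symmetric distance matrix (zero diagonal).
#' @param correction `"additive"` (default) or `"none"`.
#' @param k_max maximum number of retained axes (default 2, matching the
#'   convention of summarizing categorical trait data by the first two
#'   principal coordinates).
#' @return object of class `trait_space`: list with `coords` (taxa x k),
#'   `eigenvalues` (all, descending), `k`, `correction_applied`,
#'   `additive_constant`, `quality` (retained / total positive eigenvalue
#'   mass).
#' @export
trait_pcoa <- function(distances, correction = c("additive", "none"), k_max = 2L) {
  correction <- match.arg(correction)
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    rfd_stop("validation_error", "distance matrix must be square and symmetric")
  if (!is_count(k_max)) rfd_stop("configuration_error", "k_max must be a positive integer")
  n <- nrow(d)
  tol <- 1e-9 * max(d, 1)
  decompose <- function(dm) {
    fit <- suppressWarnings(
      cmdscale(as.dist(dm), k = max(1L, n - 1L), eig = TRUE, add = FALSE))
    fit
  }
  fit <- decompose(d)
  eig <- sort(fit$eig, decreasing = TRUE)
  applied <- FALSE
  ac <- 0
  if (correction == "additive" && min(fit$eig) < -tol) {
    cfit <- suppressWarnings(
      cmdscale(as.dist(d), k = max(1L, n - 1L), eig = TRUE, add = TRUE))
    applied <- TRUE
    ac <- cfit$ac
    fit <- cfit
    eig <- sort(fit$eig, decreasing = TRUE)
  }
  pos <- sum(eig > tol)
  if (pos == 0L) rfd_stop("degenerate_space_error", "no positive eigenvalues: degenerate trait space")
  k <- min(k_max, pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("axis", seq_len(k))
  structure(list(coords = coords, eigenvalues = eig, k = k,
                 correction_applied = applied, additive_constant = ac,
                 quality = sum(eig[seq_len(k)]) / sum(eig[eig > 0])),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("Trait space: %d taxa on %d axis/axes (%.1f%% of positive eigenvalue mass)\n",
              nrow(x$coords), x$k, 100 * x$quality))
  if (x$correction_applied)
    cat(sprintf("Additive (Cailliez) correction applied, constant %.4g\n",
                x$additive_constant))
  invisible(x)
}
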