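#' Bray-Curtis dissimilarity between samples
#'
#' Standard abundance-based Bray-Curtis on a community matrix. Samples with
#' zero total abundance cannot be scored and are excluded with a warning.
#'
#' @param community community data.frame, or a numeric sample-by-taxon
#'   matrix.
#' @return symmetric dissimilarity matrix in \[0, 1\].
#' @export
braycurtis_matrix <- function(community) {
  m <- if (is.data.frame(community)) abundance_matrix(community) else as.matrix(community)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    rfd_warn("excluding %d zero-total sample(s): %s", sum(zero),
             paste(head(rownames(m)[zero], 5), collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) < 2L) rfd_stop("domain_error", "need >= 2 samples with positive totals")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Partition beta diversity into replacement and richness difference
#'
#' Podani-family decomposition of pairwise dissimilarity. On
#' presence-absence data (Jaccard base), with a shared species, b and c
#' unique to each sample: D = (b+c)/(a+b+c), replacement
#' Repl = 2 min(b,c)/(a+b+c), richness difference RichDiff = |b-c|/(a+b+c).
#' The quantitative variant (Ruzicka base) substitutes the abundance
#' components A = sum of parallel minima and B, C the surpluses of each
#' sample. In both, D = Repl + RichDiff exactly and the similarity
#' Sim = 1 - D completes each pair's triad to 1.
#'
#' @param community community data.frame or sample-by-taxon matrix.
#' @param quantitative FALSE (default, presence-absence / Jaccard) or TRUE
#'   (abundance / Ruzicka).
#' @return object of class `beta_decomposition`: pairwise matrices `D`,
#'   `repl`, `rich`, `sim`, the `family` label, lower-triangle `means`, and
#'   `contributions` (percent of mean D from each component).
#' @export
decompose_beta <- function(community, quantitative = FALSE) {
  m <- if (is.data.frame(community)) abundance_matrix(community) else as.matrix(community)
  if (nrow(m) < 2L) rfd_stop("domain_error", "need >= 2 samples")
  if (ncol(m) == 0L) rfd_stop("domain_error", "empty community: no taxa")
  n <- nrow(m)
  if (quantitative) {
    tot <- rowSums(m)
    manh <- as.matrix(dist(m, method = "manhattan"))
    A <- (outer(tot, tot, "+") - manh) / 2
    B <- tot - A           # row sample surplus: B[i, j] = tot_i - A_ij
    C <- t(B)
  } else {
    p <- (m > 0) * 1
    A <- p %*% t(p)
    s <- rowSums(p)
    B <- s - A
    C <- t(B)
  }
  denom <- A + B + C
  safe <- ifelse(denom > 0, denom, 1)   # identical empty pairs: D = 0
  D <- (B + C) / safe
  repl <- 2 * pmin(B, C) / safe
  rich <- abs(B - C) / safe
  diag(D) <- diag(repl) <- diag(rich) <- 0
  sim <- 1 - D
  dimnames(D) <- dimnames(repl) <- dimnames(rich) <- dimnames(sim) <-
    list(rownames(m), rownames(m))
  lt <- lower.tri(D)
  means <- c(D = mean(D[lt]), repl = mean(repl[lt]), rich = mean(rich[lt]),
             sim = mean(sim[lt]))
  structure(list(D = D, repl = repl, rich = rich, sim = sim,
                 family = if (quantitative) "podani-ruzicka" else "podani-jaccard",
                 means = means,
                 contributions = tryCatch(
                   percent_contributions(mean_repl = means[["repl"]],
                                         mean_rich = means[["rich"]]),
                   error = function(e) c(repl_pct = NA_real_, rich_pct = NA_real_))),
            class = "beta_decomposition")
}

#' Percent contributions of the beta components
#'
#' Shares (in percent) of mean total dissimilarity attributable to
#' replacement and to richness difference; the two sum to 100. Accepts a
#' decomposition, or the two mean components directly.
#'
#' @param decomposition a `beta_decomposition`, or NULL when passing means.
#' @param mean_repl,mean_rich mean replacement and richness-difference
#'   components (used when `decomposition` is NULL).
#' @return named numeric: `repl_pct`, `rich_pct`.
#' @export
#' @examples
#' percent_contributions(mean_repl = 0.332, mean_rich = 0.398)
percent_contributions <- function(decomposition = NULL, mean_repl = NULL,
                                  mean_rich = NULL) {
  if (!is.null(decomposition)) {
    mean_repl <- decomposition$means[["repl"]]
    mean_rich <- decomposition$means[["rich"]]
  }
  tot <- mean_repl + mean_rich
  if (!is.finite(tot) || tot <= 0)
    rfd_stop("undefined_contribution_error",
             "mean dissimilarity is zero: contributions undefined")
  c(repl_pct = 100 * mean_repl / tot, rich_pct = 100 * mean_rich / tot)
}

#' Triad coordinates for triangular plots
#'
#' One row per sample pair with the triple (similarity = 1 - D, replacement,
#' richness difference); each triple sums to 1. The mean triple over all
#' pairs is attached as an attribute (the large point of the triangular
#' plot).
#'
#' @param decomposition a `beta_decomposition`.
#' @return data.frame `i`, `j`, `sim`, `repl`, `rich` with attribute
#'   `mean_triad`.
#' @export
triad_table <- function(decomposition) {
  if (!inherits(decomposition, "beta_decomposition"))
    rfd_stop("validation_error", "expected a beta_decomposition")
  idx <- which(lower.tri(decomposition$D), arr.ind = TRUE)
  nm <- rownames(decomposition$D)
  out <- data.frame(i = nm[idx[, 2]], j = nm[idx[, 1]],
                    sim = decomposition$sim[idx],
                    repl = decomposition$repl[idx],
                    rich = decomposition$rich[idx],
                    stringsAsFactors = FALSE)
  attr(out, "mean_triad") <- c(sim = mean(out$sim), repl = mean(out$repl),
                               rich = mean(out$rich))
  out
}

#' UPGMA clustering of a dissimilarity matrix
#'
#' Average-linkage agglomeration with nondecreasing merge heights,
#' serialized to Newick for exchange with tree tools.
#'
#' @param distances symmetric dissimilarity matrix.
#' @param linkage only `"upgma"` (average linkage) is supported.
#' @return list with the `hclust` object and the `newick` string.
#' @export
cluster_samples <- function(distances, linkage = "upgma") {
  linkage <- match.arg(linkage, "upgma")
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    rfd_stop("validation_error", "distance matrix must be square and symmetric")
  if (nrow(d) < 2L) rfd_stop("domain_error", "need >= 2 samples")
  hc <- hclust(as.dist(d), method = "average")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}

#' @export
print.beta_decomposition <- function(x, ...) {
  cat(sprintf("Beta decomposition (%s), %d samples\n", x$family, nrow(x$D)))
  cat(sprintf("  mean D = %.4f = Repl %.4f + RichDiff %.4f\n",
              x$means[["D"]], x$means[["repl"]], x$means[["rich"]]))
  if (is.finite(x$contributions[["repl_pct"]]))
    cat(sprintf("  contributions: replacement %.2f%%, richness difference %.2f%%\n",
                x$contributions[["repl_pct"]], x$contributions[["rich_pct"]]))
  invisible(x)
}
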