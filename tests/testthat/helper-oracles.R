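# Independent oracle implementations used to cross-check the package's
# functional-diversity and clustering code. Deliberately different
# algorithms: gift-wrapping hull (package uses grDevices::chull), Prim MST
# (package uses Kruskal), naive stepwise UPGMA (package uses stats::hclust),
# normal-equations regression (package uses lm).

# gift-wrapping (Jarvis march) convex hull, returns vertex indices in order
oracle_hull <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3L) return(NULL)
  cur <- p0 <- order(xy[, 1], xy[, 2])[1]
  hull <- p0
  repeat {
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (k in cand[-1]) {
      cr <- (xy[nxt, 1] - xy[cur, 1]) * (xy[k, 2] - xy[cur, 2]) -
            (xy[nxt, 2] - xy[cur, 2]) * (xy[k, 1] - xy[cur, 1])
      further <- sum((xy[k, ] - xy[cur, ])^2) > sum((xy[nxt, ] - xy[cur, ])^2)
      if (cr < 0 || (cr == 0 && further)) nxt <- k
    }
    if (nxt == p0) break
    hull <- c(hull, nxt)
    cur <- nxt
  }
  xy[hull, , drop = FALSE]
}

# triangle-fan area around the first hull vertex
oracle_hull_area <- function(xy) {
  v <- oracle_hull(xy)
  if (is.null(v)) return(0)
  a <- 0
  for (i in 2:(nrow(v) - 1)) {
    a <- a + ((v[i, 1] - v[1, 1]) * (v[i + 1, 2] - v[1, 2]) -
              (v[i, 2] - v[1, 2]) * (v[i + 1, 1] - v[1, 1])) / 2
  }
  abs(a)
}

# Prim minimum spanning tree; returns edge list (i, j, length)
oracle_mst <- function(d) {
  n <- nrow(d)
  intree <- 1L
  edges <- NULL
  while (length(intree) < n) {
    best <- c(NA, NA, Inf)
    for (i in intree) for (j in setdiff(seq_len(n), intree)) {
      if (d[i, j] < best[3]) best <- c(i, j, d[i, j])
    }
    edges <- rbind(edges, best)
    intree <- c(intree, best[2])
  }
  list(i = edges[, 1], j = edges[, 2], length = edges[, 3])
}

oracle_feve <- function(xy, ab) {
  keep <- ab > 0
  xy <- xy[keep, , drop = FALSE]; ab <- ab[keep]
  S <- length(ab)
  w <- ab / sum(ab)
  tr <- oracle_mst(as.matrix(dist(xy)))
  EW <- tr$length / (w[tr$i] + w[tr$j])
  PEW <- EW / sum(EW)
  thr <- 1 / (S - 1)
  (sum(pmin(PEW, thr)) - thr) / (1 - thr)
}

oracle_fdiv <- function(xy, ab) {
  keep <- ab > 0
  xy <- xy[keep, , drop = FALSE]; ab <- ab[keep]
  verts <- oracle_hull(xy)
  centroid <- colMeans(verts)
  di <- sqrt(rowSums(sweep(xy, 2, centroid)^2))
  dbar <- mean(di)
  w <- ab / sum(ab)
  (sum(w * (di - dbar)) + dbar) / (sum(w * abs(di - dbar)) + dbar)
}

# naive stepwise average-linkage agglomeration; returns sorted merge heights
oracle_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA, Inf)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a < b) {
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < best[3]) best <- c(a, b, h)
      }
    }
    heights <- c(heights, best[3])
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

oracle_lm_coefs <- function(x, y) {
  X <- cbind(1, x)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# random 2-axis community: coordinates + positive abundances for S species
random_planar_community <- function(S) {
  xy <- matrix(runif(2 * S), S, 2,
               dimnames = list(sprintf("t%02d", seq_len(S)), c("axis1", "axis2")))
  ab <- setNames(rexp(S) + 0.05, rownames(xy))
  list(xy = xy, ab = ab)
}

# wrap bare coordinates as a trait_space for the index functions
as_space <- function(xy) {
  structure(list(coords = xy, eigenvalues = rep(1, ncol(xy)), k = ncol(xy),
                 correction_applied = FALSE, additive_constant = 0, quality = 1),
            class = "trait_space")
}

# random small abundance community matrix (samples x taxa) with zeros
random_community_matrix <- function(n_samples, n_taxa, p_zero = 0.35) {
  m <- matrix(rexp(n_samples * n_taxa, rate = 0.1), n_samples, n_taxa)
  m[matrix(runif(length(m)) < p_zero, nrow(m))] <- 0
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("t%02d", seq_len(n_taxa)))
  m
}
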