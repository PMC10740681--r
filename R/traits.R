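# Functional-group composition and dominance screening.
#
# The community matrix convention throughout the package: a data.frame with
# metadata columns `sample_id`, `site`, `month` followed by one numeric
# column per taxon (abundances in individuals per litre).

community_meta_cols <- c("sample_id", "site", "month")

taxon_columns <- function(community) {
  setdiff(names(community), community_meta_cols)
}

abundance_matrix <- function(community) {
  taxa <- taxon_columns(community)
  m <- as.matrix(community[taxa])
  if (!is.numeric(m)) rfd_stop("validation_error", "non-numeric abundance columns")
  if (any(m < 0, na.rm = TRUE)) rfd_stop("validation_error", "negative abundances")
  rownames(m) <- community$sample_id
  m
}

#' Aggregate community composition by trait modality
#'
#' Sums taxon abundances within each modality of one trait category and
#' expresses them both absolutely (ind/L) and relative to the sample total.
#' All-zero samples are kept with `fraction = NA` and flagged.
#'
#' @param community community data.frame (`sample_id`, `site`, `month`, one
#'   column per taxon).
#' @param traits validated trait table covering every community taxon.
#' @param category one of `"trophi"`, `"size"`, `"feeding"`, `"swimming"`.
#' @return long data.frame: `sample_id`, `category`, `modality`, `abundance`,
#'   `fraction`, `total`, `degenerate`.
#' @export
composition_by_modality <- function(community, traits, category) {
  category <- match.arg(category, TRAIT_CATEGORIES)
  m <- abundance_matrix(community)
  missing <- setdiff(colnames(m), traits$taxon)
  if (length(missing))
    rfd_stop("validation_error", "taxa absent from trait table: %s",
             paste(head(missing, 5), collapse = ", "))
  modality <- traits[[category]][match(colnames(m), traits$taxon)]
  levels <- unique(traits[[category]])
  agg <- vapply(levels, function(md) rowSums(m[, modality == md, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(m), levels))
  total <- rowSums(m)
  out <- data.frame(
    sample_id = rep(rownames(m), times = length(levels)),
    category = category,
    modality = rep(levels, each = nrow(m)),
    abundance = as.vector(agg),
    total = rep(total, times = length(levels)),
    stringsAsFactors = FALSE)
  out$fraction <- ifelse(out$total > 0, out$abundance / out$total, NA_real_)
  out$degenerate <- out$total == 0
  out
}

#' Modality-by-sample composition matrix
#'
#' Convenience pivot of [composition_by_modality()] to a sample-by-modality
#' abundance matrix, the input for functional-level beta diversity.
#'
#' @inheritParams composition_by_modality
#' @return numeric matrix, samples in rows, modalities in columns.
#' @export
composition_matrix <- function(community, traits, category) {
  long <- composition_by_modality(community, traits, category)
  levels <- unique(long$modality)
  samples <- unique(long$sample_id)
  m <- matrix(long$abundance, nrow = length(samples), ncol = length(levels),
              dimnames = list(samples, levels))
  m
}

#' Dominance screen (occurrence-weighted relative abundance)
#'
#' For each unit (taxon, or trait modality within a category) and each group
#' of samples (by default the calendar month), computes the McNaughton-style
#' dominance index Y = (n_i / N) * f_i, where n_i/N is the unit's share of
#' the group's total abundance and f_i the fraction of the group's samples in
#' which it occurs. A unit is flagged dominant when Y meets the threshold;
#' the separate `high_abundance` flag marks a group relative abundance above
#' 20%, reported alongside rather than folded into Y.
#'
#' @param community community data.frame.
#' @param traits trait table (required when `unit = "modality"`).
#' @param unit `"taxon"` or `"modality"`.
#' @param category trait category used when `unit = "modality"`.
#' @param grouping name of the metadata column partitioning samples
#'   (default `"month"`).
#' @param threshold dominance cutoff on Y (default 0.02).
#' @param abundance_cutoff relative-abundance cutoff for the
#'   `high_abundance` flag (default 0.2).
#' @return data.frame: group, unit, Y, relative abundance, occurrence
#'   frequency, `dominant`, `high_abundance`.
#' @export
dominance_screen <- function(community, traits = NULL,
                             unit = c("taxon", "modality"),
                             category = "trophi", grouping = "month",
                             threshold = 0.02, abundance_cutoff = 0.2) {
  unit <- match.arg(unit)
  if (!grouping %in% names(community))
    rfd_stop("validation_error", "grouping column '%s' not in community", grouping)
  m <- if (unit == "taxon") abundance_matrix(community)
       else composition_matrix(community, traits, category)
  groups <- community[[grouping]]
  res <- lapply(unique(groups), function(g) {
    rows <- which(groups == g)
    if (length(rows) == 0L) {
      rfd_warn("empty group '%s' skipped", g)
      return(NULL)
    }
    sub <- m[rows, , drop = FALSE]
    N <- sum(sub)
    if (N == 0) {
      rfd_warn("group '%s' has zero total abundance; skipped", g)
      return(NULL)
    }
    rel <- colSums(sub) / N
    freq <- colMeans(sub > 0)
    Y <- rel * freq
    data.frame(group = g, unit = colnames(m), Y = Y, rel_abundance = rel,
               frequency = freq, dominant = Y >= threshold,
               high_abundance = rel > abundance_cutoff,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(group = character(), unit = character(),
                                      Y = numeric(), rel_abundance = numeric(),
                                      frequency = numeric(), dominant = logical(),
                                      high_abundance = logical())
  out
}
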