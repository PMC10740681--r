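#' Default rotifer trait vocabulary
#'
#' The four categorical trait categories used to assign rotifer taxa to
#' functional groups, with their fixed modality sets: trophi (jaw apparatus,
#' 7 modalities), body size class (3), feeding habit (4) and swimming mode
#' (3). Two trophi types that do not occur in running-water rotifer surveys
#' are excluded by convention.
#'
#' @return Named list mapping each trait category to its character vector of
#'   canonical modality labels.
#' @export
#' @examples
#' lengths(default_trait_vocabulary())  # 7 3 4 3
default_trait_vocabulary <- function() {
  list(
    trophi = c("malleate", "asymmetrical_virgate", "virgate", "incudate",
               "ramate", "malleoramate", "forcipate"),
    size = c("<150um", "150-300um", ">300um"),
    feeding = c("filter_feeding", "predacious", "sucking", "carnivorous"),
    swimming = c("planktonic", "benthic", "facultative_planktonic")
  )
}

TRAIT_CATEGORIES <- c("trophi", "size", "feeding", "swimming")

# label canonicalization: lower-case, trim, unify separators, then a small
# synonym map for spellings seen in the literature.
canonicalize_label <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[ –-]+", "_", y)          # spaces, hyphens, en-dash
  y <- gsub("μ", "u", y)               # micro sign
  y <- sub("^<150_?um$|^<150um$", "<150um", y)
  y <- sub("^>300_?um$|^>300um$", ">300um", y)
  y <- sub("^150_300_?um$|^150_300um$", "150-300um", y)
  syn <- c(filter_feeding = "filter_feeding", "filter_feeder" = "filter_feeding",
           facultative_plankton = "facultative_planktonic",
           facultative_planktonic = "facultative_planktonic",
           malleate_trophi = "malleate", virgate_trophi = "virgate",
           ramate_trophi = "ramate", incudate_trophi = "incudate",
           forcipate_trophi = "forcipate", malleoramate_trophi = "malleoramate",
           asymmetrical_virgate_trophi = "asymmetrical_virgate")
  hit <- y %in% names(syn)
  y[hit] <- syn[y[hit]]
  y
}

#' Validate and canonicalize a taxon-by-trait table
#'
#' Checks that every taxon carries exactly one modality per trait category,
#' that every modality is drawn from the vocabulary (after canonicalizing
#' label spellings), and that taxa are unique.
#'
#' @param table data.frame with columns `taxon`, `trophi`, `size`, `feeding`,
#'   `swimming`.
#' @param vocabulary trait vocabulary as from [default_trait_vocabulary()].
#' @return The table with canonical modality labels, invisibly classed
#'   `trait_table`.
#' @export
validate_trait_table <- function(table, vocabulary = default_trait_vocabulary()) {
  if (!is.data.frame(table)) rfd_stop("validation_error", "trait table must be a data.frame")
  if (nrow(table) == 0L) {
    rfd_warn("empty trait table: nothing to validate")
    out <- table
    class(out) <- c("trait_table", "data.frame")
    return(out)
  }
  missing_cols <- setdiff(c("taxon", TRAIT_CATEGORIES), names(table))
  if (length(missing_cols))
    rfd_stop("validation_error", "trait table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (anyDuplicated(table$taxon))
    rfd_stop("validation_error", "duplicate taxa: %s",
             paste(unique(table$taxon[duplicated(table$taxon)]), collapse = ", "))
  bad <- character(0)
  for (cat in TRAIT_CATEGORIES) {
    lab <- canonicalize_label(table[[cat]])
    unknown <- !(lab %in% vocabulary[[cat]])
    if (any(unknown))
      bad <- c(bad, sprintf("%s: unknown %s '%s'",
                            table$taxon[unknown], cat, table[[cat]][unknown]))
    table[[cat]] <- lab
  }
  if (length(bad))
    rfd_stop("validation_error", "invalid trait modalities:\n  %s",
             paste(bad, collapse = "\n  "))
  rownames(table) <- NULL
  class(table) <- c("trait_table", "data.frame")
  table
}

#' Assign a body length to its size class
#'
#' Boundary values (exactly 150 or 300 um) fall in the middle class.
#'
#' @param length_um numeric body lengths in micrometres.
#' @return character vector of size modalities.
#' @export
size_class_from_length <- function(length_um) {
  stopifnot(is.numeric(length_um), all(length_um > 0))
  ifelse(length_um < 150, "<150um", ifelse(length_um <= 300, "150-300um", ">300um"))
}
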