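# Canonical CSV readers. Schemas:
#   abundance:   sample_id, site, month, then one column per taxon (ind/L)
#   traits:      taxon, trophi, size, feeding, swimming
#   environment: sample_id, site, month, chla, tp, tn, sd, cod [, temp, dep, do, ph]
# All UTF-8, comma-delimited, header row, "." decimal.

#' Read a community abundance CSV
#' @param path file path.
#' @return community data.frame.
#' @export
read_community_csv <- function(path) {
  x <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(community_meta_cols, names(x))
  if (length(miss))
    rfd_stop("validation_error", "community CSV missing column(s): %s",
             paste(miss, collapse = ", "))
  abundance_matrix(x)   # validates numeric, nonnegative
  x
}

#' Read a taxon-by-trait CSV
#' @param path file path.
#' @param vocabulary trait vocabulary used for validation.
#' @return validated `trait_table`.
#' @export
read_trait_csv <- function(path, vocabulary = default_trait_vocabulary()) {
  validate_trait_table(read.csv(path, stringsAsFactors = FALSE), vocabulary)
}

#' Read an environment CSV
#' @param path file path.
#' @return environment data.frame.
#' @export
read_env_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "chla", "tp", "tn", "sd", "cod"), names(x))
  if (length(miss))
    rfd_stop("validation_error", "environment CSV missing column(s): %s",
             paste(miss, collapse = ", "))
  x
}
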