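#' Read an expression table
#'
#' TSV with a leading `unigene_id` column and one column per sample
#' (TPM or raw counts).
#'
#' @param path TSV path.
#' @return numeric matrix, unigenes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_tpm_matrix(df)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `station`, `depth_layer`,
#'   `fraction`, `replicate`, `rna_yield_per_liter` and optionally
#'   `volume_filtered_liters`.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "station", "depth_layer", "fraction",
                "replicate", "rna_yield_per_liter")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (any(meta$rna_yield_per_liter <= 0)) {
    stop("rna_yield_per_liter must be positive")
  }
  if (!all(meta$fraction %in% c("small", "large"))) {
    stop("fraction must be 'small' or 'large'")
  }
  dup <- duplicated(meta[, c("station", "depth_layer", "replicate",
                             "fraction")])
  if (any(dup)) {
    stop("a water sample has more than one record for the same fraction")
  }
  meta
}

#' Read an environmental-factor table
#'
#' @param path TSV keyed by `water_sample_id` with numeric environmental
#'   variables (nutrients, depth, temperature, salinity, N:P ratio).
#' @return data.frame.
#' @export
read_env_table <- function(path) {
  env <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"water_sample_id" %in% names(env)) {
    stop("environmental table must have a water_sample_id column")
  }
  env
}
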