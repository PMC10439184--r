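#' Family and proton-pump status from the best hit
#'
#' A unigene inherits the rhodopsin family of its best-hit reference and
#' that reference's proton-pump status. Proteorhodopsins (PR) and the
#' xanthorhodopsin-like clade (XR, GR) as well as bacteriorhodopsin-like
#' proteins (BR) are light-driven outward proton pumps; sensory
#' rhodopsin-I (SRI) and other rhodopsin types are not.
#'
#' @param ref_id best-hit reference id.
#' @param panel a [ppr_panel].
#' @return list with elements `family` and `is_ppr`.
#' @export
classify_family <- function(ref_id, panel) {
  entry <- panel_entry(panel, ref_id)
  list(family = entry$family, is_ppr = entry$is_ppr)
}

#' Map a query onto the canonical tuning site
#'
#' Globally aligns the query against the panel's canonical PR
#' (Needleman--Wunsch, BLOSUM62, gap open 10 / extend 1) and returns the
#' query symbol in the alignment column holding the canonical residue at
#' the tuning site (position 105 in conventional PR numbering): a residue
#' letter, `"-"` if the query is gapped in that column, or `NA` if the
#' alignment does not reach it. Global alignment is used deliberately --
#' a local alignment could truncate before the tuning site.
#'
#' @param query_aa a single amino-acid string.
#' @param panel a [ppr_panel].
#' @return single character (residue or `"-"`) or `NA_character_`.
#' @export
map_tuning_site <- function(query_aa, panel) {
  stopifnot(inherits(panel, "ppr_panel"))
  if (length(query_aa) != 1 || is.na(query_aa) || nchar(query_aa) == 0) {
    stop("query_aa must be a single non-empty amino-acid string")
  }
  canon <- panel$seqs[[panel$canonical_pr_id]]
  site <- panel$entries$tuning_site[
    panel$entries$ref_id == panel$canonical_pr_id]
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(query_aa)), Biostrings::AAString(canon),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 1)
  qal <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sal <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ref_pos <- cumsum(sal != "-")
  col <- match(site, ref_pos)
  if (is.na(col) || sal[col] == "-") return(NA_character_)
  qal[col]
}

#' Blue/green spectral classification from the tuning residue
#'
#' Applies the position-105 residue rule for proteorhodopsin spectral
#' tuning: glutamine (Q) marks a blue-absorbing PR (BPR, lambda_max =
#' 490 nm); methionine or leucine (M/L) a green-absorbing PR (GPR,
#' lambda_max = 525 nm). Any other residue, a gap, a missing mapping, a
#' non-PR family, or a non-proton-pump call is left unclassified.
#' Comparison is case-insensitive; `X` is treated as unknown.
#'
#' @param tuning_residue residue letter, `"-"`, or `NA` from
#'   [map_tuning_site].
#' @param family rhodopsin family of the call.
#' @param is_ppr logical proton-pump status.
#' @param families_with_rule families the residue rule is applied to;
#'   default `"PR"` only (the blue/green dichotomy is defined for
#'   proteorhodopsins).
#' @return list with `spectral_class` (`"BPR"`, `"GPR"` or
#'   `"unclassified"`) and `lambda_max_nm` (490, 525 or `NA`).
#' @export
classify_spectral <- function(tuning_residue, family, is_ppr,
                              families_with_rule = "PR") {
  unclassified <- list(spectral_class = "unclassified",
                       lambda_max_nm = NA_real_)
  if (!isTRUE(is_ppr) || !family %in% families_with_rule) return(unclassified)
  if (is.null(tuning_residue) || is.na(tuning_residue)) return(unclassified)
  res <- toupper(tuning_residue)
  if (res == "Q") return(list(spectral_class = "BPR", lambda_max_nm = 490))
  if (res %in% c("M", "L")) {
    return(list(spectral_class = "GPR", lambda_max_nm = 525))
  }
  unclassified
}

#' Default spectral-annotation override table
#'
#' Homology-based spectral annotation mislabels the dinoflagellate
#' proteorhodopsins of *Karlodinium micrum* and *Ceratium fusus* as green
#' absorbers; spectroscopic evidence shows they are blue absorbers. The
#' default table forces those two taxa to BPR and is user-extensible
#' ([read_overrides]).
#'
#' @return data.frame with columns `pattern`, `spectral_class`, `note`.
#' @export
default_overrides <- function() {
  path <- system.file("extdata", "spectral_overrides_default.tsv",
                      package = "pprscope", mustWork = TRUE)
  read_overrides(path)
}

#' Read a spectral override table
#'
#' @param path TSV with columns `pattern` (regular expression matched
#'   case-insensitively against `source_taxon` and `unigene_id`),
#'   `spectral_class` (`BPR` or `GPR`) and `note`.
#' @return data.frame of overrides.
#' @export
read_overrides <- function(path) {
  ov <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pattern", "spectral_class") %in% names(ov)))
  if (!all(ov$spectral_class %in% c("BPR", "GPR"))) {
    stop("override spectral_class must be BPR or GPR")
  }
  if (!"note" %in% names(ov)) ov$note <- ""
  ov
}

#' Apply literature-correction overrides to spectral calls
#'
#' For each call whose `source_taxon` or `unigene_id` matches an override
#' pattern, `spectral_class` and `lambda_max_nm` are replaced and
#' `override_applied` set. Patterns that match nothing raise a warning,
#' not an error. The operation is idempotent.
#'
#' @param calls calls data.frame (see [classify_rhodopsins]).
#' @param overrides override data.frame (see [read_overrides]); `NULL` or
#'   zero rows leaves `calls` unchanged.
#' @return the corrected calls data.frame.
#' @export
apply_overrides <- function(calls, overrides = default_overrides()) {
  if (!"override_applied" %in% names(calls)) {
    calls$override_applied <- FALSE
  }
  if (is.null(overrides) || nrow(overrides) == 0) return(calls)
  lambda_of <- c(BPR = 490, GPR = 525)
  taxon <- if ("source_taxon" %in% names(calls)) calls$source_taxon else NA
  for (i in seq_len(nrow(overrides))) {
    pat <- overrides$pattern[i]
    m <- grepl(pat, taxon, ignore.case = TRUE)
    m[is.na(m)] <- FALSE
    m <- m | grepl(pat, calls$unigene_id, ignore.case = TRUE)
    if (!any(m)) {
      warning("override pattern '", pat, "' matched no call")
      next
    }
    calls$spectral_class[m] <- overrides$spectral_class[i]
    calls$lambda_max_nm[m] <- lambda_of[[overrides$spectral_class[i]]]
    calls$override_applied[m] <- TRUE
  }
  calls
}

#' Classify rhodopsin unigenes
#'
#' Takes an identification catalog (see [identify_rhodopsins]) plus the
#' query sequences and produces per-unigene spectral calls: family and
#' proton-pump status from the best hit, the tuning residue mapped onto
#' the canonical PR coordinate system, the blue/green class with its
#' lambda_max, and any literature overrides.
#'
#' @param catalog identification catalog data.frame.
#' @param queries named character vector (or `AAStringSet`) holding at
#'   least the catalogued unigene sequences.
#' @param panel a [ppr_panel].
#' @param overrides override table, or `NULL` to skip correction.
#' @param include_xr also apply the residue rule to XR/GR calls (off by
#'   default; the dichotomy is defined for PRs).
#' @return data.frame: `unigene_id`, `family`, `is_ppr`, `domain_call`,
#'   `tuning_residue`, `spectral_class`, `lambda_max_nm`,
#'   `override_applied`, `source_taxon`.
#' @export
classify_rhodopsins <- function(catalog, queries, panel,
                                overrides = default_overrides(),
                                include_xr = FALSE) {
  if (inherits(queries, "AAStringSet")) queries <- as.character(queries)
  fams <- if (include_xr) c("PR", "XR", "GR") else "PR"
  n <- nrow(catalog)
  calls <- data.frame(
    unigene_id = catalog$unigene_id,
    family = catalog$family,
    is_ppr = vapply(catalog$ref_id, function(r) {
      panel_entry(panel, r)$is_ppr
    }, logical(1), USE.NAMES = FALSE),
    domain_call = catalog$domain_call,
    tuning_residue = NA_character_,
    spectral_class = "unclassified",
    lambda_max_nm = NA_real_,
    override_applied = FALSE,
    source_taxon = catalog$source_taxon,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (calls$is_ppr[i] && calls$family[i] %in% fams) {
      q <- queries[[calls$unigene_id[i]]]
      calls$tuning_residue[i] <- map_tuning_site(q, panel)
      sp <- classify_spectral(calls$tuning_residue[i], calls$family[i],
                              calls$is_ppr[i], families_with_rule = fams)
      calls$spectral_class[i] <- sp$spectral_class
      calls$lambda_max_nm[i] <- sp$lambda_max_nm
    }
  }
  if (!is.null(overrides)) calls <- apply_overrides(calls, overrides)
  calls
}
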