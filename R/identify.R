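#' Six-frame ORF translation
#'
#' Translates a nucleotide sequence in all six reading frames with the
#' standard genetic code and returns open reading frames (stop-to-stop
#' segments; frames are split at internal stops) of at least `min_aa_len`
#' residues, longest first. A segment only counts as an ORF when it is
#' terminated by a stop codon; a trailing frame segment that runs off the
#' end of the sequence is not returned. Ambiguous codons translate to `X`.
#'
#' @param nt_seq a single nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param min_aa_len minimum ORF length in amino acids.
#' @return character vector of candidate protein sequences (possibly empty).
#' @export
translate_orfs <- function(nt_seq, min_aa_len = 100) {
  nt_seq <- toupper(nt_seq)
  if (nchar(nt_seq) < 3) return(character(0))
  if (grepl("[^ACGTN]", nt_seq)) {
    stop("nt_seq must be over the alphabet {A,C,G,T,N}")
  }
  fwd <- Biostrings::DNAString(nt_seq)
  rev <- Biostrings::reverseComplement(fwd)
  orfs <- character(0)
  for (strand in list(fwd, rev)) {
    len <- length(strand)
    for (off in 0:2) {
      n_cod <- (len - off) %/% 3
      if (n_cod < 1) next
      frame <- Biostrings::subseq(strand, off + 1, off + 3 * n_cod)
      aa <- as.character(Biostrings::translate(frame, if.fuzzy.codon = "solve"))
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
      if (!endsWith(aa, "*") && length(pieces) > 0) {
        pieces <- pieces[-length(pieces)]
      }
      orfs <- c(orfs, pieces)
    }
  }
  orfs <- orfs[nchar(orfs) >= min_aa_len]
  orfs[order(nchar(orfs), decreasing = TRUE)]
}

# Karlin-Altschul parameters for gapped BLOSUM62 searches (gap open 11,
# extend 1), the conventional protein-search defaults. The effective search
# space is query length x total panel length.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Homology search of unigene proteins against the reference panel
#'
#' Aligns every query locally (Smith--Waterman, BLOSUM62, gap open 11 /
#' extend 1) against every panel entry and keeps hits passing the
#' annotation cutoffs: E-value below `evalue_max` and percent identity
#' above `identity_min_pct`. E-values are computed from the raw score with
#' fixed Karlin--Altschul constants (lambda = 0.267, K = 0.041) over a
#' search space of query length times total panel length, so results are
#' reproducible without an external search tool.
#'
#' @param queries named character vector (or `AAStringSet`) of query protein
#'   sequences; names are unigene ids.
#' @param panel a [ppr_panel].
#' @param evalue_max E-value cutoff (hits must be strictly below).
#' @param identity_min_pct identity cutoff in percent (strictly above);
#'   identity is computed over all aligned columns including gaps.
#' @return data.frame with columns `query_id`, `ref_id`, `score`,
#'   `bitscore`, `evalue`, `identity_pct`, `query_start`, `query_end`,
#'   `ref_start`, `ref_end`. Zero rows if nothing passes.
#' @export
search_panel <- function(queries, panel, evalue_max = 1e-5,
                         identity_min_pct = 40) {
  stopifnot(inherits(panel, "ppr_panel"))
  if (inherits(queries, "AAStringSet")) queries <- as.character(queries)
  if (length(queries) == 0) {
    return(empty_hits())
  }
  if (is.null(names(queries)) || anyNA(names(queries)) ||
      any(names(queries) == "")) {
    stop("queries must be named by unigene id")
  }
  if (any(nchar(queries) == 0)) stop("empty query sequence")

  qset <- Biostrings::AAStringSet(toupper(queries))
  panel_total_len <- sum(nchar(panel$seqs))
  out <- vector("list", length(panel$seqs))

  for (k in seq_along(panel$seqs)) {
    ref_id <- names(panel$seqs)[k]
    subj <- Biostrings::AAString(panel$seqs[[k]])
    al <- Biostrings::pairwiseAlignment(
      qset, subj, type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    raw <- Biostrings::score(al)
    bit <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
    ev <- nchar(queries) * panel_total_len * 2^(-bit)
    idpct <- Biostrings::pid(al, type = "PID1")
    keep <- ev < evalue_max & idpct > identity_min_pct
    if (!any(keep)) next
    pat <- Biostrings::pattern(al)
    sbj <- Biostrings::subject(al)
    out[[k]] <- data.frame(
      query_id = names(queries)[keep],
      ref_id = ref_id,
      score = raw[keep],
      bitscore = bit[keep],
      evalue = ev[keep],
      identity_pct = idpct[keep],
      query_start = Biostrings::start(pat)[keep],
      query_end = Biostrings::end(pat)[keep],
      ref_start = Biostrings::start(sbj)[keep],
      ref_end = Biostrings::end(sbj)[keep],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_hits())
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), ref_id = character(0),
             score = numeric(0), bitscore = numeric(0), evalue = numeric(0),
             identity_pct = numeric(0), query_start = integer(0),
             query_end = integer(0), ref_start = integer(0),
             ref_end = integer(0), stringsAsFactors = FALSE)
}

#' Best-hit assignment for one query
#'
#' The best hit is the one with maximal bitscore; ties are broken by
#' smallest E-value, then by lexicographically smallest `ref_id`. The query
#' inherits the winning reference's family, domain and taxon.
#'
#' @param hits data.frame of hits for a single query (rows of the
#'   [search_panel] output).
#' @param panel a [ppr_panel].
#' @return one-row data.frame `ref_id`, `family`, `domain_call`,
#'   `source_taxon`, `bitscore`, `evalue`, `identity_pct`, or `NULL` when
#'   `hits` is empty (query excluded from the rhodopsin catalog).
#' @export
assign_best_hit <- function(hits, panel) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  if (length(unique(hits$query_id)) > 1) {
    stop("assign_best_hit expects hits for a single query")
  }
  ord <- order(-hits$bitscore, hits$evalue, hits$ref_id)
  best <- hits[ord[1], , drop = FALSE]
  entry <- panel_entry(panel, best$ref_id)
  data.frame(ref_id = best$ref_id, family = entry$family,
             domain_call = entry$domain, source_taxon = entry$taxon,
             bitscore = best$bitscore, evalue = best$evalue,
             identity_pct = best$identity_pct, stringsAsFactors = FALSE)
}

#' Helix C--F completeness check
#'
#' A unigene enters the rhodopsin catalog only if its alignment to the best
#' reference fully covers the reference's transmembrane helices C--F, the
#' minimum-completeness criterion for rhodopsin classification.
#'
#' @param hit one row of the [search_panel] output.
#' @param panel a [ppr_panel].
#' @return `TRUE` iff `[ref_start, ref_end]` contains the reference's helix
#'   C--F span (inclusive at both ends).
#' @export
check_helix_coverage <- function(hit, panel) {
  entry <- panel_entry(panel, hit$ref_id)
  hit$ref_start <= entry$helix_cf_start & hit$ref_end >= entry$helix_cf_end
}

#' Low-expression filter
#'
#' Removes unigenes whose TPM is below `threshold` in every sample; a
#' unigene with at least one sample at or above the threshold is kept
#' (the comparison is strict: exactly `threshold` is kept).
#'
#' @param tpm_table numeric matrix (unigenes x samples) with rownames, or a
#'   data.frame whose first column is `unigene_id`.
#' @param threshold TPM threshold, default 0.1.
#' @return character vector of kept unigene ids.
#' @export
filter_low_expression <- function(tpm_table, threshold = 0.1) {
  tpm_table <- as_tpm_matrix(tpm_table)
  if (nrow(tpm_table) == 0) return(character(0))
  if (any(tpm_table < 0)) stop("TPM values must be non-negative")
  keep <- apply(tpm_table >= threshold, 1, any)
  rownames(tpm_table)[keep]
}

as_tpm_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (is.character(x[[1]]) || is.factor(x[[1]])) {
      ids <- as.character(x[[1]])
      x <- as.matrix(x[, -1, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (nrow(x) > 0 && is.null(rownames(x))) {
    stop("TPM table must carry unigene ids as rownames")
  }
  storage.mode(x) <- "double"
  x
}

#' Identify rhodopsin unigenes
#'
#' End-to-end identification: homology search against the panel with the
#' E-value/identity cutoffs, best-hit family/taxonomy assignment, the helix
#' C--F completeness flag, and (optionally, after annotation) the
#' low-expression filter.
#'
#' @param queries named character vector or `AAStringSet` of unigene
#'   proteins.
#' @param panel a [ppr_panel].
#' @param tpm optional TPM table (matrix or data.frame, see
#'   [filter_low_expression]); when given, unigenes below `min_tpm` in all
#'   samples are dropped from the catalog.
#' @param evalue_max,identity_min_pct cutoffs passed to [search_panel].
#' @param min_tpm low-expression threshold.
#' @param require_helix_cf drop unigenes whose alignment does not cover the
#'   helix C--F span (default `TRUE`).
#' @return catalog data.frame: `unigene_id`, `ref_id`, `family`,
#'   `domain_call`, `source_taxon`, `bitscore`, `evalue`, `identity_pct`,
#'   `helix_cf_covered`.
#' @export
identify_rhodopsins <- function(queries, panel, tpm = NULL,
                                evalue_max = 1e-5, identity_min_pct = 40,
                                min_tpm = 0.1, require_helix_cf = TRUE) {
  hits <- search_panel(queries, panel, evalue_max = evalue_max,
                       identity_min_pct = identity_min_pct)
  if (nrow(hits) == 0) return(empty_catalog())
  parts <- split(hits, hits$query_id)
  rows <- lapply(names(parts), function(q) {
    best <- assign_best_hit(parts[[q]], panel)
    bh <- parts[[q]][parts[[q]]$ref_id == best$ref_id, , drop = FALSE]
    bh <- bh[which.max(bh$bitscore), , drop = FALSE]
    cbind(data.frame(unigene_id = q, stringsAsFactors = FALSE), best,
          data.frame(helix_cf_covered = check_helix_coverage(bh, panel)))
  })
  catalog <- do.call(rbind, rows)
  rownames(catalog) <- NULL
  if (require_helix_cf) {
    catalog <- catalog[catalog$helix_cf_covered, , drop = FALSE]
  }
  if (!is.null(tpm)) {
    kept <- filter_low_expression(tpm, threshold = min_tpm)
    catalog <- catalog[catalog$unigene_id %in% kept, , drop = FALSE]
  }
  rownames(catalog) <- NULL
  catalog
}

empty_catalog <- function() {
  data.frame(unigene_id = character(0), ref_id = character(0),
             family = character(0), domain_call = character(0),
             source_taxon = character(0), bitscore = numeric(0),
             evalue = numeric(0), identity_pct = numeric(0),
             helix_cf_covered = logical(0), stringsAsFactors = FALSE)
}
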