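#' TPM from raw counts
#'
#' Transcripts per million: `TPM_i = (c_i / l_i) / sum_j (c_j / l_j) * 1e6`,
#' where `c` are counts and `l` effective lengths. An all-zero count vector
#' yields all-zero TPM. Columns of a count matrix are normalized
#' independently (one sample per column).
#'
#' @param counts non-negative numeric vector, or matrix (unigenes x
#'   samples).
#' @param effective_lengths positive numeric vector, recycled across
#'   samples for matrix input.
#' @return TPM in the same shape as `counts`; each sample sums to 1e6
#'   unless it has no reads.
#' @export
compute_tpm <- function(counts, effective_lengths) {
  if (any(effective_lengths <= 0)) stop("effective lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.matrix(counts)) {
    if (length(effective_lengths) != nrow(counts)) {
      stop("one effective length per unigene is required")
    }
    return(apply(counts, 2, compute_tpm, effective_lengths = effective_lengths))
  }
  if (length(counts) != length(effective_lengths)) {
    stop("counts and effective_lengths must have equal length")
  }
  rate <- counts / effective_lengths
  total <- sum(rate)
  if (total == 0) return(rep(0, length(counts)))
  rate / total * 1e6
}

#' RNA-yield-weighted merging of size-fraction expression
#'
#' Small (0.22--3 um) and large (3--200 um) size fractions of the same
#' water sample are sequenced as separate libraries, so their TPMs are not
#' directly comparable. The merged contribution weights each fraction's
#' TPM by the RNA mass extracted per liter of seawater from that fraction:
#'
#' `merged = (tpm_small * rna_small + tpm_large * rna_large) /
#'           (rna_small + rna_large)`
#'
#' Only the ratio of the yields matters, so any mass unit may be used.
#' The result is bounded by the two TPMs and linear in each TPM argument,
#' hence merging commutes with summing over unigene groups.
#'
#' @param tpm_small,tpm_large non-negative TPM values (vectorized).
#' @param rna_small_per_l,rna_large_per_l RNA yields per liter, >= 0 with a
#'   positive sum.
#' @return merged TPM-equivalent contribution.
#' @export
merge_fractions <- function(tpm_small, tpm_large,
                            rna_small_per_l, rna_large_per_l) {
  if (any(tpm_small < 0) || any(tpm_large < 0)) {
    stop("TPM values must be non-negative")
  }
  if (any(rna_small_per_l < 0) || any(rna_large_per_l < 0)) {
    stop("RNA yields must be non-negative")
  }
  if (any(rna_small_per_l + rna_large_per_l == 0)) {
    stop("both RNA yields are zero for at least one sample")
  }
  (tpm_small * rna_small_per_l + tpm_large * rna_large_per_l) /
    (rna_small_per_l + rna_large_per_l)
}

water_sample_id <- function(meta) {
  paste(meta$station, meta$depth_layer, paste0("R", meta$replicate),
        sep = "_")
}

#' Lineage contributions to the merged rhodopsin transcript pool
#'
#' For each water sample (station x depth layer x replicate), sums member
#' unigene TPMs per group within each size fraction, merges the two
#' fractions with [merge_fractions] using the per-fraction RNA yields, and
#' reports absolute merged contributions, percentage shares of the merged
#' total, and unigene-count shares. A water sample missing one fraction is
#' computed from the present fraction alone and flagged.
#'
#' @param calls calls (or catalog) data.frame holding `unigene_id` and the
#'   grouping column.
#' @param tpm TPM matrix (unigenes x samples) or data.frame with a leading
#'   `unigene_id` column; columns must be `sample_id`s present in `meta`.
#'   Unigenes without a call are ignored (they are not part of the
#'   rhodopsin pool).
#' @param meta sample metadata data.frame: `sample_id`, `station`,
#'   `depth_layer`, `fraction` (`"small"`/`"large"`), `replicate`,
#'   `rna_yield_per_liter`.
#' @param grouping name of the grouping column in `calls`: typically
#'   `"domain_call"` (prokaryote/eukaryote), `"spectral_class"`,
#'   `"family"`, or `"source_taxon"`.
#' @return data.frame: `water_sample_id`, `station`, `depth_layer`,
#'   `replicate`, `group`, `tpm_small`, `tpm_large`, `merged_tpm`,
#'   `pct_share`, `n_unigenes`, `pct_unigenes`, `fraction_missing`.
#' @export
group_contributions <- function(calls, tpm, meta, grouping = "domain_call") {
  tpm <- as_tpm_matrix(tpm)
  if (!grouping %in% names(calls)) {
    stop("grouping column '", grouping, "' not found in calls")
  }
  unknown <- setdiff(colnames(tpm), meta$sample_id)
  if (length(unknown) > 0) {
    stop("samples absent from metadata: ", paste(unknown, collapse = ", "))
  }
  calls <- calls[calls$unigene_id %in% rownames(tpm), , drop = FALSE]
  group <- as.character(calls[[grouping]])
  group[is.na(group)] <- "unassigned"
  groups <- sort(unique(group))
  sub <- tpm[calls$unigene_id, , drop = FALSE]

  # per-group per-library sums
  gsum <- rowsum(sub, group = group)            # groups x samples
  gsum <- gsum[groups, , drop = FALSE]
  ncount <- as.vector(table(factor(group, levels = groups)))

  meta$water_sample_id <- water_sample_id(meta)
  out <- list()
  for (w in unique(meta$water_sample_id[meta$sample_id %in% colnames(tpm)])) {
    mrows <- meta[meta$water_sample_id == w & meta$sample_id %in% colnames(tpm),
                  , drop = FALSE]
    s_row <- mrows[mrows$fraction == "small", , drop = FALSE]
    l_row <- mrows[mrows$fraction == "large", , drop = FALSE]
    if (nrow(s_row) > 1 || nrow(l_row) > 1) {
      stop("water sample ", w, " has more than one record per fraction")
    }
    t_s <- if (nrow(s_row) == 1) gsum[, s_row$sample_id] else NULL
    t_l <- if (nrow(l_row) == 1) gsum[, l_row$sample_id] else NULL
    missing_fraction <- is.null(t_s) || is.null(t_l)
    if (missing_fraction) {
      merged <- if (is.null(t_s)) t_l else t_s
    } else {
      merged <- merge_fractions(t_s, t_l, s_row$rna_yield_per_liter,
                                l_row$rna_yield_per_liter)
    }
    total <- sum(merged)
    out[[w]] <- data.frame(
      water_sample_id = w,
      station = mrows$station[1],
      depth_layer = mrows$depth_layer[1],
      replicate = mrows$replicate[1],
      group = groups,
      tpm_small = if (is.null(t_s)) NA_real_ else unname(t_s),
      tpm_large = if (is.null(t_l)) NA_real_ else unname(t_l),
      merged_tpm = unname(merged),
      pct_share = if (total > 0) unname(merged) / total * 100 else
        rep(NA_real_, length(groups)),
      n_unigenes = ncount,
      pct_unigenes = ncount / sum(ncount) * 100,
      fraction_missing = missing_fraction,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spectral-class expression profile by station, depth and fraction
#'
#' Long-format table of blue- vs green-absorbing PR expression per
#' sequencing library, laid out by station x depth layer x size fraction x
#' spectral class (with replicates kept separate), for depth-distribution
#' displays. Classes absent from a library are reported with zero TPM.
#'
#' @param calls calls data.frame with `unigene_id` and `spectral_class`.
#' @param tpm TPM matrix or data.frame (see [group_contributions]).
#' @param meta sample metadata (see [group_contributions]).
#' @param classes spectral classes to tabulate; default BPR and GPR.
#' @return data.frame: `station`, `depth_layer`, `fraction`, `replicate`,
#'   `sample_id`, `spectral_class`, `tpm_sum`.
#' @export
spectral_depth_profile <- function(calls, tpm, meta,
                                   classes = c("BPR", "GPR")) {
  tpm <- as_tpm_matrix(tpm)
  calls <- calls[calls$unigene_id %in% rownames(tpm), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    if (!sid %in% colnames(tpm)) next
    v <- tpm[calls$unigene_id, sid]
    sums <- vapply(classes, function(cl) {
      sum(v[calls$spectral_class == cl])
    }, numeric(1))
    out[[sid]] <- data.frame(
      station = meta$station[i], depth_layer = meta$depth_layer[i],
      fraction = meta$fraction[i], replicate = meta$replicate[i],
      sample_id = sid, spectral_class = classes, tpm_sum = unname(sums),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monotone depth-trend check on a spectral profile
#'
#' Checks, per station x fraction x replicate, whether a spectral class's
#' expression is monotone over the depth ordering SUR -> DCM -> BOT.
#'
#' @param profile output of [spectral_depth_profile].
#' @param spectral_class class to check (`"BPR"` or `"GPR"`).
#' @param direction `"increasing"` or `"decreasing"` with depth.
#' @param relative compare class shares of the tabulated total per library
#'   (default) rather than absolute TPM sums.
#' @return logical vector named by `station_fraction_Rreplicate`, `TRUE`
#'   where the trend holds strictly monotonically.
#' @export
check_depth_trend <- function(profile, spectral_class,
                              direction = c("increasing", "decreasing"),
                              relative = TRUE) {
  direction <- match.arg(direction)
  depth_order <- c("SUR", "DCM", "BOT")
  if (relative) {
    tot <- stats::aggregate(tpm_sum ~ sample_id, profile, sum)
    profile$tpm_sum <- profile$tpm_sum /
      tot$tpm_sum[match(profile$sample_id, tot$sample_id)]
  }
  p <- profile[profile$spectral_class == spectral_class, , drop = FALSE]
  key <- paste(p$station, p$fraction, paste0("R", p$replicate), sep = "_")
  vapply(split(p, key), function(d) {
    d <- d[match(depth_order, d$depth_layer), , drop = FALSE]
    v <- d$tpm_sum
    if (anyNA(v)) return(NA)
    if (direction == "increasing") all(diff(v) > 0) else all(diff(v) < 0)
  }, logical(1))
}
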