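#' Simulation configuration
#'
#' Parameters of the synthetic-community generator. Defaults emulate the
#' study design the pipeline targets: 2 stations (continental shelf C6,
#' continental slope C9) x 3 photic-zone depths (SUR, DCM, BOT) x 2 size
#' fractions (0.22--3 um, 3--200 um) x 2 replicates; log-normal unigene
#' TPMs; a merged rhodopsin pool split 70:30 between prokaryotes and
#' eukaryotes; blue-absorbing PRs increasing and green-absorbing PRs
#' decreasing with depth; and eukaryotic PPR abundance coupled to nutrient
#' concentrations at a planted correlation.
#'
#' @param seed integer seed; every random draw in [simulate_community] is
#'   derived from it.
#' @param n_unigenes total unigenes including decoys.
#' @param divergence_pct per-site substitution probability (in percent)
#'   applied outside protected sites when mutating reference sequences.
#' @param planted_shares named numeric, groups summing to 1: share of each
#'   domain in the merged rhodopsin pool of every water sample.
#' @param depth_trend named character: direction (`"increasing"` /
#'   `"decreasing"`) of the BPR share of the PR pool over SUR -> DCM ->
#'   BOT; GPR takes the complement.
#' @param env_effect_r planted correlation in `[0, 1]` between eukaryotic
#'   PPR abundance and each nutrient variable (phosphate, nitrate+nitrite,
#'   silicate), imposed through a Gaussian copula.
#' @param tpm_lognormal_meanlog,tpm_lognormal_sdlog log-normal parameters
#'   of the within-pool unigene TPM weights.
#' @param rna_yield_range interval (ug RNA per liter) the per-fraction RNA
#'   yields are drawn from, uniformly.
#' @param frac_decoy fraction of unigenes that are random non-rhodopsin
#'   decoys; decoy TPMs absorb the remainder of each library so every
#'   library sums to 1e6.
#' @param share_stage `"post_merge"` plants the domain shares exactly on
#'   the merged pool (the default, matching how merged shares are
#'   reported); `"pre_merge"` plants them on each fraction library with
#'   multiplicative noise, so merged shares recover the target only up to
#'   sampling noise.
#' @param abund_effect_r planted correlation between a taxon's relative
#'   abundance and its PPR expression (expression-vs-abundance panels).
#' @param base_pool_tpm median merged rhodopsin pool total per water
#'   sample, TPM-equivalent.
#' @param pool_sdlog log-normal sdlog of the pool total across water
#'   samples.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_unigenes = 500L,
                              divergence_pct = 10,
                              planted_shares = c(prokaryote = 0.7,
                                                 eukaryote = 0.3),
                              depth_trend = c(BPR = "increasing",
                                              GPR = "decreasing"),
                              env_effect_r = 0.6,
                              tpm_lognormal_meanlog = 0,
                              tpm_lognormal_sdlog = 1,
                              rna_yield_range = c(0.5, 5),
                              frac_decoy = 0.1,
                              share_stage = c("post_merge", "pre_merge"),
                              abund_effect_r = 0.9,
                              base_pool_tpm = 5000,
                              pool_sdlog = 0.3) {
  share_stage <- match.arg(share_stage)
  if (abs(sum(planted_shares) - 1) > 1e-9 || any(planted_shares < 0)) {
    stop("planted_shares must be non-negative and sum to 1")
  }
  if (!all(names(planted_shares) %in% c("prokaryote", "eukaryote"))) {
    stop("planted_shares must be named 'prokaryote' and 'eukaryote'")
  }
  if (divergence_pct < 0 || divergence_pct > 50) {
    stop("divergence_pct must be in [0, 50]")
  }
  if (env_effect_r < 0 || env_effect_r > 1) {
    stop("env_effect_r must be in [0, 1]")
  }
  if (length(rna_yield_range) != 2 || any(rna_yield_range <= 0) ||
      diff(rna_yield_range) < 0) {
    stop("rna_yield_range must be a positive increasing interval")
  }
  if (frac_decoy < 0 || frac_decoy >= 1) stop("frac_decoy must be in [0, 1)")
  structure(list(
    seed = as.integer(seed), n_unigenes = as.integer(n_unigenes),
    divergence_pct = divergence_pct, planted_shares = planted_shares,
    depth_trend = depth_trend, env_effect_r = env_effect_r,
    tpm_lognormal_meanlog = tpm_lognormal_meanlog,
    tpm_lognormal_sdlog = tpm_lognormal_sdlog,
    rna_yield_range = rna_yield_range, frac_decoy = frac_decoy,
    share_stage = share_stage, abund_effect_r = abund_effect_r,
    base_pool_tpm = base_pool_tpm, pool_sdlog = pool_sdlog),
    class = "sim_config")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Point-mutate a reference sequence
#'
#' Substitutes each unprotected site independently with probability
#' `divergence_pct / 100` to a uniformly random different residue.
#' Protected sites (e.g. the spectral-tuning site) are never touched.
#' Length is preserved (no indels). Deterministic under `seed`.
#'
#' @param ref_seq amino-acid string (or a single-row [ppr_panel] entry's
#'   sequence).
#' @param divergence_pct per-site substitution probability x 100, in
#'   `[0, 100]`.
#' @param protect_sites integer positions (1-based) never mutated.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return list with `seq` (mutated string) and `mutated_sites` (integer
#'   positions substituted).
#' @export
mutate_reference <- function(ref_seq, divergence_pct,
                             protect_sites = integer(0), seed = NULL) {
  if (divergence_pct < 0 || divergence_pct > 100) {
    stop("divergence_pct must be in [0, 100]")
  }
  chars <- strsplit(toupper(ref_seq), "")[[1]]
  n <- length(chars)
  if (length(protect_sites) > 0 &&
      (min(protect_sites) < 1 || max(protect_sites) > n)) {
    stop("protect_sites out of range")
  }
  with_seed(seed, {
    hit <- runif(n) < divergence_pct / 100
    hit[protect_sites] <- FALSE
    idx <- which(hit)
    for (i in idx) {
      chars[i] <- sample(setdiff(AA_ALPHABET20, chars[i]), 1)
    }
    list(seq = paste(chars, collapse = ""), mutated_sites = idx)
  })
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

# Fixed codon per amino acid (uniform synonymous choice is unnecessary for
# testing translation; one deterministic codon per residue suffices).
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Back-translate a protein to a coding nucleotide sequence
#'
#' Deterministic back-translation (one fixed codon per residue) with a
#' trailing stop codon, used to build nucleotide fixtures for ORF
#' translation tests.
#'
#' @param aa_seq amino-acid string over the 20 canonical residues.
#' @param add_stop append a `TAA` stop codon (default `TRUE`).
#' @return nucleotide string.
#' @export
back_translate <- function(aa_seq, add_stop = TRUE) {
  chars <- strsplit(toupper(aa_seq), "")[[1]]
  bad <- setdiff(unique(chars), names(CODON_OF))
  if (length(bad) > 0) stop("cannot back-translate residue(s): ",
                            paste(bad, collapse = ", "))
  nt <- paste(CODON_OF[chars], collapse = "")
  if (add_stop) nt <- paste0(nt, "TAA")
  nt
}

# Depth-dependent BPR share of the PR spectral pool.
bpr_depth_share <- function(depth_layer, depth_trend) {
  inc <- c(SUR = 0.25, DCM = 0.50, BOT = 0.75)
  b <- if (identical(depth_trend[["BPR"]], "decreasing")) 1 - inc else inc
  b[[depth_layer]]
}

# Relative expression weight of family buckets within a domain pool.
PROK_BUCKET_W <- c(PR = 0.75, nonPR_PPR = 0.20, nonPPR = 0.05)

unigene_bucket <- function(family, spectral_class, is_ppr) {
  ifelse(family == "PR",
         ifelse(spectral_class == "BPR", "PR_BPR", "PR_GPR"),
         ifelse(is_ppr, "nonPR_PPR", "nonPPR"))
}

#' Simulate a size-fractionated metatranscriptome community
#'
#' Generates a fully self-consistent fixture bundle with planted ground
#' truth: unigene proteins point-mutated from the reference panel (tuning
#' site protected, then set to the planted spectral residue), per-library
#' TPM matrices over the 2 x 3 x 2 x 2 sampling design in which every
#' library sums to 1e6, per-fraction RNA yields, an environmental table
#' whose nutrient variables are copula-coupled to eukaryotic PPR
#' abundance, and a taxon relative-abundance table coupled to the
#' corresponding PPR expression. All output is reproducible bit-for-bit
#' under the config seed.
#'
#' @param config a [simulation_config].
#' @param panel a [ppr_panel]; defaults to the bundled panel.
#' @return list of class `ppr_simulation`: `config`, `unigenes` (named
#'   character vector of proteins), `meta`, `tpm` (matrix, unigenes x
#'   libraries), `env`, `taxon_abundance`, and `truth` (per-unigene
#'   labels, per-water-sample group sums pre- and post-merge, spectral
#'   sums, the eukaryotic PPR merged vector, and generator coefficients).
#' @export
simulate_community <- function(config = simulation_config(),
                               panel = default_panel()) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "ppr_panel"))
  with_seed(config$seed, simulate_community_impl(config, panel))
}

simulate_community_impl <- function(config, panel) {
  ent <- panel$entries

  # ---- sampling frame -----------------------------------------------------
  design <- expand.grid(replicate = 1:2,
                        depth_layer = c("SUR", "DCM", "BOT"),
                        station = c("shelf_C6", "slope_C9"),
                        stringsAsFactors = FALSE)
  design <- design[, c("station", "depth_layer", "replicate")]
  wsid <- water_sample_id(design)
  code <- ifelse(design$station == "shelf_C6", "C6", "C9")
  meta <- do.call(rbind, lapply(c("small", "large"), function(fr) {
    data.frame(
      sample_id = paste(code, design$depth_layer,
                        paste0("R", design$replicate),
                        ifelse(fr == "small", "S", "L"), sep = "_"),
      station = design$station, depth_layer = design$depth_layer,
      fraction = fr, replicate = design$replicate,
      rna_yield_per_liter = runif(nrow(design), config$rna_yield_range[1],
                                  config$rna_yield_range[2]),
      volume_filtered_liters = round(runif(nrow(design), 20, 60), 1),
      stringsAsFactors = FALSE)
  }))
  meta <- meta[order(match(water_sample_id(meta), wsid), meta$fraction), ]
  rownames(meta) <- NULL
  n_ws <- nrow(design)

  # ---- unigene origins ----------------------------------------------------
  n <- config$n_unigenes
  n_decoy <- round(config$frac_decoy * n)
  n_rhod <- n - n_decoy
  shares <- config$planted_shares
  n_euk <- round(shares[["eukaryote"]] * n_rhod)
  n_prok <- n_rhod - n_euk

  prok_fams <- sample(c("PR", "XR", "GR", "BR", "SRI", "other_rhodopsin"),
                      n_prok, replace = TRUE,
                      prob = c(0.55, 0.15, 0.05, 0.10, 0.08, 0.07))
  pick_ref <- function(fam, dom) {
    ids <- ent$ref_id[ent$family == fam & ent$domain == dom]
    if (length(ids) == 0) stop("panel lacks a ", dom, " ", fam, " entry")
    sample(ids, 1)
  }
  truth <- data.frame(
    unigene_id = sprintf("UG%04d", seq_len(n)),
    is_rhodopsin = c(rep(TRUE, n_rhod), rep(FALSE, n_decoy)),
    ref_id = NA_character_, family = NA_character_,
    domain = NA_character_, spectral_class = NA_character_,
    tuning_residue = NA_character_, taxon = NA_character_,
    stringsAsFactors = FALSE)
  truth$domain[seq_len(n_prok)] <- "prokaryote"
  truth$family[seq_len(n_prok)] <- prok_fams
  if (n_euk > 0) {
    truth$domain[n_prok + seq_len(n_euk)] <- "eukaryote"
    truth$family[n_prok + seq_len(n_euk)] <- "PR"
  }
  for (i in seq_len(n_rhod)) {
    truth$ref_id[i] <- pick_ref(truth$family[i], truth$domain[i])
  }
  truth$taxon[seq_len(n_rhod)] <-
    ent$taxon[match(truth$ref_id[seq_len(n_rhod)], ent$ref_id)]

  is_pr <- !is.na(truth$family) & truth$family == "PR"
  cls <- sample(c("BPR", "GPR"), sum(is_pr), replace = TRUE)
  truth$spectral_class[is_pr] <- cls
  truth$tuning_residue[is_pr] <- ifelse(
    cls == "BPR", "Q", sample(c("M", "L"), sum(is_pr), replace = TRUE))
  truth$spectral_class[!is_pr & truth$is_rhodopsin] <- "unclassified"

  # ---- sequences ----------------------------------------------------------
  unigenes <- character(n)
  for (i in seq_len(n)) {
    if (!truth$is_rhodopsin[i]) {
      unigenes[i] <- random_protein(sample(180:300, 1))
      next
    }
    e <- ent[ent$ref_id == truth$ref_id[i], ]
    protect <- if (is_pr[i]) e$tuning_site else integer(0)
    m <- mutate_reference(panel$seqs[[e$ref_id]], config$divergence_pct,
                          protect_sites = protect)
    s <- m$seq
    if (is_pr[i]) {
      substr(s, e$tuning_site, e$tuning_site) <- truth$tuning_residue[i]
    }
    unigenes[i] <- s
  }
  names(unigenes) <- truth$unigene_id

  # ---- expression ---------------------------------------------------------
  buckets <- unigene_bucket(truth$family, truth$spectral_class,
                            ent$is_ppr[match(truth$ref_id, ent$ref_id)])
  buckets[!truth$is_rhodopsin] <- NA
  lib_ids <- meta$sample_id
  tpm <- matrix(0, n, length(lib_ids),
                dimnames = list(truth$unigene_id, lib_ids))

  yield_of <- function(w, fr) {
    meta$rna_yield_per_liter[water_sample_id(meta) == w &
                               meta$fraction == fr]
  }
  pool_total <- config$base_pool_tpm * exp(rnorm(n_ws, 0, config$pool_sdlog))
  names(pool_total) <- wsid

  # target sum for each (water sample, fraction, domain) cell
  frac_sums <- array(NA_real_, dim = c(n_ws, 2, 2),
                     dimnames = list(wsid, c("small", "large"),
                                     c("prokaryote", "eukaryote")))
  u_rng <- list(prokaryote = c(0.70, 0.90), eukaryote = c(0.10, 0.30))
  for (k in seq_len(n_ws)) {
    w <- wsid[k]
    ws <- yield_of(w, "small"); wl <- yield_of(w, "large")
    if (config$share_stage == "post_merge") {
      for (dom in c("prokaryote", "eukaryote")) {
        m_dom <- shares[[dom]] * pool_total[k]
        u <- runif(1, u_rng[[dom]][1], u_rng[[dom]][2])
        frac_sums[k, "small", dom] <- m_dom * u * (ws + wl) / ws
        frac_sums[k, "large", dom] <- m_dom * (1 - u) * (ws + wl) / wl
      }
    } else {
      # plant shares on each fraction library with mild multiplicative
      # noise; one pool total per library, shared across domains
      for (fr in c("small", "large")) {
        p_wf <- config$base_pool_tpm * exp(rnorm(1, 0, config$pool_sdlog))
        for (dom in c("prokaryote", "eukaryote")) {
          frac_sums[k, fr, dom] <- shares[[dom]] * p_wf *
            exp(rnorm(1, 0, 0.03))
        }
      }
    }
  }

  # split domain cell mass over family/spectral buckets, then over members
  for (k in seq_len(n_ws)) {
    b <- bpr_depth_share(design$depth_layer[k], config$depth_trend)
    bucket_w <- list(
      prokaryote = c(PR_BPR = PROK_BUCKET_W[["PR"]] * b,
                     PR_GPR = PROK_BUCKET_W[["PR"]] * (1 - b),
                     nonPR_PPR = PROK_BUCKET_W[["nonPR_PPR"]],
                     nonPPR = PROK_BUCKET_W[["nonPPR"]]),
      eukaryote = c(PR_BPR = b, PR_GPR = 1 - b))
    for (fr in c("small", "large")) {
      lib <- meta$sample_id[water_sample_id(meta) == wsid[k] &
                              meta$fraction == fr]
      for (dom in c("prokaryote", "eukaryote")) {
        bw <- bucket_w[[dom]]
        present <- vapply(names(bw), function(bk) {
          any(buckets == bk & truth$domain == dom, na.rm = TRUE)
        }, logical(1))
        if (!any(present)) next
        bw <- bw[present] / sum(bw[present])
        for (bk in names(bw)) {
          members <- which(!is.na(buckets) & buckets == bk &
                             truth$domain == dom)
          wgt <- rlnorm(length(members), config$tpm_lognormal_meanlog,
                        config$tpm_lognormal_sdlog)
          tpm[members, lib] <- frac_sums[k, fr, dom] * bw[[bk]] *
            wgt / sum(wgt)
        }
      }
    }
  }

  # decoys absorb the remainder so each library sums to 1e6
  if (n_decoy > 0) {
    decoys <- which(!truth$is_rhodopsin)
    for (lib in lib_ids) {
      rhod_total <- sum(tpm[, lib])
      if (rhod_total >= 1e6) {
        stop("rhodopsin pool exceeds 1e6 TPM in library ", lib,
             "; lower base_pool_tpm")
      }
      wgt <- rlnorm(n_decoy, config$tpm_lognormal_meanlog, 2)
      tpm[decoys, lib] <- (1e6 - rhod_total) * wgt / sum(wgt)
    }
  }

  # ---- per-water-sample truth sums ---------------------------------------
  sg <- list()
  for (k in seq_len(n_ws)) {
    w <- wsid[k]
    ws <- yield_of(w, "small"); wl <- yield_of(w, "large")
    for (dom in c("prokaryote", "eukaryote")) {
      s_sum <- frac_sums[k, "small", dom]
      l_sum <- frac_sums[k, "large", dom]
      sg[[length(sg) + 1]] <- data.frame(
        water_sample_id = w, group = dom, sum_small = s_sum,
        sum_large = l_sum,
        merged = merge_fractions(s_sum, l_sum, ws, wl),
        stringsAsFactors = FALSE)
    }
  }
  sample_groups <- do.call(rbind, sg)
  euk <- sample_groups[sample_groups$group == "eukaryote", ]
  euk_ppr_merged <- stats::setNames(euk$merged, euk$water_sample_id)

  # ---- environment (copula-coupled nutrients) ----------------------------
  z <- as.vector(scale(log(euk_ppr_merged)))
  r <- config$env_effect_r
  couple <- function(intercept, slope) {
    x <- r * z + sqrt(1 - r^2) * rnorm(n_ws)
    pmax(intercept + slope * x, 0.001)
  }
  depth_m <- numeric(n_ws)
  base_depth <- list(shelf_C6 = c(SUR = 5, DCM = 30, BOT = 55),
                     slope_C9 = c(SUR = 5, DCM = 50, BOT = 90))
  for (k in seq_len(n_ws)) {
    depth_m[k] <- base_depth[[design$station[k]]][[design$depth_layer[k]]] +
      runif(1, -2, 2)
  }
  po4 <- couple(0.05, 0.012)
  no3_no2 <- couple(0.60, 0.120)
  sio3 <- couple(2.50, 0.500)
  env <- data.frame(
    water_sample_id = wsid,
    no2 = pmax(0.05 + 0.015 * rnorm(n_ws), 0.001),
    po4 = po4, no3_no2 = no3_no2, sio3 = sio3,
    depth_m = depth_m,
    temperature_c = 29.5 - 0.13 * depth_m + rnorm(n_ws, 0, 0.3),
    salinity = 33.8 + rnorm(n_ws, 0, 0.15),
    stringsAsFactors = FALSE)
  env$np_ratio <- env$no3_no2 / env$po4

  # ---- taxon relative abundances coupled to their PPR expression ---------
  taxon_exp <- cbind(
    Pelagibacterales = colSums_by(tpm, meta, frac_sums, truth, buckets,
                                  "prokaryote", "PR_BPR", wsid, yield_of),
    Flavobacteriaceae = colSums_by(tpm, meta, frac_sums, truth, buckets,
                                   "prokaryote", "PR_GPR", wsid, yield_of),
    Dinophyceae = euk_ppr_merged)
  ra <- config$abund_effect_r
  mu <- c(Pelagibacterales = log(0.30), Flavobacteriaceae = log(0.15),
          Dinophyceae = log(0.10), Other = log(0.45))
  raw <- sapply(colnames(taxon_exp), function(t) {
    zt <- as.vector(scale(log(pmax(taxon_exp[, t], 1e-12))))
    exp(mu[[t]] + 0.4 * (ra * zt + sqrt(1 - ra^2) * rnorm(n_ws)))
  })
  raw <- cbind(raw, Other = exp(mu[["Other"]] + 0.4 * rnorm(n_ws)))
  rel <- raw / rowSums(raw)
  taxon_abundance <- data.frame(water_sample_id = wsid, rel,
                                stringsAsFactors = FALSE)

  structure(list(
    config = config, unigenes = unigenes, meta = meta, tpm = tpm,
    env = env, taxon_abundance = taxon_abundance,
    truth = list(unigenes = truth, sample_groups = sample_groups,
                 euk_ppr_merged = euk_ppr_merged,
                 taxon_ppr_merged = taxon_exp,
                 pool_total = pool_total,
                 env_effect_r = config$env_effect_r,
                 abund_effect_r = config$abund_effect_r)),
    class = "ppr_simulation")
}

# merged expression of one (domain, bucket) cell per water sample,
# recomputed from the emitted TPM matrix
colSums_by <- function(tpm, meta, frac_sums, truth, buckets, dom, bucket,
                       wsid, yield_of) {
  members <- which(!is.na(buckets) & buckets == bucket &
                     truth$domain == dom)
  out <- numeric(length(wsid))
  names(out) <- wsid
  for (k in seq_along(wsid)) {
    w <- wsid[k]
    s_lib <- meta$sample_id[water_sample_id(meta) == w &
                              meta$fraction == "small"]
    l_lib <- meta$sample_id[water_sample_id(meta) == w &
                              meta$fraction == "large"]
    out[k] <- merge_fractions(sum(tpm[members, s_lib]),
                              sum(tpm[members, l_lib]),
                              yield_of(w, "small"), yield_of(w, "large"))
  }
  out
}

#' @export
print.ppr_simulation <- function(x, ...) {
  cat("Synthetic metatranscriptome community\n")
  cat("  unigenes:", length(x$unigenes),
      sprintf("(%d rhodopsin, %d decoy)\n",
              sum(x$truth$unigenes$is_rhodopsin),
              sum(!x$truth$unigenes$is_rhodopsin)))
  cat("  libraries:", nrow(x$meta), " water samples:",
      length(unique(water_sample_id(x$meta))), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated fixture bundle to disk
#'
#' Emits the plain-text bundle every pipeline reader consumes:
#' `unigenes.faa`, `tpm_small.tsv`, `tpm_large.tsv`, `sample_meta.tsv`,
#' `env_table.tsv`, `taxon_abundance.tsv`, `truth_unigenes.tsv`,
#' `truth_sample_groups.tsv`. Output is byte-identical for identical
#' config and seed.
#'
#' @param sim a `ppr_simulation`.
#' @param dir output directory, created if needed.
#' @return invisibly, the file paths.
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "ppr_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    unigenes = file.path(dir, "unigenes.faa"),
    tpm_small = file.path(dir, "tpm_small.tsv"),
    tpm_large = file.path(dir, "tpm_large.tsv"),
    meta = file.path(dir, "sample_meta.tsv"),
    env = file.path(dir, "env_table.tsv"),
    taxa = file.path(dir, "taxon_abundance.tsv"),
    truth_unigenes = file.path(dir, "truth_unigenes.tsv"),
    truth_groups = file.path(dir, "truth_sample_groups.tsv"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$unigenes),
                              paths[["unigenes"]])
  write_tsv_matrix <- function(m, path) {
    df <- data.frame(unigene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  small <- sim$meta$sample_id[sim$meta$fraction == "small"]
  large <- sim$meta$sample_id[sim$meta$fraction == "large"]
  write_tsv_matrix(sim$tpm[, small, drop = FALSE], paths[["tpm_small"]])
  write_tsv_matrix(sim$tpm[, large, drop = FALSE], paths[["tpm_large"]])
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wt(sim$meta, paths[["meta"]])
  wt(sim$env, paths[["env"]])
  wt(sim$taxon_abundance, paths[["taxa"]])
  wt(sim$truth$unigenes, paths[["truth_unigenes"]])
  wt(sim$truth$sample_groups, paths[["truth_groups"]])
  invisible(paths)
}
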