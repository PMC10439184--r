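test_that("compute_tpm matches the definition and normalizes to one million", {
  expect_equal(compute_tpm(5, 1000), 1e6)
  # equal counts, lengths 1000 and 2000 -> 2:1 ratio
  out <- compute_tpm(c(10, 10), c(1000, 2000))
  expect_equal(out, c(2e6 / 3, 1e6 / 3))
  expect_equal(sum(out), 1e6)
  # zero-count transcript stays zero
  expect_equal(compute_tpm(c(0, 5), c(500, 500))[1], 0)
  # all-zero counts give all-zero TPM, not NaN
  expect_equal(compute_tpm(c(0, 0), c(100, 200)), c(0, 0))
  expect_error(compute_tpm(c(1, 2), c(100, 0)), "must be > 0")
  expect_error(compute_tpm(c(-1, 2), c(100, 100)), "non-negative")
  # matrix input: per-column normalization
  m <- matrix(c(3, 7, 0, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  tm <- compute_tpm(m, c(100, 100))
  expect_equal(colSums(tm), c(s1 = 1e6, s2 = 0))
})

test_that("fraction merging is the RNA-yield-weighted mean", {
  expect_equal(merge_fractions(100, 100, 2, 7), 100)
  expect_equal(merge_fractions(200, 0, 1, 3), 50)
  expect_equal(merge_fractions(10, 30, 4, 4), 20)  # equal yields -> mean
  expect_error(merge_fractions(1, 1, 0, 0), "both RNA yields are zero")
  expect_error(merge_fractions(-1, 1, 1, 1), "non-negative")
})

test_that("merging is bounded by the two TPMs and linear in each argument", {
  set.seed(12)
  n <- 500
  ts <- runif(n, 0, 1e4); tl <- runif(n, 0, 1e4)
  ws <- runif(n, 0.1, 10); wl <- runif(n, 0.1, 10)
  m <- merge_fractions(ts, tl, ws, wl)
  expect_true(all(m >= pmin(ts, tl) - 1e-9))
  expect_true(all(m <= pmax(ts, tl) + 1e-9))
  # linearity: merge(a+b, c+d) = merge(a,c) + merge(b,d) at fixed yields
  a <- runif(n, 0, 1e3); b <- runif(n, 0, 1e3)
  c_ <- runif(n, 0, 1e3); d <- runif(n, 0, 1e3)
  lhs <- merge_fractions(a + b, c_ + d, ws, wl)
  rhs <- merge_fractions(a, c_, ws, wl) + merge_fractions(b, d, ws, wl)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

toy_community <- function() {
  meta <- data.frame(
    sample_id = c("W1_S", "W1_L", "W2_S", "W2_L"),
    station = "shelf_C6",
    depth_layer = c("SUR", "SUR", "DCM", "DCM"),
    fraction = c("small", "large", "small", "large"),
    replicate = 1L,
    rna_yield_per_liter = c(2, 6, 1, 1),
    stringsAsFactors = FALSE)
  calls <- data.frame(
    unigene_id = c("u1", "u2"),
    domain_call = c("prokaryote", "eukaryote"),
    spectral_class = c("BPR", "GPR"),
    stringsAsFactors = FALSE)
  tpm <- matrix(100, 2, 4,
                dimnames = list(c("u1", "u2"), meta$sample_id))
  list(meta = meta, calls = calls, tpm = tpm)
}

test_that("group contributions report merged totals, percentage shares and
           unigene counts", {
  tc <- toy_community()
  out <- group_contributions(tc$calls, tc$tpm, tc$meta, "domain_call")
  # identical TPMs in both fractions -> 50/50 regardless of yields
  expect_equal(sort(unique(out$pct_share)), 50)
  expect_equal(unique(out$merged_tpm), 100)
  expect_true(all(out$n_unigenes == 1))
  # shares over an exhaustive grouping sum to 100
  tot <- tapply(out$pct_share, out$water_sample_id, sum)
  expect_equal(as.vector(tot), rep(100, 2), tolerance = 1e-9)

  # degenerate: all unigenes prokaryotic
  calls2 <- tc$calls; calls2$domain_call <- "prokaryote"
  out2 <- group_contributions(calls2, tc$tpm, tc$meta, "domain_call")
  expect_equal(unique(out2$pct_share), 100)
})

test_that("a water sample missing one fraction is computed from the present
           fraction and flagged", {
  tc <- toy_community()
  tpm <- tc$tpm[, c("W1_S", "W1_L", "W2_S")]
  out <- group_contributions(tc$calls, tpm, tc$meta, "domain_call")
  w2 <- out[out$water_sample_id == "shelf_C6_DCM_R1", ]
  expect_true(all(w2$fraction_missing))
  expect_equal(w2$merged_tpm, w2$tpm_small)
  w1 <- out[out$water_sample_id == "shelf_C6_SUR_R1", ]
  expect_false(any(w1$fraction_missing))
})

test_that("planted merged domain shares are recovered exactly by the
           quantification path", {
  panel <- default_panel()
  sim <- simulate_community(simulation_config(seed = 77, n_unigenes = 90),
                            panel)
  truth <- sim$truth$unigenes
  calls <- data.frame(unigene_id = truth$unigene_id[truth$is_rhodopsin],
                      domain_call = truth$domain[truth$is_rhodopsin],
                      stringsAsFactors = FALSE)
  out <- group_contributions(calls, sim$tpm, sim$meta, "domain_call")
  prok <- out[out$group == "prokaryote", ]
  expect_equal(prok$pct_share, rep(70, nrow(prok)), tolerance = 1e-9)
  # and the merged values match the generator's planted sums
  key <- paste(sim$truth$sample_groups$water_sample_id,
               sim$truth$sample_groups$group)
  planted <- sim$truth$sample_groups$merged[
    match(paste(out$water_sample_id, out$group), key)]
  expect_equal(out$merged_tpm, planted, tolerance = 1e-9)
})

test_that("spectral depth profile tabulates per-library class sums with
           zero-fill and detects the planted trend", {
  tc <- toy_community()
  prof <- spectral_depth_profile(tc$calls, tc$tpm, tc$meta)
  expect_equal(nrow(prof), 4 * 2)  # 4 libraries x 2 classes
  expect_true(all(c("BPR", "GPR") %in% prof$spectral_class))
  # zero GPR community still yields GPR rows with zero sums
  calls2 <- tc$calls; calls2$spectral_class <- "BPR"
  prof2 <- spectral_depth_profile(calls2, tc$tpm, tc$meta)
  expect_true(all(prof2$tpm_sum[prof2$spectral_class == "GPR"] == 0))

  panel <- default_panel()
  sim <- simulate_community(simulation_config(seed = 13, n_unigenes = 120),
                            panel)
  truth <- sim$truth$unigenes
  calls <- data.frame(
    unigene_id = truth$unigene_id[truth$is_rhodopsin],
    spectral_class = truth$spectral_class[truth$is_rhodopsin],
    stringsAsFactors = FALSE)
  prof3 <- spectral_depth_profile(calls, sim$tpm, sim$meta)
  up <- check_depth_trend(prof3, "BPR", "increasing")
  dn <- check_depth_trend(prof3, "GPR", "decreasing")
  # the BPR share of the PR pool is planted monotone increasing with depth
  expect_true(all(up))
  expect_true(all(dn))
})
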