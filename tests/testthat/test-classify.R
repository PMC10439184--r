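test_that("tuning-site mapping agrees with an exhaustive alignment oracle on
           indel fixtures", {
  panel <- default_panel()
  canon <- panel$seqs[[panel$canonical_pr_id]]
  site <- 105L
  submat <- get_blosum62_test()

  # identity alignment: residue read off directly
  expect_equal(map_tuning_site(canon, panel), "L")

  # first two residues deleted: same letter, now at query position 103
  trunc2 <- substr(canon, 3, nchar(canon))
  expect_equal(map_tuning_site(trunc2, panel), "L")
  expect_equal(oracle_residue_at(trunc2, canon, site, submat), "L")

  # tuning-site residue deleted: gap in that column
  del105 <- paste0(substr(canon, 1, 104), substr(canon, 106, nchar(canon)))
  expect_equal(oracle_residue_at(del105, canon, site, submat), "-")
  expect_equal(map_tuning_site(del105, panel), "-")

  # internal 5-residue deletion upstream shifts the site left
  del_up <- paste0(substr(canon, 1, 49), substr(canon, 55, nchar(canon)))
  expect_equal(map_tuning_site(del_up, panel),
               oracle_residue_at(del_up, canon, site, submat))

  # a 50-residue fragment is gapped at position 105 under global alignment
  expect_equal(map_tuning_site(substr(canon, 1, 50), panel), "-")

  expect_error(map_tuning_site("", panel), "non-empty")
})

test_that("the position-105 residue rule maps Q to blue and M/L to green", {
  expect_equal(classify_spectral("Q", "PR", TRUE),
               list(spectral_class = "BPR", lambda_max_nm = 490))
  expect_equal(classify_spectral("M", "PR", TRUE),
               list(spectral_class = "GPR", lambda_max_nm = 525))
  expect_equal(classify_spectral("L", "PR", TRUE)$spectral_class, "GPR")
  expect_equal(classify_spectral("q", "PR", TRUE)$spectral_class, "BPR")
  for (res in list("A", "X", "-", NA)) {
    out <- classify_spectral(res, "PR", TRUE)
    expect_equal(out$spectral_class, "unclassified")
    expect_true(is.na(out$lambda_max_nm))
  }
  # non-pump and out-of-scope families are never classified
  expect_equal(classify_spectral("Q", "SRI", FALSE)$spectral_class,
               "unclassified")
  expect_equal(classify_spectral("Q", "XR", TRUE)$spectral_class,
               "unclassified")
  expect_equal(classify_spectral("Q", "XR", TRUE,
                                 families_with_rule = c("PR", "XR"))
               $spectral_class, "BPR")
})

test_that("family classification inherits family and pump status from the
           best-hit panel entry", {
  panel <- default_panel()
  expect_equal(classify_family("AAG10475.1", panel),
               list(family = "PR", is_ppr = TRUE))
  expect_equal(classify_family("SRI_HALSAL_SYN", panel),
               list(family = "SRI", is_ppr = FALSE))
  expect_equal(classify_family("BAC88139.1", panel),
               list(family = "GR", is_ppr = TRUE))
  expect_error(classify_family("NOPE", panel), "unknown ref_id")
})

test_that("spectral recovery is exact for mutants with a protected tuning
           site", {
  panel <- default_panel()
  canon <- panel$seqs[[panel$canonical_pr_id]]
  set.seed(99)
  n <- 40
  planted <- sample(c("Q", "M", "L"), n, replace = TRUE)
  ok <- logical(n)
  for (i in seq_len(n)) {
    s <- mutate_reference(canon, 10, protect_sites = 105L)$seq
    substr(s, 105, 105) <- planted[i]
    res <- map_tuning_site(s, panel)
    cls <- classify_spectral(res, "PR", TRUE)$spectral_class
    ok[i] <- cls == ifelse(planted[i] == "Q", "BPR", "GPR")
  }
  expect_true(all(ok))
})

test_that("literature overrides flip matching taxa, warn on no-match, and
           are idempotent", {
  calls <- data.frame(
    unigene_id = c("u1", "u2", "u3"),
    family = "PR", is_ppr = TRUE,
    tuning_residue = c("M", "M", "Q"),
    spectral_class = c("GPR", "GPR", "BPR"),
    lambda_max_nm = c(525, 525, 490),
    override_applied = FALSE,
    source_taxon = c("Karlodinium micrum", "Alexandrium andersonii",
                     "uncultured marine bacterium"),
    stringsAsFactors = FALSE)
  ov <- default_overrides()
  out <- suppressWarnings(apply_overrides(calls, ov))
  expect_equal(out$spectral_class, c("BPR", "GPR", "BPR"))
  expect_equal(out$lambda_max_nm, c(490, 525, 490))
  expect_equal(out$override_applied, c(TRUE, FALSE, FALSE))
  # idempotent
  out2 <- suppressWarnings(apply_overrides(out, ov))
  expect_equal(out2, out)
  # empty table is the identity
  expect_equal(apply_overrides(calls, NULL), calls)
  # unmatched pattern warns but does not error
  ov2 <- data.frame(pattern = "Nosuchtaxon weirdii", spectral_class = "BPR",
                    note = "")
  expect_warning(apply_overrides(calls, ov2), "matched no call")
})

test_that("end-to-end classification reproduces planted spectral labels and
           applies the dinoflagellate correction", {
  panel <- default_panel()
  sim <- simulate_community(simulation_config(seed = 31, n_unigenes = 60),
                            panel)
  catalog <- identify_rhodopsins(sim$unigenes, panel)
  calls_raw <- classify_rhodopsins(catalog, sim$unigenes, panel,
                                   overrides = NULL)
  truth <- sim$truth$unigenes
  m <- merge(calls_raw, truth, by = "unigene_id")
  pr <- m[m$family.y == "PR" & m$family.x == "PR", ]
  expect_gt(nrow(pr), 10)
  expect_equal(pr$spectral_class.x, pr$spectral_class.y)
  # with overrides, K. micrum / C. fusus green calls become blue
  calls_ov <- suppressWarnings(
    classify_rhodopsins(catalog, sim$unigenes, panel))
  dino <- calls_ov$source_taxon %in% c("Karlodinium micrum", "Ceratium fusus")
  if (any(dino)) {
    expect_true(all(calls_ov$spectral_class[dino] == "BPR"))
    expect_true(all(calls_ov$lambda_max_nm[dino] == 490))
  }
  # no call may pair a non-pump with a wavelength
  expect_false(any(!calls_ov$is_ppr & !is.na(calls_ov$lambda_max_nm)))
})
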