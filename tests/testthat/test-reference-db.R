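.slot_key_of <- function(e)
  paste(e$bond_anomer, e$position, e$reducing_anomer, sep = ".")

test_that("the database indexes anomer-resolved slots and rejects others", {
  maltose_a <- reference_entry("α-Glc-(1→4)-α-Glc",
                               normalise_spectrum(ms_spectrum(c(203, 347),
                                                              c(1, 0.9))))
  maltose_b <- reference_entry("α-Glc-(1→4)-β-Glc",
                               normalise_spectrum(ms_spectrum(c(203, 347),
                                                              c(1, 0.1))))
  db <- build_db(list(maltose_a, maltose_b))
  expect_setequal(names(db$entries), c("alpha.4.alpha", "alpha.4.beta"))
  # unresolved reducing anomer violates the database's defining invariant
  expect_error(reference_entry("Glc-(1→4)-Glc",
                               normalise_spectrum(ms_spectrum(203, 1))),
               "resolved")
  expect_error(reference_entry(panose_str,
                               normalise_spectrum(ms_spectrum(203, 1))),
               "2 residues")
  expect_error(build_db(list(maltose_a, maltose_a)), "duplicate")
})

test_that("the synthetic database fills all 16 slots deterministically", {
  e1 <- synth_fingerprints(seed = 7, noise = 0.05)
  e2 <- synth_fingerprints(seed = 7, noise = 0.05)
  expect_length(e1, 16L)
  for (i in seq_along(e1))
    expect_equal(e1[[i]]$spectrum$intensity, e2[[i]]$spectrum$intensity)
  db <- build_db(synth_fingerprints())
  expect_length(db$entries, 16L)
  expect_equal(db$entries[["alpha.4.alpha"]]$common_name, "maltose")
  expect_equal(db$entries[["beta.3.alpha"]]$common_name, "laminaribiose")
  expect_error(synth_fingerprints(params = within(
    default_channel_params(), trans_dehydration <- 1.5)), "\\(0, 1\\]")
})

test_that("fingerprints obey the ordinal channel rules", {
  db <- default_db()
  i347 <- function(key) {
    b <- bin_nominal(db$entries[[key]]$spectrum)
    if ("347" %in% names(b)) unname(b["347"]) else 0
  }
  # cis (alpha) reducing end dehydrates far more than trans (beta)
  expect_gt(i347("alpha.4.alpha"), i347("alpha.4.beta"))
  expect_gt(i347("beta.3.alpha"), i347("beta.3.beta"))
  # 1->6: dehydration is a minor channel (weaker than 1->4, not the base peak)
  expect_lt(i347("alpha.6.alpha"), i347("alpha.4.alpha"))
  expect_lt(i347("alpha.6.alpha"), 1.0)
  # 1->2: dehydration minor for both anomers
  expect_lt(i347("alpha.2.alpha"), 1.0)
  # linkage position selects the cross-ring ladder support
  lad <- function(key) intersect(c("245", "275", "305"),
                                 names(bin_nominal(db$entries[[key]]$spectrum)))
  expect_equal(lad("alpha.4.alpha"), "305")
  expect_equal(lad("beta.3.beta"), "275")
  expect_setequal(lad("alpha.6.beta"), c("245", "275", "305"))
  expect_length(lad("beta.2.alpha"), 0L)
})

test_that("all 16 fingerprints are mutually distinguishable at the margin", {
  db <- default_db()
  keys <- names(db$entries)
  worst <- 0
  for (a in keys) for (b in keys) {
    if (a == b) next
    v <- spectrum_similarity(db$entries[[a]]$spectrum,
                             db$entries[[b]]$spectrum)$value
    worst <- max(worst, v)
  }
  expect_lte(worst, 1 - 0.05)
  for (a in keys)
    expect_equal(spectrum_similarity(db$entries[[a]]$spectrum,
                                     db$entries[[a]]$spectrum)$value, 1.0)
})

test_that("matching recovers the generating slot and refuses noise", {
  db <- default_db()
  # self-match: every slot recovered top-1 at zero noise
  for (key in names(db$entries)) {
    mr <- match_spectrum(db$entries[[key]]$spectrum, db)
    expect_equal(mr$ranked$slot[1], key)
  }
  # noisy queries: top-1 accuracy at least 15/16 under channel jitter
  set.seed(101)
  noisy <- synth_fingerprints(seed = 202, noise = 0.1)
  hits <- sum(vapply(noisy, function(e) {
    mr <- match_spectrum(e$spectrum, db)
    mr$ranked$slot[1] == .slot_key_of(e)
  }, logical(1)))
  expect_gte(hits, 15L)
  # pure random spectra do not clear the decision margin
  set.seed(303)
  nulls <- vapply(1:12, function(i) {
    q <- normalise_spectrum(ms_spectrum(sample(150:360, 8),
                                        stats::runif(8, 0.05, 1)))
    is.null(match_spectrum(q, db)$decision)
  }, logical(1))
  expect_gte(mean(nulls), 0.75)
  expect_error(match_spectrum(ms_spectrum(numeric(), numeric()), db),
               "empty")
})

test_that("MSP and JSON database files round-trip bit-exactly", {
  db <- default_db()
  f1 <- withr::local_tempfile(fileext = ".msp")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_msp_db(db, f1)
  write_db_json(db, f2)
  for (back in list(read_msp_db(f1), read_db_json(f2))) {
    expect_setequal(names(back$entries), names(db$entries))
    for (k in names(db$entries)) {
      expect_identical(back$entries[[k]]$spectrum$mz,
                       db$entries[[k]]$spectrum$mz)
      expect_identical(back$entries[[k]]$spectrum$intensity,
                       db$entries[[k]]$spectrum$intensity)
      expect_identical(serialise_structure(back$entries[[k]]$structure),
                       serialise_structure(db$entries[[k]]$structure))
    }
  }
})
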