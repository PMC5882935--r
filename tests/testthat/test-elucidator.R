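test_that("linear trisaccharides are fully recovered with provenance", {
  rep <- elucidate_simulated(panose_str)
  expect_identical(rep$structure_string, panose_str)
  expect_true(rep$complete)
  # every bond aspect of the answer has at least one provenance record
  expect_true(all(c("1-2", "2-3") %in% rep$assignments$bond))
  # the nonreducing bond is decided by more than one route
  n23 <- sum(rep$assignments$bond == "2-3" &
             rep$assignments$aspect == "anomer")
  expect_gte(n23, 2L)
})

test_that("the isopanose-style branched case yields the partial assignment", {
  rep <- elucidate_simulated(isopanose_str)
  expect_identical(rep$structure_string,
                   "Glc-(1→4)-[α-Glc-(1→6)]-Glc")
  expect_false(rep$complete)
  expect_true(any(grepl("1->4", rep$undetermined)))
  expect_true(any(grepl("residual near zero", rep$caveats)))
})

test_that("a linear pentasaccharide chain is recovered end to end", {
  s5 <- "β-Glc-(1→4)-α-Glc-(1→6)-β-Glc-(1→3)-α-Glc-(1→4)-Glc"
  rep <- elucidate_simulated(s5)
  expect_identical(rep$structure_string, s5)
  expect_true(rep$complete)
})

test_that("branched tetrasaccharides are classified and matched per branch", {
  sII <- "β-Glc-(1→4)-β-Glc-(1→4)-[α-Glc-(1→6)]-Glc"
  repII <- elucidate_simulated(sII)
  expect_identical(repII$structure_string, sII)
  expect_true(any(grepl("extrapolated", repII$caveats)))

  sIII <- "α-Glc-(1→3)-[α-Glc-(1→6)]-β-Glc-(1→4)-Glc"
  repIII <- elucidate_simulated(sIII)
  # dominant branch anomer assigned, minor branch left unspecified
  expect_identical(repIII$structure_string,
                   "Glc-(1→3)-[α-Glc-(1→6)]-β-Glc-(1→4)-Glc")
  expect_false(repIII$complete)

  sIV <- "α-Glc-(1→3)-[α-Glc-(1→4)]-[α-Glc-(1→6)]-Glc"
  repIV <- elucidate_simulated(sIV)
  expect_true(is.na(repIV$structure_string))
  expect_true(length(repIV$undetermined) > 0)
})

test_that("elucidation only requests paths from the decisive-ion plan", {
  for (s in c(panose_str, isopanose_str, cellotetraose_str)) {
    g <- parse_structure(s)
    rep <- elucidate_simulated(s)
    plan <- decisive_ion_plan(residue_count(g))
    expect_true(all(rep$requested_paths %in% plan$path), info = s)
  }
})

test_that("a missing decisive spectrum yields a partial report naming it", {
  g <- parse_structure(panose_str)
  tree <- simulate_tree(g, model = zero_model())
  tree$spectra[["527>509>365"]] <- NULL
  tree$spectra[["527>467>365"]] <- NULL
  tree$spectra[["527>365"]] <- NULL
  rep <- elucidate(make_tree_provider(tree), 3, default_db())
  expect_false(rep$complete)
  expect_true(any(grepl("2-3", rep$undetermined)))
  # no MS2 at all: everything undetermined
  rep2 <- elucidate(function(p) NULL, 3, default_db())
  expect_false(rep2$complete)
  expect_match(rep2$undetermined[1], "MS2")
})

test_that("subtraction crosschecks behave as in the worked examples", {
  db <- default_db()
  model <- zero_model()
  # panose: mixed 527>365 minus the identified alpha-(1->6)-alpha unit,
  # nulled at 275, leaves a 1->4 bond fingerprint
  tree <- simulate_tree(parse_structure(panose_str), model = model)
  mixed <- normalise_spectrum(tree$spectra[["527>365"]])
  cs <- crosscheck_subtraction(mixed, db$entries[["alpha.6.alpha"]], db, 275)
  expect_false(cs$no_second_component)
  expect_equal(cs$match$decision$position, 4L)
  expect_equal(cs$match$decision$bond_anomer, "alpha")
  # isopanose: subtracting the alpha-(1->6) component leaves near zero
  tri <- simulate_tree(parse_structure(isopanose_str), model = model)
  mixed2 <- normalise_spectrum(tri$spectra[["527>365"]])
  ref <- glycoMSn:::.mixture_reference(db, "alpha", 6)
  cs2 <- crosscheck_subtraction(mixed2, ref, db, 275)
  expect_true(cs2$no_second_component)
  # pure reference: zero residual by construction
  cs3 <- crosscheck_subtraction(db$entries[["beta.3.beta"]]$spectrum,
                                db$entries[["beta.3.beta"]], db, 275)
  expect_true(cs3$no_second_component)
  expect_equal(attr(cs3$residual, "residual_max"), 0)
  expect_error(crosscheck_subtraction(mixed, db$entries[["alpha.4.alpha"]],
                                      db, 275), "absent")
})

test_that("the audit records crosschecks and downgrades conflicts", {
  rep <- elucidate_simulated(panose_str)
  audit <- rep$audit
  expect_true(all(audit$agree))
  # multiply-determined: the 2-3 anomer; single-source rows are flagged
  expect_gte(audit$n_sources[audit$bond == "2-3" &
                             audit$aspect == "anomer"], 2L)
  # a single-source assignment is flagged as lacking a crosscheck
  iso_audit <- elucidate_simulated(isopanose_str)$audit
  expect_true(any(iso_audit$note == "no crosscheck"))
  # inject a conflicting determination: the assignment must downgrade
  rep$assignments <- rbind(rep$assignments, data.frame(
    bond = "2-3", aspect = "anomer", value = "beta",
    source = "injected-conflict", stringsAsFactors = FALSE))
  rep2 <- consistency_audit(rep)
  expect_false(rep2$audit$agree[rep2$audit$bond == "2-3" &
                                rep2$audit$aspect == "anomer"])
  g2 <- rep2$structure
  expect_equal(g2$root$children[[1]]$residue$children[[1]]$anomeric,
               "unspecified")
  expect_true(any(grepl("disagreeing", rep2$caveats)))
  expect_false(rep2$complete)
})
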