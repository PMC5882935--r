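test_that("MS2 loss patterns map to the documented linkage hypotheses", {
  # -18/-60: the documented linear(1->4) / branched(1->6,1->4) ambiguity
  h <- reducing_linkage_candidates(c(18, 60), 3)
  expect_setequal(paste(h$topology, h$positions), c("linear 4", "branched 6,4"))
  expect_true(all(h$status == "candidate"))
  # the full ladder pins a 1->6 reducing linkage uniquely
  h6 <- reducing_linkage_candidates(c(18, 60, 90, 120), 3)
  expect_equal(nrow(h6), 1L)
  expect_equal(paste(h6$topology, h6$positions), "linear 6")
  # an empty pattern is the kojibiose/sophorose class, with its caveat
  h2 <- reducing_linkage_candidates(integer(), 3)
  expect_equal(paste(h2$topology, h2$positions), "linear 2")
  expect_match(h2$caveat, "minor")
  # a pattern no assignment expects is an error naming the losses
  expect_error(reducing_linkage_candidates(c(120), 3), "inconsistent")
  expect_error(reducing_linkage_candidates(c(17), 3), "18, 60, 90, 120")
})

test_that("the pattern table collisions are exactly the resolvable ones", {
  tab <- loss_pattern_table()
  key <- vapply(tab$losses, function(x)
    paste(sort(as.integer(strsplit(x, ",")[[1]])), collapse = "+"),
    character(1))
  dup <- split(paste(tab$topology, tab$positions), key)
  collisions <- dup[lengths(dup) > 1]
  # the documented linear(1->4)/branched(1->6,1->4) collision is present,
  # the same mechanism also collides linear(1->3) with branched(1->6,1->3)
  # and the two -60-only branched pairs; all are separated downstream
  expect_setequal(
    unname(vapply(collisions, paste, character(1), collapse = " | ")),
    c("linear 4 | branched 6,4",
      "linear 3 | branched 6,3",
      "branched 6,2 | branched 4,2"))
  # every unambiguous row has a unique loss set
  expect_equal(sum(lengths(dup) == 1), nrow(tab) - 6L)
})

test_that("follow-up CID separates linear from branched trisaccharides", {
  lin509 <- normalise_spectrum(ms_spectrum(c(203, 347, 365), c(0.4, 0.2, 1)))
  br509 <- normalise_spectrum(ms_spectrum(c(203, 347), c(1, 0.4)))
  lin467 <- normalise_spectrum(ms_spectrum(c(203, 305, 347, 365),
                                           c(0.4, 0.3, 0.4, 1)))
  br467 <- normalise_spectrum(ms_spectrum(c(203, 305), c(1, 0.3)))
  expect_equal(resolve_linear_vs_branched(lin509, NULL)$topology, "linear")
  expect_equal(resolve_linear_vs_branched(NULL, lin467)$topology, "linear")
  expect_equal(resolve_linear_vs_branched(br509, br467)$topology, "branched")
  amb <- resolve_linear_vs_branched(br509, lin467)
  expect_equal(amb$topology, "ambiguous")
  expect_match(amb$warning, "disagree")
  none <- resolve_linear_vs_branched(NULL, NULL)
  expect_equal(none$topology, "ambiguous")
})

test_that("tetrasaccharide classification assigns I-IV from simulated trees", {
  model <- zero_model()
  structures <- list(
    I   = cellotetraose_str,
    II  = "β-Glc-(1→4)-β-Glc-(1→4)-[α-Glc-(1→6)]-Glc",
    III = "α-Glc-(1→3)-[α-Glc-(1→6)]-β-Glc-(1→4)-Glc",
    IV  = "α-Glc-(1→3)-[α-Glc-(1→4)]-[α-Glc-(1→6)]-Glc")
  for (cls in names(structures)) {
    g <- parse_structure(structures[[cls]])
    tree <- simulate_tree(g, model = model)
    ms2 <- normalise_spectrum(tree$spectra[["689"]])
    losses <- observed_losses(ms2, 4)
    opened_key <- paste0("689>", 689 - intersect(c(60, 90, 18), losses)[1])
    opened <- normalise_spectrum(tree$spectra[[opened_key]])
    res <- classify_tetrasaccharide(ms2, opened)
    expect_equal(res$class, cls, info = structures[[cls]])
    expect_true(length(res$caveats) > 0)   # footnote exceptions never silent
  }
  # missing the decisive second spectrum -> undetermined, naming the step
  g <- parse_structure(cellotetraose_str)
  ms2 <- simulate_cid(g, zero_model())
  u <- classify_tetrasaccharide(ms2, NULL)
  expect_equal(u$class, "undetermined")
  expect_match(u$missing, "689")
  # wrong precursor rejected
  ms2_tri <- simulate_cid(parse_structure(panose_str), zero_model())
  expect_error(classify_tetrasaccharide(ms2_tri), "689")
})

test_that("acquisition plans contain the decisive paths", {
  p3 <- decisive_ion_plan(3)
  expect_true(all(c("527", "527>509", "527>467", "527>509>365",
                    "527>467>365", "527>365") %in% p3$path))
  p4 <- decisive_ion_plan(4)
  expect_true(all(c("689", "689>629", "689>629>365", "689>629>467",
                    "689>629>467>365", "689>365") %in% p4$path))
  p2 <- decisive_ion_plan(2)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$role, "disaccharide_id")
  p5 <- decisive_ion_plan(5)
  expect_true(all(c("851", "851>791>365", "851>791>629>365",
                    "851>791>629>467>365", "851>365") %in% p5$path))
  expect_error(decisive_ion_plan(6))
})

test_that("every planned m/z is producible by the fragment calculus", {
  for (n in 2:5) {
    plan <- decisive_ion_plan(n)
    universe <- unlist(lapply(seq_len(n), function(k)
      vapply(c("none", "H2O", "C2H4O2", "C3H6O3", "C4H8O4"),
             function(l) sodiated_nominal(k, l), integer(1))))
    for (p in plan_paths(plan))
      expect_true(all(p %in% universe),
                  info = paste(p, collapse = ">"))
  }
})

test_that("plans export as JSON and render as a text tree", {
  plan <- decisive_ion_plan(3)
  f <- withr::local_tempfile(fileext = ".json")
  write_plan_json(plan, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$path, plan$path)
  txt <- format_plan_tree(plan)
  expect_length(txt, nrow(plan))
  expect_match(txt[1], "527")
})
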