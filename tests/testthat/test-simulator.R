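test_that("disaccharide CID reproduces the fingerprint phenomenology", {
  model <- zero_model()
  # alpha-(1->4)-alpha maltose: prominent dehydration at 347
  malt <- simulate_cid(parse_structure("α-Glc-(1→4)-α-Glc"), model)
  b <- bin_nominal(malt)
  expect_true(b["347"] >= 0.9)
  # the trans anomer barely dehydrates
  malt_b <- simulate_cid(parse_structure("α-Glc-(1→4)-β-Glc"), model)
  bb <- bin_nominal(malt_b)
  expect_lt(unname(bb["347"]), 0.2)
  # monosaccharide: no open channels
  mono <- simulate_cid(parse_structure("Glc"), model)
  expect_length(mono$mz, 0L)
})

test_that("an opened precursor only fragments glycosidically", {
  model <- zero_model()
  g <- parse_structure(panose_str)
  opened <- sodiated_species(g, "opened", "C2H4O2")   # the 467 ion
  s <- simulate_cid(opened, model)
  b <- bin_nominal(s)
  expect_true(all(c("365", "347", "305", "203") %in% names(b)))
  expect_false("467" %in% names(b))
  expect_error(simulate_cid(structure(list(), class = "junk"), model),
               "provenance")
  expect_error(sodiated_species(g, "opened"), "loss")
})

test_that("simulation is deterministic under a fixed seed", {
  g <- parse_structure(panose_str)
  t1 <- simulate_tree(g, model = channel_model(noise = 0.1, seed = 42))
  t2 <- simulate_tree(g, model = channel_model(noise = 0.1, seed = 42))
  for (k in names(t1$spectra)) {
    expect_identical(t1$spectra[[k]]$mz, t2$spectra[[k]]$mz)
    expect_identical(t1$spectra[[k]]$intensity, t2$spectra[[k]]$intensity)
  }
  # distinct seeds jitter intensities but not peak positions
  t3 <- simulate_tree(g, model = channel_model(noise = 0.1, seed = 43))
  expect_identical(t1$spectra[["527"]]$mz, t3$spectra[["527"]]$mz)
  expect_false(identical(t1$spectra[["527"]]$intensity,
                         t3$spectra[["527"]]$intensity))
})

test_that("every simulated peak is assignable by the fragment calculus", {
  model <- zero_model()
  for (s in c(linear_tri_panel()[c(1, 8, 15, 22, 29, 36)],
              branched_tri_panel()[c(1, 6, 11)], cellotetraose_str,
              isopanose_str)) {
    g <- parse_structure(s)
    n <- residue_count(g)
    universe <- unlist(lapply(seq_len(n), function(k)
      vapply(c("none", "H2O", "C2H4O2", "C3H6O3", "C4H8O4"),
             function(l) sodiated_nominal(k, l), integer(1))))
    tree <- simulate_tree(g, model = model)
    for (k in names(tree$spectra)) {
      pk <- round(tree$spectra[[k]]$mz)
      expect_true(all(pk %in% universe),
                  info = paste(s, k, paste(setdiff(pk, universe),
                                           collapse = ",")))
    }
  }
})

test_that("isolation of an isobaric m/z yields the weighted mixture", {
  # the 527>365 spectrum is the convex combination of the C2 (nonreducing,
  # resolved) and Y2 (reducing-side, solution mixture) disaccharide CIDs
  model <- zero_model()
  g <- parse_structure(panose_str)
  tree <- simulate_tree(g, model = model)
  mixed <- normalise_spectrum(tree$spectra[["527>365"]])
  c2 <- simulate_cid(parse_structure("α-Glc-(1→6)-α-Glc"), model)
  y2 <- simulate_cid(parse_structure("α-Glc-(1→4)-Glc"), model)
  keys <- sort(unique(c(names(bin_nominal(c2)), names(bin_nominal(y2)),
                        names(bin_nominal(mixed)))))
  vec <- function(s) {
    b <- bin_nominal(s)
    x <- stats::setNames(numeric(length(keys)), keys)
    x[names(b)] <- b
    x
  }
  A <- cbind(vec(c2), vec(y2))
  y <- vec(mixed)
  w <- solve(crossprod(A), crossprod(A, y))
  expect_true(all(w > 0))
  expect_lt(max(abs(y - A %*% w)), 1e-9)   # exact at zero noise
})

test_that("branch cleavage is biased to the lower acceptor position", {
  # isopanose: the 527>365 population is mainly the (root + 1->6 branch)
  # disaccharide, so the mixed spectrum matches the 1->6 bond best
  model <- zero_model()
  tree <- simulate_tree(parse_structure(isopanose_str), model = model)
  mixed <- normalise_spectrum(tree$spectra[["527>365"]])
  mb <- match_bond_spectrum(mixed, default_db())
  expect_equal(mb$ranked$position[1], 6L)
  expect_equal(mb$ranked$bond_anomer[1], "alpha")
  # with symmetric bias both branch populations appear
  sym <- channel_model(noise = 0, seed = 1, branch_bias = 0.5)
  tree2 <- simulate_tree(parse_structure(isopanose_str), model = sym)
  mixed2 <- normalise_spectrum(tree2$spectra[["527>365"]])
  ref6 <- default_db()$entries[["alpha.6.alpha"]]$spectrum
  r <- subtract_spectrum(mixed2, ref6, 275)
  expect_gt(attr(r, "residual_max"), 0.2)   # the 1->4 component remains
})

test_that("unreachable paths and monosaccharides degrade gracefully", {
  model <- zero_model()
  # a 1->3 reducing linkage opens no -60 channel: the 527>467 path is
  # unreachable and the provider reports it unavailable
  g <- parse_structure("α-Glc-(1→4)-α-Glc-(1→3)-Glc")
  tree <- simulate_tree(g, model = model)
  expect_true(isTRUE(tree$spectra[["527>467"]]$metadata$unreachable))
  expect_null(make_tree_provider(tree)(c(527, 467)))
  mono_tree <- simulate_tree(parse_structure("Glc"), model = model)
  expect_length(mono_tree$spectra, 0L)
})

test_that("spectral trees round-trip through JSON and MGF directories", {
  tree <- simulate_tree(parse_structure(panose_str), model = zero_model())
  f <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, f)
  back <- read_tree_json(f)
  expect_setequal(names(back$spectra), names(tree$spectra))
  expect_equal(back$n, 3L)
  expect_identical(back$spectra[["527>365"]]$intensity,
                   tree$spectra[["527>365"]]$intensity)
  d <- withr::local_tempdir()
  write_tree_mgf(tree, d)
  back2 <- read_tree_mgf(d)
  expect_setequal(names(back2$spectra), names(tree$spectra))
  expect_equal(back2$n, 3L)
  expect_equal(back2$spectra[["527>365"]]$mz, tree$spectra[["527>365"]]$mz,
               tolerance = 1e-4)
})
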