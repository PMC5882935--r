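# De novo elucidation: walk the decisive-ion plan against a spectrum
# provider, read the reducing-linkage pattern off the MS2, separate linear
# from branched topologies, identify disaccharide units against the
# anomer-resolved database (C-type products inherit the cleaved bond's
# configuration, which chains interior anomer assignments together), and
# crosscheck the reducing-side disaccharide by weighted subtraction of the
# mixed m/z 365 spectrum. Every bond of the report carries provenance;
# disagreeing crosschecks downgrade an anomer to unspecified.

.position_ladder <- function(pos) {
  switch(as.character(pos),
         `2` = integer(), `3` = 275L, `4` = 305L,
         `6` = c(305L, 275L, 245L), integer())
}

#' Pick the subtraction zero ion for an identified component
#'
#' The most intense ion of the reference fingerprint that is unique to the
#' identified component's cross-ring ladder (so the other component cannot
#' contribute to it). The worked trisaccharide examples use m/z 275, the
#' 0,3A ion unique to the 1->6 ladder against a 1->4 partner.
#'
#' @param ref_position linkage position of the identified component
#' @param other_position linkage position of the co-isolated component
#' @param ref_spectrum the identified component's fingerprint
#' @return nominal m/z, or NA when no unique ladder ion exists
#' @export
choose_zero_ion <- function(ref_position, other_position, ref_spectrum) {
  cand <- setdiff(.position_ladder(ref_position),
                  .position_ladder(other_position))
  if (!length(cand)) return(NA_integer_)
  b <- bin_nominal(ref_spectrum)
  ints <- b[as.character(cand)]
  ints[is.na(ints)] <- 0
  cand[which.max(ints)]
}

# reconstruct the solution-mixture (50/50 reducing-anomer) reference for a
# given bond anomer and position from the two resolved database entries.
# Entries are base-peak normalised with possibly different base peaks, so
# the beta entry is rescaled onto the alpha entry via the strongest shared
# non-dehydration peak before averaging.
.mixture_reference <- function(db, bond_anomer, position) {
  e1 <- db$entries[[.slot_key(bond_anomer, position, "alpha")]]
  e2 <- db$entries[[.slot_key(bond_anomer, position, "beta")]]
  if (is.null(e1) || is.null(e2)) return(NULL)
  v1 <- bin_nominal(e1$spectrum); v2 <- bin_nominal(e2$spectrum)
  shared <- setdiff(intersect(names(v1), names(v2)), "347")
  if (!length(shared)) return(NULL)
  anchor <- shared[which.max(v1[shared])]
  v2 <- v2 * (v1[[anchor]] / v2[[anchor]])
  keys <- union(names(v1), names(v2))
  x1 <- stats::setNames(numeric(length(keys)), keys)
  x2 <- x1
  x1[names(v1)] <- v1; x2[names(v2)] <- v2
  avg <- (x1 + x2) / 2
  normalise_spectrum(ms_spectrum(as.numeric(names(avg)), avg,
                                 precursor_path = 365L))
}

#' Match a mixture-reducing-end spectrum at the bond level
#'
#' A disaccharide population that retains the original reducing sugar
#' (a Y-type fragment) carries the solution 50/50 anomer mixture at its
#' reducing end, so it should be compared against anomer-averaged
#' references, one per (bond anomer, linkage position). The decision is a
#' bond assignment - the dual-citation convention ("alpha-(1->4)-alpha or
#' alpha-(1->4)-beta") collapsed to its shared bond.
#'
#' @param query normalised [ms_spectrum()]
#' @param db a [build_db()] database with both reducing anomers per bond
#' @param margin top-1/top-2 margin for a decision
#' @return list: ranked (bond_anomer, position, similarity), decision
#'   (list(bond_anomer, position) or NULL), margin_met
#' @export
match_bond_spectrum <- function(query, db, margin = 0.05) {
  stopifnot(inherits(db, "disaccharide_db"))
  if (!length(query$mz)) stop("empty query spectrum")
  rows <- list()
  for (a in c("alpha", "beta")) {
    for (p in DISACCH_POSITIONS) {
      ref <- .mixture_reference(db, a, p)
      if (is.null(ref)) next
      rows[[length(rows) + 1L]] <- data.frame(
        bond_anomer = a, position = p,
        similarity = spectrum_similarity(query, ref)$value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("database lacks resolved anomer pairs")
  ranked <- do.call(rbind, rows)
  ranked <- ranked[order(ranked$similarity, decreasing = TRUE), ]
  rownames(ranked) <- NULL
  margin_met <- nrow(ranked) == 1L ||
    (ranked$similarity[1] - ranked$similarity[2]) >= margin
  list(ranked = ranked,
       decision = if (margin_met)
         list(bond_anomer = ranked$bond_anomer[1],
              position = ranked$position[1]) else NULL,
       margin_met = margin_met)
}

#' Subtraction crosscheck of a mixed disaccharide spectrum
#'
#' Subtracts the identified component's fingerprint from the mixed
#' spectrum (weight chosen to null `zero_ion`) and matches the residual
#' against the database. A residual whose pre-normalisation maximum stays
#' below `near_zero` means no second component was co-isolated (the
#' isopanose outcome: one branch cleaves almost exclusively).
#'
#' @param mixed_path_spectrum normalised mixed spectrum (e.g. path 527>365)
#' @param identified_ref a [reference_entry()] or [ms_spectrum()] for the
#'   already-identified component
#' @param db the disaccharide database
#' @param zero_ion nominal m/z unique to the identified component
#' @param near_zero residual cutoff for "no second component"
#' @param margin match margin
#' @param bond_level match the residual with [match_bond_spectrum()]
#'   (appropriate when the residual population retains the original
#'   solution-mixture reducing end) instead of [match_spectrum()]
#' @return list: no_second_component, residual ([ms_spectrum()]), match
#'   (a `match_result` / bond-level match or NULL), weight
#' @export
crosscheck_subtraction <- function(mixed_path_spectrum, identified_ref, db,
                                   zero_ion, near_zero = 0.05,
                                   margin = 0.05, bond_level = TRUE) {
  refspec <- if (inherits(identified_ref, "reference_entry"))
    identified_ref$spectrum else identified_ref
  if (!inherits(refspec, "ms_spectrum")) stop("invalid reference")
  residual <- subtract_spectrum(mixed_path_spectrum, refspec, zero_ion)
  if (attr(residual, "residual_max") < near_zero)
    return(list(no_second_component = TRUE, residual = residual,
                match = NULL, weight = attr(residual, "weight")))
  m <- if (bond_level) match_bond_spectrum(residual, db, margin)
       else match_spectrum(residual, db, margin)
  list(no_second_component = FALSE, residual = residual, match = m,
       weight = attr(residual, "weight"))
}

# ---- report assembly ----------------------------------------------------

.new_collector <- function() {
  env <- new.env()
  env$assignments <- list()
  env$caveats <- character()
  env$undetermined <- character()
  env
}

.add_assign <- function(col, bond, aspect, value, source) {
  col$assignments[[length(col$assignments) + 1L]] <-
    data.frame(bond = bond, aspect = aspect, value = as.character(value),
               source = source, stringsAsFactors = FALSE)
}

.add_caveat <- function(col, msg) col$caveats <- union(col$caveats, msg)
.add_undet <- function(col, msg) col$undetermined <- union(col$undetermined, msg)

.assignment_frame <- function(col) {
  if (!length(col$assignments))
    return(data.frame(bond = character(), aspect = character(),
                      value = character(), source = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, col$assignments)
}

# resolve assignments: unique agreed value, or NA on conflict
.resolve_assignments <- function(assigns) {
  out <- list()
  if (!nrow(assigns)) return(out)
  for (key in unique(paste(assigns$bond, assigns$aspect, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    vals <- unique(assigns$value[assigns$bond == parts[1] &
                                 assigns$aspect == parts[2]])
    out[[parts[1]]][[parts[2]]] <- if (length(vals) == 1L) vals else NA_character_
  }
  out
}

.val_anomer <- function(values, bond) {
  a <- values[[bond]][["anomer"]]
  if (is.null(a) || is.na(a)) "unspecified" else a
}
.val_position <- function(values, bond) {
  p <- values[[bond]][["position"]]
  if (is.null(p) || is.na(p)) NA_integer_ else as.integer(p)
}

# build a glycan_structure from resolved per-bond values and a topology
# descriptor; NULL when a required position is missing
.build_structure <- function(topology, values) {
  leaf <- function() glycan_residue()
  switch(topology$kind,
    linear = {
      n <- topology$n
      sub <- leaf()
      for (k in seq(n - 1L, 1L)) {
        bond <- sprintf("%d-%d", k, k + 1L)
        p <- .val_position(values, bond)
        if (is.na(p)) return(NULL)
        sub <- glycan_residue(list(.link(.val_anomer(values, bond), p, sub)))
      }
      glycan_structure(sub)
    },
    branched3 = {
      kids <- lapply(topology$positions, function(p)
        .link(.val_anomer(values, sprintf("root@%d", p)), p, leaf()))
      glycan_structure(glycan_residue(kids))
    },
    tetraII = {
      if (is.na(topology$p_chain) || is.na(topology$p_leaf)) return(NULL)
      pout <- .val_position(values, "chain-outer")
      if (is.na(pout)) return(NULL)
      chain <- glycan_residue(list(
        .link(.val_anomer(values, "chain-outer"), pout, leaf())))
      kids <- list(
        .link(.val_anomer(values, sprintf("root@%d", topology$p_chain)),
              topology$p_chain, chain),
        .link(.val_anomer(values, sprintf("root@%d", topology$p_leaf)),
              topology$p_leaf, leaf()))
      glycan_structure(glycan_residue(kids))
    },
    tetraIII = {
      p1 <- .val_position(values, "1-2")
      if (is.na(p1) || any(is.na(topology$branch_positions))) return(NULL)
      kids <- lapply(topology$branch_positions, function(p)
        .link(.val_anomer(values, sprintf("res2@%d", p)), p, leaf()))
      res2 <- glycan_residue(kids)
      glycan_structure(glycan_residue(list(
        .link(.val_anomer(values, "1-2"), p1, res2))))
    },
    NULL)
}

.make_report <- function(col, topology, n, requested) {
  assigns <- .assignment_frame(col)
  values <- .resolve_assignments(assigns)
  # conflicts found during resolution become caveats + downgrades
  for (bond in names(values)) {
    for (aspect in names(values[[bond]])) {
      if (is.na(values[[bond]][[aspect]]))
        .add_caveat(col, sprintf(
          "disagreeing determinations for %s of bond %s; downgraded to unspecified",
          aspect, bond))
    }
  }
  g <- if (!is.null(topology)) .build_structure(topology, values) else NULL
  structure(list(
    structure = g,
    structure_string = if (!is.null(g)) serialise_structure(g) else NA_character_,
    n = n,
    topology = topology,
    assignments = assigns,
    caveats = col$caveats,
    undetermined = col$undetermined,
    complete = length(col$undetermined) == 0L && !is.null(g),
    requested_paths = requested()),
    class = "elucidation_report")
}

#' @export
print.elucidation_report <- function(x, ...) {
  cat("<elucidation_report>\n")
  cat("  structure : ", if (is.na(x$structure_string)) "(undetermined)"
      else x$structure_string, "\n", sep = "")
  cat("  complete  : ", x$complete, "\n", sep = "")
  if (nrow(x$assignments)) {
    cat("  provenance:\n")
    for (i in seq_len(nrow(x$assignments)))
      cat(sprintf("    %-12s %-9s %-12s <- %s\n", x$assignments$bond[i],
                  x$assignments$aspect[i], x$assignments$value[i],
                  x$assignments$source[i]))
  }
  for (cv in x$caveats) cat("  caveat: ", cv, "\n", sep = "")
  for (u in x$undetermined) cat("  undetermined: ", u, "\n", sep = "")
  invisible(x)
}

#' Audit multiply-determined assignments of a report
#'
#' For every bond aspect decided by more than one CID step the audit
#' records whether the determinations agree; any disagreement downgrades
#' that assignment to unspecified (with a caveat) in the returned report.
#' Single-source assignments are flagged "no crosscheck".
#'
#' @param report an `elucidation_report`
#' @return the report, with an `audit` data.frame element and any
#'   downgrades applied
#' @export
consistency_audit <- function(report) {
  a <- report$assignments
  keys <- unique(paste(a$bond, a$aspect, sep = "|"))
  audit <- do.call(rbind, lapply(keys, function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sel <- a$bond == parts[1] & a$aspect == parts[2]
    vals <- unique(a$value[sel])
    data.frame(bond = parts[1], aspect = parts[2],
               n_sources = sum(sel),
               agree = length(vals) == 1L,
               values = paste(sort(vals), collapse = "/"),
               note = if (sum(sel) == 1L) "no crosscheck" else "",
               stringsAsFactors = FALSE)
  }))
  if (is.null(audit))
    audit <- data.frame(bond = character(), aspect = character(),
                        n_sources = integer(), agree = logical(),
                        values = character(), note = character())
  if (any(!audit$agree)) {
    col <- .new_collector()
    col$assignments <- list(a)
    col$caveats <- report$caveats
    col$undetermined <- report$undetermined
    for (i in which(!audit$agree))
      .add_undet(col, sprintf("%s of bond %s (conflicting determinations)",
                              audit$aspect[i], audit$bond[i]))
    report2 <- .make_report(col, report$topology, report$n,
                            function() report$requested_paths)
    report2$audit <- audit
    return(report2)
  }
  report$audit <- audit
  report
}

# ---- the procedure ------------------------------------------------------

#' Elucidate a structure from a spectrum provider
#'
#' Runs the decision procedure against any provider (typically
#' [make_tree_provider()] over a [simulate_tree()] result, or recorded
#' spectra loaded from MGF): step 1 reads the reducing-sugar linkage
#' pattern off the MS2; the CID of the dehydration / cross-ring products
#' separates linear from branched; disaccharide units produced from
#' ring-opened precursors are matched against the anomer-resolved
#' database, with C-ion anomer inheritance settling interior bond
#' configurations; and the mixed m/z 365 spectrum is subtraction-checked
#' for the reducing-side disaccharide. The reducing-end anomer is always
#' reported unspecified (both solution anomers coexist).
#'
#' @param provider function(path) -> [ms_spectrum()] or NULL
#' @param n residue count (3, 4, or 5 for linear chains)
#' @param db a [build_db()] disaccharide database
#' @param threshold presence / normalisation threshold
#' @param margin database match margin
#' @param near_zero subtraction residual cutoff
#' @return an `elucidation_report`
#' @export
elucidate <- function(provider, n, db, threshold = 0.01, margin = 0.05,
                      near_zero = 0.05) {
  stopifnot(n %in% 3:5)
  n <- as.integer(n)
  M <- sodiated_nominal(n)
  plan <- decisive_ion_plan(n)
  allowed <- plan$path
  requested <- character()
  request <- function(p) {
    key <- paste(p, collapse = ">")
    stopifnot(key %in% allowed)   # measurement economy: plan paths only
    requested <<- union(requested, key)
    s <- provider(p)
    if (is.null(s)) return(NULL)
    normalise_spectrum(s, threshold)
  }
  col <- .new_collector()
  get_requested <- function() requested

  ms2 <- request(M)
  if (is.null(ms2)) {
    .add_undet(col, sprintf("everything: MS2 of m/z %d unavailable", M))
    return(.make_report(col, NULL, n, get_requested))
  }
  losses <- observed_losses(ms2, n, threshold)
  cand <- tryCatch(reducing_linkage_candidates(losses, n, threshold),
                   error = function(e) {
                     .add_caveat(col, conditionMessage(e))
                     NULL
                   })

  if (n == 3L) {
    .elucidate_tri(col, M, ms2, losses, cand, request, db, threshold,
                   margin, near_zero)
  } else if (n == 4L) {
    return(.elucidate_tetra(col, M, ms2, losses, cand, request, db,
                            threshold, margin, near_zero, get_requested))
  } else {
    .elucidate_linear(col, n, M, losses, cand, request, db, threshold,
                      margin, near_zero)
  }
  topo <- col$topology
  consistency_audit(.make_report(col, topo, n, get_requested))
}

# match a disaccharide spectrum; assign the outer bond (position + bond
# anomer) and, when the reducing anomer is resolved, the inner bond's
# anomer by C-ion inheritance. Returns the identified entry (resolved or
# top-ranked) or NULL.
.match_disacch <- function(col, spec, db, outer_bond, inner_bond, source,
                           margin) {
  mr <- match_spectrum(spec, db, margin)
  if (mr$margin_met) {
    e <- mr$decision
    .add_assign(col, outer_bond, "position", e$position, source)
    .add_assign(col, outer_bond, "anomer", e$bond_anomer, source)
    if (!is.null(inner_bond))
      .add_assign(col, inner_bond, "anomer", e$reducing_anomer,
                  paste0(source, "+inheritance"))
    return(e)
  }
  if (mr$same_bond_top2) {
    # dual citation: bond assignment accepted, reducing anomer open
    e <- db$entries[[mr$ranked$slot[1]]]
    .add_assign(col, outer_bond, "position", e$position, source)
    .add_assign(col, outer_bond, "anomer", e$bond_anomer, source)
    if (!is.null(inner_bond))
      .add_caveat(col, sprintf(
        "reducing anomer of the %s unit unresolved (dual citation); no inheritance to bond %s",
        outer_bond, inner_bond))
    return(e)
  }
  .add_caveat(col, sprintf("ambiguous database match at %s", source))
  NULL
}

.route_losses <- function(n, losses) {
  pref <- if (n == 3L) c(18L, 60L, 90L) else c(60L, 90L, 18L)
  pref[pref %in% losses]
}

.linear_position <- function(cand) {
  sel <- cand$topology == "linear"
  if (!any(sel)) return(NA_integer_)
  as.integer(cand$positions[sel][1])
}

.branched_pair <- function(cand) {
  sel <- cand$topology == "branched"
  if (!any(sel)) return(NULL)
  lapply(which(sel), function(i)
    as.integer(strsplit(cand$positions[i], ",")[[1]]))
}

# shared tail: subtraction crosscheck of the mixed [M, 365] spectrum
# against the identified nonreducing disaccharide, feeding bond "1-2"
.subtraction_tail <- function(col, M, request, db, outer_entry, p1, margin,
                              near_zero) {
  if (is.null(outer_entry) || is.na(p1)) return(invisible())
  mixed <- request(c(M, 365L))
  if (is.null(mixed)) return(invisible())
  z <- choose_zero_ion(outer_entry$position, p1, outer_entry$spectrum)
  if (is.na(z)) {
    .add_caveat(col, "no ladder ion unique to the identified component; subtraction crosscheck skipped")
    return(invisible())
  }
  cs <- crosscheck_subtraction(mixed, outer_entry, db, z, near_zero, margin)
  src <- sprintf("subtraction:%d>365 minus %s", M,
                 serialise_structure(outer_entry$structure))
  if (cs$no_second_component) {
    .add_caveat(col, "mixed-spectrum residual near zero: no reducing-side disaccharide population recovered")
    return(invisible())
  }
  mr <- cs$match
  if (mr$margin_met) {
    .add_assign(col, "1-2", "position", mr$decision$position, src)
    .add_assign(col, "1-2", "anomer", mr$decision$bond_anomer, src)
  } else {
    .add_caveat(col, "subtraction residual matched no unique linkage")
  }
  invisible()
}

# ---- trisaccharide ------------------------------------------------------

.elucidate_tri <- function(col, M, ms2, losses, cand, request, db,
                           threshold, margin, near_zero) {
  if (is.null(cand)) {
    .add_undet(col, "reducing-sugar linkage set (inconsistent MS2 pattern)")
    col$topology <- NULL
    return(invisible())
  }
  has_linear <- any(cand$topology == "linear")
  has_branched <- any(cand$topology == "branched")
  topology <- if (has_linear && !has_branched) "linear"
              else if (has_branched && !has_linear) "branched"
              else NA_character_
  s_dehy <- if (18L %in% losses) request(c(M, M - 18L)) else NULL
  a_loss <- intersect(c(60L, 90L), losses)
  s_a <- if (length(a_loss)) request(c(M, M - a_loss[1])) else NULL
  if (is.na(topology)) {
    res <- resolve_linear_vs_branched(s_dehy, s_a, 3L, threshold)
    if (!is.null(res$warning)) .add_caveat(col, res$warning)
    topology <- res$topology
  }
  if (identical(topology, "linear")) {
    p1 <- .linear_position(cand)
    .elucidate_linear(col, 3L, M, losses, cand, request, db, threshold,
                      margin, near_zero)
  } else if (identical(topology, "branched")) {
    pairs <- .branched_pair(cand)
    if (is.null(pairs) || length(pairs) != 1L) {
      .add_caveat(col, "branched linkage pair ambiguous from the MS2 pattern")
      .add_undet(col, "branch linkage positions")
      col$topology <- NULL
      return(invisible())
    }
    .elucidate_branched3(col, M, pairs[[1]], request, db, margin, near_zero)
  } else {
    .add_undet(col, "topology (linear vs branched) undecided; need CID of the -18/-60 products")
    col$topology <- NULL
  }
  invisible()
}

.elucidate_branched3 <- function(col, M, pair, request, db, margin,
                                 near_zero) {
  pair <- sort(pair, decreasing = TRUE)
  col$topology <- list(kind = "branched3", positions = pair)
  for (p in pair)
    .add_assign(col, sprintf("root@%d", p), "position", p, "ms2-pattern")
  mixed <- request(c(M, 365L))
  if (is.null(mixed)) {
    .add_undet(col, "branch anomers (mixed 365 spectrum unavailable)")
    return(invisible())
  }
  mb <- match_bond_spectrum(mixed, db, margin)
  if (!mb$margin_met) {
    .add_caveat(col, "mixed-spectrum match ambiguous across linkages")
    .add_undet(col, "branch anomers")
    return(invisible())
  }
  a_dom <- mb$decision$bond_anomer; p_dom <- mb$decision$position
  if (!(p_dom %in% pair)) {
    .add_caveat(col, sprintf(
      "dominant mixed-component linkage 1->%d not among the MS2 branch pair", p_dom))
    .add_undet(col, "branch anomers")
    return(invisible())
  }
  src <- sprintf("mixture-match:%d>365", M)
  .add_assign(col, sprintf("root@%d", p_dom), "anomer", a_dom, src)
  p_other <- setdiff(pair, p_dom)
  # the co-isolated population keeps the (solution-mixture) reducing end,
  # so the subtraction reference is the anomer-averaged fingerprint
  refmix <- .mixture_reference(db, a_dom, p_dom)
  z <- if (!is.null(refmix)) choose_zero_ion(p_dom, p_other, refmix)
       else NA_integer_
  if (is.null(refmix) || is.na(z)) {
    .add_undet(col, sprintf("anomer of branch 1->%d", p_other))
    return(invisible())
  }
  cs <- crosscheck_subtraction(mixed, refmix, db, z, near_zero, margin)
  if (cs$no_second_component) {
    .add_caveat(col, sprintf(
      "residual near zero: almost no 1->%d disaccharide produced; its anomer is undetermined",
      p_other))
    .add_undet(col, sprintf("anomer of branch 1->%d", p_other))
    return(invisible())
  }
  mr2 <- cs$match
  e2 <- if (mr2$margin_met) mr2$decision else NULL
  if (!is.null(e2) && e2$position == p_other) {
    .add_assign(col, sprintf("root@%d", p_other), "anomer", e2$bond_anomer,
                sprintf("subtraction:%d>365", M))
  } else {
    .add_caveat(col, "subtraction residual inconsistent with the second branch linkage")
    .add_undet(col, sprintf("anomer of branch 1->%d", p_other))
  }
  invisible()
}

# ---- linear chains (n = 3, 4, 5) ---------------------------------------

.elucidate_linear <- function(col, n, M, losses, cand, request, db,
                              threshold, margin, near_zero) {
  col$topology <- list(kind = "linear", n = n)
  p1 <- if (!is.null(cand)) .linear_position(cand) else NA_integer_
  if (!is.na(p1)) {
    .add_assign(col, "1-2", "position", p1, "ms2-pattern")
  } else {
    .add_undet(col, "reducing-end linkage position")
  }
  routes <- .route_losses(n, losses)
  if (!length(routes)) {
    .add_undet(col, "interior disaccharides (no ring-opened precursor available)")
    return(invisible())
  }
  primary <- routes[1]
  prefix <- c(M, M - primary)
  outer_entry <- NULL
  for (j in 0:(n - 3L)) {
    if (j > 0L) prefix <- c(prefix, prefix[length(prefix)] - 162L)
    k <- n - 1L - j                      # identifies bond k (residues k,k+1)
    path <- c(prefix, 365L)
    spec <- request(path)
    src <- sprintf("match:%s", paste(path, collapse = ">"))
    if (is.null(spec)) {
      .add_undet(col, sprintf("bond %d-%d (spectrum %s unavailable)",
                              k, k + 1L, paste(path, collapse = ">")))
      next
    }
    e <- .match_disacch(col, spec, db, sprintf("%d-%d", k, k + 1L),
                        if (k > 1L) sprintf("%d-%d", k - 1L, k) else NULL,
                        src, margin)
    if (j == 0L && !is.null(e)) outer_entry <- e
  }
  # trisaccharide: the alternative opened route is an independent
  # determination of the nonreducing disaccharide
  if (n == 3L && length(routes) > 1L) {
    path2 <- c(M, M - routes[2], 365L)
    spec2 <- request(path2)
    if (!is.null(spec2))
      .match_disacch(col, spec2, db, "2-3", "1-2",
                     sprintf("match:%s", paste(path2, collapse = ">")),
                     margin)
  }
  .subtraction_tail(col, M, request, db, outer_entry, p1, margin, near_zero)
  invisible()
}

# reverse subtraction: when the identified component has no ladder ion
# unique to it (e.g. a 1->4 unit co-isolated with a 1->6 unit, whose
# ladder contains 305 too), hypothesise each candidate second component,
# null an ion unique to THAT candidate, and keep the candidate whose
# residual best reproduces the known component's fingerprint.
.reverse_subtraction_id <- function(mixed, known_entry, db, p_other,
                                    margin) {
  scores <- list()
  for (a in c("alpha", "beta")) {
    cand <- .mixture_reference(db, a, p_other)
    if (is.null(cand)) next
    z <- choose_zero_ion(p_other, known_entry$position, cand)
    if (is.na(z)) next
    if (!isTRUE(ion_present(mixed, z))) next   # no second component signal
    res <- tryCatch(subtract_spectrum(mixed, cand, z),
                    error = function(e) NULL)
    if (is.null(res) || !length(res$mz)) next
    scores[[a]] <- spectrum_similarity(res, known_entry$spectrum)$value
  }
  if (!length(scores)) return(NULL)
  o <- order(unlist(scores), decreasing = TRUE)
  best <- names(scores)[o[1]]
  if (length(scores) > 1L &&
      (scores[[o[1]]] - scores[[o[2]]]) < margin) return(NULL)
  list(bond_anomer = best, position = p_other)
}

# ---- tetrasaccharides ---------------------------------------------------

.elucidate_tetra <- function(col, M, ms2, losses, cand, request, db,
                             threshold, margin, near_zero, get_requested) {
  routes <- .route_losses(4L, losses)
  opened <- if (length(routes)) request(c(M, M - routes[1])) else NULL
  cls <- classify_tetrasaccharide(ms2, opened, threshold)
  for (cv in cls$caveats) .add_caveat(col, cv)
  if (cls$class == "undetermined") {
    .add_undet(col, paste("topology type:", cls$missing))
    return(.make_report(col, NULL, 4L, get_requested))
  }
  if (cls$class == "I") {
    .elucidate_linear(col, 4L, M, losses, cand, request, db, threshold,
                      margin, near_zero)
  } else if (cls$class == "II") {
    .elucidate_tetra_II(col, M, losses, cand, request, db, margin, near_zero)
  } else if (cls$class == "III") {
    .elucidate_tetra_III(col, M, losses, cand, request, db, threshold,
                         margin, near_zero)
  } else {
    .add_caveat(col, "two branches on the reducing sugar: the pattern table covers linkage pairs only; positions undetermined")
    .add_undet(col, "all three branch positions and anomers")
    col$topology <- NULL
  }
  if (cls$class != "I")
    .add_caveat(col, "branched tetrasaccharide assignment extrapolated beyond the worked examples (classification scheme + per-branch matching)")
  consistency_audit(.make_report(col, col$topology, 4L, get_requested))
}

.elucidate_tetra_II <- function(col, M, losses, cand, request, db, margin,
                                near_zero) {
  pairs <- if (!is.null(cand)) .branched_pair(cand) else NULL
  if (is.null(pairs) || length(pairs) != 1L) {
    .add_caveat(col, "branch linkage pair ambiguous from the MS2 pattern")
    .add_undet(col, "branch linkage positions")
    col$topology <- NULL
    return(invisible())
  }
  pair <- sort(pairs[[1]], decreasing = TRUE)
  for (p in pair)
    .add_assign(col, sprintf("root@%d", p), "position", p, "ms2-pattern")
  routes <- .route_losses(4L, losses)
  chain_entry <- NULL
  a_att <- NULL
  if (length(routes)) {
    spec <- request(c(M, M - routes[1], 365L))
    if (!is.null(spec)) {
      mr <- match_spectrum(spec, db, margin)
      if (mr$margin_met || mr$same_bond_top2) {
        chain_entry <- if (mr$margin_met) mr$decision
                       else db$entries[[mr$ranked$slot[1]]]
        src <- sprintf("match:%d>%d>365", M, M - routes[1])
        .add_assign(col, "chain-outer", "position", chain_entry$position, src)
        .add_assign(col, "chain-outer", "anomer", chain_entry$bond_anomer, src)
        if (mr$margin_met) a_att <- chain_entry$reducing_anomer
      }
    }
  }
  p_leaf <- NA_integer_
  mixed <- request(c(M, 365L))
  if (!is.null(mixed) && !is.null(chain_entry)) {
    # the chain disaccharide (C2, resolved) co-isolates with the
    # root+leaf Y2 (mixture reducing end)
    zcand <- setdiff(.position_ladder(chain_entry$position),
                     unique(unlist(lapply(pair, .position_ladder))))
    assigned <- FALSE
    if (length(zcand)) {
      b <- bin_nominal(chain_entry$spectrum)
      ints <- b[as.character(zcand)]; ints[is.na(ints)] <- 0
      z <- zcand[which.max(ints)]
      cs <- crosscheck_subtraction(mixed, chain_entry, db, z, near_zero,
                                   margin)
      if (!cs$no_second_component && cs$match$margin_met &&
          cs$match$decision$position %in% pair) {
        e2 <- cs$match$decision
        p_leaf <- e2$position
        .add_assign(col, sprintf("root@%d", p_leaf), "anomer",
                    e2$bond_anomer, sprintf("subtraction:%d>365", M))
        assigned <- TRUE
      }
    }
    if (!assigned) {
      for (p_guess in pair) {
        id <- .reverse_subtraction_id(mixed, chain_entry, db, p_guess,
                                      margin)
        if (!is.null(id)) {
          p_leaf <- id$position
          .add_assign(col, sprintf("root@%d", p_leaf), "anomer",
                      id$bond_anomer,
                      sprintf("reverse-subtraction:%d>365", M))
          break
        }
      }
    }
  }
  p_chain <- if (!is.na(p_leaf)) setdiff(pair, p_leaf) else NA_integer_
  if (!is.na(p_chain) && !is.null(a_att))
    .add_assign(col, sprintf("root@%d", p_chain), "anomer", a_att,
                "inheritance:chain-outer")
  if (is.na(p_leaf)) {
    .add_caveat(col, "leaf-vs-chain branch assignment undetermined")
    .add_undet(col, "branch-to-position mapping")
  }
  col$topology <- list(kind = "tetraII", p_chain = p_chain, p_leaf = p_leaf)
  invisible()
}

.elucidate_tetra_III <- function(col, M, losses, cand, request, db,
                                 threshold, margin, near_zero) {
  p1 <- if (!is.null(cand)) .linear_position(cand) else NA_integer_
  if (!is.na(p1)) .add_assign(col, "1-2", "position", p1, "ms2-pattern")
  else .add_undet(col, "reducing-end linkage position")
  routes <- .route_losses(4L, losses)
  branch_pos <- c(NA_integer_, NA_integer_)
  if (length(routes) && routes[1] == 60L) {
    s527 <- request(c(M, M - 60L, 527L))
    if (!is.null(s527)) {
      tri_losses <- c(18L, 60L, 90L, 120L)
      tri_losses <- tri_losses[ion_present(s527, 527L - tri_losses, threshold)]
      cand3 <- tryCatch(reducing_linkage_candidates(tri_losses, 3L),
                        error = function(e) NULL)
      pairs <- if (!is.null(cand3)) .branched_pair(cand3) else NULL
      if (!is.null(pairs) && length(pairs) == 1L) {
        branch_pos <- sort(pairs[[1]], decreasing = TRUE)
        for (p in branch_pos)
          .add_assign(col, sprintf("res2@%d", p), "position", p,
                      sprintf("pattern:%d>%d>527", M, M - 60L))
        s365 <- request(c(M, M - 60L, 527L, 365L))
        if (!is.null(s365)) {
          mr <- match_spectrum(s365, db, margin)
          top <- db$entries[[mr$ranked$slot[1]]]
          if ((mr$margin_met || mr$same_bond_top2) &&
              top$position %in% branch_pos) {
            src <- sprintf("match:%d>%d>527>365", M, M - 60L)
            .add_assign(col, sprintf("res2@%d", top$position), "anomer",
                        top$bond_anomer, src)
            if (mr$margin_met)
              .add_assign(col, "1-2", "anomer", top$reducing_anomer,
                          paste0(src, "+inheritance"))
            p_other <- setdiff(branch_pos, top$position)
            refmix <- if (mr$margin_met) top$spectrum
                      else .mixture_reference(db, top$bond_anomer, top$position)
            z <- choose_zero_ion(top$position, p_other, top$spectrum)
            if (!is.null(refmix) && !is.na(z)) {
              cs <- crosscheck_subtraction(s365, refmix, db, z, near_zero,
                                           margin)
              e2 <- if (!cs$no_second_component && cs$match$margin_met)
                cs$match$decision else NULL
              if (!is.null(e2) && e2$position == p_other)
                .add_assign(col, sprintf("res2@%d", p_other), "anomer",
                            e2$bond_anomer,
                            sprintf("subtraction:%d>%d>527>365", M, M - 60L))
              else {
                .add_caveat(col, sprintf(
                  "residual near zero or inconsistent: anomer of the 1->%d branch undetermined", p_other))
                .add_undet(col, sprintf("anomer of branch 1->%d on residue 2",
                                        p_other))
              }
            }
          }
        }
      }
    }
  }
  if (any(is.na(branch_pos))) {
    .add_caveat(col, "nonreducing branch pair not determined (needs the 689>629>527 route)")
    .add_undet(col, "branch linkage positions on residue 2")
  }
  col$topology <- list(kind = "tetraIII", branch_positions = branch_pos)
  invisible()
}
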