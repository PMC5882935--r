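# Sodiated fragment m/z calculus. All ions are singly charged sodium
# adducts. Glycosidic B/C/Y/Z cleavage may occur at any bond; dehydration
# and cross-ring (retro-aldol) cleavage only at the reducing ring.

#' Monoisotopic mass constants (u)
#'
#' Hexose residue mass (Glc minus water), water, and the sodium cation
#' (Na minus one electron mass). Nominal equivalents are 162 / 18 / 23.
#' @export
mass_constants <- list(
  hexose_residue = 162.0528,
  water          = 18.0106,
  sodium_cation  = 22.9892
)

# retro-aldol neutral-loss ladder from the reducing ring
loss_masses <- c(
  none    = 0,
  H2O     = 18.0106,   # dehydration
  C2H4O2  = 60.0211,   # 0,2A (glycolaldehyde)
  C3H6O3  = 90.0317,   # 0,3A
  C4H8O4  = 120.0423   # 0,4A
)

loss_nominal <- c(none = 0L, H2O = 18L, C2H4O2 = 60L, C3H6O3 = 90L,
                  C4H8O4 = 120L)

#' m/z of a sodiated oligosaccharide ion with an optional neutral loss
#'
#' m/z = n x 162.0528 + 18.0106 + 22.9892 - loss. For example a sodiated
#' trisaccharide is nominal 527; its dehydration product 509; the 0,2A
#' (-60) product 467; a sodiated disaccharide 365 and its dehydration
#' product 347.
#'
#' @param residue_count number of hexose residues (>= 1)
#' @param loss one of "none", "H2O", "C2H4O2", "C3H6O3", "C4H8O4"
#' @return list with `mz_mono` and integer `mz_nominal`
#' @export
sodiated_mz <- function(residue_count, loss = "none") {
  stopifnot(length(residue_count) == 1L, residue_count >= 1,
            residue_count == round(residue_count))
  loss <- match.arg(loss, names(loss_masses))
  mono <- residue_count * mass_constants$hexose_residue +
    mass_constants$water + mass_constants$sodium_cation - loss_masses[[loss]]
  if (mono <= 0) stop("neutral loss heavier than the ion")
  list(mz_mono = mono, mz_nominal = as.integer(round(mono)))
}

#' Nominal m/z shortcut
#' @param residue_count residues
#' @param loss neutral-loss token
#' @return integer nominal m/z
#' @export
sodiated_nominal <- function(residue_count, loss = "none") {
  sodiated_mz(residue_count, loss)$mz_nominal
}

# which reducing-ring channels a linkage set opens (the fragmentation
# pattern table; see rule-engine.R for the full hypothesis table). `minor`
# marks channels the mechanism leaves open only weakly (1->2 dehydration).
reducing_ring_channels <- function(positions) {
  positions <- sort(as.integer(positions), decreasing = TRUE)
  key <- paste(positions, collapse = ",")
  if (length(positions) <= 1L) {
    switch(key,
      "2" = list(H2O = "minor"),
      "3" = list(H2O = "major", C3H6O3 = "major"),
      "4" = list(H2O = "major", C2H4O2 = "major"),
      "6" = list(H2O = "major", C2H4O2 = "major", C3H6O3 = "major",
                 C4H8O4 = "major"),
      "1" = list(),   # 1->1: no rule support
      list()
    )
  } else {
    # two-branch rules as stated; a third branch (two branches plus the
    # chain all on the reducing sugar) is treated as the union of its
    # pairs - an assumption, flagged in the pattern table provenance
    pair_ch <- function(key) {
      ch <- list()
      if (key %in% c("6,4", "6,3", "4,3")) ch$H2O <- "major"
      if (key %in% c("6,4", "6,2", "4,2")) ch$C2H4O2 <- "major"
      if (key %in% c("6,3", "3,2")) ch$C3H6O3 <- "major"
      ch
    }
    if (length(positions) == 2L) return(pair_ch(key))
    ch <- list()
    cmb <- utils::combn(positions, 2L)
    for (i in seq_len(ncol(cmb)))
      ch <- utils::modifyList(ch, pair_ch(paste(cmb[, i], collapse = ",")))
    ch
  }
}

#' Enumerate the fragment ions of a sodiated oligosaccharide
#'
#' With `mechanism = "reducing-side"` (the default, matching low-energy CID
#' of sodium adducts): B/C/Y/Z ions at every glycosidic bond, the
#' dehydration ion \\[M+Na-H2O\\]+ and the cross-ring 0,2A/0,3A/0,4A ions
#' only when the reducing-sugar linkage set opens those channels, plus the
#' complementary sodiated X0 counterparts for branched retro-aldol cases.
#' With `mechanism = "all"` every loss channel is emitted unconditionally
#' (an oracle superset, useful for mass-balance checks).
#'
#' C-type fragments carry `new_reducing_anomer`: the configuration of the
#' cleaved bond becomes the anomeric configuration of the fragment's new
#' reducing end.
#'
#' @param g a [glycan_structure()]
#' @param mechanism "reducing-side" or "all"
#' @return data.frame: label, type, mz_mono, mz_nominal, loss, residues
#'   (covered residue numbers, comma string), new_reducing_anomer, minor
#' @export
enumerate_fragments <- function(g, mechanism = c("reducing-side", "all")) {
  mechanism <- match.arg(mechanism)
  n <- residue_count(g)
  bonds <- structure_bonds(g)
  rows <- list()
  add <- function(label, type, residues_n, loss, residues_txt,
                  new_anomer = NA_character_, minor = FALSE) {
    mz <- sodiated_mz(residues_n, loss)
    mz_mono <- mz$mz_mono
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, type = type, mz_mono = mz_mono,
      mz_nominal = mz$mz_nominal, loss = loss, residues = residues_txt,
      new_reducing_anomer = new_anomer, minor = minor,
      stringsAsFactors = FALSE)
  }

  # residue coverage per subtree, for the residues column
  cover <- .subtree_members(g)

  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      b <- bonds[i, ]
      s <- b$child_size
      j <- n - s
      sub_txt <- paste(cover[[b$child]], collapse = ",")
      rem_txt <- paste(setdiff(seq_len(n), cover[[b$child]]), collapse = ",")
      add(sprintf("C%d", s), "C", s, "none", sub_txt, new_anomer = b$anomeric)
      add(sprintf("B%d", s), "B", s, "H2O", sub_txt, minor = TRUE)
      add(sprintf("Y%d", j), "Y", j, "none", rem_txt)
      add(sprintf("Z%d", j), "Z", j, "H2O", rem_txt, minor = TRUE)
    }
  }

  all_txt <- paste(seq_len(n), collapse = ",")
  if (mechanism == "all") {
    add("[M+Na-H2O]+", "dehydration", n, "H2O", all_txt)
    add(sprintf("0,2A%d", n), "A", n, "C2H4O2", all_txt)
    add(sprintf("0,3A%d", n), "A", n, "C3H6O3", all_txt)
    add(sprintf("0,4A%d", n), "A", n, "C4H8O4", all_txt)
  } else {
    ch <- reducing_ring_channels(reducing_linkages(g))
    if (!is.null(ch$H2O))
      add("[M+Na-H2O]+", "dehydration", n, "H2O", all_txt,
          minor = identical(ch$H2O, "minor"))
    if (!is.null(ch$C2H4O2)) add(sprintf("0,2A%d", n), "A", n, "C2H4O2", all_txt)
    if (!is.null(ch$C3H6O3)) add(sprintf("0,3A%d", n), "A", n, "C3H6O3", all_txt)
    if (!is.null(ch$C4H8O4)) add(sprintf("0,4A%d", n), "A", n, "C4H8O4", all_txt)
  }

  # sodiated X0 counterparts (sodium retained on the small reducing-end
  # piece) for the branched retro-aldol cases; emitted whenever the matching
  # A channel is open on a branched reducing sugar (or always in "all" mode)
  x0 <- function(loss, lab) {
    mono <- loss_masses[[loss]] + mass_constants$sodium_cation
    rows[[length(rows) + 1L]] <<- data.frame(
      label = lab, type = "X", mz_mono = mono,
      mz_nominal = as.integer(round(mono)), loss = "complement",
      residues = "1", new_reducing_anomer = NA_character_, minor = TRUE,
      stringsAsFactors = FALSE)
  }
  branched_root <- length(g$root$children) > 1L
  if (mechanism == "all") {
    x0("C2H4O2", "0,2X0"); x0("C3H6O3", "0,3X0"); x0("C4H8O4", "0,4X0")
  } else if (branched_root) {
    ch <- reducing_ring_channels(reducing_linkages(g))
    if (!is.null(ch$C2H4O2)) x0("C2H4O2", "0,2X0")
    if (!is.null(ch$C3H6O3)) x0("C3H6O3", "0,3X0")
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), type = character(), mz_mono = numeric(),
               mz_nominal = integer(), loss = character(),
               residues = character(), new_reducing_anomer = character(),
               minor = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# residue numbers (depth-first from the root, root = 1) contained in the
# subtree hanging below each residue id
.subtree_members <- function(g) {
  members <- list()
  counter <- new.env(); counter$k <- 1L
  walk <- function(r) {
    my_id <- counter$k
    mine <- my_id
    for (ch in r$children) {
      counter$k <- counter$k + 1L
      mine <- c(mine, walk(ch$residue))
    }
    members[[my_id]] <<- mine
    mine
  }
  walk(g$root)
  members
}

#' Check mass complementarity of a fragment-ion pair
#'
#' For a C/Y pair from the same bond of an n-residue parent,
#' nominal m/z(Ci) + m/z(Y(n-i)) = parent + 41 (water + sodium); for a B/Z
#' pair the sum is parent + 5 (sodium - water). The degenerate pairs (Bn
#' with Z0, Cn with Y0) are true by convention.
#'
#' @param parent_mz nominal parent m/z
#' @param ion_a,ion_b rows (1-row data.frames or lists) with `label` and
#'   `mz_nominal`
#' @return TRUE/FALSE, with a `reason` attribute when FALSE
#' @export
complementarity_check <- function(parent_mz, ion_a, ion_b) {
  fail <- function(reason) structure(FALSE, reason = reason)
  lab <- function(x) as.character(x$label)
  typ <- function(x) sub("^([A-Z]).*", "\\1", sub("^0,[0-9]", "", lab(x)))
  idx <- function(x) suppressWarnings(as.integer(sub("^[A-Z]", "", lab(x))))
  ta <- typ(ion_a); tb <- typ(ion_b)
  pair <- paste(sort(c(ta, tb)), collapse = "/")
  n_res <- round((parent_mz - 41) / 162)
  ia <- idx(ion_a); ib <- idx(ion_b)
  if (pair == "C/Y") {
    if (is.na(ia) || is.na(ib)) return(fail("unparsable ion indices"))
    if (ia + ib != n_res) return(fail("indices do not span the parent"))
    ok <- (ion_a$mz_nominal + ion_b$mz_nominal) == (parent_mz + 41)
    if (!ok) return(fail("C/Y masses do not sum to parent + 41"))
    return(TRUE)
  }
  if (pair == "B/Z") {
    if (is.na(ia) || is.na(ib)) return(fail("unparsable ion indices"))
    if (ia + ib != n_res) return(fail("indices do not span the parent"))
    ok <- (ion_a$mz_nominal + ion_b$mz_nominal) == (parent_mz + 5)
    if (!ok) return(fail("B/Z masses do not sum to parent - 18 + 23"))
    return(TRUE)
  }
  # degenerate: Bn alone (Z0 is bare Na) or Cn alone (Y0)
  if (any(c(ta, tb) %in% c("B", "C")) &&
      any(vapply(list(ion_a, ion_b), function(x) isTRUE(idx(x) == 0L) ||
                 lab(x) %in% c("Z0", "Y0"), logical(1))))
    return(TRUE)
  fail(sprintf("not a complementary pair: %s vs %s", lab(ion_a), lab(ion_b)))
}

#' Export a fragment table as TSV
#' @param fragments output of [enumerate_fragments()]
#' @param path file path
#' @return invisibly, the path
#' @export
write_fragment_tsv <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
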