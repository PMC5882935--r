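# Fragmentation-pattern table and decision logic. The MS2 neutral-loss
# pattern of the precursor constrains the linkage set on the reducing
# sugar; follow-up CID of the dehydration / cross-ring products separates
# linear from branched topologies; for tetrasaccharides a two-stage check
# assigns one of the four topology types I-IV.

# expected reducing-ring loss set per linkage assignment. Cross-ring
# cleavage follows the retro-aldol pattern: 0,2A (-60) for 1->4 and 1->6,
# 0,3A (-90) for 1->3 and 1->6, 0,4A (-120) for 1->6, dehydration (-18)
# for 1->3, 1->4 and 1->6; on a branched reducing sugar -18 for
# (6,4),(6,3),(4,3), -60 for (6,4),(6,2),(4,2), -90 for (6,3),(3,2).
#' The reducing-sugar fragmentation-pattern table
#'
#' One row per linkage assignment (linear position or branched position
#' pair), with the expected set of reducing-ring neutral losses and the
#' provenance of the row (all rows here derive from the mechanism text).
#' The linear 1->2 row expects no loss: dehydration is only a minor channel
#' there (kojibiose/sophorose) and cross-ring cleavage is closed.
#'
#' @return data.frame: topology, positions, losses (comma string of
#'   18/60/90/120), provenance
#' @export
loss_pattern_table <- function() {
  rows <- list(
    list("linear", "2", ""),
    list("linear", "3", "18,90"),
    list("linear", "4", "18,60"),
    list("linear", "6", "18,60,90,120"),
    list("branched", "6,4", "18,60"),
    list("branched", "6,3", "18,90"),
    list("branched", "6,2", "60"),
    list("branched", "4,3", "18"),
    list("branched", "4,2", "60"),
    list("branched", "3,2", "90")
  )
  data.frame(
    topology = vapply(rows, `[[`, character(1), 1),
    positions = vapply(rows, `[[`, character(1), 2),
    losses = vapply(rows, `[[`, character(1), 3),
    provenance = "text-derived",
    stringsAsFactors = FALSE)
}

.parse_losses <- function(x) {
  if (!nzchar(x)) integer() else as.integer(strsplit(x, ",")[[1]])
}

#' Linkage hypotheses consistent with an observed MS2 loss pattern
#'
#' A hypothesis is kept when its expected loss set equals the observed set
#' (absence of a loss is evidence too: a 1->6 reducing linkage must show
#' the full -18/-60/-90/-120 ladder). The documented ambiguities survive:
#' linear(1->4) vs branched(1->6, 1->4) share the pattern {-18, -60}, and
#' the follow-up CID steps are required to separate them.
#'
#' @param losses_observed integer subset of c(18, 60, 90, 120) (losses seen
#'   relative to the precursor), or an [ms_spectrum()] from which the
#'   pattern is read at the presence threshold
#' @param n residue count (3, 4 or 5)
#' @param threshold presence cutoff when `losses_observed` is a spectrum
#' @return data.frame of hypotheses: topology, positions, status, caveat
#' @export
reducing_linkage_candidates <- function(losses_observed, n, threshold = 0.01) {
  stopifnot(n %in% 3:5)
  if (inherits(losses_observed, "ms_spectrum"))
    losses_observed <- observed_losses(losses_observed, n, threshold)
  obs <- sort(as.integer(losses_observed))
  if (!all(obs %in% c(18L, 60L, 90L, 120L)))
    stop("losses must be drawn from {18, 60, 90, 120}")
  tab <- loss_pattern_table()
  hit <- vapply(tab$losses,
                function(x) identical(sort(.parse_losses(x)), obs),
                logical(1))
  out <- tab[hit, c("topology", "positions")]
  if (!nrow(out))
    stop("pattern inconsistent: no linkage assignment expects losses {",
         paste(obs, collapse = ", "), "}")
  out$status <- "candidate"
  out$caveat <- ""
  if (any(out$topology == "linear" & out$positions == "2"))
    out$caveat[out$topology == "linear" & out$positions == "2"] <-
      "absence-based call: dehydration is a minor channel for 1->2 and the mechanism differs"
  rownames(out) <- NULL
  out
}

#' Read the reducing-ring loss pattern off an MS2 spectrum
#' @param ms2 normalised [ms_spectrum()] of the precursor
#' @param n residue count
#' @param threshold presence cutoff
#' @return integer vector of observed losses
#' @export
observed_losses <- function(ms2, n, threshold = 0.01) {
  parent <- sodiated_nominal(n)
  cand <- c(18L, 60L, 90L, 120L)
  cand[ion_present(ms2, parent - cand, threshold)]
}

#' Separate the linear/branched ambiguity by follow-up CID
#'
#' For a trisaccharide: the presence of the disaccharide ion m/z 365 in the
#' CID of the dehydration product (527>509), or of m/z 347/365 in the CID
#' of the 0,2A product (527>467), confirms a linear chain; absence in both
#' confirms a branch on the reducing sugar.
#'
#' @param ms3_on_dehydration CID spectrum of the -18 product (or NULL)
#' @param ms3_on_A_ion CID spectrum of the -60 product (or NULL)
#' @param n residue count (3 supported)
#' @param threshold presence cutoff
#' @return list: topology ("linear"/"branched"/"ambiguous"), evidence,
#'   warning (NULL unless the two routes disagree)
#' @export
resolve_linear_vs_branched <- function(ms3_on_dehydration = NULL,
                                       ms3_on_A_ion = NULL, n = 3,
                                       threshold = 0.01) {
  stopifnot(n == 3L)
  sig <- c(dehydration_route = NA, A_ion_route = NA)
  if (!is.null(ms3_on_dehydration))
    sig["dehydration_route"] <- ion_present(ms3_on_dehydration, 365, threshold)
  if (!is.null(ms3_on_A_ion))
    sig["A_ion_route"] <- any(ion_present(ms3_on_A_ion, c(347, 365), threshold))
  seen <- sig[!is.na(sig)]
  if (!length(seen))
    return(list(topology = "ambiguous", evidence = sig,
                warning = "no decisive spectrum supplied"))
  if (all(seen)) return(list(topology = "linear", evidence = sig, warning = NULL))
  if (!any(seen)) return(list(topology = "branched", evidence = sig, warning = NULL))
  list(topology = "ambiguous", evidence = sig,
       warning = "decisive-ion routes disagree; both hypotheses retained")
}

# scheme footnotes carried as caveats (never silent): exception classes of
# the trisaccharide and tetrasaccharide decision trees
tetra_scheme_footnotes <- c(
  `1` = "except (1->6,1->4), (1->4,1->3), (1->3,1->2) on the reducing sugar",
  `2` = "except (1->6,1->4,1->3) and (1->4,1->3,1->2)",
  `3` = "except (1->2) between monosaccharides 2 and 1",
  `4` = "except (1->2) between monosaccharides 3 and 2",
  `5` = "only for (1->6,1->4) and (1->3,1->2) on the reducing sugar",
  `6` = "without (1->2) on the reducing sugar; (1->1) not considered"
)

#' Classify a tetrasaccharide into topology type I-IV
#'
#' Two presence checks drive the call: disaccharide-region ions (365/347)
#' in the MS2 of the sodiated tetrasaccharide (possible only when a
#' two-residue subtree or a two-residue reducing-side piece exists), and
#' trisaccharide-region ions (527/509) in the CID of a dehydration or
#' cross-ring product of the precursor (possible only when a three-residue
#' nonreducing subtree exists).
#'
#' \describe{
#'   \item{I linear}{both present}
#'   \item{II branched on the reducing sugar}{disaccharide ions only}
#'   \item{III branched on the nonreducing side}{trisaccharide ions only}
#'   \item{IV two branches on the reducing sugar}{neither}
#' }
#'
#' @param ms2 normalised MS2 spectrum of m/z 689
#' @param opened_cid normalised CID spectrum of the -18 or -60 product
#'   (path 689>671 or 689>629), or NULL
#' @param threshold presence cutoff
#' @return list: class ("I".."IV" or "undetermined"), evidence, caveats,
#'   missing (decisive paths still needed when undetermined)
#' @export
classify_tetrasaccharide <- function(ms2, opened_cid = NULL,
                                     threshold = 0.01) {
  stopifnot(inherits(ms2, "ms_spectrum"))
  if (length(ms2$precursor_path) &&
      ms2$precursor_path[length(ms2$precursor_path)] != 689L)
    stop("classify_tetrasaccharide expects the MS2 of m/z 689 (n = 4)")
  di <- any(ion_present(ms2, c(365, 347), threshold))
  if (is.null(opened_cid))
    return(list(class = "undetermined", evidence = c(disaccharide_ions = di),
                caveats = character(),
                missing = "CID of the -18 or -60 product (689>671 or 689>629)"))
  tri <- any(ion_present(opened_cid, c(527, 509), threshold))
  cls <- if (di && tri) "I" else if (di) "II" else if (tri) "III" else "IV"
  cav <- switch(cls,
    I  = tetra_scheme_footnotes[c("3", "4")],
    II = tetra_scheme_footnotes[c("1", "5", "6")],
    III = tetra_scheme_footnotes["4"],
    IV = tetra_scheme_footnotes["2"])
  list(class = cls,
       evidence = c(disaccharide_ions = di, trisaccharide_ions = tri),
       caveats = unname(cav), missing = character())
}

# ---- acquisition plans --------------------------------------------------

.path_string <- function(p) paste(p, collapse = ">")

#' Ordered MSn acquisition plan of structurally decisive spectra
#'
#' Emits the precursor paths whose CID spectra feed the decision procedure:
#' the MS2 survey; the CID of each reducing-ring loss product (-18, -60,
#' -90) for the linear/branched checks; the ring-opened "strip" chains in
#' which nonreducing-terminal residues are removed one at a time and the
#' terminal disaccharide ion m/z 365 of each strip level is sent to the
#' database; and the mixed m/z 365 isolation used for the subtraction
#' crosscheck. For a disaccharide the plan is the single direct CID.
#'
#' @param n residue count (2..5)
#' @param parent_mz nominal precursor (default: sodiated n-mer)
#' @return data.frame: path (e.g. "689>629>365"), role, bond (residue pair
#'   a disaccharide_id step identifies, reducing end = residue 1)
#' @export
decisive_ion_plan <- function(n, parent_mz = NULL) {
  stopifnot(n %in% 2:5)
  n <- as.integer(n)
  M <- if (is.null(parent_mz)) sodiated_nominal(n) else as.integer(parent_mz)
  if (n == 2L)
    return(data.frame(path = .path_string(M), role = "disaccharide_id",
                      bond = "1,2", stringsAsFactors = FALSE))
  rows <- list(data.frame(path = .path_string(M), role = "reducing_linkage",
                          bond = "", stringsAsFactors = FALSE))
  push <- function(p, role, bond = "")
    rows[[length(rows) + 1L]] <<- data.frame(path = .path_string(p),
                                             role = role, bond = bond,
                                             stringsAsFactors = FALSE)
  for (L in c(18L, 60L, 90L)) {
    v0 <- M - L
    push(c(M, v0), "linearity_check")
    strip <- c(M, v0)
    for (j in 0:(n - 3L)) {
      if (j > 0L) {
        strip <- c(strip, strip[length(strip)] - 162L)
        push(strip, "strip")
      }
      push(c(strip, 365L), "disaccharide_id",
           bond = paste(n - 1L - j, n - j, sep = ","))
    }
  }
  if (n == 4L) {
    # nonreducing trisaccharide route for a type III branch (extrapolated)
    push(c(M, M - 60L, 527L), "nonreducing_trisaccharide")
    push(c(M, M - 60L, 527L, 365L), "disaccharide_id", bond = "2,3|2,4")
  }
  push(c(M, 365L), "mixed_subtraction", bond = "1,2")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paths of a plan as integer vectors
#' @param plan output of [decisive_ion_plan()]
#' @return list of integer vectors
#' @export
plan_paths <- function(plan) {
  lapply(strsplit(plan$path, ">", fixed = TRUE), as.integer)
}

#' Export an acquisition plan as JSON
#' @param plan output of [decisive_ion_plan()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(plan, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Render an acquisition plan as an indented text tree
#' @param plan output of [decisive_ion_plan()]
#' @return character vector of lines
#' @export
format_plan_tree <- function(plan) {
  paths <- plan_paths(plan)
  vapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    indent <- strrep("  ", length(p) - 1L)
    sprintf("%s%d  [%s]%s", indent, p[length(p)], plan$role[i],
            if (nzchar(plan$bond[i]))
              paste0(" (bond ", plan$bond[i], ")") else "")
  }, character(1))
}
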