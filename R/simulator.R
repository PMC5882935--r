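# Ion-trap CID emulator. Produces MSn spectral trees for a known structure
# under the mechanism constraints: glycosidic B/C/Y/Z cleavage at any bond,
# dehydration and retro-aldol cross-ring cleavage only at the reducing
# ring, C-type products inheriting the cleaved bond's anomeric
# configuration as their new reducing-end configuration, and isolation of
# a nominal m/z co-selecting all isobaric fragment populations (so the
# daughter spectrum is their ratio-weighted mixture).

#' Channel model for the CID simulator
#'
#' @param params disaccharide fingerprint channel ratios
#'   ([default_channel_params()])
#' @param noise lognormal sdlog applied multiplicatively per channel
#'   (0 = noiseless)
#' @param seed integer seed fixing all randomness
#' @param branch_bias probability mass of the preferred cleavage at a
#'   branch point (the bond at the lowest acceptor position cleaves
#'   preferentially; 0.5 = symmetric branches)
#' @param side_split sodium retention split between the nonreducing (C/B)
#'   and reducing (Y/Z) sides of a glycosidic cleavage
#' @param yz_split partition of the reducing-side share between Y and Z
#' @param opened_split partition for CID of a ring-opened precursor:
#'   C ion, minor B ion, and the reducing-side remnant retaining the loss
#' @param oligo_ring reducing-ring channel weights at the oligosaccharide
#'   stage: `linear` (list by position) and `branched` (per open channel)
#' @param min_channel relative channel weight below which a product is not
#'   emitted (keeps peak positions seed-invariant under jitter)
#' @return object of class `channel_model`
#' @export
channel_model <- function(params = default_channel_params(), noise = 0.1,
                          seed = NULL, branch_bias = 0.97,
                          side_split = c(nonreducing = 0.55, reducing = 0.45),
                          yz_split = c(Y = 0.8, Z = 0.2),
                          opened_split = c(C = 0.55, B = 0.1, remnant = 0.35),
                          oligo_ring = NULL,
                          min_channel = 0.015) {
  .check_params(params)
  stopifnot(noise >= 0, branch_bias > 0, branch_bias < 1)
  if (is.null(oligo_ring)) {
    oligo_ring <- list(
      linear = list(`2` = c(H2O = 0.005),
                    `3` = c(H2O = 0.5, C3H6O3 = 0.35),
                    `4` = c(H2O = 0.5, C2H4O2 = 0.35),
                    `6` = c(H2O = 0.25, C2H4O2 = 0.3, C3H6O3 = 0.25,
                            C4H8O4 = 0.2)),
      branched = c(H2O = 0.4, C2H4O2 = 0.35, C3H6O3 = 0.35))
  }
  structure(list(params = params, noise = noise, seed = seed,
                 branch_bias = branch_bias, side_split = side_split,
                 yz_split = yz_split, opened_split = opened_split,
                 oligo_ring = oligo_ring, min_channel = min_channel),
            class = "channel_model")
}

#' Wrap a structure as a sodiated species
#'
#' `kind` records the provenance of the ion: "intact" (free reducing ring,
#' an [M+Na]+ molecular ion or a C/Y fragment) or "opened" (the reducing
#' ring has undergone dehydration or retro-aldol loss `loss`).
#'
#' @param structure a [glycan_structure()]
#' @param kind "intact" or "opened"
#' @param loss neutral-loss token already applied (for `kind = "opened"`)
#' @return object of class `sodiated_species`
#' @export
sodiated_species <- function(structure, kind = c("intact", "opened"),
                             loss = "none") {
  kind <- match.arg(kind)
  if (kind == "opened" && loss == "none")
    stop("an opened species must carry its neutral loss")
  structure(list(structure = structure, kind = kind, loss = loss),
            class = "sodiated_species")
}

.species_nominal <- function(sp) {
  n <- residue_count(sp$structure)
  sodiated_nominal(n, if (sp$kind == "opened") sp$loss else "none")
}

# remove the subtree hanging on bond index `bi` (row of structure_bonds
# order); returns list(sub = child structure with inherited reducing
# anomer, rem = remainder structure)
.split_at_bond <- function(g, bond_row_parent, bond_row_position) {
  strip <- function(r, id_env) {
    # rebuild residue, dropping the child at the target position when this
    # residue is the bond parent
    id_env$k <- id_env$k + 1L
    my_id <- id_env$k
    kids <- list()
    taken <- NULL
    for (ch in r$children) {
      if (my_id == bond_row_parent && ch$position == bond_row_position) {
        taken <- ch
      } else {
        res <- strip(ch$residue, id_env)
        if (!is.null(res$taken)) taken <- res$taken
        kids[[length(kids) + 1L]] <- .link(ch$anomeric, ch$position, res$residue)
      }
    }
    list(residue = glycan_residue(kids), taken = taken)
  }
  env <- new.env(); env$k <- 0L
  res <- strip(g$root, env)
  if (is.null(res$taken)) stop("bond not found")
  list(sub = glycan_structure(res$taken$residue,
                              root_anomeric = res$taken$anomeric),
       rem = glycan_structure(res$residue, root_anomeric = g$root_anomeric))
}

# per-bond glycosidic weight: bond-anomer factor x branch bias at
# multi-child residues (lowest acceptor position preferred)
.bond_weights <- function(g, model) {
  bonds <- structure_bonds(g)
  if (!nrow(bonds)) return(bonds)
  w <- model$params$glyc_weight[bonds$anomeric]
  for (p in unique(bonds$parent)) {
    idx <- which(bonds$parent == p)
    if (length(idx) > 1L) {
      o <- order(bonds$position[idx])         # ascending position
      bias <- rep((1 - model$branch_bias) / (length(idx) - 1L), length(idx))
      bias[o[1L]] <- model$branch_bias        # lowest position cleaves first
      w[idx] <- w[idx] * bias * length(idx)
    }
  }
  bonds$weight <- as.numeric(w)
  bonds
}

# product populations of one CID stage: data-frame-ish list of
# list(mz, weight, species (or NULL for terminal small ions))
.cid_products <- function(sp, model) {
  if (!inherits(sp, "sodiated_species"))
    stop("unknown provenance: CID requires a sodiated_species")
  g <- sp$structure
  n <- residue_count(g)
  out <- list()
  push <- function(mz, w, species = NULL)
    out[[length(out) + 1L]] <<- list(mz = as.integer(mz), weight = w,
                                     species = species)
  if (n == 1L) return(out)

  if (sp$kind == "intact" && n == 2L) {
    # disaccharide: the fingerprint IS the spectrum
    bond <- g$root$children[[1L]]
    red <- if (g$root_anomeric == "unspecified") "mixture" else g$root_anomeric
    v <- disaccharide_fingerprint(bond$anomeric, bond$position, red,
                                  model$params)
    for (k in names(v)) {
      species <- if (k == "203")
        sodiated_species(glycan_structure(glycan_residue(),
                                          bond$anomeric), "intact")
      else NULL
      push(as.integer(k), as.numeric(v[k]), species)
    }
    return(out)
  }

  bonds <- .bond_weights(g, model)
  if (sp$kind == "intact") {
    for (i in seq_len(nrow(bonds))) {
      b <- bonds[i, ]
      pieces <- .split_at_bond(g, b$parent, b$position)
      s <- residue_count(pieces$sub)
      wb <- b$weight
      ss <- model$side_split; yz <- model$yz_split
      csp <- model$params$c_split[[b$anomeric]]
      push(sodiated_nominal(s), wb * ss["nonreducing"] * csp["C"],
           sodiated_species(pieces$sub, "intact"))
      push(sodiated_nominal(s, "H2O"), wb * ss["nonreducing"] * csp["B"],
           sodiated_species(pieces$sub, "opened", "H2O"))
      push(sodiated_nominal(n - s), wb * ss["reducing"] * yz["Y"],
           sodiated_species(pieces$rem, "intact"))
      push(sodiated_nominal(n - s, "H2O"), wb * ss["reducing"] * yz["Z"],
           sodiated_species(pieces$rem, "opened", "H2O"))
    }
    # reducing-ring channels
    pos <- reducing_linkages(g)
    open <- reducing_ring_channels(pos)
    dehy_fac <- switch(g$root_anomeric, alpha = 1.0,
                       beta = model$params$trans_dehydration,
                       (1 + model$params$trans_dehydration) / 2)
    ring_w <- if (length(pos) == 1L)
      model$oligo_ring$linear[[as.character(pos)]]
    else model$oligo_ring$branched[names(model$oligo_ring$branched) %in% names(open)]
    for (tok in names(open)) {
      w0 <- if (!is.null(ring_w) && tok %in% names(ring_w)) ring_w[[tok]] else 0
      if (tok == "H2O") w0 <- w0 * dehy_fac
      if (w0 > 0)
        push(sodiated_nominal(n, tok), w0,
             sodiated_species(g, "opened", tok))
    }
  } else {
    # ring-opened precursor: glycosidic cleavage only; the reducing-side
    # remnant keeps the opened ring (and the loss), the nonreducing side
    # comes off as an intact C ion (minor B)
    osp <- model$opened_split
    for (i in seq_len(nrow(bonds))) {
      b <- bonds[i, ]
      pieces <- .split_at_bond(g, b$parent, b$position)
      s <- residue_count(pieces$sub)
      wb <- b$weight
      push(sodiated_nominal(s), wb * osp["C"],
           sodiated_species(pieces$sub, "intact"))
      push(sodiated_nominal(s, "H2O"), wb * osp["B"],
           sodiated_species(pieces$sub, "opened", "H2O"))
      rem_n <- n - s
      rem_mono <- rem_n * mass_constants$hexose_residue +
        mass_constants$water + mass_constants$sodium_cation -
        loss_masses[[sp$loss]]
      if (rem_mono > 100)   # remnant still in the recorded mass range
        push(round(rem_mono), wb * osp["remnant"],
             sodiated_species(pieces$rem, "opened", sp$loss))
    }
  }
  out
}

# aggregate product list into a normalised spectrum (with jitter)
.products_to_spectrum <- function(products, model, path) {
  if (!length(products))
    return(ms_spectrum(numeric(), numeric(), precursor_path = path,
                       metadata = list(unreachable = TRUE)))
  w <- vapply(products, `[[`, numeric(1), "weight")
  keep <- w / max(w) >= model$min_channel
  products <- products[keep]; w <- w[keep]
  mz <- vapply(products, `[[`, numeric(1), "mz")
  agg <- tapply(w, mz, sum)
  int <- as.numeric(agg)
  if (model$noise > 0)
    int <- int * stats::rlnorm(length(int), 0, model$noise)
  normalise_spectrum(ms_spectrum(as.numeric(names(agg)), int,
                                 precursor_path = path))
}

#' Simulate one CID stage
#'
#' @param x a [glycan_structure()] (taken as the intact sodiated molecular
#'   ion) or a [sodiated_species()]
#' @param model a [channel_model()]
#' @return normalised [ms_spectrum()]
#' @export
simulate_cid <- function(x, model = channel_model()) {
  if (inherits(x, "glycan_structure")) x <- sodiated_species(x, "intact")
  if (!is.null(model$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(model$seed)
  }
  .products_to_spectrum(.cid_products(x, model), model,
                        path = .species_nominal(x))
}

#' Simulate an MSn spectral tree
#'
#' Walks the acquisition plan: each path isolates a nominal m/z among the
#' parent node's product populations (all isobaric populations together,
#' e.g. the C2 and Y2 disaccharides at m/z 365) and records the CID
#' spectrum of that mixture. Unreachable paths yield an empty spectrum
#' tagged `unreachable`.
#'
#' @param g a [glycan_structure()]
#' @param plan acquisition plan ([decisive_ion_plan()]); defaults to the
#'   plan for `residue_count(g)`
#' @param model a [channel_model()]
#' @return object of class `spectral_tree`: list with `spectra` (named by
#'   path string) and `structure_string`
#' @export
simulate_tree <- function(g, plan = NULL, model = channel_model()) {
  n <- residue_count(g)
  if (is.null(plan)) {
    if (n == 1L) plan <- data.frame(path = character(), role = character(),
                                    bond = character())
    else plan <- decisive_ion_plan(min(max(n, 2L), 5L))
  }
  if (!is.null(model$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(model$seed)
  }
  root_key <- as.character(sodiated_nominal(n))
  pops <- list()
  pops[[root_key]] <- list(list(species = sodiated_species(g, "intact"),
                                weight = 1))
  spectra <- list()
  prods <- list()   # cached product lists per node key

  node_products <- function(key) {
    if (!is.null(prods[[key]])) return(prods[[key]])
    pop <- pops[[key]]
    if (is.null(pop) || !length(pop)) return(list())
    all <- list()
    for (member in pop) {
      pr <- .cid_products(member$species, model)
      for (p in pr) {
        p$weight <- p$weight * member$weight
        all[[length(all) + 1L]] <- p
      }
    }
    prods[[key]] <<- all
    all
  }

  paths <- plan_paths(plan)
  paths <- paths[order(lengths(paths))]
  for (p in paths) {
    key <- paste(p, collapse = ">")
    if (!is.null(spectra[[key]])) next
    if (length(p) > 1L) {
      parent_key <- paste(p[-length(p)], collapse = ">")
      if (length(p) == 2L) parent_key <- as.character(p[1L])
      target <- p[length(p)]
      parent_products <- node_products(parent_key)
      sel <- Filter(function(x) x$mz == target && !is.null(x$species),
                    parent_products)
      if (!length(sel)) {
        spectra[[key]] <- ms_spectrum(numeric(), numeric(),
                                      precursor_path = p,
                                      metadata = list(unreachable = TRUE))
        pops[[key]] <- list()
        next
      }
      tot <- sum(vapply(sel, `[[`, numeric(1), "weight"))
      pops[[key]] <- lapply(sel, function(x)
        list(species = x$species, weight = x$weight / tot))
    }
    spectra[[key]] <- .products_to_spectrum(node_products(key), model, p)
  }
  structure(list(spectra = spectra, structure_string = serialise_structure(g),
                 n = n),
            class = "spectral_tree")
}

#' @export
print.spectral_tree <- function(x, ...) {
  cat("<spectral_tree> ", x$structure_string, "\n", sep = "")
  for (k in names(x$spectra))
    cat(sprintf("  %-22s %d peaks\n", k, length(x$spectra[[k]]$mz)))
  invisible(x)
}

#' Provider closure over a spectral tree
#'
#' Returns a function mapping a precursor path (integer vector or path
#' string) to the stored spectrum, or NULL when unavailable. Repeated
#' requests return the same spectrum. Requested paths are recorded in the
#' `requested` attribute environment (measurement economy audit).
#' @param tree a [simulate_tree()] result (or a compatible list of spectra)
#' @return function(path) -> [ms_spectrum()] or NULL
#' @export
make_tree_provider <- function(tree) {
  log_env <- new.env()
  log_env$paths <- character()
  f <- function(path) {
    key <- if (is.character(path)) path else paste(path, collapse = ">")
    log_env$paths <- union(log_env$paths, key)
    s <- tree$spectra[[key]]
    if (is.null(s) || !length(s$mz) ||
        isTRUE(s$metadata$unreachable)) return(NULL)
    s
  }
  attr(f, "requested") <- log_env
  f
}

# ---- tree I/O -----------------------------------------------------------

#' Write a spectral tree as a single JSON file
#' @param tree a [simulate_tree()] result
#' @param path output file
#' @return invisibly, the path
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(structure = tree$structure_string, n = tree$n,
              spectra = lapply(tree$spectra, function(s) list(
                path = s$precursor_path, mz = s$mz, intensity = s$intensity,
                unreachable = isTRUE(s$metadata$unreachable))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a spectral tree from JSON
#' @param path file written by [write_tree_json()]
#' @return a `spectral_tree`
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  spectra <- lapply(obj$spectra, function(e)
    ms_spectrum(e$mz %||% numeric(), e$intensity %||% numeric(),
                precursor_path = e$path,
                metadata = if (isTRUE(e$unreachable))
                  list(unreachable = TRUE) else list()))
  structure(list(spectra = spectra,
                 structure_string = obj$structure %||% NA_character_,
                 n = obj$n %||% NA_integer_),
            class = "spectral_tree")
}

#' Write a spectral tree as a directory of MGF files
#' @param tree a `spectral_tree`
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_tree_mgf <- function(tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(tree$spectra)) {
    fn <- file.path(dir, paste0("p", gsub(">", "-", k, fixed = TRUE), ".mgf"))
    write_mgf(tree$spectra[[k]], fn)
  }
  invisible(dir)
}

#' Read a spectral tree from a directory of MGF files
#' @param dir directory written by [write_tree_mgf()]
#' @return a `spectral_tree`
#' @export
read_tree_mgf <- function(dir) {
  files <- list.files(dir, pattern = "\\.mgf$", full.names = TRUE)
  spectra <- list()
  for (f in files) {
    for (s in read_mgf(f)) {
      key <- paste(s$precursor_path, collapse = ">")
      spectra[[key]] <- s
    }
  }
  structure(list(spectra = spectra, structure_string = NA_character_,
                 n = if (length(spectra)) {
                   roots <- vapply(spectra, function(s)
                     s$precursor_path[1L], integer(1))
                   as.integer(round((max(roots) - 41) / 162))
                 } else NA_integer_),
            class = "spectral_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
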