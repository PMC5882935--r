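# Structure-string dialect used throughout: nonreducing end on the left,
# reducing sugar (the tree root) on the right, e.g.
#   "α-Glc-(1→6)-α-Glc-(1→4)-Glc"
# A branch is enclosed in square brackets immediately before its acceptor
# residue: "α-Glc-(1→4)-[α-Glc-(1→6)]-Glc".

ANOMERS <- c("alpha", "beta", "unspecified")
LINK_POSITIONS <- c(1L, 2L, 3L, 4L, 6L)

anomer_symbol <- c(alpha = "α", beta = "β", unspecified = "")

.norm_anomer <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return("unspecified")
  switch(x,
    "α" = "alpha", "a" = "alpha", "alpha" = "alpha",
    "β" = "beta",  "b" = "beta",  "beta"  = "beta",
    "unspecified" = "unspecified",
    stop("unknown anomeric configuration: ", x, call. = FALSE)
  )
}

#' Construct a glucose residue
#'
#' A residue holds its child linkages; each child is a list with elements
#' `anomeric` (configuration of the glycosidic bond, which belongs to the
#' child's anomeric carbon), `position` (acceptor carbon on this residue,
#' one of 1, 2, 3, 4, 6) and `residue` (the child subtree). Children are
#' kept in canonical order (descending acceptor position). Each acceptor
#' position may be used at most once and a residue carries at most three
#' children.
#'
#' @param children list of child linkages (see details)
#' @return an object of class `glycan_residue`
#' @export
glycan_residue <- function(children = list()) {
  if (length(children) > 3L)
    stop_validity("a residue may carry at most 3 children")
  pos <- vapply(children, function(ch) as.integer(ch$position), integer(1))
  if (anyDuplicated(pos))
    stop_validity(sprintf("acceptor position %d used by more than one child",
                          pos[duplicated(pos)][1]))
  if (length(pos) && !all(pos %in% LINK_POSITIONS))
    stop_validity(sprintf("illegal acceptor position %d (must be 1, 2, 3, 4 or 6)",
                          pos[!(pos %in% LINK_POSITIONS)][1]))
  children <- children[order(pos, decreasing = TRUE)]
  structure(list(monosaccharide = "Glc", children = children),
            class = "glycan_residue")
}

.link <- function(anomeric, position, residue) {
  list(anomeric = .norm_anomer(anomeric), position = as.integer(position),
       residue = residue)
}

#' Construct a glycan structure
#'
#' A rooted tree of glucose residues; the root is the reducing sugar. The
#' reducing-end anomeric configuration is usually `"unspecified"` because
#' both anomers coexist in solution (mutarotation).
#'
#' @param root a [glycan_residue()]
#' @param root_anomeric anomeric configuration of the reducing end
#' @return an object of class `glycan_structure`
#' @export
glycan_structure <- function(root, root_anomeric = "unspecified") {
  stopifnot(inherits(root, "glycan_residue"))
  structure(list(root = root, root_anomeric = .norm_anomer(root_anomeric)),
            class = "glycan_structure")
}

stop_parse <- function(...) {
  stop(structure(class = c("glyco_parse_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
stop_validity <- function(...) {
  stop(structure(class = c("glyco_validity_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# tokeniser: brackets, linkage arrows and (optionally prefixed) Glc tokens.
# ASCII aliases ("a-", "b-", "1-4", "1->4") are accepted on input only.
.tokenise <- function(text) {
  pats <- list(
    open    = "^-?\\[",
    close   = "^\\]",
    linkage = "^-\\(1(?:→|->|-)([0-9])\\)-?",
    residue = "^-?(?:(α|β|a|b)-)?Glc"
  )
  toks <- list()
  rest <- text
  while (nzchar(rest)) {
    hit <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(pats[[ty]], rest, perl = TRUE)
      if (m > 0) {
        len <- attr(m, "match.length")
        frag <- substr(rest, 1L, len)
        tok <- list(type = ty, text = frag)
        if (ty == "linkage") {
          pos <- as.integer(sub(pats[[ty]], "\\1", frag, perl = TRUE))
          if (!(pos %in% LINK_POSITIONS))
            stop_parse("illegal linkage position in token '", frag,
                       "' (5 is a ring carbon; allowed: 1, 2, 3, 4, 6)")
          tok$position <- pos
        }
        if (ty == "residue") {
          pre <- sub(pats[[ty]], "\\1", frag, perl = TRUE)
          tok$anomeric <- if (identical(pre, frag)) "unspecified" else .norm_anomer(pre)
        }
        toks[[length(toks) + 1L]] <- tok
        rest <- substr(rest, len + 1L, nchar(rest))
        hit <- TRUE
        break
      }
    }
    if (!hit)
      stop_parse("malformed structure string at '",
                 substr(rest, 1L, 12L), "'")
  }
  toks
}

# parse a residue sequence; returns list(entry|root, i). Inside brackets the
# sequence must end with a dangling linkage (the branch attaches to the
# acceptor residue that follows the closing bracket).
.parse_seq <- function(toks, i, in_bracket) {
  pending <- list()   # child links waiting for their acceptor residue
  prev <- NULL        # completed subtree whose outgoing linkage not yet seen
  while (i <= length(toks)) {
    tok <- toks[[i]]
    if (tok$type == "open") {
      res <- .parse_seq(toks, i + 1L, in_bracket = TRUE)
      pending[[length(pending) + 1L]] <- res$entry
      i <- res$i
    } else if (tok$type == "close") {
      if (!in_bracket) stop_parse("unmatched ']'")
      if (!is.null(prev) || length(pending) != 1L)
        stop_parse("a bracketed branch must end with its linkage, e.g. '[α-Glc-(1→6)]'")
      return(list(entry = pending[[1L]], i = i + 1L))
    } else if (tok$type == "residue") {
      if (!is.null(prev))
        stop_parse("two residues without a linkage near '", tok$text, "'")
      r <- glycan_residue(children = pending)
      pending <- list()
      prev <- list(residue = r, anomeric = tok$anomeric)
      i <- i + 1L
    } else { # linkage
      if (is.null(prev))
        stop_parse("linkage token '", tok$text, "' has no donor residue")
      pending[[length(pending) + 1L]] <-
        .link(prev$anomeric, tok$position, prev$residue)
      prev <- NULL
      i <- i + 1L
    }
  }
  if (in_bracket) stop_parse("unterminated '['")
  if (is.null(prev) || length(pending))
    stop_parse("structure string must end with the reducing-end residue")
  list(root = prev, i = i)
}

#' Parse a glycan structure string
#'
#' @param text structure string, nonreducing to reducing left-to-right
#' @return a [glycan_structure()]
#' @examples
#' parse_structure("α-Glc-(1→6)-α-Glc-(1→4)-Glc")
#' @export
parse_structure <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .tokenise(trimws(text))
  if (!length(toks)) stop_parse("empty structure string")
  res <- .parse_seq(toks, 1L, in_bracket = FALSE)
  glycan_structure(res$root$residue, res$root$anomeric)
}

.anom_prefix <- function(a) {
  if (a == "unspecified") "" else paste0(anomer_symbol[[a]], "-")
}

.ser_res <- function(r, anom) {
  kids <- r$children  # already descending by position
  s <- ""
  if (length(kids)) {
    main <- kids[[length(kids)]]  # lowest position stays on the main chain
    s <- paste0(.ser_res(main$residue, main$anomeric),
                "-(1→", main$position, ")-")
    if (length(kids) > 1L) {
      for (b in kids[seq_len(length(kids) - 1L)]) {
        s <- paste0(s, "[", .ser_res(b$residue, b$anomeric),
                    "-(1→", b$position, ")]")
      }
      s <- paste0(s, "-")
    }
  }
  paste0(s, .anom_prefix(anom), "Glc")
}

#' Serialise a glycan structure to its canonical string
#'
#' Canonical form: the lowest-position child continues the main chain; any
#' other branches are bracketed in descending acceptor-position order.
#' `parse_structure(serialise_structure(g))` reproduces `g`.
#'
#' @param g a [glycan_structure()]
#' @return a single string
#' @export
serialise_structure <- function(g) {
  stopifnot(inherits(g, "glycan_structure"))
  .ser_res(g$root, g$root_anomeric)
}

#' @export
format.glycan_structure <- function(x, ...) serialise_structure(x)

#' @export
print.glycan_structure <- function(x, ...) {
  cat("<glycan_structure> ", serialise_structure(x), "  (",
      residue_count(x), " residues)\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param g a [glycan_structure()] or [glycan_residue()]
#' @return integer residue count
#' @export
residue_count <- function(g) {
  count <- function(r) 1L + sum(vapply(r$children,
                                       function(ch) count(ch$residue), integer(1)))
  if (inherits(g, "glycan_structure")) count(g$root) else count(g)
}

#' Reducing-sugar linkage set
#'
#' Acceptor positions occupied on the reducing sugar, descending. A linear
#' oligosaccharide has one; a branched one has two or more.
#' @param g a [glycan_structure()]
#' @return integer vector of positions
#' @export
reducing_linkages <- function(g) {
  vapply(g$root$children, function(ch) ch$position, integer(1))
}

#' Is the structure an unbranched chain?
#' @param g a [glycan_structure()]
#' @return logical
#' @export
is_linear <- function(g) {
  ok <- function(r) length(r$children) <= 1L &&
    all(vapply(r$children, function(ch) ok(ch$residue), logical(1)))
  ok(g$root)
}

#' Enumerate the glycosidic bonds of a structure
#'
#' Residues are numbered in reducing-to-nonreducing depth-first order, root
#' first (the root is residue 1, matching the convention that the reducing
#' sugar carries label 1). Each bond row records the parent and child
#' residue numbers, acceptor position, bond anomeric configuration, the size
#' of the child subtree (the nonreducing-side fragment for a C/B ion) and
#' the depth of the parent residue.
#'
#' @param g a [glycan_structure()]
#' @return data.frame of bonds (zero rows for a monosaccharide)
#' @export
structure_bonds <- function(g) {
  rows <- list()
  counter <- new.env()
  counter$k <- 1L
  size <- function(r) 1L + sum(vapply(r$children,
                                      function(ch) size(ch$residue), integer(1)))
  walk <- function(r, my_id, depth) {
    for (ch in r$children) {
      counter$k <- counter$k + 1L
      cid <- counter$k
      rows[[length(rows) + 1L]] <<- data.frame(
        parent = my_id, child = cid, position = ch$position,
        anomeric = ch$anomeric, child_size = size(ch$residue),
        parent_depth = depth, stringsAsFactors = FALSE)
      walk(ch$residue, cid, depth + 1L)
    }
  }
  walk(g$root, 1L, 0L)
  if (!length(rows))
    return(data.frame(parent = integer(), child = integer(),
                      position = integer(), anomeric = character(),
                      child_size = integer(), parent_depth = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# ---- topology enumeration ----------------------------------------------

# canonical bracket encoding of a rooted shape: sorted child encodings
.shape_key <- function(shape) {
  if (!length(shape)) return("()")
  paste0("(", paste(sort(vapply(shape, .shape_key, character(1))), collapse = ""), ")")
}

.gen_shapes <- function(n) {
  if (n == 1L) return(list(list()))
  seen <- new.env()
  out <- list()
  smaller <- lapply(seq_len(n - 1L), .gen_shapes)
  # compositions of n-1 into at most 3 ordered parts, deduped via canonical key
  parts_list <- list()
  comp <- function(rem, acc) {
    if (rem == 0L) { parts_list[[length(parts_list) + 1L]] <<- acc; return() }
    if (length(acc) == 3L) return()
    for (p in seq_len(rem)) comp(rem - p, c(acc, p))
  }
  comp(n - 1L, integer())
  for (sizes in parts_list) {
    choice_sets <- lapply(sizes, function(s) smaller[[s]])
    idx <- lapply(choice_sets, seq_along)
    grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
    for (gi in seq_len(nrow(grid))) {
      kids <- Map(function(cs, j) cs[[j]], choice_sets, as.integer(grid[gi, ]))
      key <- .shape_key(kids)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- kids
      }
    }
  }
  out
}

.shape_linear <- function(shape) {
  length(shape) <= 1L && (!length(shape) || .shape_linear(shape[[1L]]))
}

.branch_depth <- function(shape, depth = 0L) {
  if (length(shape) > 1L) return(depth)
  if (!length(shape)) return(NA_integer_)
  .branch_depth(shape[[1L]], depth + 1L)
}

.shape_size <- function(shape) {
  1L + sum(vapply(shape, .shape_size, integer(1)))
}

#' Enumerate rooted topology classes on n residues
#'
#' Distinct rooted unlabeled tree shapes with at most three children per
#' residue, each tagged linear/branched with the depth of the shallowest
#' branch point (0 = branch on the reducing sugar). For n = 4 the four
#' classes correspond to the tetrasaccharide types: I linear, II branched on
#' the reducing sugar, III branched on the nonreducing side, IV two branches
#' on the reducing sugar.
#'
#' @param n residue count, 1..6
#' @return data.frame with columns shape, n_residues, linear, branch_depth
#'   (and tetra_type for n = 4)
#' @export
enumerate_topologies <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > 6 || n != round(n))
    stop("n must be an integer in 1..6")
  n <- as.integer(n)
  shapes <- .gen_shapes(n)
  df <- data.frame(
    shape = vapply(shapes, .shape_key, character(1)),
    n_residues = n,
    linear = vapply(shapes, .shape_linear, logical(1)),
    branch_depth = vapply(shapes, .branch_depth, integer(1)),
    stringsAsFactors = FALSE)
  df <- df[order(!df$linear, df$branch_depth, df$shape), , drop = FALSE]
  rownames(df) <- NULL
  if (n == 4L) {
    ty <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$linear[i]) ty[i] <- "I"
      else {
        shp <- shapes[[match(df$shape[i], vapply(shapes, .shape_key, character(1)))]]
        k <- length(shp)
        ty[i] <- if (k == 3L) "IV"
                 else if (k == 2L) "II"
                 else "III"
      }
    }
    df$tetra_type <- ty
  }
  df
}

#' Topology class of a concrete structure
#'
#' Returns the canonical shape key of `g`, comparable against
#' [enumerate_topologies()] output.
#' @param g a [glycan_structure()]
#' @return shape key string
#' @export
structure_shape <- function(g) {
  as_shape <- function(r) lapply(r$children, function(ch) as_shape(ch$residue))
  .shape_key(as_shape(g$root))
}
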