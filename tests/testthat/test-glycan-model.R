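test_that("structure strings parse into the expected trees", {
  g <- parse_structure(panose_str)
  expect_equal(residue_count(g), 3L)
  expect_equal(g$root_anomeric, "unspecified")
  expect_equal(reducing_linkages(g), 4L)
  r2 <- g$root$children[[1]]
  expect_equal(r2$anomeric, "alpha")
  expect_equal(r2$residue$children[[1]]$position, 6L)
  expect_equal(r2$residue$children[[1]]$anomeric, "alpha")

  expect_equal(residue_count(parse_structure("Glc")), 1L)

  iso <- parse_structure(isopanose_str)
  expect_equal(sort(reducing_linkages(iso)), c(4L, 6L))
  expect_true(all(vapply(iso$root$children, function(ch)
    ch$anomeric == "alpha", logical(1))))
  expect_false(is_linear(iso))
  expect_true(is_linear(g))
})

test_that("ASCII aliases are accepted on input but never emitted", {
  g <- parse_structure("a-Glc-(1-6)-a-Glc-(1->4)-Glc")
  expect_identical(serialise_structure(g), panose_str)
})

test_that("serialisation is canonical and round-trips", {
  expect_identical(serialise_structure(parse_structure("Glc")), "Glc")
  expect_identical(serialise_structure(parse_structure(panose_str)),
                   panose_str)
  expect_identical(serialise_structure(parse_structure(isopanose_str)),
                   isopanose_str)
  # branch order normalises to main chain = lowest acceptor position
  flip <- parse_structure("α-Glc-(1→6)-[α-Glc-(1→4)]-Glc")
  expect_identical(serialise_structure(flip), isopanose_str)
})

test_that("parse/serialise round-trips over the full small-structure panel", {
  for (s in c(linear_tri_panel(), branched_tri_panel(), cellotetraose_str,
              "β-Glc-(1→2)-Glc", "α-Glc-(1→3)-[α-Glc-(1→4)]-[α-Glc-(1→6)]-Glc")) {
    g <- parse_structure(s)
    s2 <- serialise_structure(g)
    expect_identical(serialise_structure(parse_structure(s2)), s2)
  }
})

test_that("malformed and invalid structures are rejected with named tokens", {
  expect_error(parse_structure("α-Glc-(1→5)-Glc"), "ring carbon",
               class = "glyco_parse_error")
  expect_error(parse_structure("α-Glc-(1→4)-Xyl"), "malformed",
               class = "glyco_parse_error")
  expect_error(parse_structure("α-Glc-(1→4)-α-Glc-(1→4)-"),
               class = "glyco_parse_error")
  expect_error(parse_structure(""), class = "glyco_parse_error")
  # duplicate acceptor position is a validity error, deterministically
  for (i in 1:3)
    expect_error(parse_structure("α-Glc-(1→4)-[β-Glc-(1→4)]-Glc"),
                 "position 4", class = "glyco_validity_error")
})

test_that("the 1->1 linkage is representable but carries no rule support", {
  g <- parse_structure("α-Glc-(1→1)-Glc")
  expect_equal(reducing_linkages(g), 1L)
  fr <- enumerate_fragments(g)
  expect_false(any(fr$type %in% c("dehydration", "A")))
})

# independent oracle: enumerate rooted unlabeled trees (max 3 children)
# via parent vectors p[i] < i, counting canonical forms
.oracle_count_shapes <- function(n) {
  if (n == 1) return(1L)
  canon <- function(children_of, node) {
    kids <- children_of[[node]]
    if (!length(kids)) return("()")
    paste0("(", paste(sort(vapply(kids, function(k)
      canon(children_of, k), character(1))), collapse = ""), ")")
  }
  seen <- new.env()
  grid <- expand.grid(rep(list(seq_len(n - 1)), n - 1))
  keep <- apply(grid, 1, function(p) all(p <= seq_along(p)))
  grid <- grid[keep, , drop = FALSE]
  for (i in seq_len(nrow(grid))) {
    parent <- c(0L, as.integer(grid[i, ]))
    children_of <- lapply(seq_len(n), function(j) which(parent == j) )
    if (max(lengths(children_of)) > 3L) next
    assign(canon(children_of, 1L), TRUE, envir = seen)
  }
  length(ls(seen))
}

test_that("topology enumeration matches brute-force counting", {
  for (n in 1:5)
    expect_equal(nrow(enumerate_topologies(n)), .oracle_count_shapes(n),
                 info = paste("n =", n))
  expect_error(enumerate_topologies(0))
  expect_error(enumerate_topologies(7))
})

test_that("the four tetrasaccharide classes carry their type labels", {
  t4 <- enumerate_topologies(4)
  expect_equal(nrow(t4), 4L)
  expect_setequal(t4$tetra_type, c("I", "II", "III", "IV"))
  expect_true(t4$linear[t4$tetra_type == "I"])
  expect_equal(t4$branch_depth[t4$tetra_type == "III"], 1L)
  expect_equal(t4$branch_depth[t4$tetra_type == "II"], 0L)
  # concrete structures land in their classes
  shp <- structure_shape(parse_structure(cellotetraose_str))
  expect_equal(t4$tetra_type[t4$shape == shp], "I")
  shp2 <- structure_shape(
    parse_structure("β-Glc-(1→4)-β-Glc-(1→4)-[α-Glc-(1→6)]-Glc"))
  expect_equal(t4$tetra_type[t4$shape == shp2], "II")
})
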