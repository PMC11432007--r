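test_that("a minimal hand-written glycine PDB parses to one chain, one residue, four atoms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_gly_pdb(path)
  s <- read_structure(path)
  expect_s3_class(s, "ecd_structure")
  expect_identical(chain_ids(s), "A")
  expect_identical(nrow(s$atoms), 4L)
  expect_identical(unique(s$atoms$resid), "GLY")
  expect_identical(sort(s$atoms$elety), sort(c("N", "CA", "C", "O")))
})

test_that("PDB write/read round-trips names, numbering and geometry", {
  s <- make_planted_pentamer()$structure
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_identical(s2$atoms$chain, s$atoms$chain)
  expect_identical(s2$atoms$resno, s$atoms$resno)
  expect_identical(s2$atoms$resid, s$atoms$resid)
  expect_identical(s2$atoms$elety, s$atoms$elety)
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                    as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)
  ## idempotence: a second round trip is exact
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, path2)
  s3 <- read_structure(path2)
  expect_identical(s3$atoms[, c("x", "y", "z")], s2$atoms[, c("x", "y", "z")])
})

test_that("written ATOM records use fixed-format three-decimal coordinates", {
  s <- ecd_structure(data.frame(chain = "A", resno = 1L, insert = "",
                                resid = "GLY", elety = "CA", elesy = "C",
                                x = 1.0, y = 2.0, z = 3.0))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  txt <- readLines(path)
  expect_true(any(grepl("1.000   2.000   3.000", txt, fixed = TRUE)))
  ## empty structure writes a header-only file
  empty <- ecd_structure(data.frame(chain = character(), resno = integer(),
                                    resid = character(), elety = character(),
                                    elesy = character(), x = numeric(),
                                    y = numeric(), z = numeric()))
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(empty, path2)
  expect_false(any(grepl("^ATOM", readLines(path2))))
})

test_that("oversized and unreadable inputs raise informative errors", {
  n <- 100000L
  big <- ecd_structure(data.frame(chain = "A", resno = seq_len(n),
                                  insert = "", resid = "GLY", elety = "CA",
                                  elesy = "C", x = 0, y = 0, z = 0))
  expect_error(write_structure(big, tempfile()), "99999")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", bad)
  expect_error(read_structure(bad), "parse|protein")
  expect_error(read_structure("no/such/file.pdb"), "not found")
})

test_that("chains are assigned to subunits by identity, honouring the 2:2:1 stoichiometry", {
  fr <- ecd_fragments()
  s <- seq_to_ca_structure(list(A = as.character(fr$alpha1),
                                B = as.character(fr$beta2),
                                C = as.character(fr$alpha1),
                                D = as.character(fr$beta2),
                                E = as.character(fr$gamma2)))
  asg <- assign_subunits(s, fr)
  expect_identical(asg$subunit, c("alpha1", "beta2", "alpha1", "beta2",
                                  "gamma2"))
  counts <- attr(asg, "counts")
  expect_equal(unname(counts[c("alpha1", "beta2", "gamma2")]),
               c(2L, 2L, 1L), ignore_attr = TRUE)
  expect_true(all(asg$identity[asg$subunit != "unknown"] > 99))
})

test_that("low-identity chains are unknown, assignment is order-invariant, ties error", {
  fr <- ecd_fragments()
  set.seed(42)
  rand <- random_aa(150)
  s <- seq_to_ca_structure(list(A = as.character(fr$alpha1), B = rand))
  asg <- assign_subunits(s, fr)
  expect_identical(asg$subunit[asg$chain == "B"], "unknown")
  ## permutation invariance
  s2 <- seq_to_ca_structure(list(B = rand, A = as.character(fr$alpha1)))
  asg2 <- assign_subunits(s2, fr)
  expect_identical(asg2$subunit[asg2$chain == "A"],
                   asg$subunit[asg$chain == "A"])
  expect_identical(asg2$subunit[asg2$chain == "B"],
                   asg$subunit[asg$chain == "B"])
  ## duplicate references tie
  expect_error(
    assign_subunits(s, list(ref1 = fr$alpha1, ref2 = fr$alpha1)),
    "ties")
})

test_that("numbering maps are bijective, monotone, and range-checked", {
  map <- numbering_map(101:150, origin = 101)
  expect_identical(frag_to_author(map, 5L), 105L)
  expect_identical(author_to_frag(map, 105L), 5L)
  ## identity spec: origin = first residue
  expect_identical(frag_to_author(map, 1L), 101L)
  ## composing with the inverse is the identity over the whole domain
  expect_identical(author_to_frag(map, frag_to_author(map, map$fragment)),
                   map$fragment)
  expect_error(frag_to_author(map, 51L), "outside")
  expect_error(author_to_frag(map, 100L), "outside")
  expect_error(numbering_map(101:150, origin = 99), "absent")
  ## fragment-origin anchoring: alpha1-style origin at author 28
  map2 <- numbering_map(28:248, origin = 28)
  expect_identical(frag_to_author(map2, 1L), 28L)
  expect_identical(author_to_frag(map2, 248L), 221L)
})

test_that("locate_fragment anchors fragment coordinates on author numbering", {
  fr <- ecd_fragments()
  s <- seq_to_ca_structure(list(A = as.character(fr$alpha1)))
  s$atoms$resno <- s$atoms$resno + 27L    # author numbering starts at 28
  map <- locate_fragment(s, "A", fr$alpha1)
  expect_identical(as.integer(frag_to_author(map, 70L)), 97L)
  expect_identical(author_to_frag(map, 28L), 1L)
})
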