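test_that("an ideal alpha helix is assigned mostly H", {
  hel <- build_backbone(20, -57, -47)
  ss <- assign_ss(hel)
  expect_gte(mean(ss$A == "H"), 0.8)
  ## labels are invariant under rigid motion
  set.seed(4)
  hel2 <- transform_structure(hel, random_rotation(), rnorm(3, sd = 10))
  expect_identical(assign_ss(hel2)$A, ss$A)
})

test_that("two ideal antiparallel strands produce central strand labels", {
  sA <- build_backbone(8, 180, 180, chain = "A")
  sB <- transform_structure(sA, diag(c(-1, 1, -1)), c(18.35, 4.75, 0))
  bat <- sB$atoms
  bat$resno <- bat$resno + 20L
  s <- ecd_structure(rbind(sA$atoms, bat))
  ss <- assign_ss(s)$A
  first <- ss[1:8]; second <- ss[9:16]
  expect_true(all(first[4:6] == "E"))
  expect_gte(sum(second == "E"), 2)
  expect_false(any(ss == "H"))
})

test_that("degenerate chains are coil", {
  one <- build_backbone(1, -57, -47)
  expect_identical(unname(assign_ss(one)$A), "C")
  two <- build_backbone(2, -57, -47)
  expect_true(all(assign_ss(two)$A == "C"))
  ## CA-only residues cannot be assigned and fall back to coil
  ca_only <- seq_to_ca_structure(list(A = "ACDEFGHIKL"))
  expect_true(all(assign_ss(ca_only)$A == "C"))
})

test_that("beta content is the strand percentage of a chain", {
  ss <- structure(list(A = c(rep("E", 5), rep("C", 5)),
                       B = rep("C", 4)),
                  class = "ss_assignment")
  expect_equal(beta_content(ss, "A"), 50.0)
  expect_equal(beta_content(ss, "B"), 0.0)
  expect_error(beta_content(ss, "Z"), "not in assignment")
  sm <- ss_summary(ss)
  expect_equal(sm$pct_strand[sm$chain == "A"], 50.0)
})

test_that("Kabsch superposition is exact on rigid-transformed copies and symmetric", {
  set.seed(13)
  A <- matrix(rnorm(300, sd = 8), 100, 3)
  R <- random_rotation(); tr <- rnorm(3, sd = 15)
  B <- sweep(A %*% t(R), 2, tr, "+")
  sp <- superpose(A, B)
  expect_lt(sp$rmsd_all_pairs, 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  ## symmetry of the RMSD in its arguments
  B2 <- B; B2[1, ] <- B2[1, ] + c(1, 0, 0)
  expect_equal(superpose(A, B2)$rmsd_all_pairs,
               superpose(B2, A)$rmsd_all_pairs, tolerance = 1e-6)
  ## invariance to pre-applied rigid motions of either input
  A2 <- sweep(A %*% t(random_rotation()), 2, rnorm(3), "+")
  expect_equal(superpose(A2, B2)$rmsd_all_pairs,
               superpose(A, B2)$rmsd_all_pairs, tolerance = 1e-6)
  expect_error(superpose(A[1:2, ], B[1:2, ]), "at least 3")
})

test_that("superposition RMSD agrees with an independent least-squares fit", {
  set.seed(29)
  A <- matrix(rnorm(300, sd = 8), 100, 3)
  B <- A
  B[7, ] <- B[7, ] + c(1, 0, 0)    # one CA displaced by 1 A
  R <- random_rotation(); tr <- c(3, -2, 5)
  B <- sweep(B %*% t(R), 2, tr, "+")
  sp <- superpose(A, B)
  ## bio3d's fit.xyz as the independent oracle
  fit <- bio3d::fit.xyz(fixed = as.numeric(t(A)), mobile = as.numeric(t(B)),
                        fixed.inds = 1:300, mobile.inds = 1:300)
  oracle <- bio3d::rmsd(as.numeric(t(A)), fit)
  expect_equal(sp$rmsd_all_pairs, oracle, tolerance = 1e-3)
  ## pruning drops the displaced pair and tightens the fit
  spp <- superpose(A, B, prune_cutoff = 0.5)
  expect_identical(spp$n_pruned, 99L)
  expect_lt(spp$rmsd_pruned, sp$rmsd_all_pairs)
})

test_that("alignment-derived CA pairing feeds superposition", {
  fr <- ecd_fragments()
  s1 <- seq_to_ca_structure(list(A = as.character(fr$alpha1)))
  set.seed(55)
  s2 <- transform_structure(s1, random_rotation(), rnorm(3, sd = 10))
  pr <- ca_pairs_from_alignment(s1, "A", s2, "A")
  expect_identical(pr$n, 221L)
  expect_lt(superpose(pr$a, pr$b)$rmsd_all_pairs, 1e-6)
})

test_that("density synthesis follows the molmap convention", {
  one <- ecd_structure(data.frame(chain = "A", resno = 1L, insert = "",
                                  resid = "GLY", elety = "CA", elesy = "C",
                                  x = 1, y = 2, z = 3))
  m <- synthesize_density(one, 10)
  ## maximum at the atom position
  idx <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  peak <- m$origin + (idx - 1) * m$spacing
  expect_equal(unname(peak), c(1, 2, 3), tolerance = m$spacing)
  ## integral equals the atomic number (to discretisation)
  expect_equal(map_integral(m), 6, tolerance = 0.01 * 6)
  ## linearity: two coincident atoms double the map exactly
  two <- ecd_structure(one$atoms[c(1, 1), ])
  m2 <- synthesize_density(two, 10)
  expect_equal(m2$values, 2 * m$values, tolerance = 1e-9)
})

test_that("lower resolution lowers the peak but conserves the integral", {
  s <- make_planted_pentamer()$structure
  m10 <- synthesize_density(s, 10)
  m15 <- synthesize_density(s, 15)
  expect_lt(max(m15$values), max(m10$values))
  z_total <- sum(c(H = 1, C = 6, N = 7, O = 8, P = 15,
                   S = 16)[toupper(s$atoms$elesy)])
  expect_equal(map_integral(m10), z_total, tolerance = 0.01)
  expect_equal(map_integral(m15), z_total, tolerance = 0.01)
  expect_equal(map_integral(m10), map_integral(m15), tolerance = 0.01)
})

test_that("map correlation is 1 on self, -1 on negation, high after resampling a moved copy", {
  s <- make_planted_pentamer()$structure
  m <- synthesize_density(s, 10)
  expect_equal(map_correlation(m, m), 1.0, tolerance = 1e-12)
  neg <- m; neg$values <- -neg$values
  expect_equal(map_correlation(m, neg), -1.0, tolerance = 1e-12)
  ## the same density sampled on a different grid correlates after
  ## trilinear resampling
  m2 <- synthesize_density(s, 10, spacing = 10 / 6)
  expect_gte(map_correlation(m, m2), 0.99)
  ## a rigidly moved copy whose map is aligned back coincides exactly:
  ## its bounding-box grid shifts with the structure, so after removing
  ## the shift the voxel values agree on the common grid
  s2 <- transform_structure(s, diag(3), c(1.7, -2.3, 0.9))
  m3 <- synthesize_density(s2, 10)
  m3$origin <- m3$origin - c(1.7, -2.3, 0.9)
  expect_gte(map_correlation(m, m3), 0.999)
  flat <- m; flat$values[] <- 1
  expect_error(map_correlation(flat, flat), "zero variance|undefined")
})
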