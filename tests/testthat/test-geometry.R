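test_that("ring centroids are coordinate means, equivariant under translation", {
  at <- hexagon_residue("A", 1, c(0, 0, 0))
  s <- ecd_structure(at)
  ps <- ring_centroid(s, "A", 1, "tyr_six")
  expect_equal(ps$position, c(0, 0, 0), tolerance = 1e-9)
  s2 <- ecd_structure(hexagon_residue("A", 1, c(5, 0, 0)))
  expect_equal(ring_centroid(s2, "A", 1, "tyr_six")$position, c(5, 0, 0),
               tolerance = 1e-9)
  ## general equivariance under a rigid motion
  set.seed(17)
  R <- random_rotation(); tr <- rnorm(3)
  s3 <- transform_structure(s, R, tr)
  expect_equal(ring_centroid(s3, "A", 1, "tyr_six")$position,
               as.numeric(R %*% ps$position) + tr, tolerance = 1e-9)
  ## centroid equals the plain coordinate mean of the ring atoms
  pp <- make_planted_pentamer()$structure
  trp <- pp$atoms[pp$atoms$chain == "A" & pp$atoms$resno == 1, ]
  expect_equal(ring_centroid(pp, "A", 1)$position,
               c(mean(trp$x), mean(trp$y), mean(trp$z)), tolerance = 1e-6)
})

test_that("ring definitions validate residue type and completeness", {
  s <- ecd_structure(hexagon_residue("A", 1, c(0, 0, 0)))
  expect_error(ring_centroid(s, "A", 1, "trp_indole9"), "TRP")
  incomplete <- hexagon_residue("A", 1, c(0, 0, 0))
  incomplete <- incomplete[incomplete$elety != "CZ", ]
  expect_error(ring_centroid(ecd_structure(incomplete), "A", 1, "tyr_six"),
               "CZ")
  expect_error(ring_centroid(s, "A", 1, "nonsense"), "unknown ring")
})

test_that("pi-stacking distances recover planted geometry with the strict 6 A rule", {
  s <- make_planted_pentamer(pi_distance = 5.85)$structure
  rec <- pi_stack_distance(s, "A", 1, "A", 2)
  expect_equal(rec$distance, 5.85, tolerance = 1e-6)
  expect_true(rec$within_contact)
  s2 <- make_planted_pentamer(pi_distance = 6.40)$structure
  rec2 <- pi_stack_distance(s2, "A", 1, "A", 2)
  expect_equal(rec2$distance, 6.40, tolerance = 1e-6)
  expect_false(rec2$within_contact)
  ## the contact rule is strictly less-than at the boundary
  s3 <- make_planted_pentamer(pi_distance = 6.0)$structure
  expect_false(pi_stack_distance(s3, "A", 1, "A", 2)$within_contact)
  expect_error(pi_stack_distance(s, "A", 1, "A", 1), "distinct")
})

test_that("disulfide midpoints require bonded SG pairs", {
  mk <- function(d) ecd_structure(data.frame(
    chain = "A", resno = c(1L, 2L), insert = "", resid = "CYS",
    elety = "SG", elesy = "S", x = c(0, d), y = 0, z = 0))
  ps <- disulfide_midpoint(mk(2.0), "A", 1, "A", 2)
  expect_equal(ps$position, c(1, 0, 0), tolerance = 1e-9)
  expect_error(disulfide_midpoint(mk(3.5), "A", 1, "A", 2), "not disulfide")
  bad <- ecd_structure(data.frame(chain = "A", resno = 1:2, insert = "",
                                  resid = c("SER", "CYS"), elety = "SG",
                                  elesy = "S", x = c(0, 2), y = 0, z = 0))
  expect_error(disulfide_midpoint(bad, "A", 1, "A", 2), "CYS")
})

test_that("S-pi distances recover planted Tyr/disulfide geometry, including zero", {
  s <- make_planted_pentamer(s_pi_distance = 4.5)$structure
  rec <- s_pi_distance(s, "A", 3, "A", 4, 5)
  expect_equal(rec$distance, 4.5, tolerance = 1e-6)
  ## Tyr ring centred exactly on the disulfide midpoint
  at <- rbind(hexagon_residue("A", 1, c(1, 0, 0)),
              data.frame(chain = "A", resno = c(2L, 3L), insert = "",
                         resid = "CYS", elety = "SG", elesy = "S",
                         x = c(0, 2), y = 0, z = 0))
  expect_equal(s_pi_distance(ecd_structure(at), "A", 1, "A", 2, 3)$distance,
               0, tolerance = 1e-9)
})

test_that("hydrogen-bond detection honours the distance cutoff and planted decoys", {
  pp <- make_planted_pentamer(hbond_distance = 2.9, decoy_distance = 4.2)
  hb <- detect_hbonds(pp$structure, "A", "B")
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_identical(hb$donor_chain, "B")
  expect_identical(hb$donor_resno, 6L)
  expect_identical(hb$acceptor_chain, "A")
  expect_identical(hb$acceptor_resno, 7L)
  ## widening the cutoff reveals the decoy pair too
  hb2 <- detect_hbonds(pp$structure, "A", "B", max_da = 4.5)
  expect_identical(nrow(hb2), 2L)
  expect_true(any(abs(hb2$distance - 4.2) < 1e-6))
  expect_error(detect_hbonds(pp$structure, "A", "A"), "distinct")
})

test_that("the D-H...A angle test applies only when explicit hydrogens exist", {
  mk <- function(acc_pos) {
    at <- rbind(
      data.frame(chain = "A", resno = 1L, insert = "", resid = "GLY",
                 elety = c("N", "H"), elesy = c("N", "H"),
                 x = c(0, 1), y = 0, z = 0),
      data.frame(chain = "B", resno = 1L, insert = "", resid = "ALA",
                 elety = "O", elesy = "O",
                 x = acc_pos[1], y = acc_pos[2], z = acc_pos[3]))
    ecd_structure(at)
  }
  ## linear D-H...A at 2.9 A passes
  expect_identical(nrow(detect_hbonds(mk(c(2.9, 0, 0)), "A", "B")), 1L)
  ## same distance but bent to ~71 degrees fails the angle criterion
  expect_identical(nrow(detect_hbonds(mk(c(0, 2.9, 0)), "A", "B")), 0L)
})

test_that("bond-set comparison partitions by donor/acceptor residue key", {
  mk <- function(pairs) data.frame(donor_resno = pairs[, 1],
                                   acceptor_resno = pairs[, 2])
  a <- mk(cbind(c(1, 2, 3), c(11, 12, 13)))
  same <- compare_bond_sets(a, a)
  expect_identical(nrow(same$shared), 3L)
  expect_identical(nrow(same$only_a), 0L)
  expect_identical(nrow(same$only_b), 0L)
  b <- mk(cbind(c(2, 3, 4), c(12, 13, 14)))
  cmp <- compare_bond_sets(a, b)
  expect_identical(cmp$shared$donor_resno, c(2, 3))
  expect_identical(cmp$only_a$donor_resno, 1)
  expect_identical(cmp$only_b$donor_resno, 4)
})

test_that("distance aggregation matches a naive two-pass oracle", {
  dt <- aggregate_distances(data.frame(s1 = c(5, 5, 5)))
  expect_equal(unname(dt$mean), 5)
  expect_equal(unname(dt$sem), 0)
  expect_equal(unname(dt$max), 5)
  expect_equal(unname(dt$min), 5)
  set.seed(33)
  for (k in 1:10) {
    m <- matrix(runif(24, 3, 7), 8, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    dt <- aggregate_distances(m)
    for (cc in colnames(m)) {
      o <- naive_mean_sem(m[, cc])
      expect_equal(unname(dt$mean[cc]), o$mean, tolerance = 1e-9)
      expect_equal(unname(dt$sem[cc]), o$sem, tolerance = 1e-9)
    }
    expect_true(all(dt$min <= dt$mean & dt$mean <= dt$max))
  }
  expect_error(aggregate_distances(data.frame(a = 1)), "SEM undefined")
})

test_that("all measured distances are invariant under rigid motion", {
  pp <- make_planted_pentamer()
  s <- pp$structure
  d0 <- c(pi = pi_stack_distance(s, "A", 1, "A", 2)$distance,
          spi = s_pi_distance(s, "A", 3, "A", 4, 5)$distance,
          hb = detect_hbonds(s, "A", "B")$distance)
  set.seed(99)
  for (k in 1:5) {
    st <- transform_structure(s, random_rotation(), rnorm(3, sd = 20))
    d1 <- c(pi = pi_stack_distance(st, "A", 1, "A", 2)$distance,
            spi = s_pi_distance(st, "A", 3, "A", 4, 5)$distance,
            hb = detect_hbonds(st, "A", "B")$distance)
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})
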