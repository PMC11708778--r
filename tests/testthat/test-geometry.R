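test_that("distances follow Euclid and resolve selectors by residue/atom", {
  st <- toy_state(c(0, 0, 0, 3, 4, 0), residue_id = c(190L, 1L),
                  atom_name = c("OG", "C"), element = c("O", "C"))
  expect_equal(atom_distance(st, sel(190, "OG"), sel(1, "C")), 5)
  expect_equal(atom_distance(st, sel(190, "OG"), sel(190, "OG")), 0)
  expect_error(atom_distance(st, sel(99, "XX"), sel(1, "C")), "resolved to 0")
})

test_that("a nucleophilic-attack fixture reproduces the 2.72 A approach distance", {
  st <- toy_state(c(0, 0, 0, 2.72, 0, 0), residue_id = c(190L, 500L),
                  atom_name = c("OG", "C1"), element = c("O", "C"))
  expect_equal(atom_distance(st, sel(190, "OG"), sel(500, "C1")), 2.72)
})

test_that("the Buergi-Dunitz angle handles collinear, right-angle and 108-degree cases", {
  mk <- function(nu) toy_state(rbind(nu, c(0, 0, 0), c(1, 0, 0)),
                               residue_id = c(190L, 500L, 500L),
                               atom_name = c("OG", "C1", "O1"),
                               element = c("O", "C", "O"))
  expect_equal(burgi_dunitz_angle(mk(c(-1, 0, 0)), sel(190, "OG"),
                                  sel(500, "C1"), sel(500, "O1")), 180)
  expect_equal(burgi_dunitz_angle(mk(c(0, 1, 0)), sel(190, "OG"),
                                  sel(500, "C1"), sel(500, "O1")), 90)
  ang <- 108 * pi / 180
  st <- mk(c(cos(ang), sin(ang), 0))
  expect_equal(burgi_dunitz_angle(st, sel(190, "OG"), sel(500, "C1"),
                                  sel(500, "O1")), 108, tolerance = 0.1)
  bad <- mk(c(0, 0, 0))   # nucleophile coincident with the carbonyl carbon
  expect_error(burgi_dunitz_angle(bad, sel(190, "OG"), sel(500, "C1"),
                                  sel(500, "O1")), "degenerate")
})

test_that("hydrogen-bond scans filter by cutoff and sort ascending", {
  st <- toy_state(rbind(c(0, 0, 0), c(1, 0, 0), c(2.56, 0, 0), c(1, 1.6, 0)),
                  residue_id = c(166L, 166L, 91L, 167L),
                  atom_name = c("OG", "HG", "NZ", "OG"),
                  element = c("O", "H", "N", "O"))
  donors <- list(list(sel(166, "OG"), sel(166, "HG")))
  hits <- hbond_scan(st, donors, list(sel(91, "NZ"), sel(167, "OG")),
                     h_a_cutoff = 2.5)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$distance, c(1.56, 1.6))   # sorted ascending
  expect_equal(hits$acceptor[1], "91:NZ")

  none <- hbond_scan(st, donors, list(sel(91, "NZ")), h_a_cutoff = 1.0)
  expect_equal(nrow(none), 0)
})

test_that("distances and angles are invariant under common rigid transforms", {
  set.seed(31)
  st <- toy_state(matrix(stats::rnorm(15), 5, 3), residue_id = rep(1L, 5),
                  atom_name = paste0("C", 1:5))
  d0 <- atom_distance(st, sel(1, "C1"), sel(1, "C4"))
  a0 <- burgi_dunitz_angle(st, sel(1, "C1"), sel(1, "C2"), sel(1, "C3"))
  for (i in 1:8) {
    tr <- transform_state(st, random_rotation(), stats::rnorm(3, sd = 10))
    expect_equal(atom_distance(tr, sel(1, "C1"), sel(1, "C4")), d0,
                 tolerance = 1e-9)
    expect_equal(burgi_dunitz_angle(tr, sel(1, "C1"), sel(1, "C2"),
                                    sel(1, "C3")), a0, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD is zero for congruent structures and symmetric in its arguments", {
  set.seed(5)
  st <- toy_state(matrix(stats::rnorm(18), 6, 3), residue_id = rep(1L, 6),
                  atom_name = paste0("C", 1:6))
  expect_equal(kabsch_rmsd(st, st), 0, tolerance = 1e-12)
  for (i in 1:6) {
    tr <- transform_state(st, random_rotation(), stats::rnorm(3, sd = 5))
    expect_lt(kabsch_rmsd(st, tr), 1e-9)
  }
  perturbed <- st
  perturbed$atoms$x[1] <- perturbed$atoms$x[1] + 0.8
  r_ab <- kabsch_rmsd(st, perturbed)
  expect_equal(r_ab, kabsch_rmsd(perturbed, st), tolerance = 1e-10)
  expect_gt(r_ab, 0)
})

test_that("Kabsch RMSD matches an independent rotation-grid oracle on 4-atom toys", {
  set.seed(17)
  for (i in 1:3) {
    A <- matrix(stats::rnorm(12), 4, 3)
    B <- A
    B[4, ] <- B[4, ] + stats::rnorm(3) / sqrt(3)   # ~1 A displacement
    rot <- random_rotation()
    B <- B %*% t(rot)
    sa <- toy_state(A, residue_id = rep(1L, 4), atom_name = paste0("C", 1:4))
    sb <- toy_state(B, residue_id = rep(1L, 4), atom_name = paste0("C", 1:4))
    expect_equal(kabsch_rmsd(sa, sb), grid_rmsd_oracle(A, B),
                 tolerance = 1e-5)
  }
})

test_that("Kabsch RMSD agrees with the bio3d superposition routine", {
  set.seed(23)
  A <- matrix(stats::rnorm(24), 8, 3)
  B <- A + matrix(stats::rnorm(24, sd = 0.3), 8, 3)
  sa <- toy_state(A, residue_id = rep(1L, 8), atom_name = paste0("C", 1:8))
  sb <- toy_state(B, residue_id = rep(1L, 8), atom_name = paste0("C", 1:8))
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  # bio3d reports the RMSD rounded to three decimals
  expect_equal(round(kabsch_rmsd(sa, sb), 3), ref)
})

test_that("underdetermined or mismatched superpositions are rejected", {
  sa <- toy_state(matrix(1:6, 2, 3), residue_id = rep(1L, 2),
                  atom_name = c("C1", "C2"))
  expect_error(kabsch_rmsd(sa, sa), "at least 3")
  sb <- toy_state(matrix(1:12, 4, 3), residue_id = rep(1L, 4),
                  atom_name = paste0("C", 1:4))
  sc <- toy_state(matrix(1:9, 3, 3), residue_id = rep(1L, 3),
                  atom_name = paste0("C", 1:3))
  expect_error(kabsch_rmsd(sb, sc), "do not match")
})

test_that("charge deltas report per-atom electron-density rearrangement", {
  mk <- function(q) toy_state(rbind(c(0, 0, 0), c(1, 1, 1)),
                              residue_id = c(190L, 500L),
                              atom_name = c("OG", "OC"), charge = q,
                              element = "O")
  same <- charge_delta(mk(c(-0.2, -0.3)), mk(c(-0.2, -0.3)))
  expect_equal(same$delta_q, c(0, 0))
  # serine O-gamma upon activation; carbonyl O upon nucleophilic attack
  d <- charge_delta(mk(c(-0.22, -0.28)), mk(c(-0.33, -0.32)))
  expect_equal(d$delta_q[d$atom_name == "OG"], -0.11)
  expect_equal(d$delta_q[d$atom_name == "OC"], -0.04)
  no_q <- toy_state(rbind(c(0, 0, 0), c(1, 1, 1)), residue_id = c(190L, 500L),
                    atom_name = c("OG", "OC"))
  expect_error(charge_delta(no_q, no_q), "charges missing")
})
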