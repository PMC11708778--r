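# Toy two-pole QM system shared across scan tests: positive pole atom at
# (+2,0,0), negative pole at (-2,0,0); the TS transfers 0.5 e between them.
two_pole_pair <- function(shell_atoms, shell_charges) {
  qm <- tibble::tibble(
    element = "O", x = c(2, -2), y = 0, z = 0,
    residue_id = c(1L, 2L), residue_name = c("SER", "LIG"),
    region = "QM", atom_name = c("OG", "OS"))
  mk <- function(q_qm) {
    atoms <- dplyr::bind_rows(
      dplyr::mutate(qm, charge = q_qm),
      dplyr::mutate(shell_atoms, charge = shell_charges, region = "MM"))
    stationary_state(atoms, label = "S", stage = "acylation")
  }
  list(reactant = mk(c(0.1, -0.1)), ts = mk(c(0.6, -0.6)),
       poles = pole_definition(sel(1, "OG"), sel(2, "OS")))
}

shell_atom <- function(id, name, x, y = 0, z = 0, atom = "CB") {
  tibble::tibble(element = "C", x = x, y = y, z = z, residue_id = id,
                 residue_name = name, atom_name = atom)
}

test_that("Coulomb pair energies match the closed form and ignore neutral atoms", {
  plus <- data.frame(x = 0, y = 0, z = 0, charge = 1)
  minus <- data.frame(x = 1, y = 0, z = 0, charge = -1)
  expect_equal(interaction_energy(plus, minus), -332.0637, tolerance = 1e-10)
  neutral <- data.frame(x = 5, y = 0, z = 0, charge = 0)
  expect_equal(interaction_energy(neutral, minus), 0)
  too_close <- data.frame(x = 0.3, y = 0, z = 0, charge = 1)
  expect_error(interaction_energy(too_close, plus), "0.5 A")
})

test_that("vectorized Coulomb sums equal the brute-force oracle to 1e-9", {
  set.seed(13)
  for (i in 1:5) {
    res <- tibble::tibble(x = stats::runif(25, 8, 20),
                          y = stats::runif(25, -10, 10),
                          z = stats::runif(25, -10, 10),
                          charge = stats::runif(25, -1, 1))
    qm <- tibble::tibble(x = stats::runif(25, -2, 2),
                         y = stats::runif(25, -2, 2),
                         z = stats::runif(25, -2, 2),
                         charge = stats::runif(25, -0.5, 0.5))
    expect_equal(interaction_energy(res, qm), coulomb_oracle(res, qm),
                 tolerance = 1e-9)
  }
})

test_that("identical QM charges in reactant and TS give zero contributions", {
  pair <- make_state_pair(default_shell_spec(8), dipole_shift = 0,
                          charge_jitter = 0, seed = 4)
  scan <- deletion_scan(pair$reactant, pair$ts)
  expect_equal(scan$contribution, rep(0, 8), tolerance = 1e-12)
})

test_that("planted charges near each pole take the constructed contribution sign", {
  shell <- dplyr::bind_rows(
    shell_atom(101L, "ARG", x = 10, atom = "CZ"),   # +1 near + pole
    shell_atom(102L, "LYS", x = -10, atom = "CE"))  # +1 near - pole
  pair <- two_pole_pair(shell, c(1, 1))
  scan <- deletion_scan(pair$reactant, pair$ts)
  expect_gt(scan$contribution[scan$residue_id == 101], 0)  # destabilizer
  expect_lt(scan$contribution[scan$residue_id == 102], 0)  # stabilizer
})

test_that("a residue present in only one state is a consistency error", {
  pair <- make_state_pair(default_shell_spec(4), seed = 2)
  ts <- pair$ts
  ts$atoms <- ts$atoms[ts$atoms$residue_id != 101L, ]
  expect_error(deletion_scan(pair$reactant, ts), "only one state")
})

test_that("per-residue contributions add up to the one-pass environment shift", {
  pair <- make_state_pair(default_shell_spec(24), dipole_shift = 2, seed = 9)
  scan <- deletion_scan(pair$reactant, pair$ts)
  env_r <- dplyr::filter(pair$reactant$atoms, region == "MM")
  env_ts <- dplyr::filter(pair$ts$atoms, region == "MM")
  qm_r <- dplyr::filter(pair$reactant$atoms, region == "QM")
  qm_ts <- dplyr::filter(pair$ts$atoms, region == "QM")
  total <- interaction_energy(env_ts, qm_ts) - interaction_energy(env_r, qm_r)
  expect_equal(sum(scan$contribution), total, tolerance = 1e-8)
})

test_that("far test charges follow the point-dipole sign prediction", {
  # unit charge at 10x the QM-region extent on each side of the dipole axis:
  # interaction with the R->TS dipole change predicts the contribution sign
  shell <- dplyr::bind_rows(
    shell_atom(101L, "ARG", x = 40, atom = "CZ"),
    shell_atom(102L, "ARG", x = -40, atom = "CZ"))
  pair <- two_pole_pair(shell, c(1, 1))
  scan <- deletion_scan(pair$reactant, pair$ts)
  # dipole gained 0.5 e x 4 A pointing +x; +q on the +x side is repelled more
  expect_gt(scan$contribution[scan$residue_id == 101], 0)
  expect_lt(scan$contribution[scan$residue_id == 102], 0)
})

test_that("the macrodipole metric is a signed pole-distance difference", {
  shell <- dplyr::bind_rows(
    shell_atom(101L, "GLY", x = 0, y = 7, atom = "CA"),  # equidistant
    shell_atom(102L, "ALA", x = 8, atom = "CB"))
  pair <- two_pole_pair(shell, c(0, 0))
  expect_equal(macrodipole_metric(pair$ts, 101L, pair$poles), 0,
               tolerance = 1e-12)
  expect_equal(macrodipole_metric(pair$ts, 102L, pair$poles), 6 - 10)
  expect_error(macrodipole_metric(pair$ts, 999L, pair$poles), "not found")
})

test_that("planted shells are fully recovered in sign and strength ranking", {
  pair <- make_state_pair(default_shell_spec(40), dipole_shift = 2, seed = 1)
  scan <- residue_scan(pair$reactant, pair$ts, pair$poles)
  gt <- pair$ground_truth
  expect_equal(sign(scan$contribution), gt$intended_sign)
  rho <- stats::cor(abs(scan$contribution), abs(gt$analytic_contribution),
                    method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("mutation proposals follow the macrodipole rules for the canonical cases", {
  shell <- dplyr::bind_rows(
    shell_atom(101L, "ASP", x = -9, atom = "CG"),   # negative, near - pole
    shell_atom(102L, "ARG", x = 9, atom = "CZ"),    # positive, near + pole
    shell_atom(103L, "LYS", x = 9, y = 3, atom = "CE"),
    shell_atom(104L, "LYS", x = -9, y = 3, atom = "CE"))  # stabilizer
  pair <- two_pole_pair(shell, c(-1, 1, 1, 1))
  contrib <- tibble::tibble(
    residue_id = c(101L, 102L, 103L, 104L),
    residue_name = c("ASP", "ARG", "LYS", "LYS"),
    contribution = c(1.5, 2.0, 1.2, -1.5))
  ann <- classify_and_propose(contrib, pair$ts, pair$poles,
                              relevance_cutoff = 1.0)
  expect_equal(ann$charge_class, c("negative", "positive", "positive",
                                   "positive"))
  expect_true(all(ann$relevant))

  asp <- ann$proposals[[1]]
  expect_setequal(asp$target, c("ASN", "LYS", "ARG"))
  expect_equal(asp$strategy[asp$target == "ASN"], "conservative")
  expect_setequal(asp$strategy[asp$target %in% c("LYS", "ARG")],
                  "aggressive")

  arg <- ann$proposals[[2]]
  expect_setequal(arg$target, c("GLN", "HIS", "MET"))

  lys <- ann$proposals[[3]]
  expect_setequal(lys$target[lys$strategy == "conservative"], c("GLN", "MET"))
  expect_setequal(lys$target[lys$strategy == "aggressive"], c("ASP", "GLU"))

  expect_equal(nrow(ann$proposals[[4]]), 0)   # stabilizers get no proposals

  sub <- classify_and_propose(dplyr::mutate(contrib, contribution = 0.5),
                              pair$ts, pair$poles)
  expect_false(any(sub$relevant))
  expect_true(all(vapply(sub$proposals, nrow, integer(1)) == 0))
})

test_that("scan summaries rank the strongest destabilizer first", {
  pair <- make_state_pair(default_shell_spec(16), dipole_shift = 2, seed = 6)
  scan <- residue_scan(pair$reactant, pair$ts, pair$poles)
  gl <- glance(scan)
  expect_equal(gl$n_residues, 16)
  expect_equal(gl$top_contribution, max(scan$contribution))
  p <- ggplot2::autoplot(scan)
  expect_s3_class(p, "ggplot")
})
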