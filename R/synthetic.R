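# Seed-deterministic synthetic-data generators: stationary-state pairs
# with a controlled macrodipole shift and a shell of planted environment
# residues, toy step tables (including the in-paper presets), and
# trajectory distance series with a planted pass fraction.

# Run expr with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic residue shell
#'
#' Describes the planted environment around a synthetic QM region: how
#' many single-point-charge pseudo-residues, their charge classes, and
#' which macrodipole pole each one sits near.
#'
#' @param planted Data frame with columns `charge_class` (`"positive"`,
#'   `"negative"`, `"polar"`, `"hydrophobic"`) and `pole_side`
#'   (`"positive"` or `"negative"`), one row per residue.
#' @param radius_range Length-2 numeric, angstrom: radial band in which
#'   residues are placed. Its minimum must exceed the QM-region extent
#'   (about 2 angstrom half-width) so shell charges never clash with QM
#'   atoms.
#' @return An object of class `shell_spec`.
#' @examples
#' shell_spec(data.frame(charge_class = c("positive", "negative"),
#'                       pole_side = c("positive", "negative")))
#' @export
shell_spec <- function(planted, radius_range = c(8, 16)) {
  planted <- tibble::as_tibble(planted)
  stopifnot(all(c("charge_class", "pole_side") %in% names(planted)),
            length(radius_range) == 2, radius_range[1] < radius_range[2],
            radius_range[1] > 4)
  stopifnot(all(planted$charge_class %in%
                  c("positive", "negative", "polar", "hydrophobic")),
            all(planted$pole_side %in% c("positive", "negative")))
  structure(list(planted = planted, radius_range = radius_range),
            class = "shell_spec")
}

#' Balanced default shell for recovery experiments
#'
#' A 40-residue shell cycling through all eight combinations of the four
#' charge classes and the two pole sides, so both stabilizers and
#' destabilizers of every class are planted — the standard conditions for
#' sign-recovery tests of the deletion scan.
#'
#' @param n_residues Number of pseudo-residues (default 40).
#' @return A `shell_spec`.
#' @export
default_shell_spec <- function(n_residues = 40) {
  combos <- tidyr::expand_grid(
    charge_class = c("positive", "negative", "polar", "hydrophobic"),
    pole_side = c("positive", "negative")
  )
  idx <- rep(seq_len(nrow(combos)), length.out = n_residues)
  shell_spec(combos[idx, ])
}

# Point charge assigned to each charge class (a.u.).
.class_charge <- c(positive = 1, negative = -1, polar = 0.25,
                   hydrophobic = 0.05)
.class_resname <- list(positive = c("LYS", "ARG"), negative = c("ASP", "GLU"),
                       polar = c("ASN", "SER"), hydrophobic = c("LEU", "ALA"))

#' Generate a reactant/transition-state pair with a planted macrodipole shift
#'
#' Builds a ~10-atom synthetic QM region flanked by the two macrodipole
#' pole atoms 4 angstrom apart on the x axis, plus a shell of single-atom
#' MM pseudo-residues per the spec. The reactant and transition state
#' share geometry; their QM charges sum to the same total, but the TS
#' transfers `dipole_shift / 4` a.u. of charge from the negative-pole atom
#' to the positive-pole atom (a dipole change of `dipole_shift` e-angstrom
#' along the pole axis) and adds a small zero-sum jitter on the remaining
#' QM atoms, mimicking electron-density rearrangement at the barrier.
#'
#' The returned ground-truth table records, per shell residue, the planted
#' sign and the analytic two-point-charge contribution estimate
#' \eqn{k q \delta (1/r_+ - 1/r_-)}, sufficient to score sign recovery and
#' rank correlation without re-deriving expectations.
#'
#' @param spec A [shell_spec()].
#' @param dipole_shift Dipole change between reactant and TS, e-angstrom
#'   (>= 0). Default 2.
#' @param seed Integer seed; the same inputs always produce bit-identical
#'   states.
#' @param charge_jitter Standard deviation of the zero-sum TS charge
#'   jitter on non-pole QM atoms, a.u. (default 0.01).
#' @return A list with `reactant` and `ts` (`stationary_state` objects),
#'   `ground_truth` (tibble), and `poles` (a [pole_definition()] for the
#'   pair).
#' @export
make_state_pair <- function(spec = default_shell_spec(), dipole_shift = 2,
                            seed = 1, charge_jitter = 0.01) {
  stopifnot(inherits(spec, "shell_spec"), dipole_shift >= 0)
  .with_seed(seed, {
    n_qm <- 10
    pole_sep <- 4
    x_pos <- pole_sep / 2
    x_neg <- -pole_sep / 2

    draw_inner <- function() tibble::tibble(
      x = stats::runif(n_qm - 2, -1.7, 1.7),
      y = stats::runif(n_qm - 2, -1.2, 1.2),
      z = stats::runif(n_qm - 2, -1.2, 1.2)
    )
    inner <- draw_inner()
    # reject inner atoms too close to each other or the poles
    for (tries in 1:500) {
      pts <- rbind(c(x_pos, 0, 0), c(x_neg, 0, 0), as.matrix(inner))
      if (min(stats::dist(pts)) > 0.7) break
      if (tries == 500)
        stop("could not place QM atoms without clashes", call. = FALSE)
      inner <- draw_inner()
    }

    q0 <- stats::runif(n_qm, -0.4, 0.4)
    q0 <- q0 - mean(q0)                      # net-neutral QM region
    delta <- dipole_shift / pole_sep
    jit <- stats::rnorm(n_qm - 2, 0, charge_jitter)
    jit <- jit - mean(jit)
    q_ts <- q0
    q_ts[1] <- q_ts[1] + delta               # positive pole gains + charge
    q_ts[2] <- q_ts[2] - delta
    q_ts[3:n_qm] <- q_ts[3:n_qm] + jit

    qm_atoms <- tibble::tibble(
      element = c("O", "O", rep("C", n_qm - 2)),
      x = c(x_pos, x_neg, inner$x),
      y = c(0, 0, inner$y),
      z = c(0, 0, inner$z),
      residue_id = c(1L, 2L, rep(3L, n_qm - 2)),
      residue_name = c("SER", "LIG", rep("QMC", n_qm - 2)),
      region = "QM",
      atom_name = c("OG", "OS", paste0("C", seq_len(n_qm - 2)))
    )

    planted <- spec$planted
    n_res <- nrow(planted)
    side_sign <- ifelse(planted$pole_side == "positive", 1, -1)
    ux <- stats::runif(n_res, 0.3, 0.95) * side_sign
    phi <- stats::runif(n_res, 0, 2 * pi)
    uperp <- sqrt(1 - ux^2)
    r <- stats::runif(n_res, spec$radius_range[1], spec$radius_range[2])
    rx <- r * ux
    ry <- r * uperp * cos(phi)
    rz <- r * uperp * sin(phi)
    resname <- vapply(seq_len(n_res), function(i) {
      opts <- .class_resname[[planted$charge_class[i]]]
      opts[1 + (i %% length(opts))]
    }, character(1))
    ref_map <- default_reference_atoms()
    shell_atoms <- tibble::tibble(
      element = "C",
      x = rx, y = ry, z = rz,
      residue_id = 100L + seq_len(n_res),
      residue_name = resname,
      region = "MM",
      atom_name = unname(ifelse(resname %in% names(ref_map),
                                ref_map[resname], ref_map[["*"]]))
    )

    q_shell <- unname(.class_charge[planted$charge_class])
    atoms_r <- dplyr::bind_rows(
      dplyr::mutate(qm_atoms, charge = q0),
      dplyr::mutate(shell_atoms, charge = q_shell)
    )
    atoms_ts <- dplyr::bind_rows(
      dplyr::mutate(qm_atoms, charge = q_ts),
      dplyr::mutate(shell_atoms, charge = q_shell)
    )

    k <- .const$coulomb
    d_pos <- sqrt((rx - x_pos)^2 + ry^2 + rz^2)
    d_neg <- sqrt((rx - x_neg)^2 + ry^2 + rz^2)
    analytic <- k * q_shell * delta * (1 / d_pos - 1 / d_neg)
    ground_truth <- tibble::tibble(
      residue_id = shell_atoms$residue_id,
      residue_name = resname,
      charge_class = planted$charge_class,
      pole_side = planted$pole_side,
      intended_sign = if (dipole_shift == 0) 0 else sign(analytic),
      analytic_contribution = analytic
    )

    list(
      reactant = stationary_state(atoms_r, label = "R", stage = "acylation"),
      ts = stationary_state(atoms_ts, label = "TS", stage = "acylation"),
      ground_truth = ground_truth,
      poles = pole_definition(sel(1, "OG"), sel(2, "OS"))
    )
  })
}

#' Generate a trajectory distance series with a planted pass fraction
#'
#' Frames are written at 0.2 ns spacing. Each frame is drawn as passing
#' (all five distances strictly below their thresholds) with probability
#' `pass_fraction`; otherwise exactly one metric, chosen uniformly, is
#' placed above its threshold. Construction is direct (no rejection
#' sampling), so generation is O(n).
#'
#' @param n_frames Number of frames (>= 1).
#' @param pass_fraction Planted probability that a frame passes, in [0, 1].
#' @param seed Integer seed.
#' @return A tibble with columns `time` (ns) and `d1`..`d5` (angstrom).
#' @export
make_trajectory_series <- function(n_frames, pass_fraction, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  stopifnot(pass_fraction >= 0, pass_fraction <= 1)
  .with_seed(seed, {
    passing <- stats::runif(n_frames) < pass_fraction
    d <- matrix(stats::runif(n_frames * 5, 1.5, 2.45), n_frames, 5)
    d[, 3] <- stats::runif(n_frames, 2.0, 3.45)
    violator <- sample.int(5, n_frames, replace = TRUE)
    for (i in which(!passing)) {
      j <- violator[i]
      d[i, j] <- if (j == 3) stats::runif(1, 3.6, 5.0) else stats::runif(1, 2.6, 4.0)
    }
    tibble::tibble(
      time = seq_len(n_frames) * 0.2,
      d1 = d[, 1], d2 = d[, 2], d3 = d[, 3], d4 = d[, 4], d5 = d[, 5]
    )
  })
}

#' Build a step-energy table from a shape or a preset
#'
#' Either pass a data frame of step energies or one of the canned presets
#' reproducing the printed per-step Gibbs energies of the two catalytic
#' stages of the urethanase mechanism: `"stage1-paper"` (acylation — serine
#' activation, nucleophilic attack, tetrahedral-intermediate breakdown
#' with urethane-bond cleavage, and a barrierless final proton transfer)
#' and `"stage2-paper"` (deacylation — hydrolysis of the acyl-enzyme and
#' triad regeneration).
#'
#' @param shape A preset name, or a data frame with columns
#'   `dg_activation` (kcal/mol, `NA` = barrierless) and `dg_reaction`
#'   (kcal/mol), plus optional `step_id`, `from_label`, `ts_label`,
#'   `to_label`, `reference_label`. Missing labels are auto-generated
#'   (`M0, TS1, M1, ...`); a missing reference defaults to each step's
#'   starting state.
#' @return A tibble of step records suitable for [assemble_profile()].
#' @examples
#' make_step_table("stage1-paper")
#' make_step_table(data.frame(dg_activation = 5, dg_reaction = -1))
#' @export
make_step_table <- function(shape) {
  if (is.character(shape) && length(shape) == 1) {
    return(switch(shape,
      "stage1-paper" = tibble::tibble(
        step_id = c("s1", "s2", "s3", "s4"),
        from_label = c("R", "INT1", "INT2-TI", "INT3"),
        ts_label = c("TS1", "TS2", "TS3", "TS4"),
        to_label = c("INT1", "INT2-TI", "INT3", "AE"),
        dg_activation = c(0.3, 17.4, 4.8, NA),
        dg_reaction = c(1.5, 16.0, -3.2, -1.9),
        reference_label = c("R", "R", "INT2-TI", "INT3")
      ),
      "stage2-paper" = tibble::tibble(
        step_id = c("s5", "s6"),
        from_label = c("AE*", "INT5"),
        ts_label = c("TS5", "TS6"),
        to_label = c("INT5", "P"),
        dg_activation = c(17.8, 0.5),
        dg_reaction = c(-6.0, 1.6),
        reference_label = c("AE*", "INT5")
      ),
      stop("unknown preset '", shape, "'", call. = FALSE)
    ))
  }
  shape <- tibble::as_tibble(shape)
  if (nrow(shape) == 0)
    return(tibble::tibble(step_id = character(0), from_label = character(0),
                          ts_label = character(0), to_label = character(0),
                          dg_activation = numeric(0), dg_reaction = numeric(0),
                          reference_label = character(0)))
  stopifnot(all(c("dg_activation", "dg_reaction") %in% names(shape)))
  n <- nrow(shape)
  has <- function(col) col %in% names(shape)
  if (!has("step_id")) shape$step_id <- paste0("s", seq_len(n))
  if (!has("from_label")) shape$from_label <- paste0("M", seq_len(n) - 1)
  if (!has("ts_label")) shape$ts_label <- paste0("TS", seq_len(n))
  if (!has("to_label")) shape$to_label <- paste0("M", seq_len(n))
  if (!has("reference_label")) shape$reference_label <- shape$from_label
  shape[c("step_id", "from_label", "ts_label", "to_label",
          "dg_activation", "dg_reaction", "reference_label")]
}
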