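# Rigid-rotor/harmonic-oscillator thermochemistry from vibrational
# wavenumbers, with a vibrational-temperature cutoff on the thermal and
# entropic sums.

#' Vibrational temperatures of normal modes
#'
#' Converts real wavenumbers to vibrational temperatures
#' \eqn{\Theta_i = c_2 \tilde\nu_i} with the second radiation constant
#' \eqn{c_2 = hc/k_B = 1.4387769} cm K. Order is preserved.
#'
#' @param freqs Numeric vector of real (positive) wavenumbers, cm^-1.
#' @return Numeric vector of vibrational temperatures, K.
#' @examples
#' vibrational_temperatures(c(100, 1000))
#' @export
vibrational_temperatures <- function(freqs) {
  stopifnot(is.numeric(freqs))
  if (any(freqs < 0))
    stop("negative wavenumber: imaginary modes must be filtered before ",
         "computing vibrational temperatures", call. = FALSE)
  .const$c2 * freqs
}

#' Classify a stationary point from its vibrational spectrum
#'
#' Counts imaginary modes (negative wavenumbers): none for a minimum,
#' exactly one for a transition state, two or more for a higher-order
#' saddle.
#'
#' @param freqs Non-empty numeric vector of wavenumbers, cm^-1.
#' @return `"minimum"`, `"transition_state"` or `"higher_order_saddle"`.
#' @examples
#' classify_stationary_point(c(-151.1, 300, 900))
#' @export
classify_stationary_point <- function(freqs) {
  stopifnot(is.numeric(freqs))
  if (length(freqs) == 0)
    stop("cannot classify a stationary point from an empty frequency list",
         call. = FALSE)
  n_imag <- sum(freqs < 0)
  if (n_imag == 0) "minimum"
  else if (n_imag == 1) "transition_state"
  else "higher_order_saddle"
}

#' Thermal corrections to the Gibbs energy (RRHO)
#'
#' Computes zero-point, thermal and entropic corrections from a vibrational
#' spectrum under the harmonic-oscillator model, optionally adding
#' ideal-gas translational and rigid-rotor rotational terms.
#'
#' Imaginary modes (negative wavenumbers) are dropped and counted — for a
#' transition state the mode along the reaction coordinate has no thermal
#' meaning. The zero-point energy \eqn{\sum_i R\Theta_i/2} runs over all
#' real modes, while the vibrational thermal-energy and entropy sums
#' include only modes whose vibrational temperature exceeds `cutoff_K`
#' (default 120 K): very soft modes of a large cluster are poorly described
#' by the harmonic approximation, so their thermal and entropic terms are
#' excluded.
#'
#' The per-mode terms are the standard harmonic-oscillator
#' partition-function results, with \eqn{u_i = \Theta_i/T}:
#' \deqn{E_{vib,i} = R\,\Theta_i / (e^{u_i}-1), \qquad
#'       S_{vib,i} = R\,[\,u_i/(e^{u_i}-1) - \ln(1-e^{-u_i})\,].}
#' With `include_trans_rot = TRUE` (requires `masses` and `coords`),
#' translational terms use the Sackur–Tetrode entropy at `pressure_atm`
#' and \eqn{E_{trans} = 3RT/2} plus the \eqn{RT} enthalpy term, and
#' rotational terms use the classical rigid-rotor expressions from the
#' principal moments of inertia (symmetry number 1).
#'
#' @param freqs Numeric vector of wavenumbers, cm^-1 (negative = imaginary).
#' @param temperature Temperature, K (> 0). Default 298.15.
#' @param cutoff_K Vibrational-temperature cutoff for the thermal/entropic
#'   sums, K. Default 120.
#' @param include_trans_rot Add ideal-gas translational + rotational terms
#'   (off by default: a condensed-phase QM/MM cluster has no free
#'   translation or rotation).
#' @param masses,coords Atomic masses (amu) and an n-by-3 coordinate matrix
#'   (angstrom); required when `include_trans_rot = TRUE`.
#' @param pressure_atm Pressure for the translational entropy, atm.
#' @return A one-row tibble: `temperature`, `zpe`, `thermal_enthalpy`,
#'   `entropy` (kcal/(mol K)), `gibbs_correction` (all energies kcal/mol),
#'   and the bookkeeping counts `n_modes_used`, `n_modes_cut`,
#'   `n_imaginary_dropped`. Always
#'   `gibbs_correction = zpe + thermal_enthalpy - temperature * entropy`.
#' @examples
#' gibbs_correction(c(50, 1000))
#' @export
gibbs_correction <- function(freqs, temperature = 298.15, cutoff_K = 120,
                             include_trans_rot = FALSE, masses = NULL,
                             coords = NULL, pressure_atm = 1) {
  stopifnot(is.numeric(freqs))
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  R <- .const$R_kcal

  imag <- freqs < 0
  real <- freqs[!imag]
  theta <- vibrational_temperatures(real)
  used <- theta > cutoff_K

  zpe <- sum(R * theta / 2)
  u <- theta[used] / temperature
  e_vib <- sum(R * theta[used] / (exp(u) - 1))
  s_vib <- sum(R * (u / (exp(u) - 1) - log1p(-exp(-u))))

  h_therm <- e_vib
  s_tot <- s_vib
  if (include_trans_rot) {
    if (is.null(masses) || is.null(coords))
      stop("include_trans_rot = TRUE requires masses and coords", call. = FALSE)
    tr <- .trans_rot_terms(masses, coords, temperature, pressure_atm)
    h_therm <- h_therm + tr$energy + R * temperature  # + RT: H = E + PV
    s_tot <- s_tot + tr$entropy
  }

  tibble::tibble(
    temperature = temperature,
    zpe = zpe,
    thermal_enthalpy = h_therm,
    entropy = s_tot,
    gibbs_correction = zpe + h_therm - temperature * s_tot,
    n_modes_used = sum(used),
    n_modes_cut = sum(!used),
    n_imaginary_dropped = sum(imag)
  )
}

# Ideal-gas translational + classical rigid-rotor rotational energy (kcal/mol)
# and entropy (kcal/(mol K)). Masses amu, coords angstrom, sigma = 1.
.trans_rot_terms <- function(masses, coords, temperature, pressure_atm) {
  coords <- as.matrix(coords)
  stopifnot(length(masses) == nrow(coords), ncol(coords) == 3)
  k <- .const
  R <- k$R_kcal
  T <- temperature
  kT <- k$kB * T

  m_kg <- sum(masses) * k$amu
  p_pa <- pressure_atm * 101325
  lambda3 <- (2 * pi * m_kg * kT / k$h^2)^1.5       # 1/m^3 density of states
  s_trans <- R * (log(lambda3 * kT / p_pa) + 2.5)
  e_trans <- 1.5 * R * T

  # principal moments of inertia, kg m^2
  m <- masses * k$amu
  xyz <- sweep(coords, 2, colSums(coords * masses) / sum(masses)) * 1e-10
  ixx <- sum(m * (xyz[, 2]^2 + xyz[, 3]^2))
  iyy <- sum(m * (xyz[, 1]^2 + xyz[, 3]^2))
  izz <- sum(m * (xyz[, 1]^2 + xyz[, 2]^2))
  ixy <- -sum(m * xyz[, 1] * xyz[, 2])
  ixz <- -sum(m * xyz[, 1] * xyz[, 3])
  iyz <- -sum(m * xyz[, 2] * xyz[, 3])
  inertia <- matrix(c(ixx, ixy, ixz, ixy, iyy, iyz, ixz, iyz, izz), 3, 3)
  ev <- sort(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values)

  tiny <- 1e-52
  if (nrow(coords) == 1 || all(ev < tiny)) {        # single atom: no rotation
    s_rot <- 0; e_rot <- 0
  } else if (ev[1] < tiny) {                        # linear molecule
    theta_r <- k$h^2 / (8 * pi^2 * ev[3] * k$kB)
    s_rot <- R * (log(T / theta_r) + 1)
    e_rot <- R * T
  } else {
    theta_r <- k$h^2 / (8 * pi^2 * ev * k$kB)
    s_rot <- R * (log(sqrt(pi) * sqrt(prod(T / theta_r))) + 1.5)
    e_rot <- 1.5 * R * T
  }
  list(energy = e_trans + e_rot, entropy = s_trans + s_rot)
}

#' Atomic masses for common elements
#'
#' Standard atomic weights (amu) for the elements found in organic active
#' sites; used by the optional translational/rotational thermochemistry
#' terms.
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of masses, amu.
#' @examples
#' atomic_masses(c("C", "H", "O"))
#' @export
atomic_masses <- function(elements) {
  m <- .atomic_masses[elements]
  if (any(is.na(m)))
    stop("no tabulated mass for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "), call. = FALSE)
  unname(m)
}
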