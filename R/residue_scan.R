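# Per-residue electrostatic decomposition of the rate-limiting barrier:
# fixed-charge Coulomb interactions between each environment residue and
# the QM-region charge distributions of reactant and transition state,
# macrodipole distance metric, charge-class assignment and mutation
# proposals.

#' Fixed point-charge interaction model
#'
#' Coulomb prefactor and dielectric for residue/QM-region interaction
#' energies. The default dielectric of 1 corresponds to the vacuum
#' embedding of an electrostatic-embedding QM/MM setup, where environment
#' point charges polarize the quantum region directly.
#'
#' @param coulomb_constant Coulomb prefactor, kcal A/(mol e^2).
#' @param dielectric Relative dielectric (dimensionless, > 0).
#' @return An object of class `charge_model`.
#' @examples
#' charge_model()
#' @export
charge_model <- function(coulomb_constant = 332.0637, dielectric = 1.0) {
  stopifnot(coulomb_constant > 0, dielectric > 0)
  structure(list(coulomb_constant = coulomb_constant, dielectric = dielectric),
            class = "charge_model")
}

#' Electrostatic interaction energy between a residue and the QM region
#'
#' Pairwise Coulomb sum
#' \eqn{E = (k/\epsilon) \sum_i \sum_j q_i q_j / r_{ij}}
#' over residue atoms i and QM atoms j, with charges in elementary-charge
#' units and distances in angstrom.
#'
#' @param residue_atoms,qm_atoms Data frames with columns `x`, `y`, `z`,
#'   `charge`.
#' @param model A [charge_model()].
#' @return Interaction energy, kcal/mol.
#' @examples
#' a <- data.frame(x = 0, y = 0, z = 0, charge = 1)
#' b <- data.frame(x = 1, y = 0, z = 0, charge = -1)
#' interaction_energy(a, b)
#' @export
interaction_energy <- function(residue_atoms, qm_atoms, model = charge_model()) {
  stopifnot(inherits(model, "charge_model"))
  qa <- residue_atoms$charge
  qb <- qm_atoms$charge
  if (any(is.na(qa)) || any(is.na(qb)))
    stop("charges missing on interacting atoms", call. = FALSE)
  pa <- as.matrix(residue_atoms[, c("x", "y", "z")])
  pb <- as.matrix(qm_atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 0.5))
    stop("atom pair closer than 0.5 A: residue overlaps the QM region ",
         "(mis-assembled input)", call. = FALSE)
  model$coulomb_constant / model$dielectric * sum(outer(qa, qb) / r)
}

#' Residue-deletion scan of the rate-limiting barrier
#'
#' For each environment residue, computes the electrostatic contribution
#' to the activation barrier as
#' `contribution = E_int(residue, TS) - E_int(residue, R)`. A positive
#' contribution means the residue destabilizes the transition state
#' relative to the reactant — deleting (or neutralizing) it would lower
#' the barrier, making it a mutation target. The decomposition is exactly
#' additive: the contributions sum to the total environment electrostatic
#' barrier shift.
#'
#' @param reactant_state,ts_state `stationary_state` objects with charges.
#'   QM-region membership (atoms with `region == "QM"`) must be identical
#'   in both.
#' @param residue_ids Optional integer vector of residue ids to scan; by
#'   default every `MM`-region residue (frozen-solvent atoms are always
#'   excluded).
#' @param model A [charge_model()].
#' @return A tibble with columns `residue_id`, `residue_name`,
#'   `contribution` (kcal/mol).
#' @export
deletion_scan <- function(reactant_state, ts_state, residue_ids = NULL,
                          model = charge_model()) {
  stopifnot(inherits(reactant_state, "stationary_state"),
            inherits(ts_state, "stationary_state"))
  qm_r <- dplyr::filter(reactant_state$atoms, .data$region == "QM")
  qm_ts <- dplyr::filter(ts_state$atoms, .data$region == "QM")
  key_r <- paste(qm_r$residue_id, qm_r$atom_name)
  key_ts <- paste(qm_ts$residue_id, qm_ts$atom_name)
  if (!setequal(key_r, key_ts) || nrow(qm_r) != nrow(qm_ts))
    stop("QM-region membership differs between reactant and TS", call. = FALSE)
  mm_r <- dplyr::filter(reactant_state$atoms, .data$region == "MM")
  mm_ts <- dplyr::filter(ts_state$atoms, .data$region == "MM")
  if (is.null(residue_ids)) residue_ids <- sort(unique(mm_r$residue_id))
  purrr::map_dfr(residue_ids, function(rid) {
    res_r <- dplyr::filter(mm_r, .data$residue_id == rid)
    res_ts <- dplyr::filter(mm_ts, .data$residue_id == rid)
    if (nrow(res_r) == 0 || nrow(res_ts) == 0)
      stop("residue ", rid, " present in only one state", call. = FALSE)
    tibble::tibble(
      residue_id = rid,
      residue_name = res_r$residue_name[1],
      contribution = interaction_energy(res_ts, qm_ts, model) -
        interaction_energy(res_r, qm_r, model)
    )
  })
}

#' Define the transition-state macrodipole poles
#'
#' @param positive_pole Selector for the positive side of the macrodipole
#'   (the nucleophilic serine O-gamma in a serine hydrolase).
#' @param negative_pole Selector for the negative side (the substrate's
#'   ester oxygen).
#' @return An object of class `pole_definition`.
#' @export
pole_definition <- function(positive_pole, negative_pole) {
  structure(list(positive_pole = positive_pole, negative_pole = negative_pole),
            class = "pole_definition")
}

#' Default reference atoms for the macrodipole distance metric
#'
#' One reference carbon per residue type: the outermost side-chain carbon
#' (Arg CZ, Lys CE, Asp CG, Glu CD, Gly CA, otherwise CB).
#'
#' @return Named character vector mapping residue names to atom names; the
#'   `"*"` entry is the fallback.
#' @export
default_reference_atoms <- function() {
  c(ARG = "CZ", LYS = "CE", ASP = "CG", GLU = "CD", GLY = "CA", "*" = "CB")
}

#' Macrodipole distance metric for a residue
#'
#' Difference between the residue reference atom's distance to the
#' positive pole and to the negative pole of the transition-state
#' macrodipole. Negative values mean the residue sits closer to the
#' positive pole.
#'
#' @param state A `stationary_state` (normally the transition state).
#' @param residue_id Residue to measure.
#' @param poles A [pole_definition()].
#' @param reference_atom_map Named residue-name to atom-name map (see
#'   [default_reference_atoms()]). A residue consisting of a single atom
#'   uses that atom directly.
#' @return Delta-distance in angstrom.
#' @export
macrodipole_metric <- function(state, residue_id, poles,
                               reference_atom_map = default_reference_atoms()) {
  stopifnot(inherits(poles, "pole_definition"))
  res <- dplyr::filter(state$atoms, .data$residue_id == !!residue_id)
  if (nrow(res) == 0)
    stop("residue ", residue_id, " not found in state '", state$label, "'",
         call. = FALSE)
  if (nrow(res) == 1) {
    ref <- res
  } else {
    rname <- res$residue_name[1]
    aname <- if (rname %in% names(reference_atom_map)) reference_atom_map[[rname]]
    else if ("*" %in% names(reference_atom_map)) reference_atom_map[["*"]]
    else stop("residue type '", rname, "' missing from reference-atom map",
              call. = FALSE)
    ref <- dplyr::filter(res, .data$atom_name == aname)
    if (nrow(ref) != 1)
      stop("reference atom '", aname, "' not found once in residue ",
           residue_id, call. = FALSE)
  }
  pp <- resolve_atom(state, poles$positive_pole)
  np <- resolve_atom(state, poles$negative_pole)
  d_pos <- sqrt((ref$x - pp$x)^2 + (ref$y - pp$y)^2 + (ref$z - pp$z)^2)
  d_neg <- sqrt((ref$x - np$x)^2 + (ref$y - np$y)^2 + (ref$z - np$z)^2)
  d_pos - d_neg
}

#' Charge class of a residue from its name
#'
#' Lys/Arg/His+ (`HIP`) are positive; Asp/Glu negative; Ser/Thr/Asn/Gln/
#' Tyr/Cys and neutral His (`HIS`, `HID`, `HIE`) polar; everything else
#' hydrophobic.
#'
#' @param residue_name Character vector of 3-letter residue codes.
#' @return Character vector: `"positive"`, `"negative"`, `"polar"` or
#'   `"hydrophobic"`.
#' @export
charge_class <- function(residue_name) {
  rn <- toupper(residue_name)
  dplyr::case_when(
    rn %in% c("LYS", "ARG", "HIP") ~ "positive",
    rn %in% c("ASP", "GLU") ~ "negative",
    rn %in% c("SER", "THR", "ASN", "GLN", "TYR", "CYS",
              "HIS", "HID", "HIE") ~ "polar",
    TRUE ~ "hydrophobic"
  )
}

#' Classify residue contributions and propose mutations
#'
#' Annotates per-residue barrier contributions with the macrodipole
#' distance metric, charge class, a relevance flag
#' (`|contribution| > relevance_cutoff`), and mutation proposals for
#' relevant destabilizers:
#' \itemize{
#'   \item a negative residue near the negative pole (`delta_d > 0`):
#'     conservative Asn; aggressive Lys or Arg — replacing or inverting the
#'     charge that repels the pole's growing negative charge;
#'   \item an Arg near the positive pole (`delta_d < 0`): Gln, His or Met —
#'     a polar/hydrophobic swap that removes the unstabilized positive
#'     charge;
#'   \item any other positive residue near the positive pole: conservative
#'     Gln or Met; aggressive Asp or Glu.
#' }
#' Stabilizing residues (negative contribution) never receive proposals.
#'
#' @param contributions Tibble from [deletion_scan()], or any data frame
#'   with `residue_id`, `residue_name`, `contribution` — e.g. an imported
#'   per-residue barrier table from engine-level deletion calculations.
#' @param state State used for the distance metric (normally the TS).
#' @param poles A [pole_definition()].
#' @param relevance_cutoff Relevance threshold on `|contribution|`,
#'   kcal/mol (default 1.0).
#' @param reference_atom_map See [macrodipole_metric()].
#' @return A `residue_scan` tibble: input columns plus `delta_d`,
#'   `charge_class`, `relevant`, and `proposals` (list column of tibbles
#'   with `target` and `strategy`).
#' @export
classify_and_propose <- function(contributions, state, poles,
                                 relevance_cutoff = 1.0,
                                 reference_atom_map = default_reference_atoms()) {
  contributions <- tibble::as_tibble(contributions)
  out <- dplyr::mutate(
    contributions,
    delta_d = purrr::map_dbl(.data$residue_id, macrodipole_metric,
                             state = state, poles = poles,
                             reference_atom_map = reference_atom_map),
    charge_class = charge_class(.data$residue_name),
    relevant = abs(.data$contribution) > relevance_cutoff
  )
  out$proposals <- purrr::pmap(
    list(out$residue_name, out$charge_class, out$contribution, out$delta_d,
         out$relevant),
    .propose_mutations
  )
  class(out) <- c("residue_scan", class(out))
  attr(out, "relevance_cutoff") <- relevance_cutoff
  out
}

.propose_mutations <- function(residue_name, cls, contribution, delta_d,
                               relevant) {
  none <- tibble::tibble(target = character(0), strategy = character(0))
  if (!relevant || contribution <= 0) return(none)
  if (cls == "negative" && delta_d > 0) {
    tibble::tibble(target = c("ASN", "LYS", "ARG"),
                   strategy = c("conservative", "aggressive", "aggressive"))
  } else if (cls == "positive" && delta_d < 0) {
    if (toupper(residue_name) == "ARG")
      tibble::tibble(target = c("GLN", "HIS", "MET"),
                     strategy = rep("conservative", 3))
    else
      tibble::tibble(target = c("GLN", "MET", "ASP", "GLU"),
                     strategy = c("conservative", "conservative",
                                  "aggressive", "aggressive"))
  } else {
    none
  }
}

#' Full residue scan of the rate-limiting barrier
#'
#' Convenience pipeline: [deletion_scan()] then [classify_and_propose()],
#' with the distance metric measured on the transition state.
#'
#' @inheritParams deletion_scan
#' @inheritParams classify_and_propose
#' @return A `residue_scan` tibble (see [classify_and_propose()]).
#' @export
residue_scan <- function(reactant_state, ts_state, poles, residue_ids = NULL,
                         model = charge_model(), relevance_cutoff = 1.0,
                         reference_atom_map = default_reference_atoms()) {
  contributions <- deletion_scan(reactant_state, ts_state,
                                 residue_ids = residue_ids, model = model)
  classify_and_propose(contributions, state = ts_state, poles = poles,
                       relevance_cutoff = relevance_cutoff,
                       reference_atom_map = reference_atom_map)
}

#' One-row summary of a residue scan
#'
#' @param x A `residue_scan` tibble.
#' @param ... Unused.
#' @return A one-row tibble: residue counts by role, the strongest
#'   destabilizer and its contribution, and the total electrostatic
#'   barrier shift.
#' @export
glance.residue_scan <- function(x, ...) {
  worst <- dplyr::slice_max(x, .data$contribution, n = 1, with_ties = FALSE)
  tibble::tibble(
    n_residues = nrow(x),
    n_relevant = sum(x$relevant),
    n_destabilizing = sum(x$contribution > 0),
    top_target = worst$residue_name[1],
    top_contribution = worst$contribution[1],
    total_shift = sum(x$contribution)
  )
}
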