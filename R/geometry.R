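# Structural analytics on stationary states: distances, the Buergi-Dunitz
# attack angle, hydrogen-bond scans, Kabsch superposition RMSD and
# per-atom charge differences between states.

#' Interatomic distance
#'
#' Euclidean distance between two atoms of a stationary state.
#'
#' @param state A `stationary_state`.
#' @param sel_a,sel_b Atom selectors (see [sel()]).
#' @return Distance in angstrom.
#' @examples
#' st <- stationary_state(
#'   data.frame(element = c("O", "C"), x = c(0, 3), y = c(0, 4), z = 0),
#'   label = "R", stage = "acylation")
#' atom_distance(st, sel(1, "O1"), sel(1, "C2"))
#' @export
atom_distance <- function(state, sel_a, sel_b) {
  a <- resolve_atom(state, sel_a)
  b <- resolve_atom(state, sel_b)
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

#' Buergi-Dunitz approach angle
#'
#' The nucleophile--carbonyl-carbon--carbonyl-oxygen angle, measured at the
#' carbonyl carbon. Values near 105-110 degrees are characteristic of a
#' nucleophile poised for addition to a carbonyl group.
#'
#' @param state A `stationary_state`.
#' @param nucleophile_sel Selector for the attacking nucleophile atom
#'   (e.g. the serine O-gamma).
#' @param carbonyl_c_sel,carbonyl_o_sel Selectors for the carbonyl carbon
#'   and oxygen of the attacked bond.
#' @return Angle in degrees, in [0, 180].
#' @export
burgi_dunitz_angle <- function(state, nucleophile_sel, carbonyl_c_sel,
                               carbonyl_o_sel) {
  nu <- resolve_atom(state, nucleophile_sel)
  cc <- resolve_atom(state, carbonyl_c_sel)
  oo <- resolve_atom(state, carbonyl_o_sel)
  v1 <- c(nu$x - cc$x, nu$y - cc$y, nu$z - cc$z)
  v2 <- c(oo$x - cc$x, oo$y - cc$y, oo$z - cc$z)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9)
    stop("degenerate geometry: coincident atoms in angle definition",
         call. = FALSE)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Hydrogen-bond scan by donor-hydrogen / acceptor distance
#'
#' Enumerates all hydrogen--acceptor pairs with H...A distance at or below
#' the cutoff, sorted ascending. The criterion is distance-only (no
#' angular term): mechanism reports quote hydrogen bonds as H...A
#' distances.
#'
#' @param state A `stationary_state`.
#' @param donors List of `(D, H)` selector pairs; only the hydrogen member
#'   is used for the distance.
#' @param acceptors List of acceptor selectors.
#' @param h_a_cutoff H...A distance cutoff, angstrom (default 2.5).
#' @return A tibble with columns `donor`, `acceptor`, `distance`, sorted by
#'   ascending distance.
#' @export
hbond_scan <- function(state, donors, acceptors, h_a_cutoff = 2.5) {
  if (h_a_cutoff <= 0) stop("h_a_cutoff must be > 0", call. = FALSE)
  hits <- purrr::map_dfr(donors, function(dh) {
    h <- resolve_atom(state, dh[[2]])
    purrr::map_dfr(acceptors, function(acc) {
      a <- resolve_atom(state, acc)
      d <- sqrt((h$x - a$x)^2 + (h$y - a$y)^2 + (h$z - a$z)^2)
      tibble::tibble(
        donor = paste0(h$residue_id, ":", h$atom_name),
        acceptor = paste0(a$residue_id, ":", a$atom_name),
        distance = d
      )
    })
  })
  if (nrow(hits) == 0)
    return(tibble::tibble(donor = character(0), acceptor = character(0),
                          distance = numeric(0)))
  dplyr::arrange(dplyr::filter(hits, .data$distance <= h_a_cutoff),
                 .data$distance)
}

#' Minimal RMSD after optimal rigid-body superposition (Kabsch)
#'
#' Superposes matched atom selections of two states by the optimal
#' rotation and translation (Kabsch algorithm, via singular value
#' decomposition with a proper-rotation determinant correction) and
#' returns the residual root-mean-square deviation.
#'
#' Atoms are matched across states by `(residue_id, atom_name)`, so
#' reordered bundles compare correctly.
#'
#' @param state_a,state_b `stationary_state` objects.
#' @param selection Optional list of atom selectors; by default all atoms
#'   of `state_a` are matched into `state_b`.
#' @return RMSD in angstrom.
#' @export
kabsch_rmsd <- function(state_a, state_b, selection = NULL) {
  pa <- .selected_coords(state_a, selection)
  pb <- .selected_coords(state_b, selection)
  key_a <- paste(pa$residue_id, pa$atom_name)
  key_b <- paste(pb$residue_id, pb$atom_name)
  if (nrow(pa) != nrow(pb) || !setequal(key_a, key_b))
    stop("selections do not match between states", call. = FALSE)
  pb <- pb[match(key_a, key_b), ]
  A <- as.matrix(pa[, c("x", "y", "z")])
  B <- as.matrix(pb[, c("x", "y", "z")])
  if (nrow(A) < 3)
    stop("superposition requires at least 3 atoms", call. = FALSE)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(A, B))                 # covariance H = A^T B
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)  # A %*% rot best matches B
  diffs <- A %*% rot - B
  sqrt(sum(diffs^2) / nrow(A))
}

.selected_coords <- function(state, selection) {
  stopifnot(inherits(state, "stationary_state"))
  if (is.null(selection)) return(state$atoms)
  dplyr::bind_rows(lapply(selection, function(s) resolve_atom(state, s)))
}

#' Per-atom charge differences between two states
#'
#' Reports the partial-charge change of each matched atom when moving from
#' one state to another — the signature of electron-density rearrangement
#' along a reaction step. Atoms are matched by `(residue_id, atom_name)`.
#'
#' @param state_a,state_b `stationary_state` objects with charges present.
#' @param selection Optional list of atom selectors; default all atoms of
#'   `state_a`.
#' @return A tibble with columns `residue_id`, `atom_name`, `q_a`, `q_b`,
#'   `delta_q` (a.u., `q_b - q_a`).
#' @export
charge_delta <- function(state_a, state_b, selection = NULL) {
  pa <- .selected_coords(state_a, selection)
  pb <- .selected_coords(state_b, selection)
  key_a <- paste(pa$residue_id, pa$atom_name)
  key_b <- paste(pb$residue_id, pb$atom_name)
  if (nrow(pa) != nrow(pb) || !setequal(key_a, key_b))
    stop("selections do not match between states", call. = FALSE)
  pb <- pb[match(key_a, key_b), ]
  if (any(is.na(pa$charge)) || any(is.na(pb$charge)))
    stop("charges missing on selected atoms", call. = FALSE)
  tibble::tibble(
    residue_id = pa$residue_id,
    atom_name = pa$atom_name,
    q_a = pa$charge,
    q_b = pb$charge,
    delta_q = pb$charge - pa$charge
  )
}
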