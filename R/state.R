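#' Construct a stationary state on a reaction path
#'
#' A stationary state is one optimized structure on the catalytic pathway —
#' a minimum (reactant, intermediate, product) or a transition state — with
#' its atoms, optional per-atom partial charges, optional vibrational
#' spectrum and optional electronic energy.
#'
#' When frequencies are supplied the kind is inferred from the number of
#' imaginary modes (encoded as negative wavenumbers): none for a minimum,
#' exactly one for a transition state. Two or more imaginary modes indicate
#' a higher-order saddle and are rejected, since such structures are not
#' stationary states of a reaction path.
#'
#' @param atoms Data frame of atoms with at least columns `element`, `x`,
#'   `y`, `z`. Optional columns: `index` (1-based), `charge` (a.u.),
#'   `residue_id`, `residue_name`, `region` (one of `"QM"`, `"MM"`,
#'   `"frozen_solvent"`), `atom_name`. Missing optional columns are filled
#'   with defaults.
#' @param label State label, e.g. `"R"`, `"TS3"`, `"INT2-TI"`.
#' @param stage `"acylation"` or `"deacylation"`.
#' @param frequencies Optional numeric vector of wavenumbers in cm^-1;
#'   imaginary modes are negative.
#' @param electronic_energy Optional electronic energy in kcal/mol on a
#'   shared zero.
#' @param kind Optional explicit kind (`"minimum"`, `"transition_state"`,
#'   `"unknown"`); by default inferred from `frequencies`, or `"unknown"`
#'   when no frequencies are given.
#'
#' @return An object of class `stationary_state`: a list with elements
#'   `label`, `kind`, `stage`, `atoms` (a tibble), `frequencies`,
#'   `electronic_energy`.
#' @examples
#' atoms <- data.frame(element = c("O", "H", "H"),
#'                     x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0)
#' st <- stationary_state(atoms, label = "R", stage = "acylation")
#' st$kind
#' @export
stationary_state <- function(atoms, label, stage = c("acylation", "deacylation"),
                             frequencies = NULL, electronic_energy = NULL,
                             kind = NULL) {
  stage <- match.arg(stage)
  atoms <- .normalise_atoms(atoms)
  if (!is.null(frequencies)) {
    stopifnot(is.numeric(frequencies))
    n_imag <- sum(frequencies < 0)
    inferred <- if (n_imag == 0) "minimum" else if (n_imag == 1) "transition_state"
    else stop("state '", label, "' has ", n_imag,
              " imaginary frequencies: higher-order saddle, not a stationary state of the path",
              call. = FALSE)
    if (is.null(kind)) kind <- inferred
    if (kind == "transition_state" && n_imag != 1)
      stop("transition state '", label, "' must have exactly one imaginary frequency",
           call. = FALSE)
    if (kind == "minimum" && n_imag != 0)
      stop("minimum '", label, "' must have no imaginary frequencies", call. = FALSE)
  } else if (is.null(kind)) {
    kind <- "unknown"
  }
  kind <- match.arg(kind, c("minimum", "transition_state", "unknown"))
  structure(
    list(label = label, kind = kind, stage = stage, atoms = atoms,
         frequencies = frequencies, electronic_energy = electronic_energy),
    class = "stationary_state"
  )
}

.normalise_atoms <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms table lacks required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom positions must be finite", call. = FALSE)
  if (any(!nzchar(atoms$element)))
    stop("element symbols must be non-empty", call. = FALSE)
  n <- nrow(atoms)
  has <- function(col) col %in% names(atoms)
  if (!has("index")) atoms$index <- seq_len(n)
  if (!has("charge")) atoms$charge <- NA_real_
  if (!has("residue_id")) atoms$residue_id <- 1L
  if (!has("residue_name")) atoms$residue_name <- "LIG"
  if (!has("region")) atoms$region <- "QM"
  if (!has("atom_name"))
    atoms$atom_name <- paste0(atoms$element, atoms$index)
  if (any(!is.na(atoms$residue_id) & atoms$residue_id < 1))
    stop("residue_id must be >= 1", call. = FALSE)
  bad_region <- setdiff(unique(atoms$region), c("QM", "MM", "frozen_solvent"))
  if (length(bad_region) > 0)
    stop("unknown region label(s): ", paste(bad_region, collapse = ", "), call. = FALSE)
  dplyr::select(atoms, "index", "element", "x", "y", "z", "charge",
                "residue_id", "residue_name", "region", "atom_name")
}

#' @export
print.stationary_state <- function(x, ...) {
  cat("<stationary_state> ", x$label, " (", x$kind, ", ", x$stage, " stage)\n", sep = "")
  cat("  atoms: ", nrow(x$atoms),
      "; charges: ", sum(!is.na(x$atoms$charge)), " present", sep = "")
  if (!is.null(x$frequencies))
    cat("; modes: ", length(x$frequencies),
        " (", sum(x$frequencies < 0), " imaginary)", sep = "")
  if (!is.null(x$electronic_energy))
    cat("; E_elec: ", format(x$electronic_energy), " kcal/mol", sep = "")
  cat("\n")
  invisible(x)
}

#' Select a single atom from a stationary state
#'
#' Atom selectors address atoms by `(residue_id, atom_name)` — stable across
#' reordered bundles — and must resolve to exactly one atom.
#'
#' @param residue_id Residue number (1-based, as in PDB numbering).
#' @param atom_name Atom name in PDB v3 conventions (e.g. `"OG"`, `"CA"`).
#' @return An object of class `atom_selector`.
#' @examples
#' sel(190, "OG")
#' @export
sel <- function(residue_id, atom_name) {
  structure(list(residue_id = as.integer(residue_id),
                 atom_name = as.character(atom_name)),
            class = "atom_selector")
}

#' @export
print.atom_selector <- function(x, ...) {
  cat("<atom_selector> residue ", x$residue_id, ", atom ", x$atom_name, "\n", sep = "")
  invisible(x)
}

# Resolve a selector to a single atom row; errors if it matches 0 or >1 atoms.
resolve_atom <- function(state, selector) {
  stopifnot(inherits(state, "stationary_state"))
  if (!inherits(selector, "atom_selector"))
    selector <- sel(selector[[1]], selector[[2]])
  hit <- dplyr::filter(state$atoms,
                       .data$residue_id == selector$residue_id,
                       .data$atom_name == selector$atom_name)
  if (nrow(hit) != 1)
    stop("selector (residue ", selector$residue_id, ", atom ", selector$atom_name,
         ") resolved to ", nrow(hit), " atoms in state '", state$label, "'",
         call. = FALSE)
  hit
}
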