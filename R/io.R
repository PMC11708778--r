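# Readers/writers for the plain-text formats the pipeline consumes:
# XYZ and PDB coordinates, delimited charge/frequency sidecars, step-energy
# tables and trajectory distance tables.

#' Read an XYZ coordinate file
#'
#' Standard two-header-line XYZ dialect: atom count, comment line, then one
#' `element x y z` row per atom (coordinates in angstrom).
#'
#' @param path Path to an `.xyz` file.
#' @return A tibble with columns `index`, `element`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("not an XYZ file (fewer than 2 lines): ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ header atom count is not an integer: ", path, call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("XYZ file declares ", n, " atoms but has ", length(body), " rows", call. = FALSE)
  fields <- strsplit(trimws(body[seq_len(n)]), "\\s+")
  tibble::tibble(
    index = seq_len(n),
    element = vapply(fields, `[[`, character(1), 1),
    x = as.numeric(vapply(fields, `[[`, character(1), 2)),
    y = as.numeric(vapply(fields, `[[`, character(1), 3)),
    z = as.numeric(vapply(fields, `[[`, character(1), 4))
  )
}

#' Write an XYZ coordinate file
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`, or a
#'   `stationary_state`.
#' @param path Output path.
#' @param comment Comment line (second header line).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(atoms, path, comment = "") {
  if (inherits(atoms, "stationary_state")) atoms <- atoms$atoms
  lines <- c(
    as.character(nrow(atoms)),
    comment,
    sprintf("%-2s %14.8f %14.8f %14.8f", atoms$element, atoms$x, atoms$y, atoms$z)
  )
  writeLines(lines, path)
  invisible(path)
}

# Read coordinates from PDB via bio3d; keeps residue/atom naming.
read_pdb_atoms <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package", call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  tibble::tibble(
    index = seq_len(nrow(a)),
    element = ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                     substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    residue_id = as.integer(a$resno),
    residue_name = trimws(a$resid),
    atom_name = trimws(a$elety)
  )
}

#' Read a stationary-state bundle
#'
#' Assembles a [stationary_state()] from a coordinate file (XYZ or PDB)
#' plus optional delimited sidecars: a per-atom partial-charge table (one
#' row per atom, keyed by `index`) and a one-number-per-line frequency list
#' (negative = imaginary). The state kind is inferred from the frequency
#' signs when frequencies are supplied, else `"unknown"`.
#'
#' @param coords_path Path to `.xyz` or `.pdb` coordinates.
#' @param charges_path Optional delimited table (CSV/TSV, header) with
#'   column `index` and `charge`; may also carry `residue_id`,
#'   `residue_name`, `region`, `atom_name` columns to annotate atoms.
#' @param freqs_path Optional plain-text list of wavenumbers in cm^-1.
#' @param label,stage Passed to [stationary_state()].
#' @param electronic_energy Optional electronic energy, kcal/mol.
#' @return A `stationary_state`.
#' @export
read_state_bundle <- function(coords_path, charges_path = NULL, freqs_path = NULL,
                              label, stage = c("acylation", "deacylation"),
                              electronic_energy = NULL) {
  stage <- match.arg(stage)
  ext <- tolower(tools::file_ext(coords_path))
  atoms <- switch(ext,
    xyz = read_xyz(coords_path),
    pdb = read_pdb_atoms(coords_path),
    stop("unsupported coordinate format '.", ext, "' (use XYZ or PDB)", call. = FALSE)
  )
  if (!is.null(charges_path)) {
    ch <- .read_delim_auto(charges_path)
    if (!all(c("index", "charge") %in% names(ch)))
      stop("charge table must have columns 'index' and 'charge'", call. = FALSE)
    if (nrow(ch) != nrow(atoms))
      stop("atom-count mismatch: ", nrow(atoms), " atoms in coordinates vs ",
           nrow(ch), " rows in charge table", call. = FALSE)
    ch <- ch[order(ch$index), ]
    if (!identical(as.integer(ch$index), as.integer(atoms$index)))
      stop("charge table indices do not match the coordinate file", call. = FALSE)
    atoms$charge <- .parse_num(ch$charge, "charge")
    for (col in c("residue_id", "residue_name", "region", "atom_name"))
      if (col %in% names(ch)) atoms[[col]] <- ch[[col]]
  }
  freqs <- NULL
  if (!is.null(freqs_path)) {
    raw <- readLines(freqs_path, warn = FALSE)
    raw <- trimws(raw[nzchar(trimws(raw))])
    raw <- raw[!startsWith(raw, "#")]
    freqs <- .parse_num(raw, "frequency")
  }
  stationary_state(atoms, label = label, stage = stage, frequencies = freqs,
                   electronic_energy = electronic_energy)
}

#' Write a stationary-state bundle
#'
#' Writes the coordinates as XYZ and, when charges are present, a CSV
#' sidecar carrying charges and residue/region annotation. Positions and
#' charges round-trip through [read_state_bundle()] to 1e-6.
#'
#' @param state A `stationary_state`.
#' @param coords_path Output XYZ path.
#' @param charges_path Optional output CSV path for the charge sidecar.
#' @param freqs_path Optional output path for the frequency list.
#' @return `coords_path`, invisibly.
#' @export
write_state_bundle <- function(state, coords_path, charges_path = NULL,
                               freqs_path = NULL) {
  stopifnot(inherits(state, "stationary_state"))
  write_xyz(state, coords_path, comment = paste(state$label, state$stage))
  if (!is.null(charges_path)) {
    out <- dplyr::select(state$atoms, "index", "charge", "residue_id",
                         "residue_name", "region", "atom_name")
    out$charge <- sprintf("%.8f", out$charge)
    utils::write.csv(out, charges_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(freqs_path) && !is.null(state$frequencies))
    writeLines(sprintf("%.4f", state$frequencies), freqs_path)
  invisible(coords_path)
}

#' Read a step-energy table
#'
#' Delimited text (CSV/TSV, header) with one row per mechanistic step:
#' `step_id, from_label, ts_label, to_label, dg_activation, dg_reaction,
#' reference_label`. An empty `dg_activation` field marks a barrierless
#' step. Energies are kcal/mol, measured from `reference_label`. Unicode
#' minus signs are accepted.
#'
#' @param path Path to the table.
#' @return A tibble of step records; `dg_activation` is `NA` for
#'   barrierless steps.
#' @export
read_step_table <- function(path) {
  tab <- .read_delim_auto(path, all_character = TRUE)
  req <- c("step_id", "from_label", "ts_label", "to_label",
           "dg_activation", "dg_reaction", "reference_label")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0)
    stop("step table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tab$dg_activation <- .parse_num(tab$dg_activation, "dg_activation",
                                  allow_empty = TRUE)
  tab$dg_reaction <- .parse_num(tab$dg_reaction, "dg_reaction")
  tibble::as_tibble(tab[req])
}

#' Read a trajectory distance table
#'
#' Delimited text with columns `time` (ns) and the five catalytic-competence
#' distances `d1`..`d5` (angstrom).
#'
#' @param path Path to the table.
#' @return A tibble with columns `time`, `d1`..`d5`.
#' @export
read_distance_table <- function(path) {
  tab <- .read_delim_auto(path)
  req <- c("time", paste0("d", 1:5))
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0)
    stop("distance table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tibble::as_tibble(tab[req])
}

# -- internal helpers ---------------------------------------------------------

# Sniff comma vs tab vs whitespace delimiter from the header line.
.read_delim_auto <- function(path, all_character = FALSE) {
  header <- readLines(path, n = 1, warn = FALSE)
  delim <- if (grepl(",", header)) "," else if (grepl("\t", header)) "\t" else " "
  col_types <- if (all_character) readr::cols(.default = readr::col_character())
  else readr::cols()
  out <- readr::read_delim(path, delim = delim, col_types = col_types,
                           trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  tibble::as_tibble(out)
}

# Strict numeric parser: accepts unicode minus, reports the offending row.
.parse_num <- function(x, what, allow_empty = FALSE) {
  x <- gsub("−", "-", as.character(x))
  x[is.na(x)] <- ""
  empty <- !nzchar(trimws(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !empty
  if (any(bad))
    stop("non-numeric ", what, " value '", x[which(bad)[1]], "' at row ",
         which(bad)[1], call. = FALSE)
  if (!allow_empty && any(empty))
    stop("empty ", what, " value at row ", which(empty)[1], call. = FALSE)
  out
}
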