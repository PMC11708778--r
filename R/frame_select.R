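# Catalytic-competence frame selection from an MD trajectory distance
# table: five named distances per frame, strict thresholds, equilibration
# exclusion, and ranking by ascending distance sum.

#' Evaluate catalytic-competence criteria per trajectory frame
#'
#' Each frame carries five distances: `d1` H-gamma(Ser_nuc)--O-gamma(Ser_cis),
#' `d2` H-gamma(Ser_cis)--N-zeta(Lys), `d3` O-gamma(Ser_nuc)--C_carbonyl
#' (the nucleophilic-attack distance), and `d4`/`d5` the carbonyl oxygen to
#' the two oxyanion-hole backbone amides. A frame passes when `d3` is
#' strictly below `c_attack` and each of the other four is strictly below
#' `c_other`.
#'
#' @param frames Data frame with columns `time` (ns) and `d1`..`d5`
#'   (angstrom, positive).
#' @param c_attack Threshold for the attack distance `d3`, angstrom
#'   (default 3.5).
#' @param c_other Threshold for `d1`, `d2`, `d4`, `d5`, angstrom
#'   (default 2.5).
#' @return A tibble: the input columns plus `passes` (logical) and `dsum`
#'   (sum of the five distances, angstrom).
#' @examples
#' evaluate_frames(data.frame(time = 1, d1 = 2, d2 = 2, d3 = 3.4,
#'                            d4 = 2, d5 = 2))
#' @export
evaluate_frames <- function(frames, c_attack = 3.5, c_other = 2.5) {
  frames <- tibble::as_tibble(frames)
  req <- c("time", paste0("d", 1:5))
  missing_cols <- setdiff(req, names(frames))
  if (length(missing_cols) > 0)
    stop("distance table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- frames[paste0("d", 1:5)]
  if (any(as.matrix(d) <= 0))
    stop("all distances must be positive", call. = FALSE)
  dplyr::mutate(
    frames,
    passes = .data$d3 < c_attack & .data$d1 < c_other & .data$d2 < c_other &
      .data$d4 < c_other & .data$d5 < c_other,
    dsum = .data$d1 + .data$d2 + .data$d3 + .data$d4 + .data$d5
  )
}

#' Select the catalytically competent frame
#'
#' Among passing frames recorded at or after the equilibration window, the
#' frame with the smallest distance sum is chosen (ties broken by earliest
#' time). The pass fraction is reported over the full series, including the
#' excluded window.
#'
#' @param frames Data frame of distances (see [evaluate_frames()]); the
#'   pass flags and sums are (re)computed with the thresholds given here.
#' @param exclude_before_ns Frames earlier than this time are never
#'   selected (default 20 ns), ensuring an equilibrated structure.
#' @param c_attack,c_other Thresholds passed to [evaluate_frames()].
#' @return A list with `frame` (one-row tibble, or zero rows when no frame
#'   qualifies — an explicit empty selection, not an error) and
#'   `pass_fraction` (over all frames).
#' @examples
#' traj <- make_trajectory_series(100, pass_fraction = 0.5, seed = 1)
#' select_frame(traj)$pass_fraction
#' @export
select_frame <- function(frames, exclude_before_ns = 20, c_attack = 3.5,
                         c_other = 2.5) {
  metrics <- evaluate_frames(frames, c_attack = c_attack, c_other = c_other)
  if (nrow(metrics) < 1) stop("need at least one frame", call. = FALSE)
  pass_fraction <- mean(metrics$passes)
  eligible <- dplyr::filter(metrics, .data$passes,
                            .data$time >= exclude_before_ns)
  chosen <- dplyr::slice_head(
    dplyr::arrange(eligible, .data$dsum, .data$time), n = 1)
  list(frame = chosen, pass_fraction = pass_fraction)
}
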