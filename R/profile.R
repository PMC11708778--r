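# Assembly of per-stage Gibbs free-energy profiles from step records,
# energetic-span identification of the rate-limiting barrier, and flags
# for barrierless steps and Gibbs-unstable stationary states.

#' Assemble a cumulative Gibbs profile for one reaction stage
#'
#' Places every stationary state of a stage on a common energy scale from
#' per-step records. Each record carries an activation energy (to its
#' transition state) and a reaction energy (to its product), both measured
#' from an explicit `reference_label` — which need not be the immediately
#' preceding state: when an intermediate is not a stable Gibbs minimum, the
#' next step's energies are usually quoted from an earlier reference.
#'
#' The first `from_label` defines the stage zero. Cumulative energies are
#' `G(TS) = G(reference) + dg_activation` and
#' `G(product) = G(reference) + dg_reaction`. A missing (`NA`) activation
#' energy marks a barrierless step: its transition state is placed
#' degenerate with the higher of the two flanking minima so that spans and
#' plots stay well-defined. Stages are assembled on separate zeros and
#' never concatenated.
#'
#' @param steps Data frame of step records with columns `step_id`,
#'   `from_label`, `ts_label`, `to_label`, `dg_activation` (kcal/mol, `NA`
#'   = barrierless), `dg_reaction` (kcal/mol), `reference_label`. Rows must
#'   chain: each `from_label` equals the previous `to_label`.
#' @param stage `"acylation"` or `"deacylation"`.
#' @return An object of class `reaction_profile`: a list with `stage`,
#'   `states` (tibble of `label`, `role`, `G`, `step_id`, `barrierless`),
#'   `barrierless_steps`, `unstable_states`, and `rate_limiting`
#'   (`ts_label` + `span`).
#' @examples
#' stage1 <- make_step_table("stage1-paper")
#' prof <- assemble_profile(stage1, stage = "acylation")
#' prof$rate_limiting
#' @export
assemble_profile <- function(steps, stage = c("acylation", "deacylation")) {
  stage <- match.arg(stage)
  steps <- tibble::as_tibble(steps)
  if (nrow(steps) == 0) stop("no steps to assemble", call. = FALSE)
  req <- c("step_id", "from_label", "ts_label", "to_label",
           "dg_activation", "dg_reaction", "reference_label")
  missing_cols <- setdiff(req, names(steps))
  if (length(missing_cols) > 0)
    stop("step table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  G <- stats::setNames(0, steps$from_label[1])
  rows <- list(tibble::tibble(label = steps$from_label[1], role = "minimum",
                              G = 0, step_id = NA_character_, barrierless = FALSE))
  for (i in seq_len(nrow(steps))) {
    s <- steps[i, ]
    if (i > 1 && s$from_label != steps$to_label[i - 1])
      stop("broken chain at step '", s$step_id, "': from_label '", s$from_label,
           "' does not match previous to_label '", steps$to_label[i - 1], "'",
           call. = FALSE)
    if (!s$reference_label %in% names(G))
      stop("step '", s$step_id, "' references unknown state '",
           s$reference_label, "'", call. = FALSE)
    if (s$to_label %in% names(G) || s$ts_label %in% names(G))
      stop("duplicate state label in step '", s$step_id, "'", call. = FALSE)
    g_ref <- G[[s$reference_label]]
    g_to <- g_ref + s$dg_reaction
    barrierless <- is.na(s$dg_activation)
    g_ts <- if (barrierless) max(G[[s$from_label]], g_to) else g_ref + s$dg_activation
    G[s$ts_label] <- g_ts
    G[s$to_label] <- g_to
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = c(s$ts_label, s$to_label),
      role = c("transition_state", "minimum"),
      G = c(g_ts, g_to),
      step_id = s$step_id,
      barrierless = barrierless
    )
  }
  states <- dplyr::bind_rows(rows)

  prof <- structure(
    list(stage = stage, states = states,
         barrierless_steps = steps$step_id[is.na(steps$dg_activation)],
         unstable_states = character(0),
         rate_limiting = NULL),
    class = "reaction_profile"
  )
  prof$rate_limiting <- rate_limiting_barrier(prof)
  prof$unstable_states <- detect_unstable_states(prof)
  prof
}

#' Rate-limiting barrier of a profile (energetic span)
#'
#' For each transition state, the span is its Gibbs energy minus the lowest
#' Gibbs energy among all states preceding it in the stage. The
#' rate-limiting barrier is the largest such span; ties are broken toward
#' the later transition state.
#'
#' @param profile A `reaction_profile`.
#' @return A list with `ts_label` and `span` (kcal/mol).
#' @examples
#' prof <- assemble_profile(make_step_table("stage1-paper"), "acylation")
#' rate_limiting_barrier(prof)
#' @export
rate_limiting_barrier <- function(profile) {
  stopifnot(inherits(profile, "reaction_profile"))
  st <- profile$states
  ts_idx <- which(st$role == "transition_state")
  if (length(ts_idx) == 0)
    stop("profile contains no transition state", call. = FALSE)
  spans <- vapply(ts_idx, function(i) st$G[i] - min(st$G[seq_len(i - 1)]),
                  numeric(1))
  best <- max(spans)
  pick <- max(which(spans >= best - 1e-12))   # ties -> later TS
  list(ts_label = st$label[ts_idx[pick]], span = spans[pick])
}

#' Detect Gibbs-unstable stationary states
#'
#' A potential-energy minimum whose Gibbs energy lies at or above an
#' adjacent transition state is not a minimum of the free-energy profile:
#' the thermal and entropic corrections have erased the barrier around it.
#' Transition states placed by the barrierless convention (degenerate with
#' a flanking minimum) are not treated as evidence of instability.
#'
#' @param profile A `reaction_profile`.
#' @return Character vector of unstable state labels.
#' @examples
#' prof <- assemble_profile(make_step_table("stage1-paper"), "acylation")
#' detect_unstable_states(prof)
#' @export
detect_unstable_states <- function(profile) {
  stopifnot(inherits(profile, "reaction_profile"))
  st <- profile$states
  n <- nrow(st)
  unstable <- character(0)
  for (i in seq_len(n)) {
    if (st$role[i] != "minimum") next
    for (j in c(i - 1, i + 1)) {
      if (j < 1 || j > n) next
      if (st$role[j] == "transition_state" && !st$barrierless[j] &&
          st$G[j] <= st$G[i]) {
        unstable <- c(unstable, st$label[i])
        break
      }
    }
  }
  unstable
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat("<reaction_profile> ", x$stage, " stage: ", nrow(x$states), " states\n",
      sep = "")
  cat("  rate-limiting: ", x$rate_limiting$ts_label, " (span ",
      format(x$rate_limiting$span), " kcal/mol)\n", sep = "")
  if (length(x$barrierless_steps) > 0)
    cat("  barrierless steps: ", paste(x$barrierless_steps, collapse = ", "),
        "\n", sep = "")
  if (length(x$unstable_states) > 0)
    cat("  Gibbs-unstable states: ", paste(x$unstable_states, collapse = ", "),
        "\n", sep = "")
  print(x$states)
  invisible(x)
}

#' Tidy a reaction profile into its state table
#'
#' @param x A `reaction_profile`.
#' @param ... Unused.
#' @return A tibble with one row per stationary state: `stage`, `label`,
#'   `role`, `G` (kcal/mol), `step_id`, `barrierless`, `unstable`.
#' @export
tidy.reaction_profile <- function(x, ...) {
  dplyr::mutate(x$states,
                stage = x$stage,
                unstable = .data$label %in% x$unstable_states,
                .before = 1)
}

#' One-row summary of a reaction profile
#'
#' @param x A `reaction_profile`.
#' @param ... Unused.
#' @return A one-row tibble: `stage`, `n_states`, `rate_limiting_ts`,
#'   `rate_limiting_span`, `n_barrierless`, `n_unstable`.
#' @export
glance.reaction_profile <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    n_states = nrow(x$states),
    rate_limiting_ts = x$rate_limiting$ts_label,
    rate_limiting_span = x$rate_limiting$span,
    n_barrierless = length(x$barrierless_steps),
    n_unstable = length(x$unstable_states)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
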