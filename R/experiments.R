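#' Run one replicate of a scenario
#'
#' Executes the full pipeline of a single replicate: sample the interaction
#' matrix and the equilibrium, derive the growth rates, evaluate local
#' stability of the interior equilibrium, perturb, integrate the governing
#' model, and classify the outcome. Given the same `seed` the record is
#' bit-reproducible.
#'
#' @param config A [scenario_config()].
#' @param replicate_id Integer identifier recorded in the output.
#' @param seed Seed for this replicate. Defaults to `config$seed +
#'   replicate_id`, but sweeps pre-assign independent seeds.
#' @return A one-row tibble with columns `S`, `replicate_id`, `seed`,
#'   `is_stable`, `marginal`, `max_real_part`, `stop_reason`, `t_stop`,
#'   `n_alive`, `n_at_ceiling`, `blow_up`, `all_alive`, `returned_to_Nstar`
#'   and `delta_mean_interaction` (the interaction-selection statistic, `NA`
#'   when undefined or for unbounded runs).
#' @export
run_replicate <- function(config, replicate_id = 1L,
                          seed = config$seed + replicate_id) {
  config <- validate_scenario_config(config)
  set.seed(seed)
  smp <- sample_community(config)
  model <- smp$model
  stab <- local_stability(model)
  sim <- simulate_community(model, smp$N0, config)
  delta <- if (config$bounded) {
    interaction_selection_statistic(model$A, sim$alive_mask)
  } else {
    NA_real_
  }
  tibble::tibble(
    S = config$S,
    replicate_id = as.integer(replicate_id),
    seed = as.integer(seed),
    is_stable = stab$is_stable,
    marginal = stab$marginal,
    max_real_part = stab$max_real_part,
    stop_reason = sim$stop_reason,
    t_stop = sim$t_stop,
    n_alive = sim$n_alive,
    n_at_ceiling = sim$n_at_ceiling,
    blow_up = sim$stop_reason == "blow_up",
    all_alive = sim$n_alive == config$S,
    returned_to_Nstar = sim$returned_to_Nstar,
    delta_mean_interaction = delta
  )
}

#' Replicated sweep over a richness gradient
#'
#' For each richness in `S_grid`, runs `n_reps` independent replicates of the
#' scenario and aggregates per-richness summaries. Per-replicate seeds are
#' pre-assigned from the root seed, so records are independent of execution
#' order and any single replicate can be reproduced in isolation with
#' [run_replicate()].
#'
#' @param config A [scenario_config()]; its `S` field is overridden by the
#'   grid values.
#' @param S_grid Ascending vector of richness values. Defaults to
#'   `seq(10, 250, by = 10)`.
#' @param n_reps Replicates per richness value (defaults to `config$n_reps`).
#' @param progress If `TRUE`, log one line per richness value to stderr.
#' @return An object of class `glv_sweep`: a list with `records` (one row
#'   per replicate, the columns of [run_replicate()]), `summary` (one row per
#'   richness, see [summarize_sweep()]), `config` and `S_grid`.
#' @export
run_richness_sweep <- function(config, S_grid = seq(10, 250, by = 10),
                               n_reps = config$n_reps, progress = FALSE) {
  config <- validate_scenario_config(config)
  if (length(S_grid) < 1 || is.unsorted(S_grid))
    stop("S_grid must be a nonempty ascending vector", call. = FALSE)
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(S_grid) * n_reps),
                  nrow = n_reps)
  records <- purrr::imap(S_grid, function(S, k) {
    if (progress)
      message(sprintf("[glvsim] S = %d (%d replicates)", S, n_reps))
    cfg_S <- config
    cfg_S$S <- as.integer(S)
    purrr::map(seq_len(n_reps), function(i) {
      run_replicate(cfg_S, replicate_id = i, seed = seeds[i, k])
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(list(records = records,
                 summary = summarize_sweep(records, config),
                 config = config, S_grid = S_grid),
            class = "glv_sweep")
}

#' Per-richness summary of sweep records
#'
#' @param records Tibble of replicate records as produced by
#'   [run_replicate()].
#' @param config The scenario configuration the records were generated under
#'   (used for the near-total-extinction cutoff).
#' @return A tibble with one row per `S`: `n_reps`, `prop_stable`,
#'   `prop_blow_up`, `mean_n_alive`, `mean_n_at_ceiling`,
#'   `prop_no_extinction`, `prop_near_total_extinction` and
#'   `mean_delta_interaction` (mean over replicates where the selection
#'   statistic is defined).
#' @export
summarize_sweep <- function(records, config) {
  frac <- config$near_total_fraction
  records |>
    dplyr::group_by(.data$S) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      prop_stable = mean(.data$is_stable),
      prop_blow_up = mean(.data$blow_up),
      mean_n_alive = mean(.data$n_alive),
      mean_n_at_ceiling = mean(.data$n_at_ceiling),
      prop_no_extinction = mean(.data$all_alive),
      prop_near_total_extinction = mean(.data$n_alive <= frac * .data$S),
      mean_delta_interaction = if (all(is.na(.data$delta_mean_interaction))) {
        NA_real_
      } else {
        mean(.data$delta_mean_interaction, na.rm = TRUE)
      },
      .groups = "drop"
    )
}

#' @export
print.glv_sweep <- function(x, ...) {
  cat(sprintf("<glv_sweep> %s, sign_mode = %s; %d richness values x %d replicates\n",
              if (x$config$bounded) "bounded GLV" else "GLV",
              x$config$sign_mode, length(x$S_grid),
              nrow(x$records) / length(x$S_grid)))
  print(x$summary)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.glv_sweep <- function(x, ...) x$records

#' @rdname tidiers
#' @export
glance.glv_sweep <- function(x, ...) x$summary

#' Ecological selection of interaction strength
#'
#' Difference between the mean realised (nonzero, off-diagonal) interaction
#' coefficient within the surviving subcommunity and the same mean over the
#' full initial community. A positive value means stronger (more positive)
#' interactions were retained. The statistic is undefined (`NA`) when fewer
#' than two species survive or when the survivor submatrix carries no
#' realised interaction.
#'
#' @param A Interaction matrix of the initial community.
#' @param alive_mask Logical mask of surviving species.
#' @return A single number, or `NA_real_` when undefined.
#' @examples
#' A <- matrix(0, 3, 3); diag(A) <- -1
#' A[1, 2] <- A[2, 1] <- 0.4; A[1, 3] <- A[3, 1] <- -0.6
#' interaction_selection_statistic(A, c(TRUE, TRUE, FALSE)) # 0.5
#' @export
interaction_selection_statistic <- function(A, alive_mask) {
  if (sum(alive_mask) < 2) return(NA_real_)
  off_nonzero <- function(M) {
    v <- M[row(M) != col(M)]
    v[v != 0]
  }
  sub <- A[alive_mask, alive_mask, drop = FALSE]
  nz_sub <- off_nonzero(sub)
  if (length(nz_sub) == 0) return(NA_real_)
  mean(nz_sub) - mean(off_nonzero(A))
}

#' Classify the terminal outcome of an all-positive scenario
#'
#' Communities with exclusively positive interspecific interactions and an
#' unstable initial equilibrium end up in one of two contrasting states:
#' either every species survives (converging to the ceiling in the bounded
#' model), or almost all go extinct. Classification uses `n_alive = S`
#' for the first and `n_alive <= near_total_fraction * S` for the second.
#'
#' @param n_alive Number of surviving species.
#' @param S Initial richness.
#' @param near_total_fraction Cutoff fraction for "near-total extinction".
#' @return One of `"all_alive"`, `"near_total_extinction"`, `"other"`.
#' @export
classify_positive_outcome <- function(n_alive, S, near_total_fraction = 0.1) {
  dplyr::case_when(
    n_alive == S ~ "all_alive",
    n_alive <= near_total_fraction * S ~ "near_total_extinction",
    .default = "other"
  )
}
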