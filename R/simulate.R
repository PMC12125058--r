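# Generative simulation and likelihoods, backed by the compiled engines.

#' Simulate one agent playing the IGT
#'
#' Runs a model generatively: on each trial the choice is sampled from the
#' model's current choice probabilities, the outcome is served from the chosen
#' deck's schedule, and the latent state is updated. States start at zero so
#' first-trial probabilities are uniform. The run is fully deterministic given
#' `(params, schedule, seed)`.
#'
#' Raw schedule points are multiplied by `outcome_scale` before entering the
#' model equations; the default 1/100 maps the 100-point reward to 1.
#'
#' @param params an [orl_params()], [vse_params()] or [legacy_params()] object.
#' @param schedule an [igt_schedule()]; built fresh from `seed` (shuffled
#'   blocks) when `NULL`.
#' @param n_trials number of trials (used when `schedule` is `NULL`, and
#'   bounded by the schedule length otherwise).
#' @param seed integer seed for the choice sampling (and schedule, if built
#'   here).
#' @param outcome_scale multiplier applied to raw points before the model
#'   equations (default 0.01).
#' @param subjID subject label for the output.
#' @return A tibble with columns `subjID`, `trial`, `deck` (A-D), `gain`,
#'   `loss` (raw points, loss as a magnitude).
#' @examples
#' trials <- simulate_agent(vse_params(.5, .8, .3, .5, 1), seed = 1)
#' count_choices(trials)
#' @export
simulate_agent <- function(params, schedule = NULL, n_trials = 100,
                           seed = NULL, outcome_scale = 0.01,
                           subjID = "sim1") {
  model <- model_name(params)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (is.null(schedule)) schedule <- igt_schedule(n_trials, seed = seed)
  stopifnot(inherits(schedule, "igt_schedule"))
  n_trials <- min(n_trials, schedule$n_trials)
  m <- schedule_matrices(schedule)
  sim <- cpp_simulate_agent(MODEL_IDS[[model]], param_vector(params),
                            m$gain, m$loss, as.integer(n_trials),
                            as.double(seed), outcome_scale)
  tibble(subjID = subjID, trial = seq_len(n_trials),
         deck = DECKS[sim$deck], gain = sim$gain, loss = sim$loss)
}

check_trials <- function(data) {
  need <- c("subjID", "trial", "deck", "gain", "loss")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("trial data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$deck %in% DECKS)) {
    stop("`deck` must contain only A, B, C, D", call. = FALSE)
  }
  if (any(data$gain < 0) || any(data$loss < 0)) {
    stop("`gain` and `loss` must be non-negative (loss is a magnitude)",
         call. = FALSE)
  }
  data
}

#' Log-likelihood of observed IGT choices under a model
#'
#' Evaluates `sum_t log p(choice_t | state before t)` with the latent state
#' evolved along the observed choices and outcomes (teacher forcing). With
#' several subjects in `data`, the same parameter vector is applied to each
#' and the log-likelihoods are summed (or concatenated if `pointwise`).
#'
#' @inheritParams simulate_agent
#' @param data trial tibble with columns `subjID`, `trial`, `deck`, `gain`,
#'   `loss` (raw points).
#' @param pointwise return the per-trial log-probability vector (subjects in
#'   label order, trials ascending within subject) instead of the sum.
#' @return A scalar log-likelihood, or a numeric vector if `pointwise`.
#' @export
log_lik <- function(params, data, outcome_scale = 0.01, pointwise = FALSE) {
  check_trials(data)
  model <- model_name(params)
  out <- lapply(split(seq_len(nrow(data)), data$subjID), function(idx) {
    idx <- idx[order(data$trial[idx])]
    cpp_loglik(MODEL_IDS[[model]], param_vector(params),
               match(data$deck[idx], DECKS), data$gain[idx], data$loss[idx],
               outcome_scale, pointwise)
  })
  if (pointwise) unlist(out, use.names = FALSE) else sum(unlist(out))
}
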