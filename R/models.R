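# Model parameter containers and pure-R reference implementations of the
# trial-by-trial update and choice rules. The compiled engines in src/ are
# used for bulk simulation, likelihoods and PSP; these R versions define the
# semantics and are cross-checked against the compiled path in the tests.

MODEL_IDS <- c(orl = 1L, vse = 2L, ev = 3L, pvl = 4L, evpu = 5L, pvldelta = 6L)

check_range <- function(x, name, lo, hi) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop("`", name, "` must be a single number", call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop("`", name, "` must be in [", lo, ", ", hi, "]", call. = FALSE)
  }
  as.double(x)
}

#' ORL model parameters
#'
#' The Outcome-Representation Learning model tracks, per deck, an expected
#' value `EV` (delta rule on the net outcome, with separate learning rates for
#' rewarded and punished trials), an expected win frequency `EF` (delta rule
#' on the sign of the net outcome; unchosen decks move toward the opposite
#' sign split over the three alternatives, with the learning rate of the
#' opposite outcome type — the counterfactual update of the original model),
#' and a perseverance value `PS`
#' decaying at rate `1/(1+K)` with `K = 3^K_prime - 1`. Decks are chosen by a
#' softmax with unit sensitivity on `V = EV + EF * beta_F + PS * beta_P`.
#'
#' @param A_rew,A_pun learning rates for non-negative / negative net outcomes,
#'   in `[0, 1]`.
#' @param K_prime perseverance-decay exponent in `[0, 5]`; the effective decay
#'   is `K = 3^K_prime - 1` in `[0, 242]`.
#' @param beta_F,beta_P win-frequency and perseverance weights (unbounded).
#' @return A named parameter object of class `orl_params`.
#' @examples
#' p <- orl_params(0.3, 0.1, 1, 1.5, 1)
#' orl_decay_K(5) # 242
#' @export
orl_params <- function(A_rew, A_pun, K_prime, beta_F, beta_P) {
  structure(
    list(A_rew = check_range(A_rew, "A_rew", 0, 1),
         A_pun = check_range(A_pun, "A_pun", 0, 1),
         K_prime = check_range(K_prime, "K_prime", 0, 5),
         beta_F = check_range(beta_F, "beta_F", -Inf, Inf),
         beta_P = check_range(beta_P, "beta_P", -Inf, Inf)),
    class = c("orl_params", "igt_params")
  )
}

#' @rdname orl_params
#' @export
orl_decay_K <- function(K_prime) 3^K_prime - 1

#' VSE model parameters
#'
#' The Value plus Sequential Exploration model combines an exploitation
#' weight per deck (decaying accumulation of the utility
#' `v = gain^theta - loss^theta`) with an exploration weight that is reset to
#' zero for the chosen deck and drifts toward the exploration bonus `phi` for
#' unchosen decks. Choice is a softmax on `(Explore + Exploit) * c` with
#' consistency `c = 3^beta - 1`; `beta = 0` gives uniformly random choice.
#'
#' @param theta utility sensitivity in `[0, 1]`.
#' @param delta exploitation decay in `[0, 1]`.
#' @param alpha exploration learning rate in `[0, 1]`.
#' @param phi exploration bonus (unbounded).
#' @param beta inverse temperature in `[0, 5]`; consistency `c = 3^beta - 1`.
#' @return A named parameter object of class `vse_params`.
#' @export
vse_params <- function(theta, delta, alpha, phi, beta) {
  structure(
    list(theta = check_range(theta, "theta", 0, 1),
         delta = check_range(delta, "delta", 0, 1),
         alpha = check_range(alpha, "alpha", 0, 1),
         phi = check_range(phi, "phi", -Inf, Inf),
         beta = check_range(beta, "beta", 0, 5)),
    class = c("vse_params", "igt_params")
  )
}

#' @rdname vse_params
#' @export
vse_consistency <- function(beta) 3^beta - 1

#' Parameters for the classical IGT reinforcement-learning models
#'
#' Expectancy-Valence (`"ev"`), Prospect Valence Learning (`"pvl"`), EV with
#' prospect utility (`"evpu"`) and PVL with delta-rule learning
#' (`"pvldelta"`). EV uses the valence utility `(1-w)*gain - w*loss`, a delta
#' rule on the chosen deck, and trial-dependent sensitivity `(t/10)^cons`.
#' PVL uses the prospect utility `x^shape` for gains and `-w*|x|^shape` for
#' losses, a decay rule over all decks, and sensitivity `3^cons - 1`; EV-PU
#' and PVL-Delta recombine those components (prospect utility with delta-rule
#' learning, EV-style or PVL-style sensitivity respectively).
#'
#' @param model one of `"ev"`, `"pvl"`, `"evpu"`, `"pvldelta"`.
#' @param shape prospect-utility shape in `[0, 1]` (PVL family only).
#' @param loss_aversion loss-aversion weight: attention to losses `w` in
#'   `[0, 1]` for EV, multiplicative loss aversion in `[0, 5]` otherwise.
#' @param rate updating (delta) or recency (decay) rate in `[0, 1]`.
#' @param cons choice consistency: `[-5, 5]` for the trial-dependent EV /
#'   EV-PU rule, `[0, 5]` for the PVL-style rule.
#' @return A parameter object of class `legacy_params`.
#' @export
legacy_params <- function(model = c("ev", "pvl", "evpu", "pvldelta"),
                          shape = NULL, loss_aversion, rate, cons) {
  model <- match.arg(model)
  if (model == "ev") {
    if (!is.null(shape)) stop("the EV model has no shape parameter", call. = FALSE)
    par <- list(loss_aversion = check_range(loss_aversion, "loss_aversion", 0, 1),
                rate = check_range(rate, "rate", 0, 1),
                cons = check_range(cons, "cons", -5, 5))
  } else {
    cons_lo <- if (model == "evpu") -5 else 0
    par <- list(shape = check_range(shape, "shape", 0, 1),
                loss_aversion = check_range(loss_aversion, "loss_aversion", 0, 5),
                rate = check_range(rate, "rate", 0, 1),
                cons = check_range(cons, "cons", cons_lo, 5))
  }
  structure(c(list(model = model), par),
            class = c("legacy_params", "igt_params"))
}

model_name <- function(params) {
  if (inherits(params, "orl_params")) return("orl")
  if (inherits(params, "vse_params")) return("vse")
  if (inherits(params, "legacy_params")) return(params$model)
  stop("`params` must be an orl_params, vse_params or legacy_params object",
       call. = FALSE)
}

param_vector <- function(params) {
  switch(model_name(params),
    orl = c(params$A_rew, params$A_pun, params$K_prime, params$beta_F,
            params$beta_P),
    vse = c(params$theta, params$delta, params$alpha, params$phi, params$beta),
    ev = c(params$loss_aversion, params$rate, params$cons),
    c(params$shape, params$loss_aversion, params$rate, params$cons)
  )
}

softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

deck_index <- function(deck) {
  if (is.character(deck)) match(check_deck(deck), DECKS) else as.integer(deck)
}

# ---- ORL ------------------------------------------------------------------

#' ORL latent state
#'
#' All-zero initial state, so first-trial choice probabilities are uniform.
#'
#' @return A list with 4-vectors `EV`, `EF`, `PS`, `V` (named by deck).
#' @export
orl_state <- function() {
  z <- stats::setNames(numeric(4), DECKS)
  list(EV = z, EF = z, PS = z, V = z)
}

#' One ORL update step
#'
#' @param state an [orl_state()].
#' @param params an [orl_params()].
#' @param chosen deck id (`"A"`..`"D"` or 1..4).
#' @param outcome list or one-row data frame with `gain` and `loss` (loss as a
#'   non-negative magnitude) already on the model's outcome scale.
#' @return The updated state, with `V` recomputed.
#' @export
orl_update <- function(state, params, chosen, outcome) {
  j <- deck_index(chosen)
  x <- outcome$gain - outcome$loss
  if (!is.finite(x) || any(!is.finite(unlist(state)))) {
    stop("non-finite state or outcome", call. = FALSE)
  }
  A <- if (x >= 0) params$A_rew else params$A_pun
  # fictive updates use the opposite rate: a win on the chosen deck is a
  # relative loss for the three alternatives, and vice versa
  A_fic <- if (x >= 0) params$A_pun else params$A_rew
  sg <- sign(x)
  state$EV[j] <- state$EV[j] + A * (x - state$EV[j])
  target <- rep(-sg / 3, 4)
  rate <- rep(A_fic, 4)
  target[j] <- sg
  rate[j] <- A
  state$EF <- state$EF + rate * (target - state$EF)
  K <- orl_decay_K(params$K_prime)
  state$PS <- state$PS / (1 + K)
  state$PS[j] <- 1 / (1 + K)
  state$V <- state$EV + state$EF * params$beta_F + state$PS * params$beta_P
  state
}

#' ORL choice probabilities
#'
#' Softmax with unit sensitivity over the integrated value signal `V`.
#'
#' @param state an [orl_state()] (after [orl_update()]).
#' @return A named 4-vector of probabilities summing to one.
#' @export
orl_choice_probs <- function(state) {
  stopifnot(all(is.finite(state$V)))
  softmax(state$V)
}

# ---- VSE ------------------------------------------------------------------

#' VSE latent state
#' @return A list with 4-vectors `exploit` and `explore` (named by deck).
#' @export
vse_state <- function() {
  z <- stats::setNames(numeric(4), DECKS)
  list(exploit = z, explore = z)
}

#' VSE utility of an outcome
#'
#' `v = gain^theta - loss^theta` with the loss entering as a non-negative
#' magnitude and no loss-aversion weight. At `theta = 0` the power convention
#' `0^0 = 1` is used, so the utility is identically zero and choice is driven
#' entirely by exploration.
#'
#' @param gain,loss non-negative outcome magnitudes (model scale).
#' @param theta sensitivity in `[0, 1]`.
#' @return The utility value (vectorized over `gain`/`loss`).
#' @export
vse_utility <- function(gain, loss, theta) {
  check_range(theta, "theta", 0, 1)
  if (any(gain < 0) || any(loss < 0)) {
    stop("`gain` and `loss` must be non-negative magnitudes", call. = FALSE)
  }
  gain^theta - loss^theta
}

#' One VSE update step
#'
#' Exploitation weights decay by `delta` (the chosen deck additionally
#' receives the trial utility); the chosen deck's exploration weight resets to
#' zero while unchosen decks' weights move toward the exploration bonus `phi`
#' by a delta rule with rate `alpha`.
#'
#' @inheritParams orl_update
#' @param params a [vse_params()].
#' @return The updated state.
#' @export
vse_update <- function(state, params, chosen, outcome) {
  j <- deck_index(chosen)
  if (any(!is.finite(unlist(state))) || !is.finite(outcome$gain - outcome$loss)) {
    stop("non-finite state or outcome", call. = FALSE)
  }
  v <- vse_utility(outcome$gain, outcome$loss, params$theta)
  state$exploit <- state$exploit * params$delta
  state$exploit[j] <- state$exploit[j] + v
  state$explore <- state$explore + params$alpha * (params$phi - state$explore)
  state$explore[j] <- 0
  state
}

#' VSE choice probabilities
#'
#' Softmax over `(Explore + Exploit) * c` with `c = 3^beta - 1`.
#'
#' @param state a [vse_state()].
#' @param params a [vse_params()].
#' @return A named 4-vector of probabilities summing to one.
#' @export
vse_choice_probs <- function(state, params) {
  w <- state$explore + state$exploit
  stopifnot(all(is.finite(w)))
  softmax(w * vse_consistency(params$beta))
}

# ---- classical models -----------------------------------------------------

#' Latent state for the classical models
#' @return A named 4-vector of deck expectancies, initialized at zero.
#' @export
legacy_state <- function() stats::setNames(numeric(4), DECKS)

#' One update step for a classical model
#'
#' @param params a [legacy_params()].
#' @param state a [legacy_state()].
#' @param chosen deck id.
#' @param outcome list with `gain` and `loss` magnitude on the model scale.
#' @return The updated expectancy vector.
#' @export
legacy_update <- function(params, state, chosen, outcome) {
  j <- deck_index(chosen)
  x <- outcome$gain - outcome$loss
  if (params$model == "ev") {
    u <- (1 - params$loss_aversion) * outcome$gain -
      params$loss_aversion * outcome$loss
    state[j] <- state[j] + params$rate * (u - state[j])
    return(state)
  }
  u <- if (x >= 0) x^params$shape else -params$loss_aversion * (-x)^params$shape
  if (params$model == "pvl") {
    state <- state * params$rate
    state[j] <- state[j] + u
  } else {
    state[j] <- state[j] + params$rate * (u - state[j])
  }
  state
}

#' Choice probabilities for a classical model
#'
#' @inheritParams legacy_update
#' @param trial 1-based trial index (the EV-style sensitivity `(t/10)^cons`
#'   depends on it).
#' @return A named 4-vector of probabilities.
#' @export
legacy_choice_probs <- function(params, state, trial) {
  th <- if (params$model %in% c("ev", "evpu")) {
    (trial / 10)^params$cons
  } else {
    3^params$cons - 1
  }
  softmax(th * state)
}
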