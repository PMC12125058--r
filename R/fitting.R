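# Hierarchical Bayesian estimation of ORL / VSE on multi-subject datasets and
# information-criterion model comparison.
#
# Individual-level parameters are drawn from group-level normal distributions
# on an unconstrained scale and mapped to their ranges by a probit (standard
# normal CDF) transform scaled to the range upper bound; unbounded parameters
# use the identity. The joint posterior is approximated by mean-field
# variational inference (ADVI): stochastic gradient ascent on the ELBO with
# reparameterized draws and analytic forward-sensitivity gradients of the
# trial-level likelihood, on the non-centered parameterization. The backend
# contract — deterministic given the seed, returns S draws plus pointwise
# log-likelihoods — is what the rest of the package relies on, so other
# backends (e.g. a sampler) can be substituted.

hier_param_names <- function(model) {
  if (model == "orl") c("A_rew", "A_pun", "K_prime", "beta_F", "beta_P")
  else c("theta", "delta", "alpha", "phi", "beta")
}

hier_types <- function(model) {
  if (model == "orl") {
    list(type = c(0, 0, 1, 2, 2), ub = c(1, 1, 5, NA, NA))
  } else {
    list(type = c(0, 0, 0, 2, 1), ub = c(1, 1, 1, NA, 5))
  }
}

hier_transform_one <- function(model, p, x) {
  ty <- hier_types(model)
  switch(ty$type[p] + 1, pnorm(x), ty$ub[p] * pnorm(x), x)
}

hier_transform <- function(model, x) {
  # natural-scale 5-vector from unconstrained values
  vapply(1:5, function(p) hier_transform_one(model, p, x[p]), numeric(1))
}

hier_untransform <- function(model, v) {
  # inverse transform of a natural-scale 5-vector
  if (model == "orl") {
    c(qnorm(v[1]), qnorm(v[2]), qnorm(v[3] / 5), v[4], v[5])
  } else {
    c(qnorm(v[1]), qnorm(v[2]), qnorm(v[3]), v[4], qnorm(v[5] / 5))
  }
}

hier_data <- function(data) {
  check_trials(data)
  ids <- unique(data$subjID)
  if (length(ids) == 0) stop("no subjects in `data`", call. = FALSE)
  lens <- integer(length(ids))
  choices <- integer(0); gain <- numeric(0); loss <- numeric(0)
  for (i in seq_along(ids)) {
    d <- data[data$subjID == ids[i], ]
    d <- d[order(d$trial), ]
    if (nrow(d) < 2) {
      stop("subject ", ids[i], " has fewer than 2 trials", call. = FALSE)
    }
    lens[i] <- nrow(d)
    choices <- c(choices, match(d$deck, DECKS))
    gain <- c(gain, d$gain)
    loss <- c(loss, d$loss)
  }
  list(ids = ids, off = as.integer(c(0, cumsum(lens))),
       choices = as.integer(choices), gain = gain, loss = loss)
}

#' Fit a hierarchical ORL or VSE model
#'
#' Group-level normal distributions (probit-transformed for range-bounded
#' parameters) with per-subject deviates, estimated by seeded mean-field
#' variational inference (ADVI with reparameterized gradients; default
#' 10,000 iterations); `draws` posterior samples (default 1000) and the
#' pointwise log-likelihood matrix are produced for WAIC, and summed
#' log-likelihood at per-subject posterior means feeds AIC/BIC with
#' `k = 5 * n_subjects` and `n =` total trials (both conventions are echoed
#' in the result).
#'
#' Hyperpriors follow the model-specific conventions: for ORL, `mu ~ N(0,1)`
#' with half-normal(0.2) hyper-SDs for bounded parameters and half-Cauchy(1)
#' for the unbounded weights; for VSE, normal hyperpriors with mean 0 and SD
#' 3.0 throughout.
#'
#' @param data trial tibble (`subjID`, `trial`, `deck`, `gain`, `loss`; raw
#'   points).
#' @param model `"orl"` or `"vse"`.
#' @param draws number of posterior draws (default 1000).
#' @param seed seed for the variational optimization and posterior draws.
#' @param outcome_scale multiplier applied to raw points before the model
#'   equations.
#' @param iters ADVI iterations (default 10000); ignored by the HMC backend.
#' @param lr Adam base step size (ADVI backend).
#' @param backend `"hmc"` (default): Hamiltonian Monte Carlo with
#'   dual-averaging step-size and diagonal mass adaptation; `"advi"`:
#'   mean-field variational inference. Both are deterministic given `seed`
#'   and satisfy the same contract (S draws + pointwise log-likelihoods).
#' @param warmup HMC warmup iterations.
#' @return An object of class `igt_fit` with posterior draws, pointwise
#'   log-likelihoods, information criteria and convergence diagnostics.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_hierarchical <- function(data, model = c("orl", "vse"), draws = 1000,
                             seed = 1, outcome_scale = 0.01,
                             backend = c("hmc", "advi"), iters = 10000,
                             lr = 0.05, warmup = 600) {
  model <- match.arg(model)
  backend <- match.arg(backend)
  hd <- hier_data(data)
  N <- length(hd$ids); P <- 5L
  dim <- 2L * P + N * P
  mid <- MODEL_IDS[[model]]
  if (backend == "advi") {
    vb <- cpp_hier_advi(mid, hd$off, hd$choices, hd$gain, hd$loss,
                        outcome_scale, as.integer(iters), as.double(seed), lr)
    m <- vb$mean
    sdev <- exp(vb$log_sd)
    withr::with_seed(seed, {
      z <- matrix(rnorm(draws * dim), nrow = draws)
    })
    dr <- sweep(sweep(z, 2, sdev, "*"), 2, m, "+")
    diag_info <- list(code = 0L)
  } else {
    hmc <- cpp_hier_hmc(mid, hd$off, hd$choices, hd$gain, hd$loss,
                        outcome_scale, as.integer(warmup), as.integer(draws),
                        as.double(seed), 30L)
    dr <- hmc$draws
    diag_info <- list(code = if (hmc$accept_rate > 0.5) 0L else 1L,
                      accept_rate = hmc$accept_rate,
                      step_size = hmc$step_size)
    vb <- list(mean = colMeans(dr), log_sd = log(apply(dr, 2, stats::sd)),
               elbo_trace = numeric(0))
    m <- vb$mean
    sdev <- exp(vb$log_sd)
  }
  ll <- cpp_hier_pointwise(mid, dr, hd$off, hd$choices, hd$gain, hd$loss,
                           outcome_scale)
  # per-subject posterior-mean natural parameters -> logL-hat for AIC/BIC
  subj_par <- matrix(0, N, P)
  for (i in seq_len(N)) {
    unc <- dr[, 1:P, drop = FALSE] +
      exp(dr[, (P + 1):(2 * P), drop = FALSE]) *
        dr[, (2 * P + (i - 1) * P + 1):(2 * P + i * P), drop = FALSE]
    nat <- t(apply(unc, 1, function(x) hier_transform(model, x)))
    subj_par[i, ] <- colMeans(nat)
  }
  loglik_hat <- 0
  for (i in seq_len(N)) {
    idx <- (hd$off[i] + 1):hd$off[i + 1]
    loglik_hat <- loglik_hat +
      as.numeric(cpp_loglik(mid, subj_par[i, ], hd$choices[idx], hd$gain[idx],
                            hd$loss[idx], outcome_scale, FALSE))
  }
  n_obs <- length(hd$choices)
  k <- P * N
  w <- waic_from_pointwise(ll)
  elbo <- vb$elbo_trace
  elbo <- elbo[elbo != 0]
  n_tail <- max(1, length(elbo) %/% 5)
  elbo_drift <- if (length(elbo) >= 2 * n_tail) {
    mean(utils::tail(elbo, n_tail)) -
      mean(utils::head(utils::tail(elbo, 2 * n_tail), n_tail))
  } else NA_real_
  diag_info$elbo_trace <- elbo
  diag_info$elbo_drift <- elbo_drift
  structure(
    list(model = model, param_names = hier_param_names(model),
         subject_ids = hd$ids, n_subjects = N, n_obs = n_obs, k = k,
         vb_mean = m, vb_sd = sdev, draws = dr, subject_means = subj_par,
         pointwise_ll = ll, lppd = w$lppd, p_waic = w$p_waic, waic = w$waic,
         waic_se = w$waic_se, loglik_hat = loglik_hat,
         aic = -2 * loglik_hat + 2 * k,
         bic = -2 * loglik_hat + k * log(n_obs),
         convergence = diag_info,
         config = list(draws = draws, seed = seed,
                       outcome_scale = outcome_scale, iters = iters, lr = lr,
                       backend = backend,
                       k_convention = "parameters_per_subject * n_subjects",
                       n_convention = "total_trials",
                       point_estimate = "per-subject posterior mean")),
    class = "igt_fit"
  )
}

waic_from_pointwise <- function(ll) {
  if (nrow(ll) < 2) stop("WAIC needs at least 2 posterior draws", call. = FALSE)
  S <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx)))) # log mean exp, stable
  p_i <- apply(ll, 2, var)
  waic_i <- -2 * (lppd_i - p_i)
  list(lppd = sum(lppd_i), p_waic = sum(p_i), waic = sum(waic_i),
       waic_se = sqrt(length(waic_i) * var(waic_i)))
}

#' Information criteria for a fit
#'
#' `AIC = -2 logL + 2k`, `BIC = -2 logL + k log n`,
#' `WAIC = -2 (lppd - p_waic)` with `lppd = sum_i log mean_s exp(ll_is)` and
#' `p_waic = sum_i var_s(ll_is)`, and
#' `WAIC_SE = sqrt(n * var(pointwise WAIC contributions))`.
#'
#' @param x an `igt_fit`, or a scalar point log-likelihood.
#' @param ... passed on to methods.
#' @return A one-row tibble with `AIC`, `BIC`, `WAIC`, `WAIC_SE`, `lppd`,
#'   `p_waic`, `k`, `n` (WAIC columns are `NA` when no pointwise matrix is
#'   available).
#' @export
information_criteria <- function(x, ...) UseMethod("information_criteria")

#' @rdname information_criteria
#' @param k parameter count used for AIC/BIC.
#' @param n observation count used for BIC.
#' @param ll_pointwise optional S x n matrix of pointwise log-likelihood
#'   draws for WAIC.
#' @export
information_criteria.numeric <- function(x, k, n, ll_pointwise = NULL, ...) {
  w <- if (is.null(ll_pointwise)) {
    list(lppd = NA_real_, p_waic = NA_real_, waic = NA_real_,
         waic_se = NA_real_)
  } else {
    waic_from_pointwise(ll_pointwise)
  }
  tibble(AIC = -2 * x + 2 * k, BIC = -2 * x + k * log(n), WAIC = w$waic,
         WAIC_SE = w$waic_se, lppd = w$lppd, p_waic = w$p_waic, k = k, n = n)
}

#' @rdname information_criteria
#' @export
information_criteria.igt_fit <- function(x, ...) {
  tibble(AIC = x$aic, BIC = x$bic, WAIC = x$waic, WAIC_SE = x$waic_se,
         lppd = x$lppd, p_waic = x$p_waic, k = x$k, n = x$n_obs)
}

#' Compare two fitted models
#'
#' One model is declared superior only when its AIC, BIC and WAIC are all
#' lower *and* the WAIC gap exceeds the larger of the two WAIC standard
#' errors (`|WAIC_A - WAIC_B| > max(SE_A, SE_B)`); anything else —
#' disagreeing criteria or a gap within the standard error — is
#' `inconclusive`.
#'
#' @param fit_a,fit_b `igt_fit` objects (or stubs with `aic`, `bic`, `waic`,
#'   `waic_se`, `n_obs`) fitted to the same dataset.
#' @return A one-row tibble with both models' criteria, `delta_waic`,
#'   `max_waic_se` and `verdict` in `A_superior` / `B_superior` /
#'   `inconclusive`.
#' @export
compare_models <- function(fit_a, fit_b) {
  need <- c("aic", "bic", "waic", "waic_se", "n_obs")
  for (f in list(fit_a, fit_b)) {
    if (!all(need %in% names(f))) {
      stop("fits must carry aic, bic, waic, waic_se and n_obs", call. = FALSE)
    }
  }
  if (!isTRUE(all.equal(fit_a$n_obs, fit_b$n_obs))) {
    stop("fits must be on the same dataset (observation counts differ)",
         call. = FALSE)
  }
  dwaic <- fit_a$waic - fit_b$waic
  mse <- max(fit_a$waic_se, fit_b$waic_se)
  a_wins <- fit_a$aic < fit_b$aic && fit_a$bic < fit_b$bic &&
    fit_a$waic < fit_b$waic && abs(dwaic) > mse
  b_wins <- fit_b$aic < fit_a$aic && fit_b$bic < fit_a$bic &&
    fit_b$waic < fit_a$waic && abs(dwaic) > mse
  verdict <- if (a_wins) "A_superior" else if (b_wins) "B_superior" else
    "inconclusive"
  tibble(model_a = fit_a$model %||% "A", model_b = fit_b$model %||% "B",
         aic_a = fit_a$aic, aic_b = fit_b$aic, bic_a = fit_a$bic,
         bic_b = fit_b$bic, waic_a = fit_a$waic, waic_b = fit_b$waic,
         waic_se_a = fit_a$waic_se, waic_se_b = fit_b$waic_se,
         delta_waic = dwaic, max_waic_se = mse, verdict = verdict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimal fit stub for comparison logic
#'
#' Builds an object accepted by [compare_models()] from bare criterion
#' values, useful for reasoning about the decision rule itself.
#'
#' @param aic,bic,waic,waic_se,n_obs criterion values.
#' @param model label.
#' @return A list mimicking the comparison-relevant slots of an `igt_fit`.
#' @export
fit_stub <- function(aic, bic, waic, waic_se, n_obs = 100, model = "stub") {
  list(model = model, aic = aic, bic = bic, waic = waic, waic_se = waic_se,
       n_obs = n_obs)
}

#' @export
print.igt_fit <- function(x, ...) {
  cat("<igt_fit> hierarchical", toupper(x$model), "-", x$n_subjects,
      "subjects,", x$n_obs, "trials\n")
  cat(sprintf("  AIC %.1f  BIC %.1f  WAIC %.1f (SE %.1f)\n", x$aic, x$bic,
              x$waic, x$waic_se))
  invisible(x)
}

#' @export
#' @method tidy igt_fit
#' @rdname fit_hierarchical
#' @param x,conf_level for `tidy()`: the fit and credible level. `estimate`
#'   is the posterior mean of the natural-scale group mean (the average of
#'   the subject-level parameters), with quantile credible bounds;
#'   `group_median` is the posterior mean of the transformed group location
#'   `T(mu)`; `mu`/`sigma` summarize the unconstrained group-level
#'   distribution.
#' @param ... unused.
tidy.igt_fit <- function(x, conf_level = 0.95, ...) {
  P <- length(x$param_names)
  N <- x$n_subjects
  a <- (1 - conf_level) / 2
  out <- vector("list", P)
  for (p in seq_len(P)) {
    sig <- exp(x$draws[, P + p])
    nat_subj <- vapply(seq_len(N), function(i) {
      hier_transform_one(x$model, p,
                         x$draws[, p] + sig * x$draws[, 2 * P + (i - 1) * P + p])
    }, numeric(nrow(x$draws)))
    gm <- rowMeans(nat_subj)
    out[[p]] <- tibble(
      parameter = x$param_names[p],
      estimate = mean(gm), std.error = stats::sd(gm),
      conf.low = as.numeric(stats::quantile(gm, a)),
      conf.high = as.numeric(stats::quantile(gm, 1 - a)),
      group_median = mean(hier_transform_one(x$model, p, x$draws[, p])),
      mu = mean(x$draws[, p]), sigma = mean(sig)
    )
  }
  dplyr::bind_rows(out)
}

#' @export
glance.igt_fit <- function(x, ...) {
  tibble(model = x$model, n_subjects = x$n_subjects, n_obs = x$n_obs,
         AIC = x$aic, BIC = x$bic, WAIC = x$waic, WAIC_SE = x$waic_se,
         lppd = x$lppd, p_waic = x$p_waic, logLik = x$loglik_hat,
         converged = x$convergence$code == 0)
}
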