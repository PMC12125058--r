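# Simulated cohorts with controlled pattern composition: the test-bed used in
# place of behavioural data throughout the package.

default_group_means <- function(model) {
  if (model == "orl") {
    c(A_rew = 0.3, A_pun = 0.1, K_prime = 1, beta_F = 1.5, beta_P = 1)
  } else {
    c(theta = 0.5, delta = 0.8, alpha = 0.3, phi = 0.5, beta = 1)
  }
}

# pattern-targeted presets for the simulated GOB / BOG-style datasets:
# GOB-leaning means are the defaults; BOG-leaning ORL switches off punishment
# learning (losses barely update EV, so the high-gain bad decks stay
# attractive) and adds perseverance, while low-sensitivity VSE contributes
# IOF-style win-frequency behaviour.
preset_means <- function(preset, model) {
  if (preset == "bog") {
    if (model == "orl") {
      c(A_rew = 0.3, A_pun = 0.05, K_prime = 1, beta_F = 0, beta_P = 2)
    } else {
      c(theta = 0.1, delta = 0.8, alpha = 0.3, phi = 0.5, beta = 1)
    }
  } else if (preset == "gob" && model == "vse") {
    c(theta = 0.9, delta = 0.8, alpha = 0.2, phi = 0, beta = 1)
  } else {
    default_group_means(model)
  }
}

#' Specify a simulated cohort
#'
#' Describes a cohort of simulated IGT subjects: how many, the generating
#' model mix (half ORL, half VSE by default, mirroring the simulated
#' reference datasets), the group-level parameter distributions, and an
#' optional restricted-pattern filter enforced by rejection sampling.
#' Subject-level parameters are drawn from normal distributions on the
#' unconstrained (probit) scale centred on the group means with SD
#' `sd_unconstrained`.
#'
#' The presets reproduce the construction of the pattern-curated simulated
#' datasets: `"gob"` keeps only restricted-GOB/IOF subjects (so no
#' Bad-Over-Good instance can occur) and `"bog"` only restricted-BOG/IOF
#' subjects, both with 20 subjects, half per model.
#'
#' @param n_subjects cohort size.
#' @param model_mix named fractions of subjects per generating model; must
#'   sum to 1.
#' @param orl_means,vse_means named natural-scale group means (defaults are
#'   preset-dependent).
#' @param sd_unconstrained group-level SD on the unconstrained scale.
#' @param include_patterns,restricted labels a subject must have (empty =
#'   no constraint).
#' @param exclude_patterns restricted labels that force rejection; disjoint
#'   from `include_patterns`.
#' @param n_trials trials per subject.
#' @param outcome_scale model outcome scale.
#' @param max_attempts total rejection-sampling attempts before failing.
#' @param preset `"none"`, `"gob"` or `"bog"`.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(preset = "gob")
#' @export
cohort_spec <- function(n_subjects = 20,
                        model_mix = c(orl = 0.5, vse = 0.5),
                        orl_means = NULL, vse_means = NULL,
                        sd_unconstrained = 0.3,
                        include_patterns = character(),
                        exclude_patterns = character(),
                        n_trials = 100, outcome_scale = 0.01,
                        max_attempts = 400 * max(n_subjects, 1),
                        preset = c("none", "gob", "bog")) {
  preset <- match.arg(preset)
  if (preset == "gob" && !length(include_patterns)) {
    include_patterns <- c("GOB", "IOF")
  }
  if (preset == "bog" && !length(include_patterns)) {
    include_patterns <- c("BOG", "IOF")
  }
  if (is.null(orl_means)) orl_means <- preset_means(preset, "orl")
  if (is.null(vse_means)) vse_means <- preset_means(preset, "vse")
  if (abs(sum(model_mix) - 1) > 1e-8) {
    stop("`model_mix` fractions must sum to 1", call. = FALSE)
  }
  if (!all(names(model_mix) %in% c("orl", "vse"))) {
    stop("`model_mix` names must be 'orl' and/or 'vse'", call. = FALSE)
  }
  if (length(intersect(include_patterns, exclude_patterns))) {
    stop("`include_patterns` and `exclude_patterns` must be disjoint",
         call. = FALSE)
  }
  bad <- setdiff(c(include_patterns, exclude_patterns), RESTRICTED_LABELS)
  if (length(bad)) {
    stop("unknown restricted label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), model_mix = model_mix,
         orl_means = orl_means, vse_means = vse_means,
         sd_unconstrained = sd_unconstrained,
         include_patterns = include_patterns,
         exclude_patterns = exclude_patterns,
         n_trials = as.integer(n_trials), outcome_scale = outcome_scale,
         max_attempts = max_attempts, preset = preset),
    class = "cohort_spec"
  )
}

params_from_natural <- function(model, v) {
  if (model == "orl") do.call(orl_params, as.list(unname(v)))
  else do.call(vse_params, as.list(unname(v)))
}

draw_subject_params <- function(model, means, sd_unc) {
  mu <- hier_untransform(model, as.numeric(means))
  unc <- mu + rnorm(5, 0, sd_unc)
  hier_transform(model, unc)
}

#' Generate a simulated cohort
#'
#' Simulates subjects as specified, classifies each with the restricted
#' definition, and rejection-samples until the pattern constraints are met
#' for `n_subjects` subjects (or `max_attempts` is exhausted). All
#' randomness flows from `seed`; the metadata records each accepted
#' subject's generating model, parameters and simulation seed, which
#' suffices to replay its trials exactly via [simulate_agent()].
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return An object of class `igt_cohort`: list with `data` (trial tibble),
#'   `meta` (one row per subject: model, natural-scale parameters, labels,
#'   simulation seed), `spec` and `seed`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 4), seed = 1)
#' summarise_patterns(classify_subjects(coh$data))
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (n == 0) {
    return(structure(list(data = tibble(subjID = character(),
                                        trial = integer(),
                                        deck = character(), gain = numeric(),
                                        loss = numeric()),
                          meta = tibble(), spec = spec, seed = seed),
                     class = "igt_cohort"))
  }
  frac_orl <- if ("orl" %in% names(spec$model_mix)) {
    spec$model_mix[["orl"]]
  } else 0
  n_orl <- round(n * frac_orl)
  models <- c(rep("orl", n_orl), rep("vse", n - n_orl))
  data_rows <- vector("list", n)
  meta_rows <- vector("list", n)
  withr::with_seed(seed, {
    attempts <- 0
    for (i in seq_len(n)) {
      model <- models[i]
      means <- if (model == "orl") spec$orl_means else spec$vse_means
      repeat {
        attempts <- attempts + 1
        if (attempts > spec$max_attempts) {
          stop("max_attempts exhausted while generating a subject ",
               "satisfying include={",
               paste(spec$include_patterns, collapse = ","), "} exclude={",
               paste(spec$exclude_patterns, collapse = ","), "}",
               call. = FALSE)
        }
        nat <- draw_subject_params(model, means, spec$sd_unconstrained)
        sim_seed <- sample.int(.Machine$integer.max, 1)
        id <- sprintf("S%03d", i)
        params <- params_from_natural(model, nat)
        trials <- simulate_agent(params, n_trials = spec$n_trials,
                                 seed = sim_seed,
                                 outcome_scale = spec$outcome_scale,
                                 subjID = id)
        lab <- classify_restricted(count_choices(trials),
                                   require_100 = spec$n_trials == 100)
        ok <- !(lab$restricted %in% spec$exclude_patterns) &&
          (!length(spec$include_patterns) ||
             lab$restricted %in% spec$include_patterns)
        if (ok) {
          data_rows[[i]] <- trials
          meta_rows[[i]] <- dplyr::bind_cols(
            tibble(subjID = id, model = model, sim_seed = sim_seed,
                   broad = lab$broad, restricted = lab$restricted),
            tibble::as_tibble_row(stats::setNames(
              as.numeric(nat), hier_param_names(model)))
          )
          break
        }
      }
    }
  })
  structure(
    list(data = dplyr::bind_rows(data_rows),
         meta = dplyr::bind_rows(meta_rows), spec = spec, seed = seed,
         attempts = attempts),
    class = "igt_cohort"
  )
}

#' @export
print.igt_cohort <- function(x, ...) {
  cat("<igt_cohort>", nrow(x$meta), "subjects,",
      nrow(x$data), "trials (preset", x$spec$preset, ")\n")
  invisible(x)
}

#' Write / read trial data
#'
#' `"long_csv"` uses columns `subjID`, `trial`, `deck` (A-D), `gain`, `loss`
#' (loss as a non-negative magnitude). `"wide_manylabs"` uses one row per
#' subject with three 100-column blocks (`choice_1..`, `wins_1..`,
#' `losses_1..`), decks coded 1-4 and losses written as negative values; on
#' read, losses given as magnitudes are also accepted (autodetected, with a
#' message).
#'
#' @param x an `igt_cohort` or a trial tibble.
#' @param path file path.
#' @param format `"long_csv"` or `"wide_manylabs"`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the trial tibble.
#' @export
write_cohort <- function(x, path, format = c("long_csv", "wide_manylabs")) {
  format <- match.arg(format)
  data <- if (inherits(x, "igt_cohort")) x$data else check_trials(x)
  if (format == "long_csv") {
    readr::write_csv(data, path)
  } else {
    wide <- data |>
      dplyr::arrange(.data$subjID, .data$trial) |>
      dplyr::group_by(.data$subjID) |>
      dplyr::summarise(
        choice = list(match(.data$deck, DECKS)),
        wins = list(.data$gain), losses = list(-.data$loss),
        .groups = "drop"
      )
    nt <- lengths(wide$choice)
    if (length(unique(nt)) != 1) {
      stop("wide format requires equal trial counts per subject",
           call. = FALSE)
    }
    m <- cbind(do.call(rbind, wide$choice), do.call(rbind, wide$wins),
               do.call(rbind, wide$losses))
    colnames(m) <- c(paste0("choice_", seq_len(nt[1])),
                     paste0("wins_", seq_len(nt[1])),
                     paste0("losses_", seq_len(nt[1])))
    readr::write_csv(dplyr::bind_cols(tibble(subjID = wide$subjID),
                                      as_tibble(m)), path)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, format = c("long_csv", "wide_manylabs")) {
  format <- match.arg(format)
  if (format == "long_csv") {
    data <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              subjID = readr::col_character(),
                              trial = readr::col_integer(),
                              deck = readr::col_character(),
                              gain = readr::col_double(),
                              loss = readr::col_double()))
    bad <- which(data$gain < 0 | data$loss < 0 | !data$deck %in% DECKS)
    if (length(bad)) {
      stop("malformed trial row(s) at line(s): ",
           paste(head(bad + 1, 5), collapse = ", "),
           " (negative gain/loss magnitude or unknown deck)", call. = FALSE)
    }
    return(data)
  }
  wide <- readr::read_csv(path, show_col_types = FALSE)
  ch_cols <- grep("^choice_", names(wide))
  wn_cols <- grep("^wins_", names(wide))
  ls_cols <- grep("^losses_", names(wide))
  nt <- length(ch_cols)
  stopifnot(nt > 0, length(wn_cols) == nt, length(ls_cols) == nt)
  losses <- as.matrix(wide[, ls_cols])
  if (any(losses < 0)) {
    message("wide losses detected as negative values; using magnitudes")
    losses <- -losses
  }
  if (any(losses < 0)) {
    stop("wide losses mix signs; expected all-negative or all-magnitude",
         call. = FALSE)
  }
  subj <- if ("subjID" %in% names(wide)) as.character(wide$subjID) else
    sprintf("S%03d", seq_len(nrow(wide)))
  purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    tibble(subjID = subj[i], trial = seq_len(nt),
           deck = DECKS[as.integer(unlist(wide[i, ch_cols]))],
           gain = as.numeric(unlist(wide[i, wn_cols])),
           loss = as.numeric(losses[i, ]))
  })
}
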