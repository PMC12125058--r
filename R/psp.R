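# Parameter space partitioning: grid the parameter space, simulate one
# 100-trial run per parameter set, classify, aggregate pattern proportions.

default_bounds <- function(model) {
  switch(model,
    orl = tibble(parameter = c("A_rew", "A_pun", "K_prime", "beta_F", "beta_P"),
                 min = c(0, 0, 0, -5, -5), max = c(1, 1, 5, 5, 5)),
    vse = tibble(parameter = c("theta", "delta", "alpha", "phi", "beta"),
                 min = c(0, 0, 0, -5, 0), max = c(1, 1, 1, 5, 5)),
    ev = tibble(parameter = c("loss_aversion", "rate", "cons"),
                min = c(0, 0, -5), max = c(1, 1, 5)),
    pvl = tibble(parameter = c("shape", "loss_aversion", "rate", "cons"),
                 min = c(0, 0, 0, 0), max = c(1, 5, 1, 5)),
    evpu = tibble(parameter = c("shape", "loss_aversion", "rate", "cons"),
                  min = c(0, 0, 0, -5), max = c(1, 5, 1, 5)),
    pvldelta = tibble(parameter = c("shape", "loss_aversion", "rate", "cons"),
                      min = c(0, 0, 0, 0), max = c(1, 5, 1, 5))
  )
}

#' Define a PSP parameter grid
#'
#' Equally spaced, endpoint-inclusive grid over each parameter's range, with
#' the same number of points per parameter; the Cartesian product is streamed
#' by lexicographic index (first listed parameter slowest), never
#' materialized. Unbounded parameters (the ORL frequency and perseverance
#' weights, the VSE exploration bonus) default to the truncation bounds
#' `[-5, 5]` on the scaled-outcome convention.
#'
#' @param model one of `"orl"`, `"vse"`, `"ev"`, `"pvl"`, `"evpu"`,
#'   `"pvldelta"`.
#' @param points grid points per parameter (a single point sits at the range
#'   midpoint).
#' @param bounds optional tibble with columns `parameter`, `min`, `max`
#'   overriding the defaults; all bounds must be finite.
#' @return An object of class `psp_grid` (a tibble of per-parameter bounds
#'   with the model and point count attached).
#' @examples
#' n_param_sets(psp_grid("orl", points = 60)) # 777,600,000
#' @export
psp_grid <- function(model = c("orl", "vse", "ev", "pvl", "evpu", "pvldelta"),
                     points = 10, bounds = NULL) {
  model <- match.arg(model)
  if (points < 1) stop("`points` must be >= 1", call. = FALSE)
  b <- if (is.null(bounds)) default_bounds(model) else as_tibble(bounds)
  stopifnot(all(c("parameter", "min", "max") %in% names(b)))
  if (any(!is.finite(b$min)) || any(!is.finite(b$max))) {
    stop("unbounded parameter without finite truncation bounds", call. = FALSE)
  }
  if (any(b$min >= b$max)) stop("each `min` must be < `max`", call. = FALSE)
  structure(b, class = c("psp_grid", class(b)),
            model = model, points = as.integer(points))
}

#' @rdname psp_grid
#' @export
n_param_sets <- function(grid) {
  stopifnot(inherits(grid, "psp_grid"))
  as.numeric(attr(grid, "points"))^nrow(grid)
}

#' Parameter values along one grid axis
#' @param grid a [psp_grid()].
#' @param parameter parameter name.
#' @return Numeric vector of the grid points for that parameter.
#' @export
grid_points <- function(grid, parameter) {
  row <- grid[grid$parameter == parameter, ]
  if (nrow(row) != 1) stop("unknown parameter ", parameter, call. = FALSE)
  k <- attr(grid, "points")
  if (k == 1) (row$min + row$max) / 2 else seq(row$min, row$max, length.out = k)
}

#' Run a parameter space partitioning study
#'
#' For every parameter set on the grid, simulates one IGT session (a
#' 100-trial subject by default) with a per-set seed derived deterministically
#' from the global seed and the set index, classifies the resulting deck
#' counts, and aggregates pattern proportions. Aggregation is commutative
#' counting, so results are identical for any chunking of the grid.
#'
#' @param grid a [psp_grid()].
#' @param seed global seed; per-run seeds are mixed from `(seed, set index,
#'   replicate)`.
#' @param n_trials trials per simulated session.
#' @param outcome_scale multiplier applied to raw points before the model
#'   equations.
#' @param definition `"both"` (default), `"broad"`, or `"restricted"`.
#' @param schedule_policy loss-position policy for the per-run schedules.
#' @param replicates simulated sessions per parameter set (1, as in the
#'   one-run-per-set design; more reduces classification noise).
#' @param chunk_size parameter sets simulated per C++ call (memory knob).
#' @param keep_labels retain the per-set broad labels (only sensible for
#'   modest grids).
#' @return An object of class `psp_result`: list with `proportions` (tibble
#'   `definition`, `label`, `n`, `proportion`), `n_sets`, `n_runs`, `model`,
#'   `grid`, `seed`, and optionally `labels`.
#' @examples
#' run_psp(psp_grid("vse", points = 3), seed = 1)$proportions
#' @export
run_psp <- function(grid, seed = 1, n_trials = 100, outcome_scale = 0.01,
                    definition = c("both", "broad", "restricted"),
                    schedule_policy = c("shuffled_block", "fixed_canonical"),
                    replicates = 1, chunk_size = 50000, keep_labels = FALSE) {
  stopifnot(inherits(grid, "psp_grid"))
  definition <- match.arg(definition)
  schedule_policy <- match.arg(schedule_policy)
  model <- attr(grid, "model")
  if (definition != "broad" && n_trials != 100) {
    stop("the restricted definition is defined on 100-trial sessions",
         call. = FALSE)
  }
  n_sets <- n_param_sets(grid)
  broad_n <- stats::setNames(numeric(5), BROAD_LABELS)
  restr_n <- stats::setNames(numeric(4), RESTRICTED_LABELS)
  labels <- if (keep_labels) character(0) else NULL
  canonical <- schedule_policy == "fixed_canonical"
  for (r in seq_len(replicates)) {
    from <- 0
    while (from < n_sets) {
      to <- min(from + chunk_size, n_sets)
      counts <- cpp_psp_counts(MODEL_IDS[[model]], grid$min, grid$max,
                               attr(grid, "points"), from, to,
                               as.integer(n_trials), as.double(seed),
                               outcome_scale, canonical, as.integer(r))
      cc <- tibble(subjID = sprintf("set%d", seq_len(nrow(counts))),
                   nA = counts[, 1], nB = counts[, 2], nC = counts[, 3],
                   nD = counts[, 4])
      cls <- if (definition == "broad") {
        classify_broad(cc)
      } else {
        classify_restricted(cc)
      }
      tb <- table(factor(cls$broad, levels = BROAD_LABELS))
      broad_n <- broad_n + as.numeric(tb)
      if (definition != "broad") {
        tr <- table(factor(cls$restricted, levels = RESTRICTED_LABELS))
        restr_n <- restr_n + as.numeric(tr)
      }
      if (keep_labels) labels <- c(labels, cls$broad)
      from <- to
    }
  }
  n_runs <- n_sets * replicates
  props <- list(tibble(definition = "broad", label = BROAD_LABELS,
                       n = broad_n, proportion = broad_n / n_runs))
  if (definition != "broad") {
    props$raw <- tibble(definition = "restricted_raw",
                        label = RESTRICTED_LABELS, n = restr_n,
                        proportion = restr_n / n_runs)
    qual <- restr_n[c("GOB", "BOG", "IOF")]
    if (sum(qual) > 0) {
      props$renorm <- tibble(definition = "restricted_renorm",
                             label = names(qual), n = qual,
                             proportion = qual / sum(qual))
    }
  }
  structure(
    list(proportions = dplyr::bind_rows(props), n_sets = n_sets,
         n_runs = n_runs, model = model, grid = grid, seed = seed,
         definition = definition, n_trials = n_trials,
         outcome_scale = outcome_scale, schedule_policy = schedule_policy,
         labels = labels),
    class = "psp_result"
  )
}

#' @export
print.psp_result <- function(x, ...) {
  cat("<psp_result> model", x$model, "-", format(x$n_runs, big.mark = ","),
      "runs\n")
  print(x$proportions)
  invisible(x)
}

#' Compare the parameter spaces of several models
#'
#' Builds the models-by-labels proportion matrix from a list of PSP results.
#'
#' @param results list of [run_psp()] results.
#' @param definition which proportion block to compare (must be present in
#'   every result).
#' @return A tibble with one row per label and one column per model.
#' @export
compare_parameter_spaces <- function(results, definition = "broad") {
  if (length(results) == 0) stop("no PSP results supplied", call. = FALSE)
  if (inherits(results, "psp_result")) results <- list(results)
  cols <- lapply(results, function(r) {
    stopifnot(inherits(r, "psp_result"))
    p <- r$proportions[r$proportions$definition == definition, ]
    if (nrow(p) == 0) {
      stop("result for model ", r$model, " lacks the '", definition,
           "' definition", call. = FALSE)
    }
    stats::setNames(p$proportion, p$label)
  })
  labs <- names(cols[[1]])
  if (!all(vapply(cols, function(x) identical(names(x), labs), logical(1)))) {
    stop("results use mismatched definitions", call. = FALSE)
  }
  out <- tibble(label = labs)
  for (i in seq_along(cols)) {
    nm <- results[[i]]$model
    if (nm %in% names(out)) nm <- paste0(nm, "_", i)
    out[[nm]] <- as.numeric(cols[[i]])
  }
  out
}
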