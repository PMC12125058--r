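# Choice-pattern classification (broad and restricted definitions) and
# sequential-exploration (SeqE) indices.

BROAD_LABELS <- c("GOB", "BOG", "IOF", "FOI", "Remaining")
RESTRICTED_LABELS <- c("GOB", "BOG", "IOF", "none")

#' Tally deck choices per subject
#'
#' @param data trial tibble with columns `subjID` and `deck` (A-D).
#' @return A tibble with one row per subject: `subjID`, `nA`..`nD`,
#'   `n_trials`.
#' @export
count_choices <- function(data) {
  if (nrow(data) == 0) stop("empty trial data", call. = FALSE)
  if (!all(data$deck %in% DECKS)) {
    stop("`deck` must contain only A, B, C, D", call. = FALSE)
  }
  data |>
    dplyr::count(.data$subjID, .data$deck) |>
    tidyr::pivot_wider(names_from = "deck", values_from = "n",
                       values_fill = 0L, names_prefix = "n") |>
    dplyr::bind_rows(tibble(subjID = character(), nA = integer(),
                            nB = integer(), nC = integer(), nD = integer())) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("nA", "nB", "nC", "nD")),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::mutate(n_trials = .data$nA + .data$nB + .data$nC + .data$nD) |>
    dplyr::select(dplyr::all_of(c("subjID", "nA", "nB", "nC", "nD",
                                  "n_trials")))
}

ensure_counts <- function(x) {
  if ("deck" %in% names(x) && !"nA" %in% names(x)) x <- count_choices(x)
  need <- c("nA", "nB", "nC", "nD")
  if (!all(need %in% names(x))) {
    stop("expected per-subject counts with columns nA..nD", call. = FALSE)
  }
  x
}

#' Broad choice-pattern classification
#'
#' Classifies deck-count profiles into Good-Over-Bad (GOB), Bad-Over-Good
#' (BOG), Infrequent-Over-Frequent (IOF), Frequent-Over-Infrequent (FOI) or
#' Remaining. The value contrast is `d_value = (nC+nD) - (nA+nB)` (good minus
#' bad decks) and the frequency contrast `d_freq = (nB+nD) - (nA+nC)`
#' (infrequent- minus frequent-loss decks). The dominant dimension decides
#' the label, with the value dimension taking priority on magnitude ties;
#' `Remaining` is returned only when both contrasts are exactly zero, so the
#' five labels are exhaustive and mutually exclusive.
#'
#' @param counts per-subject counts from [count_choices()] (raw trial data is
#'   accepted and tallied first).
#' @return The input tibble with columns `d_value`, `d_freq` and `broad`
#'   added.
#' @examples
#' classify_broad(tibble::tibble(subjID = "s", nA = 10, nB = 10,
#'                               nC = 40, nD = 40))
#' @export
classify_broad <- function(counts) {
  counts <- ensure_counts(counts)
  counts |>
    dplyr::mutate(
      d_value = (.data$nC + .data$nD) - (.data$nA + .data$nB),
      d_freq = (.data$nB + .data$nD) - (.data$nA + .data$nC),
      broad = dplyr::case_when(
        d_value == 0 & d_freq == 0 ~ "Remaining",
        abs(.data$d_value) >= abs(.data$d_freq) & .data$d_value > 0 ~ "GOB",
        abs(.data$d_value) >= abs(.data$d_freq) & .data$d_value < 0 ~ "BOG",
        .data$d_freq > 0 ~ "IOF",
        TRUE ~ "FOI"
      )
    )
}

#' Restricted choice-pattern classification
#'
#' Applies the threshold-based restricted definition on top of the broad
#' label: GOB requires `nC + nD >= 65`, BOG `nA + nB >= 65` and IOF
#' `nB + nD >= 65` (out of 100 trials); everything else — including every FOI
#' profile, which has no restricted category — maps to `"none"`.
#'
#' @inheritParams classify_broad
#' @param thresholds named pair-sum thresholds; override together with
#'   `require_100 = FALSE` to classify runs of other lengths.
#' @param require_100 error on subjects without exactly 100 trials (the
#'   thresholds are defined on 100-trial sessions).
#' @return The input tibble with a `restricted` column added.
#' @export
classify_restricted <- function(counts,
                                thresholds = c(GOB = 65, BOG = 65, IOF = 65),
                                require_100 = TRUE) {
  counts <- classify_broad(ensure_counts(counts))
  n <- counts$nA + counts$nB + counts$nC + counts$nD
  if (require_100 && any(n != 100)) {
    stop("restricted classification is defined on 100-trial sessions; ",
         "override `thresholds` and set `require_100 = FALSE` otherwise",
         call. = FALSE)
  }
  counts |>
    dplyr::mutate(
      restricted = dplyr::case_when(
        .data$broad == "GOB" & .data$nC + .data$nD >= thresholds[["GOB"]] ~ "GOB",
        .data$broad == "BOG" & .data$nA + .data$nB >= thresholds[["BOG"]] ~ "BOG",
        .data$broad == "IOF" & .data$nB + .data$nD >= thresholds[["IOF"]] ~ "IOF",
        TRUE ~ "none"
      )
    )
}

count_distinct_runs <- function(ch, w, sliding = TRUE) {
  if (is.character(ch)) ch <- match(ch, DECKS)
  n <- length(ch)
  if (sliding) {
    if (n < w) return(0L)
    wins <- embed(ch, w)
    sum(apply(wins, 1, function(r) length(unique(r)) == w))
  } else {
    k <- n %/% w
    if (k == 0) return(0L)
    idx <- matrix(ch[seq_len(k * w)], nrow = w)
    sum(apply(idx, 2, function(r) length(unique(r)) == w))
  }
}

#' Sequential-exploration (SeqE) indices
#'
#' Directed-exploration counts per subject: `DE3` is the number of sliding
#' 3-trial windows containing three distinct decks (over `n - 2` windows),
#' `DE4` the number of sliding 4-trial windows with four distinct decks, and
#' `DE4F` the number of distinct-4 chunks when the sequence is partitioned
#' into `floor(n/4)` non-overlapping chunks of four (25 chunks for a
#' 100-trial session).
#'
#' @param data trial tibble with `subjID`, `trial`, `deck`.
#' @return A tibble with one row per subject: `subjID`, `DE3`, `DE4`, `DE4F`.
#' @export
seqe_indices <- function(data) {
  if (!all(data$deck %in% DECKS)) {
    stop("`deck` must contain only A, B, C, D", call. = FALSE)
  }
  data |>
    dplyr::arrange(.data$subjID, .data$trial) |>
    dplyr::group_by(.data$subjID) |>
    dplyr::summarise(
      DE3 = {
        if (dplyr::n() < 4) stop("SeqE indices need at least 4 trials",
                                 call. = FALSE)
        count_distinct_runs(.data$deck, 3L)
      },
      DE4 = count_distinct_runs(.data$deck, 4L),
      DE4F = count_distinct_runs(.data$deck, 4L, sliding = FALSE),
      .groups = "drop"
    )
}

#' Full per-subject pattern table
#'
#' Convenience pipeline: deck counts, broad and restricted labels, and SeqE
#' indices for every subject in a trial tibble.
#'
#' @inheritParams seqe_indices
#' @param restricted also compute the restricted label (requires 100-trial
#'   subjects).
#' @return A tibble with one row per subject.
#' @export
classify_subjects <- function(data, restricted = TRUE) {
  counts <- count_choices(data)
  out <- if (restricted) classify_restricted(counts) else classify_broad(counts)
  dplyr::left_join(out, seqe_indices(data), by = "subjID")
}

#' Cohort-level pattern proportions
#'
#' @param classified output of [classify_subjects()] (or any tibble with
#'   `broad` / `restricted` columns).
#' @return A tibble with columns `definition`, `label`, `n`, `proportion`.
#' @export
summarise_patterns <- function(classified) {
  out <- list()
  if ("broad" %in% names(classified)) {
    tab <- table(factor(classified$broad, levels = BROAD_LABELS))
    out$broad <- tibble(definition = "broad", label = names(tab),
                        n = as.integer(tab),
                        proportion = as.numeric(tab) / nrow(classified))
  }
  if ("restricted" %in% names(classified)) {
    tab <- table(factor(classified$restricted, levels = RESTRICTED_LABELS))
    out$restricted <- tibble(definition = "restricted_raw", label = names(tab),
                             n = as.integer(tab),
                             proportion = as.numeric(tab) / nrow(classified))
    qual <- tab[c("GOB", "BOG", "IOF")]
    if (sum(qual) > 0) {
      out$renorm <- tibble(definition = "restricted_renorm",
                           label = names(qual), n = as.integer(qual),
                           proportion = as.numeric(qual) / sum(qual))
    }
  }
  dplyr::bind_rows(out)
}
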