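#' @importFrom rlang .data
NULL

# stereotyped defensive responses recognized per species; "none" codes a
# negative trial
.response_sets <- list(
  rat = c("none", "head_bobbing", "upward_rearing", "freezing"),
  mouse = c("none", "upward_rearing", "freezing", "running")
)

#' Valid response labels for a species
#'
#' Rats show head bobbing, upward rearing, and freezing; mice show upward
#' rearing, freezing, and running. `"none"` codes a trial without any
#' stereotyped response.
#'
#' @param species `"rat"` or `"mouse"`.
#' @return Character vector of valid `response_type` labels.
#' @export
response_types <- function(species = c("rat", "mouse")) {
  .response_sets[[match.arg(species)]]
}

.trial_cols <- c("animal_id", "species", "sex", "age", "zt_window",
                 "treatment", "genotype", "level_id", "magnitude",
                 "trial_index", "observer_id", "response_type")

.covariate_cols <- c("species", "sex", "age", "zt_window", "treatment",
                     "genotype")

validate_observer_scores <- function(scores, strict = TRUE) {
  scores <- tibble::as_tibble(scores)
  miss <- setdiff(.trial_cols, names(scores))
  if (length(miss)) {
    stop("trial table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_sp <- !scores$species %in% names(.response_sets)
  if (any(bad_sp)) {
    stop("unknown species: ", paste(unique(scores$species[bad_sp]),
                                    collapse = ", "), call. = FALSE)
  }
  ok <- mapply(function(sp, rt) is.na(rt) || rt %in% .response_sets[[sp]],
               scores$species, scores$response_type)
  if (any(!ok)) {
    msg <- sprintf(
      "%d score(s) with response labels invalid for their species (e.g. %s for %s)",
      sum(!ok), scores$response_type[!ok][1], scores$species[!ok][1])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    scores <- scores[ok, , drop = FALSE]
  }
  scores
}

#' Read / write tidy observer-scored trial tables
#'
#' The tidy trial CSV holds one row per (stimulus presentation, observer)
#' with columns `animal_id`, `species`, `sex`, `age`, `zt_window`,
#' `treatment`, `genotype`, `level_id`, `magnitude`, `trial_index`,
#' `observer_id`, `response_type`. Cross-species response labels (e.g.
#' `head_bobbing` scored for a mouse) indicate scoring-sheet errors and are
#' rejected in strict mode (the default) or dropped with a warning in
#' lenient mode.
#'
#' @param path CSV path.
#' @param strict Reject (`TRUE`) or warn-and-drop (`FALSE`) on
#'   species-invalid response labels.
#' @return A tibble of observer scores.
#' @export
read_trials <- function(path, strict = TRUE) {
  scores <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              animal_id = "c", level_id = "c",
                              observer_id = "c", response_type = "c",
                              trial_index = "i", magnitude = "d",
                              .default = "c"))
  validate_observer_scores(scores, strict = strict)
}

#' @param scores Observer-score tibble.
#' @rdname read_trials
#' @export
write_trials <- function(scores, path) {
  readr::write_csv(scores[, .trial_cols], path)
  invisible(path)
}

consensus_one <- function(labels, tie_policy) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_character_)
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  # tied top count: positive wins iff more observers saw *some* response
  # than saw none; among tied response labels the policy picks the label
  n_resp <- sum(labels != "none")
  n_none <- sum(labels == "none")
  if (n_resp <= n_none) return("none")
  top <- setdiff(top, "none")
  switch(tie_policy,
         lexicographic = sort(top)[1],
         stop("unknown tie policy: ", tie_policy, call. = FALSE))
}

#' Observer consensus per trial
#'
#' Collapses the per-observer scores to one consensus record per stimulus
#' presentation: majority vote on `response_type`; when the top label is
#' tied but a majority of observers saw some response, the trial is positive
#' and the label tie is broken by the configured deterministic policy
#' (default: lexicographically first among the tied response labels). A
#' trial is `positive` iff its consensus `response_type` is not `"none"` —
#' all stereotyped responses count, with no severity weighting.
#'
#' @param scores Observer-score tibble (see [read_trials()]).
#' @param n_observers Designed number of observers per trial (default 3).
#' @param strict If `TRUE` (default), error when a trial does not have
#'   exactly `n_observers` scores or a response label is invalid for the
#'   species; if `FALSE`, warn and keep going.
#' @param tie_policy Deterministic tie-break among tied response labels;
#'   only `"lexicographic"` is built in.
#' @return A tibble with one row per trial: the covariate columns plus
#'   consensus `response_type` and logical `positive`.
#' @export
consensus_trials <- function(scores, n_observers = 3, strict = TRUE,
                             tie_policy = "lexicographic") {
  scores <- validate_observer_scores(scores, strict = strict)
  key_cols <- c("animal_id", "trial_index")
  counts <- dplyr::count(scores, dplyr::across(dplyr::all_of(key_cols)))
  off <- counts$n != n_observers
  if (any(off)) {
    msg <- sprintf("%d trial(s) without exactly %d observer scores",
                   sum(off), n_observers)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out <- scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(key_cols, .covariate_cols, "level_id", "magnitude")))) |>
    dplyr::summarise(
      response_type = consensus_one(.data$response_type, tie_policy),
      .groups = "drop") |>
    dplyr::mutate(positive = !is.na(.data$response_type) &
                    .data$response_type != "none") |>
    dplyr::arrange(.data$animal_id, .data$trial_index)
  out
}

#' Per-animal per-contrast response frequencies
#'
#' The response frequency is the ratio of positive responses to total
#' stimuli applied for each contrast in each animal, with the total stimuli
#' per contrast fixed by design (the repetitions R). This is the unit of
#' observation for the psychometric model.
#'
#' @param records Consensus trial tibble from [consensus_trials()] (or any
#'   tibble with the covariate columns, `level_id`, `magnitude`,
#'   `trial_index`, and logical `positive`).
#' @return A tibble with one row per (animal, contrast level): covariates,
#'   `magnitude`, `n_positive`, `n_trials`, `frequency`.
#' @export
response_frequencies <- function(records) {
  records <- tibble::as_tibble(records)
  dup <- duplicated(records[, c("animal_id", "trial_index")])
  if (any(dup)) {
    stop("duplicate (animal_id, trial_index) keys in trial records",
         call. = FALSE)
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("animal_id", .covariate_cols, "level_id", "magnitude")))) |>
    dplyr::summarise(
      n_positive = sum(.data$positive),
      n_trials = dplyr::n(),
      frequency = .data$n_positive / .data$n_trials,
      .groups = "drop") |>
    dplyr::arrange(.data$animal_id, .data$magnitude)
}

#' Distribution of response types across contrast magnitudes
#'
#' For each contrast magnitude, the proportion of each stereotyped response
#' among the positive trials (head bobbing prevails at low/middle contrasts
#' in rats; freezing and running at high contrasts in mice). Magnitudes with
#' no positive trials get an all-zero row flagged `undefined = TRUE`.
#'
#' @param records Consensus trial tibble (see [response_frequencies()]).
#' @return Tibble with `magnitude`, `response_type`, `n`, `proportion`,
#'   `undefined`.
#' @export
response_type_distribution <- function(records) {
  records <- tibble::as_tibble(records)
  if (!nrow(records)) stop("no trial records", call. = FALSE)
  species <- unique(records$species)
  types <- setdiff(unique(unlist(.response_sets[species])), "none")
  pos <- dplyr::filter(records, .data$positive)
  counts <- tidyr::expand_grid(magnitude = sort(unique(records$magnitude)),
                               response_type = types) |>
    dplyr::left_join(
      dplyr::count(pos, .data$magnitude, .data$response_type),
      by = c("magnitude", "response_type")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  counts |>
    dplyr::group_by(.data$magnitude) |>
    dplyr::mutate(
      undefined = sum(.data$n) == 0,
      proportion = ifelse(.data$undefined, 0, .data$n / sum(.data$n))) |>
    dplyr::ungroup()
}

#' Write per-animal response frequencies to CSV
#'
#' @param freq Frequency tibble from [response_frequencies()].
#' @param path Output CSV path.
#' @export
write_frequencies <- function(freq, path) {
  readr::write_csv(freq, path)
  invisible(path)
}

#' @rdname write_frequencies
#' @export
read_frequencies <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    animal_id = "c", level_id = "c",
                    magnitude = "d", n_positive = "i", n_trials = "i",
                    frequency = "d", .default = "c"))
}
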