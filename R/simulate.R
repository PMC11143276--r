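#' Canonical session designs
#'
#' The contrast-level designs used by the assay: rats see 5 contrast levels
#' repeated 3 times (15 stimuli, within their ~30 min exploratory window),
#' mice 6 levels repeated 4 times (24 stimuli, ~45 min window). Magnitudes
#' are percent Michelson contrast magnitude, spanning from a contrast low
#' enough to elicit no response up to one that reliably does.
#'
#' @param species `"rat"` or `"mouse"`.
#' @return List with `magnitudes` (percent) and `reps`.
#' @export
ltcv_design <- function(species = c("rat", "mouse")) {
  switch(match.arg(species),
         rat = list(magnitudes = c(20, 40, 60, 80, 100), reps = 3L),
         mouse = list(magnitudes = c(15, 30, 45, 60, 75, 90), reps = 4L))
}

#' Ground-truth parameters for a simulated group
#'
#' Defines the psychometric ground truth of one cohort group: per-trial
#' responses are Bernoulli with probability
#' `plogis(logit_slope * (magnitude - animal_c50))`, where each animal's
#' threshold is drawn once as `Normal(true_c50, animal_c50_sd)` —
#' between-animal variability lives on the interpretable C50 (percent
#' contrast) scale. A `non_responder` group (e.g. cohorts lacking all
#' photoreceptor classes) never responds at any contrast.
#'
#' @param group Group label.
#' @param species `"rat"` or `"mouse"`; sets the session design unless
#'   `magnitudes`/`reps` are given.
#' @param true_c50 Group-level C50, percent contrast magnitude.
#' @param logit_slope Psychometric slope on the logit scale, per percent
#'   contrast; must be > 0 for responding groups.
#' @param animal_c50_sd Between-animal SD of the C50, percent.
#' @param n_animals Animals in the group.
#' @param magnitudes Contrast magnitudes (percent) of the session design.
#' @param reps Repetitions per contrast level (R).
#' @param non_responder If `TRUE`, response probability is 0 everywhere.
#' @param covariates Named list of covariate labels attached to every
#'   animal of the group (sex, age, zt_window, treatment, genotype).
#' @param observer_flip Per-observer probability of mis-labelling a trial
#'   (symmetric flip to a random other valid label); exercises the
#'   consensus step, default 0.
#' @return A list of class `ltcv_truth_params`.
#' @export
truth_params <- function(group, species = c("rat", "mouse"),
                         true_c50 = 50, logit_slope = 0.1,
                         animal_c50_sd = 5, n_animals = 7L,
                         magnitudes = NULL, reps = NULL,
                         non_responder = FALSE,
                         covariates = list(), observer_flip = 0) {
  species <- match.arg(species)
  design <- ltcv_design(species)
  if (is.null(magnitudes)) magnitudes <- design$magnitudes
  if (is.null(reps)) reps <- design$reps
  if (!non_responder && logit_slope <= 0) {
    stop("logit_slope must be > 0 for responding groups", call. = FALSE)
  }
  stopifnot(n_animals >= 1, reps >= 1, length(magnitudes) >= 1,
            observer_flip >= 0, observer_flip < 1)
  defaults <- list(sex = "male", age = "young", zt_window = "ZT4-6",
                   treatment = "none", genotype = "control")
  covariates <- utils::modifyList(defaults, covariates)
  structure(
    list(group = group, species = species, true_c50 = true_c50,
         logit_slope = logit_slope, animal_c50_sd = animal_c50_sd,
         n_animals = as.integer(n_animals), magnitudes = magnitudes,
         reps = as.integer(reps), non_responder = non_responder,
         covariates = covariates, observer_flip = observer_flip),
    class = "ltcv_truth_params"
  )
}

# contrast-dependent mixture over stereotyped responses, emulating the
# qualitative pattern of the assay: in rats head bobbing prevails at
# low/middle contrasts, freezing and rearing at high; in mice rearing
# prevails at low/middle, freezing and running at high
response_type_weights <- function(species, magnitude) {
  m <- magnitude / 100
  if (species == "rat") {
    c(head_bobbing = 1 - 0.8 * m, upward_rearing = 0.5 + 0.2 * m,
      freezing = 0.2 + 0.8 * m)
  } else {
    c(upward_rearing = 1 - 0.8 * m, freezing = 0.2 + 0.8 * m,
      running = 0.1 + 0.6 * m)
  }
}

sim_animal_trials <- function(params, animal_index, animal_c50) {
  mags <- params$magnitudes
  level_ids <- sprintf("L%d", seq_along(mags))
  # randomized R x C presentation order, as in the live session
  ord <- sample(rep(seq_along(mags), times = params$reps))
  n <- length(ord)
  p <- if (params$non_responder) rep(0, n) else {
    inv_logit(params$logit_slope * (mags[ord] - animal_c50))
  }
  positive <- stats::runif(n) < p
  rtype <- rep("none", n)
  for (i in which(positive)) {
    w <- response_type_weights(params$species, mags[ord[i]])
    rtype[i] <- sample(names(w), 1, prob = w)
  }
  tibble::tibble(
    animal_id = sprintf("%s_%02d", params$group, animal_index),
    species = params$species,
    sex = params$covariates$sex, age = params$covariates$age,
    zt_window = params$covariates$zt_window,
    treatment = params$covariates$treatment,
    genotype = params$covariates$genotype,
    group = params$group,
    level_id = level_ids[ord], magnitude = mags[ord],
    trial_index = seq_len(n), response_type = rtype
  )
}

#' Simulate one animal's session
#'
#' Draws the animal's C50 from the group distribution and generates its
#' full randomized session of Bernoulli trials with contrast-dependent
#' response types.
#'
#' @param params A [truth_params()] object.
#' @param animal_index Index of the animal within the group.
#' @param seed Integer seed; identical inputs reproduce the records
#'   bit-for-bit.
#' @return Tibble of consensus-level trial records (one row per stimulus)
#'   with a `positive` column.
#' @export
simulate_animal <- function(params, animal_index = 1L, seed = 1L) {
  stopifnot(inherits(params, "ltcv_truth_params"))
  withr::with_seed(as.integer(seed), {
    a_c50 <- stats::rnorm(1, params$true_c50, params$animal_c50_sd)
    out <- sim_animal_trials(params, animal_index, a_c50)
    dplyr::mutate(out, positive = .data$response_type != "none")
  })
}

flip_labels <- function(labels, species, flip_prob) {
  if (flip_prob <= 0) return(labels)
  valid <- .response_sets[[species]]
  hit <- stats::runif(length(labels)) < flip_prob
  labels[hit] <- vapply(labels[hit], function(l) {
    sample(setdiff(valid, l), 1)
  }, character(1))
  labels
}

#' Simulate a full cohort with observer scores and ground truth
#'
#' Generates a multi-group cohort: per-animal thresholds, randomized
#' sessions, Bernoulli responses, contrast-dependent response types, and
#' per-trial scores from `n_observers` masked observers (identical to the
#' true label unless `observer_flip > 0`). The output `scores` table is in
#' the tidy one-row-per-(trial, observer) format accepted by
#' [consensus_trials()], and `truth` carries every generating parameter —
#' including each animal's drawn C50 — for recovery scoring.
#'
#' @param groups A [truth_params()] object or list of them (distinct group
#'   labels).
#' @param seed Integer seed for the whole cohort.
#' @param n_observers Observers per trial.
#' @return An object of class `ltcv_cohort`: list with `scores`, `trials`
#'   (consensus-level records with the true labels), and `truth`.
#' @examples
#' coh <- simulate_cohort(truth_params("ctrl", "mouse", n_animals = 2), seed = 7)
#' nrow(coh$trials)  # 2 animals x 24 stimuli
#' @export
simulate_cohort <- function(groups, seed = 1L, n_observers = 3L) {
  if (inherits(groups, "ltcv_truth_params")) groups <- list(groups)
  labels <- vapply(groups, `[[`, character(1), "group")
  if (anyDuplicated(labels)) stop("group labels must be distinct", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    animal_truth <- list()
    trials <- list()
    for (g in groups) {
      a_c50 <- stats::rnorm(g$n_animals, g$true_c50, g$animal_c50_sd)
      for (i in seq_len(g$n_animals)) {
        tr <- sim_animal_trials(g, i, a_c50[i])
        trials[[length(trials) + 1L]] <- tr
        animal_truth[[tr$animal_id[1]]] <- list(
          group = g$group, animal_c50 = a_c50[i],
          non_responder = g$non_responder)
      }
    }
    trials <- dplyr::bind_rows(trials)

    scores <- tidyr::expand_grid(
      trials, observer_id = sprintf("obs%d", seq_len(n_observers)))
    flip <- stats::setNames(
      vapply(groups, `[[`, numeric(1), "observer_flip"), labels)
    scores <- scores |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(response_type = flip_labels(
        .data$response_type, .data$species[1], flip[.data$group[1]])) |>
      dplyr::ungroup()

    truth <- list(
      seed = as.integer(seed), n_observers = as.integer(n_observers),
      groups = lapply(groups, function(g) unclass(g)),
      animals = animal_truth)

    structure(
      list(scores = scores,
           trials = dplyr::mutate(trials,
                                  positive = .data$response_type != "none"),
           truth = truth),
      class = "ltcv_cohort")
  })
}

#' Write a simulated cohort to disk
#'
#' Writes the tidy observer-score CSV (loadable by [read_trials()]) and the
#' ground-truth JSON sidecar.
#'
#' @param cohort An `ltcv_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ltcv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials_path <- file.path(dir, "trials.csv")
  truth_path <- file.path(dir, "truth.json")
  readr::write_csv(cohort$scores[, .trial_cols], trials_path)
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(trials = trials_path, truth = truth_path))
}
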