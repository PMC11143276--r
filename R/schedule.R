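#' Randomized R x C stimulus schedule
#'
#' Builds the randomized presentation list for one session: each of the `C`
#' contrast levels repeated `reps` (`R`) times, in a seeded uniform random
#' permutation (Fisher-Yates via R's sampler). Randomizing the order
#' minimizes order and habituation effects. The emitted session plan carries
#' an earliest-allowed onset time per trial spaced by the presentation
#' duration plus `min_isi` (actual triggering is manual, when the animal is
#' near the arena center, so these are lower bounds).
#'
#' The canonical designs are 5 levels x 3 reps = 15 stimuli for rats and
#' 6 levels x 4 reps = 24 stimuli for mice.
#'
#' @param levels An `ltcv_levels` table from [contrast_levels()], or a
#'   character vector of level ids.
#' @param reps Repetitions per contrast level (R), >= 1.
#' @param seed Integer seed; equal seeds give identical schedules.
#' @param config An [stimulus_config()] object.
#' @param no_immediate_repeat If `TRUE`, re-draws (deterministically, from
#'   the same seed stream) until no level directly follows itself; off by
#'   default since plain uniform randomization is the reference behavior.
#' @return An object of class `ltcv_schedule`: list with `trials` (tibble of
#'   `trial_index`, `level_id`, `earliest_onset_s`), `n_levels`,
#'   `reps_per_level`, `seed`, `config`.
#' @examples
#' lv <- contrast_levels(data.frame(level_id = paste0("L", 1:5),
#'                                  Id = c(39, 30, 20, 10, 0), Ib = 39))
#' sch <- build_schedule(lv, reps = 3, seed = 1, config = stimulus_config("rat"))
#' nrow(sch$trials)  # 15
#' @export
build_schedule <- function(levels, reps, seed, config,
                           no_immediate_repeat = FALSE) {
  stopifnot(inherits(config, "ltcv_config"))
  ids <- if (is.character(levels)) levels else tibble::as_tibble(levels)$level_id
  if (length(ids) < 1) stop("need at least one contrast level", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate level_ids", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)

  pool <- rep(ids, times = reps)
  order <- withr::with_seed(as.integer(seed), {
    out <- sample(pool)
    if (no_immediate_repeat && length(ids) > 1) {
      while (any(out[-1] == out[-length(out)])) out <- sample(pool)
    }
    out
  })

  dur <- build_timeline(config)$total_duration_s
  n <- length(order)
  trials <- tibble::tibble(
    trial_index = seq_len(n),
    level_id = order,
    earliest_onset_s = (seq_len(n) - 1) * (dur + config$min_isi)
  )
  structure(
    list(trials = trials, n_levels = length(ids),
         reps_per_level = as.integer(reps), seed = as.integer(seed),
         config = config),
    class = "ltcv_schedule"
  )
}

#' Write a session plan to disk
#'
#' Writes the trial plan as CSV and a JSON sidecar with the configuration
#' and seed for provenance.
#'
#' @param schedule An `ltcv_schedule` from [build_schedule()].
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "ltcv_schedule"))
  readr::write_csv(schedule$trials, path)
  cfg <- schedule$config
  side <- list(
    seed = schedule$seed, n_levels = schedule$n_levels,
    reps_per_level = schedule$reps_per_level,
    config = cfg[setdiff(names(cfg), "expansion_profile")],
    package_version = as.character(utils::packageVersion("ltcv"))
  )
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.ltcv_schedule <- function(x, ...) {
  cat(sprintf("<ltcv_schedule> %d levels x %d reps = %d trials (seed %d)\n",
              x$n_levels, x$reps_per_level, nrow(x$trials), x$seed))
  print(x$trials, ...)
  invisible(x)
}
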