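#' Phase timeline of one stimulus presentation
#'
#' Lays out the contiguous phases of a single looming presentation:
#' `n_expansions` cycles of (`expand`, `hold`), separated by `gap` phases,
#' with no trailing gap after the final hold. Total duration is
#' `n (e + h) + (n - 1) g`; the defaults give 4 s.
#'
#' @param config An [stimulus_config()] object.
#' @return An object of class `ltcv_timeline`: a list with `phases` (tibble
#'   of `phase_kind`, `start_s`, `end_s`, `cycle`), `total_duration_s`, and
#'   the config.
#' @examples
#' build_timeline(stimulus_config("rat"))$total_duration_s  # 4
#' @export
build_timeline <- function(config) {
  stopifnot(inherits(config, "ltcv_config"))
  n <- config$n_expansions
  e <- config$expansion_duration
  h <- config$hold_duration
  g <- config$inter_expansion_gap

  kinds <- character(0); cycles <- integer(0); durs <- numeric(0)
  for (i in seq_len(n)) {
    kinds <- c(kinds, "expand", "hold")
    cycles <- c(cycles, i, i)
    durs <- c(durs, e, h)
    if (i < n) {
      kinds <- c(kinds, "gap"); cycles <- c(cycles, i); durs <- c(durs, g)
    }
  }
  ends <- cumsum(durs)
  phases <- tibble::tibble(
    phase_kind = kinds, cycle = cycles,
    start_s = c(0, ends[-length(ends)]), end_s = ends
  )
  structure(
    list(phases = phases, total_duration_s = ends[length(ends)],
         config = config),
    class = "ltcv_timeline"
  )
}

#' Disk radius at a time point within a presentation
#'
#' The disk grows from radius 0 to `r_max` over each expansion phase
#' (linearly by default; the growth profile is injectable via
#' `stimulus_config(expansion_profile = )`), stays at `r_max` through the
#' hold, and is absent (radius 0) during gaps.
#'
#' @param t Time in seconds since presentation onset; vectorized. Must lie
#'   in `[0, total_duration_s]`.
#' @param config An [stimulus_config()] object.
#' @return Disk radius in cm at each `t`.
#' @examples
#' cfg <- stimulus_config("rat")
#' disk_radius(c(0, 0.25, 0.5), cfg)  # 0, 10, 20
#' @export
disk_radius <- function(t, config) {
  tl <- build_timeline(config)
  if (any(t < 0 | t > tl$total_duration_s)) {
    stop(sprintf("t outside stimulus timeline [0, %g]", tl$total_duration_s),
         call. = FALSE)
  }
  ph <- tl$phases
  vapply(t, function(ti) {
    # last phase whose start <= ti (phase boundaries belong to the later
    # phase, except the overall end point)
    idx <- max(which(ph$start_s <= ti))
    kind <- ph$phase_kind[idx]
    if (kind == "hold") return(config$r_max)
    if (kind == "gap") return(0)
    frac <- (ti - ph$start_s[idx]) / (ph$end_s[idx] - ph$start_s[idx])
    config$r_max * config$expansion_profile(frac)
  }, numeric(1))
}

#' @export
print.ltcv_timeline <- function(x, ...) {
  cat(sprintf("<ltcv_timeline> %d phases, %.3g s total\n",
              nrow(x$phases), x$total_duration_s))
  print(x$phases, ...)
  invisible(x)
}
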