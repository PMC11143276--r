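#' Stimulus configuration for the looming test
#'
#' Geometry and phase timings of the expanding-disk looming stimulus. One
#' stimulus presentation consists of `n_expansions` repetitions of a
#' two-phase disk cycle (linear expansion from radius 0 to `r_max`, then a
#' static hold at `r_max`), with an `inter_expansion_gap` between cycles but
#' no trailing gap after the last hold. With the defaults (three 0.5 s
#' expansions, 0.5 s holds, 0.5 s gaps) a presentation lasts exactly 4 s.
#'
#' Species presets fix the arena geometry: rats run in a 70 cm arena with a
#' 20 cm maximum disk radius, mice in a 40 cm arena with a 15 cm maximum
#' radius. Both use a 39 lux gray background.
#'
#' @param species Species preset, `"rat"` or `"mouse"`. Sets `r_max` and
#'   `arena_side` unless overridden.
#' @param r_max Maximum disk radius in cm at full expansion.
#' @param expansion_duration Duration of the expansion phase, seconds.
#' @param hold_duration Duration of the static hold at `r_max`, seconds.
#' @param inter_expansion_gap Gap between consecutive expansions, seconds
#'   (disk absent).
#' @param n_expansions Number of expansion cycles per stimulus presentation.
#' @param min_isi Minimum interval between consecutive stimulus
#'   presentations, seconds.
#' @param background_lux Gray background illuminance, lux.
#' @param arena_side Arena side length, cm.
#' @param expansion_profile Monotone function mapping a fraction of the
#'   expansion phase in `[0, 1]` to a fraction of `r_max` in `[0, 1]`;
#'   defaults to linear growth (`identity`). Must satisfy f(0) = 0,
#'   f(1) = 1.
#' @return An object of class `ltcv_config`.
#' @examples
#' cfg <- stimulus_config("rat")
#' cfg$r_max            # 20
#' stimulus_config("mouse")$r_max  # 15
#' @export
stimulus_config <- function(species = c("rat", "mouse"),
                            r_max = NULL,
                            expansion_duration = 0.5,
                            hold_duration = 0.5,
                            inter_expansion_gap = 0.5,
                            n_expansions = 3L,
                            min_isi = 30,
                            background_lux = 39,
                            arena_side = NULL,
                            expansion_profile = identity) {
  species <- match.arg(species)
  presets <- list(rat = list(r_max = 20, arena_side = 70),
                  mouse = list(r_max = 15, arena_side = 40))
  if (is.null(r_max)) r_max <- presets[[species]]$r_max
  if (is.null(arena_side)) arena_side <- presets[[species]]$arena_side

  stopifnot(
    "expansion_duration must be > 0" = expansion_duration > 0,
    "hold_duration must be > 0" = hold_duration > 0,
    "inter_expansion_gap must be > 0" = inter_expansion_gap > 0,
    "n_expansions must be >= 1" = n_expansions >= 1,
    "r_max must be > 0" = r_max > 0,
    "min_isi must be >= 0" = min_isi >= 0,
    "arena_side must be > 0" = arena_side > 0,
    "expansion_profile must be a function" = is.function(expansion_profile)
  )
  structure(
    list(species = species, r_max = r_max,
         expansion_duration = expansion_duration,
         hold_duration = hold_duration,
         inter_expansion_gap = inter_expansion_gap,
         n_expansions = as.integer(n_expansions),
         min_isi = min_isi, background_lux = background_lux,
         arena_side = arena_side, expansion_profile = expansion_profile),
    class = "ltcv_config"
  )
}

#' @export
print.ltcv_config <- function(x, ...) {
  tl <- build_timeline(x)
  cat(sprintf("<ltcv_config> %s preset\n", x$species))
  cat(sprintf("  r_max %g cm, arena %g cm, background %g lux\n",
              x$r_max, x$arena_side, x$background_lux))
  cat(sprintf("  %d expansion(s): %.3g s expand + %.3g s hold, %.3g s gap\n",
              x$n_expansions, x$expansion_duration, x$hold_duration,
              x$inter_expansion_gap))
  cat(sprintf("  presentation %.3g s, min inter-stimulus interval %g s\n",
              tl$total_duration_s, x$min_isi))
  invisible(x)
}
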