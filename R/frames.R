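#' Render a stimulus presentation as grayscale frames
#'
#' Offline visualization of the looming stimulus: a square view of the arena
#' ceiling with the disk drawn at its radius for each frame time. Gray
#' values are normalized to `[0, 1]` with the background at 0.5 and the disk
#' at `0.5 * (1 + MI/100)`, so dark disks (negative Michelson index) render
#' darker than the background and a zero-contrast disk is invisible.
#'
#' @param level One row of an `ltcv_levels` table (or any list with
#'   `michelson_pct`).
#' @param config An [stimulus_config()] object.
#' @param fps Frames per second, > 0.
#' @param px_per_cm Spatial scale of the rendering; the image is
#'   `arena_side * px_per_cm` pixels on a side.
#' @return 3-D array `[row, col, frame]` of gray values in `[0, 1]`, with
#'   `ceiling(total_duration * fps)` frames; frame `f` shows time
#'   `(f - 1) / fps`.
#' @examples
#' lv <- contrast_levels(data.frame(level_id = "L1", Id = 13, Ib = 39))
#' fr <- render_frames(lv[1, ], stimulus_config("mouse"), fps = 2)
#' dim(fr)[3]  # 8 frames for the 4 s presentation
#' @export
render_frames <- function(level, config, fps, px_per_cm = 1) {
  stopifnot(inherits(config, "ltcv_config"))
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  mi <- level$michelson_pct
  if (is.null(mi)) stop("level must carry michelson_pct", call. = FALSE)

  total <- build_timeline(config)$total_duration_s
  n_frames <- ceiling(total * fps)
  side_px <- max(2L, as.integer(round(config$arena_side * px_per_cm)))
  bg <- 0.5
  disk_val <- 0.5 * (1 + mi / 100)

  # squared distance (cm^2) of each pixel center from the image center
  ax <- (seq_len(side_px) - (side_px + 1) / 2) / px_per_cm
  d2 <- outer(ax^2, ax^2, `+`)

  frames <- array(bg, dim = c(side_px, side_px, n_frames))
  for (f in seq_len(n_frames)) {
    t <- min((f - 1) / fps, total)
    r <- disk_radius(t, config)
    if (r > 0) {
      slab <- frames[, , f]
      slab[d2 <= r^2] <- disk_val
      frames[, , f] <- slab
    }
  }
  frames
}

#' Write rendered frames as a PNG sequence
#'
#' @param frames Array from [render_frames()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths written, invisibly.
#' @export
write_frames <- function(frames, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write frames", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(dim(frames)[3])
  for (f in seq_len(dim(frames)[3])) {
    paths[f] <- file.path(dir, sprintf("frame_%04d.png", f))
    png::writePNG(frames[, , f], paths[f])
  }
  invisible(paths)
}
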