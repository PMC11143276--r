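#' Michelson contrast index
#'
#' Quantifies disk/background contrast from the irradiance of the fully
#' expanded disk (`Id`) and of the background alone (`Ib`), both measured at
#' the arena center in the same (arbitrary) instrument units:
#' \deqn{MI(\%) = (I_d - I_b) \cdot 100 / (I_d + I_b)}
#' Dark disks (`Id < Ib`) give negative values; the index is bounded in
#' \[-100, 100\] and is invariant to the irradiance unit.
#'
#' @param Id Disk irradiance, >= 0. Vectorized.
#' @param Ib Background irradiance, >= 0 (and `Id + Ib > 0`). Vectorized.
#' @return Michelson index in percent.
#' @examples
#' michelson_index(13, 39)  # -50
#' michelson_index(0, 39)   # -100
#' @export
michelson_index <- function(Id, Ib) {
  if (any(Id < 0) || any(Ib < 0)) {
    stop("irradiances must be non-negative", call. = FALSE)
  }
  if (any(Id + Ib == 0)) {
    stop("contrast undefined: Id + Ib = 0", call. = FALSE)
  }
  (Id - Ib) * 100 / (Id + Ib)
}

#' Weber contrast
#'
#' Background-referenced contrast `(Id - Ib) / Ib`. This convention
#' (difference over background) is the package's declared one; it is 0 for
#' an invisible disk and -1 for a fully dark disk.
#'
#' @inheritParams michelson_index
#' @return Dimensionless Weber contrast.
#' @examples
#' weber_contrast(0, 39)   # -1
#' weber_contrast(78, 39)  # 1
#' @export
weber_contrast <- function(Id, Ib) {
  if (any(Ib <= 0)) stop("background irradiance must be > 0", call. = FALSE)
  if (any(Id < 0)) stop("irradiances must be non-negative", call. = FALSE)
  (Id - Ib) / Ib
}

#' Build a calibrated contrast-level table
#'
#' Takes photometer calibration measurements (one row per displayed gray
#' level: disk irradiance `Id` with the disk fully expanded, background
#' irradiance `Ib`) and derives the Michelson index, Weber contrast, and
#' contrast magnitude `|MI|` used as the model covariate downstream.
#'
#' @param calibration Data frame with columns `level_id`, `Id`, `Ib`.
#' @return A tibble with columns `level_id`, `Id`, `Ib`, `michelson_pct`,
#'   `weber`, `magnitude`, classed `ltcv_levels`.
#' @examples
#' contrast_levels(data.frame(level_id = c("L1", "L2"),
#'                            Id = c(13, 0), Ib = c(39, 39)))
#' @export
contrast_levels <- function(calibration) {
  calibration <- tibble::as_tibble(calibration)
  need <- c("level_id", "Id", "Ib")
  miss <- setdiff(need, names(calibration))
  if (length(miss)) {
    stop("calibration table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(calibration$level_id)) {
    stop("duplicate level_id in calibration table", call. = FALSE)
  }
  out <- dplyr::mutate(
    calibration,
    level_id = as.character(.data$level_id),
    michelson_pct = michelson_index(.data$Id, .data$Ib),
    weber = weber_contrast(.data$Id, .data$Ib),
    magnitude = abs(.data$michelson_pct)
  )
  class(out) <- c("ltcv_levels", class(out))
  out
}

#' Read / write a contrast calibration table
#'
#' `read_calibration()` reads a CSV with columns `level_id,Id,Ib` and returns
#' the derived level table; `write_levels()` writes the derived table
#' (including `michelson_pct`, `weber`, `magnitude`) back to CSV.
#'
#' @param path CSV file path.
#' @return `read_calibration()`: an `ltcv_levels` tibble.
#' @export
read_calibration <- function(path) {
  contrast_levels(readr::read_csv(path, show_col_types = FALSE))
}

#' @param levels An `ltcv_levels` table from [contrast_levels()].
#' @rdname read_calibration
#' @export
write_levels <- function(levels, path) {
  readr::write_csv(tibble::as_tibble(levels), path)
  invisible(path)
}
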