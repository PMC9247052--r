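#' Wavelength grid of the hyperspectral camera
#'
#' The push-broom camera records reflectance from 500 to 995 nm in 5 nm
#' steps, i.e. 100 spectral bands. `make_wavelength_grid()` constructs that
#' grid (or a coarser/finer one for reduced problem sizes) and validates its
#' internal consistency.
#'
#' @param start_nm First band centre in nanometres.
#' @param stop_nm Last band centre in nanometres.
#' @param step_nm Band spacing in nanometres.
#'
#' @return An object of class `wavelength_grid`: a list with elements
#'   `start_nm`, `stop_nm`, `step_nm`, `n_bands` and `wavelengths_nm`.
#' @examples
#' grid <- make_wavelength_grid()
#' grid$n_bands # 100
#' @export
make_wavelength_grid <- function(start_nm = 500, stop_nm = 995, step_nm = 5) {
  if (!is.numeric(start_nm) || !is.numeric(stop_nm) || !is.numeric(step_nm) ||
      step_nm <= 0 || stop_nm < start_nm) {
    abort("`start_nm`, `stop_nm`, `step_nm` must define a non-empty increasing grid.")
  }
  if (abs((stop_nm - start_nm) %% step_nm) > 1e-9 &&
      abs(step_nm - (stop_nm - start_nm) %% step_nm) > 1e-9) {
    abort("`stop_nm - start_nm` must be a multiple of `step_nm`.")
  }
  wl <- seq(start_nm, stop_nm, by = step_nm)
  structure(
    list(
      start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
      n_bands = length(wl), wavelengths_nm = wl
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %g-%g nm in %g nm steps (%d bands)\n",
    x$start_nm, x$stop_nm, x$step_nm, x$n_bands
  ))
  invisible(x)
}

#' Band column names for a wavelength grid
#'
#' Spectra tables store one column per band, named `b<wavelength>` (e.g.
#' `b500`, `b505`, ...). These helpers map between grids, column names and
#' numeric wavelengths.
#'
#' @param grid A `wavelength_grid`.
#' @return `band_columns()`: character vector of column names.
#' @export
band_columns <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  sprintf("b%g", grid$wavelengths_nm)
}

#' @rdname band_columns
#' @param tbl A spectra table (data frame with `b<wavelength>` columns).
#' @return `spectra_band_columns()`: the band column names present in `tbl`.
#' @export
spectra_band_columns <- function(tbl) {
  grep("^b[0-9]+(\\.[0-9]+)?$", names(tbl), value = TRUE)
}

#' @rdname band_columns
#' @return `spectra_wavelengths()`: numeric wavelengths of `tbl`'s band columns.
#' @export
spectra_wavelengths <- function(tbl) {
  as.numeric(sub("^b", "", spectra_band_columns(tbl)))
}

#' @rdname band_columns
#' @return `spectra_matrix()`: the band columns of `tbl` as a numeric matrix
#'   (one row per spectrum).
#' @export
spectra_matrix <- function(tbl) {
  as.matrix(tbl[spectra_band_columns(tbl)])
}

#' Fixed vocabularies of the acquisition protocol
#'
#' The study annotates 20 porcine organ and tissue classes and records every
#' scene from three camera angles: perpendicular to the tissue surface and
#' 25 degrees from either side.
#'
#' @return Character vectors of labels. The first entries (`"stomach"`,
#'   `"perpendicular"`) are the reference categories of the mixed model.
#' @export
porcine_organs <- function() {
  c(
    "stomach", "jejunum", "colon", "liver", "gallbladder", "pancreas",
    "kidney", "spleen", "bladder", "omentum", "lung", "heart", "cartilage",
    "bone", "skin", "muscle", "peritoneum", "vena_cava",
    "kidney_with_fascia", "bile_fluid"
  )
}

#' @rdname porcine_organs
#' @export
hsi_angles <- function() {
  c("perpendicular", "side_a_25deg", "side_b_25deg")
}
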