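#' Hyperspectral datacube
#'
#' A datacube couples a 3-D reflectance array (x, y, band) with the
#' wavelength grid it was recorded on. Reflectance is in arbitrary units;
#' the spatial extent is metadata and never assumed constant across images.
#'
#' @param reflectance Numeric 3-D array, dimensions `c(width, height, n_bands)`.
#'   All values must be finite and non-negative.
#' @param grid A [make_wavelength_grid()] object; `dim(reflectance)[3]` must
#'   equal `grid$n_bands`.
#' @param image_id Identifier of the recording.
#' @return An object of class `datacube`.
#' @export
datacube <- function(reflectance, grid = make_wavelength_grid(), image_id = "img") {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3L) {
    abort("`reflectance` must be a 3-D array (width x height x bands).")
  }
  if (dim(reflectance)[3] != grid$n_bands) {
    abort(sprintf(
      "Band dimension (%d) does not match grid (%d bands).",
      dim(reflectance)[3], grid$n_bands
    ))
  }
  if (anyNA(reflectance) || any(!is.finite(reflectance))) {
    abort("`reflectance` must be finite.")
  }
  if (any(reflectance < 0)) {
    abort("`reflectance` must be non-negative.")
  }
  structure(
    list(reflectance = reflectance, grid = grid, image_id = as.character(image_id),
         normalized = FALSE),
    class = "datacube"
  )
}

#' @export
print.datacube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf(
    "<datacube> %s: %d x %d pixels, %d bands%s\n",
    x$image_id, d[1], d[2], d[3], if (isTRUE(x$normalized)) " (l1-normalized)" else ""
  ))
  invisible(x)
}

#' Pixel-level l1 normalization of a datacube
#'
#' Divides every pixel spectrum by the sum of its band values so that each
#' pixel sums to one, removing the global illumination scale. Pixels whose
#' spectrum sums to zero (sensor dropouts) cannot be normalized: they are
#' flagged in the attached QC log and zeroed, and are excluded from any
#' later median-spectrum extraction.
#'
#' @param cube A [datacube()].
#' @return The normalized `datacube` with `normalized = TRUE` and a `qc`
#'   element: a list with `n_invalid_pixels` and a tibble `invalid_pixels`
#'   of (x, y) coordinates.
#' @export
l1_normalize_pixels <- function(cube) {
  stopifnot(inherits(cube, "datacube"))
  refl <- cube$reflectance
  sums <- rowSums(refl, dims = 2L) # (width x height) pixel sums over bands
  bad <- !is.finite(sums) | sums <= 0
  sums[bad] <- 1 # avoid 0/0; flagged pixels are zeroed below
  out <- refl / as.vector(sums) # first two dims vary fastest: correct recycling
  if (any(bad)) {
    for (b in seq_len(dim(refl)[3])) {
      plane <- out[, , b]
      plane[bad] <- 0
      out[, , b] <- plane
    }
    idx <- which(bad, arr.ind = TRUE)
    invalid <- tibble::tibble(x = unname(idx[, 1]) - 1L,
                              y = unname(idx[, 2]) - 1L)
  } else {
    invalid <- tibble::tibble(x = integer(), y = integer())
  }
  cube$reflectance <- out
  cube$normalized <- TRUE
  cube$qc <- list(n_invalid_pixels = sum(bad), invalid_pixels = invalid)
  cube
}

#' Annotation of one organ region in one image
#'
#' An annotation couples an expert-drawn pixel mask with the acquisition
#' metadata the mixed model needs: the pig, the organ label, the recording,
#' the organ position ("image" factor), the camera angle and the repetition
#' index of the standardized protocol.
#'
#' @param pig_id,image_id,position_id Identifiers. `position_id` is the level
#'   of the "image" random factor and must be unique within a pig.
#' @param organ Organ label; must belong to `vocabulary`.
#' @param angle One of [hsi_angles()].
#' @param repetition Integer in 1..3.
#' @param mask Logical matrix (width x height), `TRUE` for annotated pixels.
#'   Coordinates are 0-based in exported form, x = column, y = row.
#' @param vocabulary Allowed organ labels (default [porcine_organs()]).
#' @return An object of class `annotation_record`.
#' @export
annotation_record <- function(pig_id, organ, image_id, position_id, angle,
                              repetition, mask, vocabulary = porcine_organs()) {
  if (!organ %in% vocabulary) {
    abort(sprintf("Unknown organ label '%s' (not in the %d-label vocabulary).",
                  organ, length(vocabulary)))
  }
  if (!angle %in% hsi_angles()) {
    abort(sprintf("Unknown angle '%s'; expected one of %s.",
                  angle, paste(hsi_angles(), collapse = ", ")))
  }
  repetition <- as.integer(repetition)
  if (is.na(repetition) || repetition < 1L || repetition > 3L) {
    abort("`repetition` must be an integer in 1..3.")
  }
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("`mask` must be a logical matrix (width x height).")
  }
  if (!any(mask)) {
    abort("`mask` must contain at least one annotated pixel.")
  }
  structure(
    list(
      pig_id = as.character(pig_id), organ = organ,
      image_id = as.character(image_id), position_id = as.character(position_id),
      angle = angle, repetition = repetition, mask = mask
    ),
    class = "annotation_record"
  )
}

#' Median spectrum of an annotation
#'
#' Computes, per band, the median over all annotated pixels of an
#' l1-normalized cube. The per-band median of unit-sum spectra is not itself
#' exactly unit-sum, so the result is re-normalized to sum one; the
#' pre-renormalization mass is recorded in the `median_l1_sum` column.
#' Pixels flagged invalid during normalization are excluded from the mask.
#'
#' @param cube An l1-normalized [datacube()].
#' @param ann An [annotation_record()] whose mask matches the cube's spatial
#'   dimensions.
#' @return A one-row tibble with the annotation metadata (`pig_id`, `organ`,
#'   `image_id`, `position_id`, `angle`, `repetition`), `n_pixels`,
#'   `median_l1_sum` and one `b<wavelength>` column per band.
#' @export
extract_median_spectrum <- function(cube, ann) {
  stopifnot(inherits(cube, "datacube"), inherits(ann, "annotation_record"))
  if (!isTRUE(cube$normalized)) {
    abort("`cube` must be l1-normalized first (see `l1_normalize_pixels()`).")
  }
  d <- dim(cube$reflectance)
  if (!identical(dim(ann$mask), d[1:2])) {
    bad <- which(ann$mask, arr.ind = TRUE)
    oob <- bad[bad[, 1] > d[1] | bad[, 2] > d[2], , drop = FALSE]
    coords <- if (nrow(oob)) {
      paste(sprintf("(%d,%d)", oob[, 1] - 1L, oob[, 2] - 1L), collapse = ", ")
    } else {
      "mask/cube dimension mismatch"
    }
    abort(sprintf("Mask does not fit cube %s: %s", cube$image_id, coords))
  }
  mask <- ann$mask
  if (!is.null(cube$qc) && cube$qc$n_invalid_pixels > 0) {
    inv <- cube$qc$invalid_pixels
    mask[cbind(inv$x + 1L, inv$y + 1L)] <- FALSE
  }
  idx <- which(mask)
  if (length(idx) == 0L) {
    abort("Mask is empty after excluding invalid pixels.")
  }
  # n_pixels x n_bands matrix of pixel spectra
  px <- matrix(cube$reflectance[as.vector(outer(idx, (seq_len(d[3]) - 1L) * d[1] * d[2], "+"))],
               nrow = length(idx))
  med <- apply(px, 2L, median)
  mass <- sum(med)
  values <- med / mass
  out <- tibble::tibble(
    pig_id = ann$pig_id, organ = ann$organ, image_id = ann$image_id,
    position_id = ann$position_id, angle = ann$angle,
    repetition = ann$repetition, n_pixels = length(idx),
    median_l1_sum = mass
  )
  bands <- band_columns(cube$grid)
  out[bands] <- as.list(values)
  out
}

#' Read and write spectra tables as CSV
#'
#' A spectra table holds one row per annotation: the metadata columns
#' `pig_id`, `organ`, `position_id`, `angle`, `repetition`, `n_pixels`
#' (plus optional extras) and one `b<wavelength>` column per band.
#'
#' @param tbl A spectra table.
#' @param path CSV file path.
#' @return `read_spectra_csv()` returns a tibble; `write_spectra_csv()`
#'   returns `path` invisibly.
#' @export
write_spectra_csv <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
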