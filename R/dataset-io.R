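# On-disk dataset layout
#
#   <dir>/<image_id>.hdr   text header: samples/lines/bands/interleave/wavelengths
#   <dir>/<image_id>.img   raw binary reflectance, BSQ, little-endian double
#   <dir>/annotations.json one entry per annotation: metadata + RLE-coded mask
#
# Masks are run-length encoded over column-major (x fastest) pixel order.

rle_encode_mask <- function(mask) {
  r <- rle(as.vector(mask))
  pos <- cumsum(c(1L, r$lengths))
  keep <- r$values
  list(
    width = nrow(mask), height = ncol(mask),
    starts = as.integer(pos[-length(pos)][keep]),
    lengths = as.integer(r$lengths[keep])
  )
}

rle_decode_mask <- function(rle) {
  mask <- matrix(FALSE, rle$width, rle$height)
  for (i in seq_along(rle$starts)) {
    mask[rle$starts[i] + seq_len(rle$lengths[i]) - 1L] <- TRUE
  }
  mask
}

write_envi_cube <- function(cube, dir) {
  hdr <- file.path(dir, paste0(cube$image_id, ".hdr"))
  img <- file.path(dir, paste0(cube$image_id, ".img"))
  d <- dim(cube$reflectance)
  writeLines(c(
    "ENVI",
    sprintf("samples = %d", d[1]),
    sprintf("lines = %d", d[2]),
    sprintf("bands = %d", d[3]),
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("normalized = %d", as.integer(isTRUE(cube$normalized))),
    sprintf("wavelength = { %s }", paste(cube$grid$wavelengths_nm, collapse = ", "))
  ), hdr)
  con <- file(img, "wb")
  on.exit(close(con))
  writeBin(as.double(cube$reflectance), con, size = 8L, endian = "little")
  invisible(c(hdr, img))
}

read_envi_cube <- function(hdr_path) {
  lines <- readLines(hdr_path)
  field <- function(key) {
    m <- grep(sprintf("^%s\\s*=", key), lines, value = TRUE)
    if (!length(m)) abort(sprintf("Header %s: missing field '%s'.", hdr_path, key))
    sub("^[^=]*=\\s*", "", m[1])
  }
  samples <- as.integer(field("samples"))
  nlines <- as.integer(field("lines"))
  bands <- as.integer(field("bands"))
  wl <- as.numeric(strsplit(gsub("[{}]", "", field("wavelength")), ",")[[1]])
  if (length(wl) != bands) {
    abort(sprintf("Header %s: %d wavelengths for %d bands.", hdr_path, length(wl), bands))
  }
  step <- unique(round(diff(wl), 9))
  if (length(step) != 1L) abort(sprintf("Header %s: non-uniform wavelength grid.", hdr_path))
  grid <- make_wavelength_grid(wl[1], wl[length(wl)], step)
  img_path <- sub("\\.hdr$", ".img", hdr_path)
  n <- samples * nlines * bands
  con <- file(img_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(vals) != n) {
    abort(sprintf("%s: expected %d values, read %d.", img_path, n, length(vals)))
  }
  cube <- datacube(array(vals, dim = c(samples, nlines, bands)), grid,
                   image_id = sub("\\.hdr$", "", basename(hdr_path)))
  cube$normalized <- identical(field("normalized"), "1")
  cube
}

#' Write a hyperspectral dataset to disk
#'
#' Serializes datacubes as ENVI-style header+binary pairs (band-sequential,
#' little-endian double precision, lossless round trip) and annotations as a
#' JSON file with run-length-encoded masks.
#'
#' @param cubes List of [datacube()] objects.
#' @param annotations List of [annotation_record()] objects; each
#'   `image_id` must refer to one of `cubes`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_hsi_dataset <- function(cubes, annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cubes, function(c) c$image_id, character(1))
  for (cube in cubes) write_envi_cube(cube, dir)
  ann_json <- lapply(annotations, function(a) {
    if (!a$image_id %in% ids) {
      abort(sprintf("Annotation references unknown image '%s'.", a$image_id))
    }
    list(
      pig_id = a$pig_id, organ = a$organ, image_id = a$image_id,
      position_id = a$position_id, angle = a$angle, repetition = a$repetition,
      mask_rle = rle_encode_mask(a$mask)
    )
  })
  jsonlite::write_json(ann_json, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a hyperspectral dataset from disk
#'
#' Inverse of [write_hsi_dataset()]. Every annotation is validated against
#' the organ vocabulary and its cube's spatial extent; cubes are returned
#' sorted by image id and annotations by (pig, image).
#'
#' @param dir Dataset directory.
#' @param vocabulary Allowed organ labels.
#' @return A list with elements `cubes` (list of `datacube`) and
#'   `annotations` (list of `annotation_record`).
#' @export
read_hsi_dataset <- function(dir, vocabulary = porcine_organs()) {
  hdrs <- sort(list.files(dir, pattern = "\\.hdr$", full.names = TRUE))
  if (!length(hdrs)) abort(sprintf("No .hdr files found in %s.", dir))
  cubes <- lapply(hdrs, read_envi_cube)
  names(cubes) <- vapply(cubes, function(c) c$image_id, character(1))
  ann_path <- file.path(dir, "annotations.json")
  if (!file.exists(ann_path)) abort(sprintf("Missing %s.", ann_path))
  raw <- jsonlite::read_json(ann_path)
  required <- c("pig_id", "organ", "image_id", "position_id", "angle", "repetition")
  annotations <- lapply(seq_along(raw), function(i) {
    a <- raw[[i]]
    missing <- setdiff(required, names(a))
    if (length(missing)) {
      abort(sprintf("Annotation %d: missing metadata field(s) %s.",
                    i, paste(missing, collapse = ", ")))
    }
    if (!a$image_id %in% names(cubes)) {
      abort(sprintf("Annotation %d references unknown image '%s'.", i, a$image_id))
    }
    rle <- a$mask_rle
    rle$starts <- unlist(rle$starts)
    rle$lengths <- unlist(rle$lengths)
    mask <- rle_decode_mask(rle)
    cube_dim <- dim(cubes[[a$image_id]]$reflectance)
    if (!identical(dim(mask), cube_dim[1:2])) {
      abort(sprintf("Annotation %d: mask %dx%d does not match cube %dx%d.",
                    i, nrow(mask), ncol(mask), cube_dim[1], cube_dim[2]))
    }
    annotation_record(a$pig_id, a$organ, a$image_id, a$position_id, a$angle,
                      a$repetition, mask, vocabulary = vocabulary)
  })
  ord <- order(
    vapply(annotations, function(a) a$pig_id, character(1)),
    vapply(annotations, function(a) a$image_id, character(1))
  )
  list(cubes = unname(cubes), annotations = annotations[ord])
}

#' Preprocess a dataset directory into a spectra table
#'
#' Runs the full preprocessing chain on a dataset written by
#' [write_hsi_dataset()]: pixel-level l1 normalization of every cube, then
#' per-annotation median-spectrum extraction.
#'
#' @inheritParams read_hsi_dataset
#' @return A list with `spectra` (tibble, one row per annotation) and `qc`
#'   (tibble of per-image invalid-pixel counts).
#' @export
preprocess_dataset <- function(dir, vocabulary = porcine_organs()) {
  ds <- read_hsi_dataset(dir, vocabulary = vocabulary)
  cubes <- lapply(ds$cubes, function(cube) {
    if (isTRUE(cube$normalized)) cube else l1_normalize_pixels(cube)
  })
  names(cubes) <- vapply(cubes, function(c) c$image_id, character(1))
  spectra <- purrr::map_dfr(ds$annotations, function(a) {
    extract_median_spectrum(cubes[[a$image_id]], a)
  })
  qc <- purrr::map_dfr(cubes, function(cube) {
    tibble::tibble(
      image_id = cube$image_id,
      n_invalid_pixels = if (is.null(cube$qc)) 0L else cube$qc$n_invalid_pixels
    )
  })
  list(spectra = spectra, qc = qc)
}
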