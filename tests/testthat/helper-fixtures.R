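# Small in-code fixtures shared across test files. Everything is generated
# at test time; nothing is read from disk.

# a tiny cube with known pixel spectra: values (x, y, band)
toy_cube <- function(width = 4L, height = 3L, grid = make_wavelength_grid(),
                     fill = 1) {
  datacube(array(fill, dim = c(width, height, grid$n_bands)), grid,
           image_id = "toy")
}

toy_mask <- function(width = 4L, height = 3L, pixels = cbind(1L, 1L)) {
  mask <- matrix(FALSE, width, height)
  mask[pixels] <- TRUE
  mask
}

toy_annotation <- function(mask, organ = "stomach", pig = "P01") {
  annotation_record(
    pig_id = pig, organ = organ, image_id = "toy",
    position_id = paste0(pig, "_", organ, "_pos1"),
    angle = "perpendicular", repetition = 1L, mask = mask
  )
}

# coarse grid keeps mixed-model tests fast
coarse_grid <- function(n_bands = 4L) {
  make_wavelength_grid(500, 500 + (n_bands - 1L) * 25, 25)
}

small_simulation <- function(n_pigs = 4L, n_organs = 3L, n_positions = 2L,
                             comps = generative_components(1e-6, 2e-6, 1e-6),
                             seed = 42L, grid = coarse_grid(), ...) {
  organs <- porcine_organs()[seq_len(n_organs)]
  lib <- make_fingerprint_library(organs, seed = seed, grid = grid)
  design <- make_standardized_design(n_pigs, organs, n_positions)
  list(
    lib = lib, design = design, comps = comps,
    spectra = simulate_spectra(design, lib, comps, seed = seed + 1L, ...)
  )
}
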