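#' Generate a 4D BOLD phantom with known spectral content
#'
#' Builds a small resting-state phantom for validating the pALFF stage:
#' three voxel blocks contain (1) a sinusoid inside the low-frequency band
#' (0.05 Hz by default), (2) a sinusoid above the band (0.20 Hz), and
#' (3) white noise, each with a per-voxel random phase (sinusoids) and an
#' additive Gaussian noise floor. Defaults follow the study's acquisition:
#' 427 volumes at TR 1.65 s. The mask covers the three blocks and the atlas
#' labels them as distinct ROIs with hemisphere tags.
#'
#' @param config A [synthetic_config()]; the `phantom_*` fields are used.
#' @return A list with `bold` (a `volume4d`), `mask` (a `volume3d` of
#'   0/1), and `atlas` (an [atlas_volume()] labeling the blocks
#'   `inband` / `outband` / `noise`).
#' @export
generate_phantom_bold <- function(config) {
  validate_synthetic_config(config)
  shape <- as.integer(config$phantom_shape)
  nt <- as.integer(config$phantom_n_volumes)
  tr <- config$phantom_tr
  nyq <- nyquist(tr)
  for (f in c(config$phantom_inband_freq, config$phantom_outband_freq)) {
    if (f > nyq) {
      stop(sprintf("sinusoid frequency %.3f Hz above Nyquist %.3f Hz",
                   f, nyq), call. = FALSE)
    }
  }
  with_seed(derive_seed(config$seed, "phantom"), {
    # three blocks along x, centered in y/z
    third <- floor(shape[1] / 3)
    xr <- list(seq_len(max(third - 1, 1)),
               seq(third + 1, 2 * third - 1),
               seq(2 * third + 1, min(3 * third - 1, shape[1])))
    yr <- seq(2, shape[2] - 1)
    zr <- seq(2, shape[3] - 1)

    labels <- array(0L, dim = shape)
    labels[xr[[1]], yr, zr] <- 1L
    labels[xr[[2]], yr, zr] <- 2L
    labels[xr[[3]], yr, zr] <- 3L
    label_map <- data.frame(
      label = 1:3,
      roi = c("inband", "outband", "noise"),
      hemisphere = c("L", "R", "L"))

    tt <- (seq_len(nt) - 1) * tr
    arr <- array(0, dim = c(shape, nt))
    flat <- matrix(arr, ncol = nt)
    lab_vec <- as.vector(labels)
    for (block in 1:3) {
      vox <- which(lab_vec == block)
      for (v in vox) {
        signal <- switch(block,
          sin(2 * pi * config$phantom_inband_freq * tt +
                stats::runif(1, 0, 2 * pi)),
          sin(2 * pi * config$phantom_outband_freq * tt +
                stats::runif(1, 0, 2 * pi)),
          stats::rnorm(nt))
        flat[v, ] <- signal
      }
    }
    if (config$phantom_noise_sd > 0) {
      in_mask <- lab_vec > 0
      flat[in_mask, ] <- flat[in_mask, ] +
        stats::rnorm(sum(in_mask) * nt, 0, config$phantom_noise_sd)
    }
    arr <- array(flat, dim = c(shape, nt))

    list(bold = volume4d(arr, tr = tr, voxel_mm = c(3, 3, 3)),
         mask = volume3d(array(as.numeric(labels > 0), dim = shape),
                         voxel_mm = c(3, 3, 3)),
         atlas = atlas_volume(labels, label_map, voxel_mm = c(3, 3, 3)))
  })
}
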