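#' Nyquist frequency of a regularly sampled series
#'
#' The highest detectable frequency, `1 / (2 * tr)`. At the study's
#' resting-state TR of 1.65 s this is 0.303 Hz, the upper edge of the
#' "entire detectable frequency range" in the pALFF denominator.
#'
#' @param tr Repetition (sampling) interval in seconds, > 0.
#' @return Frequency in Hz.
#' @examples
#' nyquist(1.65)  # 0.303 Hz
#' @export
nyquist <- function(tr) {
  if (!is.numeric(tr) || any(tr <= 0)) {
    stop("tr must be positive", call. = FALSE)
  }
  1 / (2 * tr)
}

# FWHM (mm) -> Gaussian sigma (mm); 2 * sqrt(2 * log(2)) = 2.3548
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# dense 1D smoothing operator along one axis: rows are output voxels,
# truncated at 6 sigma and row-renormalized, so constants are preserved
# everywhere including the boundary (zero padding + renormalization)
smooth_operator <- function(n, sigma_vox) {
  if (sigma_vox == 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma_vox^2))
  k[abs(d) > ceiling(6 * sigma_vox)] <- 0
  k / rowSums(k)
}

#' Smooth a 3D volume with an isotropic Gaussian kernel
#'
#' Separable Gaussian blur with per-axis sigma (in voxels) equal to
#' `fwhm / (voxel size * 2 * sqrt(2 * log(2)))`, the convention used when
#' gray-matter maps are smoothed with an 8 mm FWHM kernel before ROI
#' averaging. The kernel is truncated at 6 sigma and renormalized at the
#' boundary, so a constant volume stays constant everywhere. `fwhm = 0`
#' returns the input unchanged.
#'
#' @param vol A `volume3d` (or plain 3D array, assumed 1 mm voxels).
#' @param fwhm Full width at half maximum, mm, >= 0.
#' @return A `volume3d` on the same grid.
#' @export
gaussian_smooth <- function(vol, fwhm) {
  if (!is.numeric(fwhm) || fwhm < 0) {
    stop("fwhm must be nonnegative", call. = FALSE)
  }
  if (is.array(vol)) vol <- volume3d(vol)
  arr <- vol$data
  if (fwhm == 0) return(vol)
  sigma_mm <- fwhm_to_sigma(fwhm)
  dims <- dim(arr)
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / vol$voxel_mm[axis]
    op <- smooth_operator(dims[axis], sigma_vox)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    a <- array(op %*% matrix(a, nrow = dims[axis]), dim = dims[perm])
    arr <- aperm(a, order(perm))
  }
  volume3d(arr, voxel_mm = vol$voxel_mm)
}

#' Average a volume over atlas ROIs
#'
#' Arithmetic mean of the volume's voxels within each requested atlas
#' label, e.g. a single average gray-matter value per ROI per participant.
#'
#' @param vol A `volume3d` or 3D array on the same grid as the atlas.
#' @param atlas An [atlas_volume()].
#' @param labels Subset of labels to aggregate; default all labels in the
#'   atlas `label_map`.
#' @return A tibble with `label`, `roi`, `hemisphere`, `value` (the ROI
#'   mean).
#' @export
roi_aggregate <- function(vol, atlas, labels = NULL) {
  arr <- as_vol_array(vol)
  if (!inherits(atlas, "atlas_volume")) {
    stop("atlas must be an atlas_volume", call. = FALSE)
  }
  if (!identical(dim(arr), dim(atlas$data))) {
    stop("volume and atlas grids differ", call. = FALSE)
  }
  map <- atlas$label_map
  if (is.null(labels)) labels <- map$label
  if (length(labels) == 0L) stop("empty ROI selection", call. = FALSE)
  unknown <- setdiff(labels, map$label)
  if (length(unknown)) {
    stop("labels not in label_map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lab_vec <- as.vector(atlas$data)
  val_vec <- as.vector(arr)
  out <- vapply(labels, function(l) {
    sel <- lab_vec == l
    if (!any(sel)) {
      stop(sprintf("label %s has no voxels in the atlas volume", l),
           call. = FALSE)
    }
    mean(val_vec[sel])
  }, numeric(1))
  idx <- match(labels, map$label)
  tibble::tibble(label = labels, roi = map$roi[idx],
                 hemisphere = map$hemisphere[idx], value = unname(out))
}

#' pALFF configuration
#'
#' @param band_low,band_high Frequency band in Hz; defaults 0.01-0.08, the
#'   classic low-frequency fluctuation band. `0 <= band_low < band_high`
#'   and `band_high` must not exceed the Nyquist frequency of the series.
#' @param detrend Remove a per-voxel linear trend before the spectrum
#'   (default `TRUE`; an untreated scanner drift otherwise dominates the
#'   denominator).
#' @param exclude_dc Drop the zero-frequency bin from the denominator
#'   (default `TRUE`).
#' @param use_amplitude Sum spectral amplitude (`sqrt` power) instead of
#'   power. The default (`FALSE`) takes "power spectrum" literally as the
#'   squared FFT magnitude; the amplitude variant matches classic ALFF
#'   implementations.
#' @return A `palff_config` list.
#' @export
palff_config <- function(band_low = 0.01, band_high = 0.08,
                         detrend = TRUE, exclude_dc = TRUE,
                         use_amplitude = FALSE) {
  if (band_low < 0 || band_high <= band_low) {
    stop("need 0 <= band_low < band_high", call. = FALSE)
  }
  structure(list(band_low = band_low, band_high = band_high,
                 detrend = detrend, exclude_dc = exclude_dc,
                 use_amplitude = use_amplitude),
            class = "palff_config")
}

#' Rectangular-window periodogram
#'
#' Power at the FFT's natural frequency grid, scaled so that the sum of
#' power over all bins (including DC) equals the time-domain sum of squares
#' (Parseval).
#'
#' @param x Numeric time series.
#' @param tr Sampling interval, seconds.
#' @return A tibble with `freq` (Hz, all FFT bins `0 .. (n-1)/(n*tr)`) and
#'   `power`.
#' @export
periodogram <- function(x, tr) {
  n <- length(x)
  tibble::tibble(freq = (seq_len(n) - 1) / (n * tr),
                 power = Mod(stats::fft(x))^2 / n)
}

#' Compute a pALFF map from a 4D BOLD series
#'
#' Per in-mask voxel: optional linear detrend, rectangular-window FFT
#' periodogram, then the raw ratio of summed power over bins with
#' `band_low <= f <= band_high` to summed power over all
#' positive-frequency bins up to Nyquist (DC excluded when `exclude_dc`).
#' The final map divides each raw ratio by the mean raw ratio within the
#' mask, so the masked mean of the returned map is exactly 1. Out-of-mask
#' voxels are 0.
#'
#' @param bold A `volume4d` with at least 8 time points.
#' @param mask A `volume3d` / 3D array, nonzero = in-mask; must not be
#'   empty.
#' @param cfg A [palff_config()].
#' @param normalize Divide by the masked mean (default `TRUE`); set
#'   `FALSE` to get the raw band-power ratios.
#' @return A `volume3d` of pALFF values.
#' @export
compute_palff <- function(bold, mask, cfg = palff_config(),
                          normalize = TRUE) {
  if (!inherits(bold, "volume4d")) {
    stop("bold must be a volume4d", call. = FALSE)
  }
  m <- as_vol_array(mask) != 0
  if (!identical(dim(m), dim(bold$data)[1:3])) {
    stop("mask grid does not match the BOLD grid", call. = FALSE)
  }
  if (!any(m)) stop("empty mask", call. = FALSE)
  nt <- dim(bold$data)[4]
  nyq <- nyquist(bold$tr)
  if (cfg$band_high > nyq + 1e-12) {
    stop(sprintf("band_high %.4f Hz exceeds the Nyquist frequency %.4f Hz",
                 cfg$band_high, nyq), call. = FALSE)
  }

  ts_mat <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = nt)[, as.vector(m),
                                                               drop = FALSE]
  if (cfg$detrend) {
    X <- cbind(1, seq_len(nt))
    qx <- qr.Q(qr(X))
    ts_mat <- ts_mat - qx %*% (crossprod(qx, ts_mat))
  }
  pw <- Mod(stats::mvfft(ts_mat))^2 / nt
  if (cfg$use_amplitude) pw <- sqrt(pw)

  freq <- (seq_len(nt) - 1) / (nt * bold$tr)
  k_max <- floor(nt / 2)              # bins up to Nyquist
  detectable <- seq_len(k_max + 1)    # indices 1..k_max+1 <-> k = 0..k_max
  if (cfg$exclude_dc) detectable <- detectable[-1]
  in_band <- detectable[freq[detectable] >= cfg$band_low - 1e-12 &
                        freq[detectable] <= cfg$band_high + 1e-12]

  denom <- colSums(pw[detectable, , drop = FALSE])
  numer <- colSums(pw[in_band, , drop = FALSE])
  ratio <- numeric(length(denom))
  live <- denom > 0
  ratio[live] <- numer[live] / denom[live]
  if (any(!live)) {
    warning("all-zero time series in mask; raw ratio set to 0")
  }
  if (normalize) ratio <- ratio / mean(ratio)

  out <- array(0, dim = dim(m))
  out[m] <- ratio
  volume3d(out, voxel_mm = bold$voxel_mm)
}
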