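# Paired coverage-track fixtures (ChIP signal/control) and punctate
# cuticle (trichome-field) phantoms.

#' Shape specification for a synthetic coverage track
#'
#' @param baseline constant per-bin baseline value.
#' @param peaks optional data frame with columns `center` (1-based bin
#'   index), `height` and `width_bins` (Gaussian SD in bins; 0 gives a
#'   single-bin impulse).
#' @param noise_sd additive Gaussian noise SD per bin.
#' @return a `track_spec` list.
#' @export
track_spec <- function(baseline = 0, peaks = NULL, noise_sd = 0) {
  if (!is.null(peaks)) {
    stopifnot(all(c("center", "height", "width_bins") %in% names(peaks)))
  }
  structure(list(baseline = baseline, peaks = peaks, noise_sd = noise_sd),
            class = "track_spec")
}

render_track_values <- function(spec, n_bins) {
  v <- rep(spec$baseline, n_bins)
  if (!is.null(spec$peaks)) {
    idx <- seq_len(n_bins)
    for (k in seq_len(nrow(spec$peaks))) {
      p <- spec$peaks[k, ]
      if (p$width_bins <= 0) {
        v[p$center] <- v[p$center] + p$height
      } else {
        v <- v + p$height * exp(-(idx - p$center)^2 / (2 * p$width_bins^2))
      }
    }
  }
  v
}

#' Generate a paired signal/control coverage track
#'
#' Both tracks live on the same chromosome and bin grid; pre-noise values
#' are retained as ground truth. Noise draws for signal and control come
#' from separate substreams of the same root seed.
#'
#' @param n_bins number of uniform bins (> 0).
#' @param bin_size_bp bin width in bp.
#' @param signal_spec,control_spec [track_spec()] objects.
#' @param chrom chromosome name.
#' @param seed integer root seed.
#' @return list with `signal` and `control` ([genomic_track()] objects)
#'   and `truth` holding the pre-noise values.
#' @export
gen_track_pair <- function(n_bins, bin_size_bp = 100,
                           signal_spec = track_spec(),
                           control_spec = track_spec(),
                           chrom = "chr2L", seed = 1) {
  stopifnot_scalar_pos(n_bins, "n_bins")
  sig0 <- render_track_values(signal_spec, n_bins)
  ctl0 <- render_track_values(control_spec, n_bins)
  sig <- with_seed(substream_seed(seed, "track_signal"), {
    sig0 + stats::rnorm(n_bins, 0, signal_spec$noise_sd)
  })
  ctl <- with_seed(substream_seed(seed, "track_control"), {
    ctl0 + stats::rnorm(n_bins, 0, control_spec$noise_sd)
  })
  list(
    signal = genomic_track(sig, chrom = chrom, bin_size_bp = bin_size_bp),
    control = genomic_track(ctl, chrom = chrom, bin_size_bp = bin_size_bp),
    truth = list(signal_values = sig0, control_values = ctl0)
  )
}

#' Lightweight calibrated 2D image
#'
#' @param data numeric matrix (row = image row).
#' @param pixel_size pixel side length, in `units`.
#' @param units unit of `pixel_size` (`"um"` or `"mm"`).
#' @return an `Image2D` object.
#' @export
image2d <- function(data, pixel_size = NULL, units = c("um", "mm")) {
  stopifnot(is.matrix(data), length(data) > 0)
  units <- match.arg(units)
  if (!is.null(pixel_size)) stopifnot_scalar_pos(pixel_size, "pixel_size")
  structure(list(data = data, pixel_size = pixel_size, units = units),
            class = "Image2D")
}

#' Generate a punctate cuticle (trichome-field) phantom
#'
#' Trichomes are rendered as Gaussian bright spots over a noisy background,
#' placed at integer pixel positions at least `spacing_px` apart (and away
#' from the image border). Ground truth records the spot coordinates
#' (1-based `row`, `col`).
#'
#' @param n_trichomes number of spots.
#' @param roi image shape `c(H, W)`, or a logical matrix restricting where
#'   spots may be placed.
#' @param spacing_px minimum pairwise spot distance, pixels.
#' @param amplitude spot peak height above background.
#' @param background_mean,background_sd background level and noise SD.
#' @param sigma_px spot Gaussian radius, pixels.
#' @param seed integer root seed.
#' @return list with `image` (an [image2d()]) and `truth` (data frame of
#'   spot coordinates).
#' @export
gen_cuticle_phantom <- function(n_trichomes, roi = c(64, 96), spacing_px = 4,
                                amplitude = 100, background_mean = 50,
                                background_sd = 5, sigma_px = 1.2, seed = 1) {
  if (is.matrix(roi)) {
    shape <- dim(roi)
    mask <- roi
  } else {
    shape <- as.integer(roi)
    mask <- matrix(TRUE, shape[1], shape[2])
  }
  margin <- ceiling(3 * sigma_px) + 1L
  with_seed(substream_seed(seed, "cuticle"), {
    pts <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n_trichomes)) {
      ok <- FALSE
      for (tr in 1:500) {
        r <- margin + sample.int(shape[1] - 2L * margin, 1L)
        cc <- margin + sample.int(shape[2] - 2L * margin, 1L)
        if (!mask[r, cc]) next
        if (nrow(pts) > 0 &&
            any((pts[, 1] - r)^2 + (pts[, 2] - cc)^2 < spacing_px^2)) next
        pts <- rbind(pts, c(r, cc))
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("could not place trichomes at the requested spacing in this ROI")
      }
    }
    img <- matrix(background_mean, shape[1], shape[2])
    if (background_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, background_sd),
                          shape[1], shape[2])
    }
    rr <- -ceiling(3 * sigma_px):ceiling(3 * sigma_px)
    bump <- amplitude * exp(-outer(rr^2, rr^2, "+") / (2 * sigma_px^2))
    for (i in seq_len(nrow(pts))) {
      ri <- pts[i, 1] + rr; ci <- pts[i, 2] + rr
      img[ri, ci] <- img[ri, ci] + bump
    }
    truth <- data.frame(row = pts[, 1], col = pts[, 2])
    if (n_trichomes == 0) truth <- data.frame(row = integer(0), col = integer(0))
    list(image = image2d(img, pixel_size = NULL), truth = truth)
  })
}
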