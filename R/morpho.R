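# Trichome counting in user-defined ROIs (prominence-based local maxima,
# the automated counterpart of interactive find-maxima tools) and body
# morphometrics from thresholded silhouettes.

# Topographic prominence of local maxima via union-find over pixels in
# decreasing intensity order: when two basins meet at level v, the lower
# peak dies with prominence = its height - v. Surviving peaks get
# peak - min(roi). Invariant to additive offsets and to image rotation.
prominence_maxima <- function(img, roi = NULL) {
  H <- nrow(img); W <- ncol(img)
  in_roi <- if (is.null(roi)) rep(TRUE, H * W) else as.vector(roi > 0)
  idx <- which(in_roi)
  vals <- img[idx]
  ord <- idx[order(-vals, idx)]
  rank <- integer(H * W)            # activation order, 0 = not yet active
  parent <- integer(H * W)
  peak_idx <- integer(H * W)        # root -> index of its peak pixel
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  off <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  peaks <- integer(length(idx)); proms <- numeric(length(idx))
  n_dead <- 0L
  for (step in seq_along(ord)) {
    p <- ord[step]
    parent[p] <- p
    peak_idx[p] <- p
    rank[p] <- step
    r <- ((p - 1L) %% H) + 1L
    v <- img[p]
    for (o in off) {
      q <- p + o
      if (q < 1L || q > H * W || rank[q] == 0L) next
      qr <- ((q - 1L) %% H) + 1L
      if (abs(qr - r) > 1L) next              # column wrap guard
      rq <- find_root(q)
      rp <- find_root(p)
      if (rq == rp) next
      # lower (or later-activated, on ties) peak dies at the current level
      pk_p <- peak_idx[rp]; pk_q <- peak_idx[rq]
      die_first <- img[pk_p] < img[pk_q] ||
        (img[pk_p] == img[pk_q] && rank[pk_p] > rank[pk_q])
      die <- if (die_first) rp else rq
      live <- if (die_first) rq else rp
      n_dead <- n_dead + 1L
      peaks[n_dead] <- peak_idx[die]
      proms[n_dead] <- img[peak_idx[die]] - v
      parent[die] <- live
    }
  }
  roots <- unique(vapply(idx, find_root, 0L))
  base <- min(vals)
  peaks <- c(peaks[seq_len(n_dead)], peak_idx[roots])
  proms <- c(proms[seq_len(n_dead)], img[peak_idx[roots]] - base)
  data.frame(
    row = ((peaks - 1L) %% H) + 1L,
    col = ((peaks - 1L) %/% H) + 1L,
    value = img[peaks],
    prominence = proms
  )
}

#' Count trichomes in a region of interest
#'
#' Finds intensity maxima whose topographic prominence (height above the
#' saddle connecting them to any higher maximum) reaches
#' `min_prominence`, then suppresses maxima closer than
#' `min_separation_px` to a stronger one. Prominence rather than a raw
#' threshold makes the count robust to uneven illumination and to
#' additive intensity offsets; the procedure is deterministic.
#'
#' @param image an [image2d()] or plain numeric matrix.
#' @param roi optional logical matrix (same shape) restricting the count;
#'   empty ROIs are an error.
#' @param min_prominence minimum prominence of a counted maximum.
#' @param min_separation_px minimum pairwise distance of counted maxima.
#' @return list with `count` and `coordinates` (data frame `row`, `col`,
#'   `value`, `prominence`; 1-based pixel indices).
#' @export
count_trichomes <- function(image, roi = NULL, min_prominence = 20,
                            min_separation_px = 3) {
  img <- if (inherits(image, "Image2D")) image$data else image
  stopifnot(is.matrix(img))
  if (!is.null(roi)) {
    stopifnot(all(dim(roi) == dim(img)))
    if (sum(roi > 0) == 0) stop("ROI is empty")
  }
  cand <- prominence_maxima(img, roi)
  cand <- cand[cand$prominence >= min_prominence, , drop = FALSE]
  if (nrow(cand) > 0 && min_separation_px > 0) {
    keep <- nms_points(as.matrix(cand[, c("row", "col")]), cand$value,
                       min_separation_px)
    cand <- cand[keep, , drop = FALSE]
  }
  rownames(cand) <- NULL
  list(count = nrow(cand), coordinates = cand)
}

#' Body area and length from a silhouette image
#'
#' Thresholds the image (Otsu by default), keeps the largest 4-connected
#' foreground component, and reports its area (pixel count times pixel
#' area) and its length as the major-axis length of the component's
#' second-moment (inertia-equivalent) ellipse: `4 * sqrt(lambda_max)`
#' where `lambda_max` is the largest eigenvalue of the pixel-coordinate
#' covariance. For a solid ellipse this recovers the full major-axis
#' length exactly. The moment-axis definition of "length" is this
#' package's convention for a measurement the source protocol drew by
#' hand.
#'
#' @param image an [image2d()] with a calibrated pixel size.
#' @param threshold absolute foreground threshold; `NULL` for Otsu.
#' @return list with `area_mm2`, `length_mm`, `width_mm`, `n_pixels`,
#'   `threshold`.
#' @export
body_metrics <- function(image, threshold = NULL) {
  stopifnot(inherits(image, "Image2D"))
  if (is.null(image$pixel_size)) stop("body_metrics needs a calibrated image")
  px_mm <- if (image$units == "um") image$pixel_size / 1000 else
    image$pixel_size
  img <- image$data
  if (is.null(threshold)) {
    rng <- range(img)
    if (rng[2] <= rng[1]) stop("image is constant; no foreground component")
    thr01 <- EBImage::otsu(EBImage::Image((t(img) - rng[1]) /
                                            (rng[2] - rng[1])))
    threshold <- rng[1] + thr01 * (rng[2] - rng[1])
  }
  fg <- img > threshold
  if (!any(fg)) stop("no foreground component above the threshold")
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(fg) * 1))))
  tab <- tabulate(lab[lab > 0])
  main <- which.max(tab)
  idx <- which(lab == main, arr.ind = TRUE)
  n_px <- nrow(idx)
  area <- n_px * px_mm^2
  ev <- if (n_px > 1) {
    eigen(stats::cov(idx) * (n_px - 1) / n_px, symmetric = TRUE)$values
  } else {
    c(0, 0)   # a point mass has zero second moments
  }
  list(
    area_mm2 = area,
    length_mm = 4 * sqrt(max(ev)) * px_mm,
    width_mm = 4 * sqrt(max(min(ev), 0)) * px_mm,
    n_pixels = n_px,
    threshold = threshold
  )
}
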