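# Single-larva deconvolution of population-level MALDI imaging mass
# spectrometry: total-ion-current segmentation of larvae, per-larva
# abundance matrices, a location/scale batch adjustment ("combat_lite"),
# column-standardized PCA, and lipid-class enrichment via a rank-sum test
# on per-channel fold changes ("class_ranksum"). The batch and enrichment
# steps are deliberately transparent stand-ins for full empirical-Bayes
# batch correction and ontology-based lipid enrichment, and are named to
# avoid overclaiming.

#' Segment larvae from a MALDI ion-image stack
#'
#' Thresholds the total-ion-current (TIC, per-pixel sum over channels)
#' image — Otsu by default — optionally applies a morphological closing,
#' labels 4-connected components, discards components below `min_area_px`,
#' and renumbers labels in row-major centroid order. An all-background
#' stack yields an empty (0-label) mask.
#'
#' @param stack an `IonImageStack` (see [gen_ion_phantom()] for the
#'   structure, or [read_ion_dir()]).
#' @param threshold absolute TIC threshold; `NULL` (default) for Otsu.
#' @param close_radius radius (px) of a morphological closing applied to
#'   the foreground before labeling; 0 (default) disables it, keeping
#'   larvae separated by even a single background pixel distinct.
#' @param min_area_px minimum component area, pixels.
#' @return a `LarvaLabelMask`: list with `labels` (integer matrix, 0 =
#'   background), `n_larvae`, `areas_px` and `tic_threshold`.
#' @export
segment_larvae <- function(stack, threshold = NULL, close_radius = 0,
                           min_area_px = 20) {
  stopifnot(inherits(stack, "IonImageStack"))
  tic <- apply(stack$planes, c(1, 2), sum)
  if (max(tic) <= 0) {
    return(structure(list(labels = matrix(0L, nrow(tic), ncol(tic)),
                          n_larvae = 0L, areas_px = integer(0),
                          tic_threshold = NA_real_),
                     class = "LarvaLabelMask"))
  }
  if (is.null(threshold)) {
    rng <- range(tic)
    thr01 <- EBImage::otsu(EBImage::Image(t(tic) / rng[2]),
                           range = c(rng[1] / rng[2], 1))
    threshold <- thr01 * rng[2]
  }
  fg <- tic > threshold
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    fg_img <- EBImage::closing(EBImage::Image(t(fg) * 1), brush)
    fg <- t(EBImage::imageData(fg_img)) > 0
  }
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(fg) * 1))))
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  keep <- ids[vapply(ids, function(i) sum(lab == i), 0L) >= min_area_px]
  # renumber in row-major centroid order
  cent <- t(vapply(keep, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    colMeans(idx)
  }, c(0, 0)))
  out <- matrix(0L, nrow(fg), ncol(fg))
  if (length(keep) > 0) {
    ord <- order(round(cent[, 1]), cent[, 2])
    for (k in seq_along(ord)) out[lab == keep[ord[k]]] <- k
  }
  areas <- if (length(keep) > 0) {
    vapply(seq_along(keep), function(k) sum(out == k), 0L)
  } else {
    integer(0)
  }
  structure(list(labels = out, n_larvae = length(keep), areas_px = areas,
                 tic_threshold = threshold),
            class = "LarvaLabelMask")
}

#' @export
print.LarvaLabelMask <- function(x, ...) {
  cat(sprintf("LarvaLabelMask: %d larva(e), TIC threshold %.4g\n",
              x$n_larvae, x$tic_threshold))
  invisible(x)
}

#' Per-larva metabolite abundance matrix
#'
#' Cell `(i, c)` is the mean (default) or sum of ion-image plane `c` over
#' the pixels of label `i`. The mean is the default aggregation because it
#' is robust to larva-size differences between groups; sums weight large
#' larvae more.
#'
#' @param stack an `IonImageStack`.
#' @param mask a `LarvaLabelMask` on the same grid.
#' @param aggregation `"mean"` (default) or `"sum"`.
#' @param meta optional data frame of per-larva metadata (`larva_id`,
#'   `group`, `batch`), matched to labels by row order.
#' @return an `AbundanceMatrix`: list with `values` (larva x channel
#'   matrix), `meta`, `channels` and `aggregation`.
#' @export
per_larva_abundance <- function(stack, mask, aggregation = c("mean", "sum"),
                                meta = NULL) {
  stopifnot(inherits(stack, "IonImageStack"),
            inherits(mask, "LarvaLabelMask"))
  aggregation <- match.arg(aggregation)
  if (mask$n_larvae == 0) stop("mask has no larvae; segment first")
  if (!all(dim(mask$labels) == dim(stack$planes)[1:2])) {
    stop("mask and stack grids differ")
  }
  n <- mask$n_larvae
  C <- dim(stack$planes)[3]
  vals <- matrix(NA_real_, n, C)
  hw <- prod(dim(stack$planes)[1:2])
  for (i in seq_len(n)) {
    idx <- which(mask$labels == i)
    for (ch in seq_len(C)) {
      px <- stack$planes[idx + (ch - 1L) * hw]
      vals[i, ch] <- if (aggregation == "mean") mean(px) else sum(px)
    }
  }
  if (is.null(meta)) {
    meta <- data.frame(larva_id = seq_len(n), group = NA_character_,
                       batch = 1L)
  }
  stopifnot(nrow(meta) == n)
  dimnames(vals) <- list(sprintf("larva_%02d", seq_len(n)),
                         format(stack$channels$mz))
  structure(list(values = vals, meta = meta, channels = stack$channels,
                 aggregation = aggregation),
            class = "AbundanceMatrix")
}

#' Build an AbundanceMatrix from a plain matrix
#'
#' @param values larva x channel numeric matrix.
#' @param meta per-larva metadata (`larva_id`, `group`, `batch`).
#' @param channels channel table (`mz`, `formula`, `adduct`,
#'   `lipid_class`).
#' @param aggregation aggregation label carried along.
#' @return an `AbundanceMatrix`.
#' @export
abundance_matrix <- function(values, meta, channels, aggregation = "mean") {
  stopifnot(is.matrix(values), nrow(meta) == nrow(values),
            nrow(channels) == ncol(values))
  if (anyNA(values)) stop("abundance matrix must have no missing cells")
  structure(list(values = values, meta = meta, channels = channels,
                 aggregation = aggregation),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d larva(e) x %d channels (%s aggregation)\n",
              nrow(x$values), ncol(x$values), x$aggregation))
  invisible(x)
}

#' Location/scale batch adjustment ("combat_lite")
#'
#' Per channel, each batch is centered and scaled so that all batch means
#' equal the grand mean and all batch SDs equal the pooled within-batch SD
#' of that channel. This is a transparent location/scale stand-in for
#' empirical-Bayes batch correction: it uses no shrinkage and ignores
#' group labels. Matching the pooled *within-batch* SD (rather than the
#' grand SD) makes the operation exactly idempotent. Batches with zero
#' within-batch variance in a channel are centered only; with fewer than
#' 2 samples in any batch the matrix is returned unchanged with a
#' warning.
#'
#' @param am an `AbundanceMatrix` with a `batch` column in its `meta`.
#' @return the adjusted `AbundanceMatrix` (attribute `method` =
#'   `"combat_lite"`).
#' @export
batch_adjust <- function(am) {
  stopifnot(inherits(am, "AbundanceMatrix"))
  batch <- as.factor(am$meta$batch)
  if (any(table(batch) < 2)) {
    warning("every batch needs >= 2 samples; returning matrix unadjusted")
    return(am)
  }
  v <- am$values
  if (nlevels(batch) > 1) {
    for (ch in seq_len(ncol(v))) {
      x <- v[, ch]
      m_b <- tapply(x, batch, mean)
      s_b <- tapply(x, batch, stats::sd)
      n_b <- tapply(x, batch, length)
      grand <- mean(x)
      pooled_sd <- sqrt(sum((n_b - 1) * s_b^2) / sum(n_b - 1))
      for (b in levels(batch)) {
        i <- batch == b
        centred <- x[i] - m_b[[b]]
        if (s_b[[b]] > 0 && pooled_sd > 0) {
          centred <- centred / s_b[[b]] * pooled_sd
        }
        v[i, ch] <- centred + grand
      }
    }
  }
  out <- am
  out$values <- v
  attr(out, "method") <- "combat_lite"
  out
}

#' Column-standardized PCA of an abundance matrix
#'
#' Channels are centered and scaled to unit variance before the
#' decomposition; constant channels are dropped with a warning. The sign
#' of each component is fixed so its largest-magnitude loading is
#' positive. Variance fractions are relative to the total variance of the
#' standardized matrix, so over all components they sum to 1.
#'
#' @param am an `AbundanceMatrix`.
#' @param n_components number of components to return.
#' @return list with `scores` (larva x component), `loadings`
#'   (channel x component), `variance_fraction` and `dropped_channels`.
#' @export
pca_profiles <- function(am, n_components = 2) {
  stopifnot(inherits(am, "AbundanceMatrix"))
  v <- am$values
  if (nrow(v) < 2) stop("PCA needs more than one larva")
  sds <- apply(v, 2, stats::sd)
  keep_ch <- sds > 0
  dropped <- if (is.null(colnames(v))) which(!keep_ch) else
    colnames(v)[!keep_ch]
  if (any(!keep_ch)) {
    warning(sprintf("dropping %d constant channel(s)", sum(!keep_ch)))
    v <- v[, keep_ch, drop = FALSE]
  }
  if (ncol(v) < n_components) stop("fewer varying channels than components")
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  keep <- seq_len(min(n_components, ncol(pc$rotation)))
  flip <- vapply(keep, function(k) {
    sign(pc$rotation[which.max(abs(pc$rotation[, k])), k])
  }, 0)
  scores <- sweep(pc$x[, keep, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, keep, drop = FALSE], 2, flip, `*`)
  list(
    scores = scores, loadings = loadings,
    variance_fraction = (pc$sdev^2 / sum(pc$sdev^2))[keep],
    dropped_channels = dropped
  )
}

#' Lipid-class enrichment between two groups ("class_ranksum")
#'
#' Computes a per-channel log2 fold change of group B over group A
#' (means of per-larva abundances) and summarizes each lipid class by the
#' median log2 fold change of its member channels plus a Wilcoxon
#' rank-sum test of members versus all non-member channels. A transparent
#' stand-in for ontology-based lipid enrichment: it tests whether a class
#' shifts coherently relative to the rest of the panel.
#'
#' @param am an `AbundanceMatrix`.
#' @param groups group label per larva; defaults to `meta$group`. Exactly
#'   two groups; the first level (or `reference`) is the denominator.
#' @param reference optional reference (denominator) group label.
#' @param class_map channel class per channel; defaults to the stack's
#'   `lipid_class` column.
#' @return data frame with one row per class: `class`, `n_channels`,
#'   `median_log2fc`, `p_value`, ordered by `p_value`.
#' @export
class_enrichment <- function(am, groups = NULL, reference = NULL,
                             class_map = NULL) {
  stopifnot(inherits(am, "AbundanceMatrix"))
  if (is.null(groups)) groups <- am$meta$group
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("class_enrichment needs exactly two groups")
  if (is.null(reference)) reference <- lv[1]
  other <- setdiff(lv, reference)
  if (sum(groups == reference) < 2 || sum(groups == other) < 2) {
    stop("both groups need at least 2 larvae")
  }
  if (is.null(class_map)) class_map <- am$channels$lipid_class
  mean_a <- colMeans(am$values[groups == reference, , drop = FALSE])
  mean_b <- colMeans(am$values[groups == other, , drop = FALSE])
  l2fc <- log2(mean_b / mean_a)
  classes <- unique(class_map[!is.na(class_map)])
  rows <- lapply(classes, function(cls) {
    member <- !is.na(class_map) & class_map == cls
    if (sum(member) == 0) return(NULL)
    if (all(member)) {
      warning(sprintf("class '%s' covers every channel; no test possible",
                      cls))
      return(data.frame(class = cls, n_channels = sum(member),
                        median_log2fc = stats::median(l2fc[member]),
                        p_value = NA_real_))
    }
    p <- suppressWarnings(
      stats::wilcox.test(l2fc[member], l2fc[!member], exact = FALSE)$p.value
    )
    if (is.nan(p)) p <- 1   # all fold changes identical (e.g. both groups equal)
    data.frame(class = cls, n_channels = sum(member),
               median_log2fc = stats::median(l2fc[member]), p_value = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- "class_ranksum"
  attr(out, "comparison") <- sprintf("%s vs %s (reference %s)", other,
                                     reference, reference)
  out[order(out$p_value), ]
}

#' Read / write ion-image stacks as a directory of TIFF planes
#'
#' The plain on-disk form of an `IonImageStack`: one 32-bit float TIFF per
#' channel (`channel_001.tif`, ...) plus a `channels.tsv` table (columns
#' `mz`, `formula`, `adduct`, `lipid_class`) and a `meta.json` holding
#' the pixel size and intensity scale.
#'
#' @param stack an `IonImageStack`.
#' @param dir directory to create/read.
#' @return `read_ion_dir`: an `IonImageStack`.
#' @export
write_ion_dir <- function(stack, dir) {
  stopifnot(inherits(stack, "IonImageStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  C <- dim(stack$planes)[3]
  scale <- max(1, max(stack$planes))
  for (ch in seq_len(C)) {
    tiff::writeTIFF(stack$planes[, , ch] / scale,
                    file.path(dir, sprintf("channel_%03d.tif", ch)),
                    bits.per.sample = 32L)
  }
  utils::write.table(stack$channels, file.path(dir, "channels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um, intensity_scale = scale),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_ion_dir
#' @export
read_ion_dir <- function(dir) {
  channels <- utils::read.table(file.path(dir, "channels.tsv"), sep = "\t",
                                header = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  C <- nrow(channels)
  first <- tiff::readTIFF(file.path(dir, "channel_001.tif"))
  planes <- array(0, c(nrow(first), ncol(first), C))
  planes[, , 1] <- first
  for (ch in seq_len(C)[-1]) {
    planes[, , ch] <- tiff::readTIFF(file.path(dir,
                                               sprintf("channel_%03d.tif", ch)))
  }
  structure(list(planes = planes * meta$intensity_scale, channels = channels,
                 pixel_size_um = meta$pixel_size_um),
            class = "IonImageStack")
}
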