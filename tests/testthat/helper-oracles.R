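# Shared oracles and scoring helpers, independent of the implementation
# paths they check.

# Greedy one-to-one matching of detections to ground-truth sites within a
# voxel radius; returns precision/recall/F1.
match_sites <- function(det, truth, radius_vox = 3) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(det))) {
    d2 <- (truth$z - det$z[i])^2 + (truth$y - det$y[i])^2 +
      (truth$x - det$x[i])^2
    j <- which(!used & d2 <= radius_vox^2)
    if (length(j) > 0) {
      used[j[which.min(d2[j])]] <- TRUE
      tp <- tp + 1L
    }
  }
  precision <- if (nrow(det) > 0) tp / nrow(det) else 1
  recall <- if (nrow(truth) > 0) tp / nrow(truth) else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  list(precision = precision, recall = recall, f1 = f1)
}

# Score detected head-cast events against injected ones within a time
# tolerance (one-to-one greedy matching).
match_events <- function(det_times, true_times, tol_s = 1.0) {
  used <- rep(FALSE, length(true_times))
  fp <- 0L
  for (t in det_times) {
    j <- which(!used & abs(true_times - t) <= tol_s)
    if (length(j) > 0) used[j[1]] <- TRUE else fp <- fp + 1L
  }
  list(tp = sum(used), fn = sum(!used), fp = fp)
}

# Detector performance pooled over the movers of one generated cohort.
cohort_event_scores <- function(tj, tol_s = 1.0) {
  trs <- split_trajectories(tj$table)
  tp <- 0L; fn <- 0L; fp <- 0L
  for (id in names(trs)) {
    if (!classify_moving(trs[[id]])) next
    ev <- detect_head_casts(trs[[id]])
    tru <- tj$truth$events$time_s[tj$truth$events$larva_id == as.integer(id)]
    sc <- match_events(ev$time_s, tru, tol_s)
    tp <- tp + sc$tp; fn <- fn + sc$fn; fp <- fp + sc$fp
  }
  list(recall = if (tp + fn > 0) tp / (tp + fn) else 1,
       precision = if (tp + fp > 0) tp / (tp + fp) else 1)
}

# Match segmentation labels to ground-truth larvae by majority overlap;
# returns the truth index for each segmented label.
match_labels <- function(seg_labels, truth_labels) {
  vapply(seq_len(max(seg_labels)), function(i) {
    tl <- truth_labels[seg_labels == i]
    tl <- tl[tl > 0]
    as.integer(names(which.max(table(tl))))
  }, 0L)
}

# IoU of segmented label against its matched truth larva.
label_iou <- function(seg_labels, truth_labels, seg_id, truth_id) {
  s <- seg_labels == seg_id
  t <- truth_labels == truth_id
  sum(s & t) / sum(s | t)
}

# Analytic value at radius r of a Gaussian enrichment of amplitude A and
# width sigma after convolution with an axis-wise Gaussian PSF: product of
# per-axis width ratios scales the amplitude; widths add in quadrature.
blurred_enrichment <- function(r, amplitude, sigma, psf_sigma) {
  shrink <- prod(sigma / sqrt(sigma^2 + psf_sigma^2))
  sig_eff <- sqrt(sigma^2 + max(psf_sigma)^2)  # isotropic approximation
  1 + (amplitude - 1) * shrink * exp(-r^2 / (2 * mean(sig_eff)^2))
}

# Pooled-variance two-sample t statistic, closed form.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
}
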