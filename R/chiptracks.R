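# Control-subtracted, smoothed, replicate-averaged coverage tracks:
# the normalization applied to chromatin-mark ChIP-seq before
# visualization — histone-H3 control subtraction, a 500 bp centered
# moving average, and averaging of replicates with pairwise Pearson
# correlations reported.

#' Uniformly binned genomic coverage track
#'
#' Bins are 0-based and half-open: bin `i` covers
#' `[start_bp + i * bin_size_bp, start_bp + (i + 1) * bin_size_bp)`.
#' Values may be negative (e.g. after control subtraction).
#'
#' @param values numeric vector, one value per bin.
#' @param chrom chromosome name.
#' @param bin_size_bp bin width in bp (> 0).
#' @param start_bp 0-based start of the first bin.
#' @return a `GenomicTrack` object.
#' @export
genomic_track <- function(values, chrom = "chr2L", bin_size_bp = 100,
                          start_bp = 0) {
  stopifnot_scalar_pos(bin_size_bp, "bin_size_bp")
  stopifnot(length(values) > 0, start_bp >= 0)
  structure(
    list(chrom = chrom, bin_size_bp = as.integer(bin_size_bp),
         start_bp = as.integer(start_bp), values = as.numeric(values)),
    class = "GenomicTrack"
  )
}

#' @export
print.GenomicTrack <- function(x, ...) {
  cat(sprintf("GenomicTrack: %s, %d bins of %d bp from %d (%.4g .. %.4g)\n",
              x$chrom, length(x$values), x$bin_size_bp, x$start_bp,
              min(x$values), max(x$values)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$chrom, b$chrom) && a$bin_size_bp == b$bin_size_bp &&
    a$start_bp == b$start_bp && length(a$values) == length(b$values)
}

#' Subtract a control track from a signal track
#'
#' Per-bin `signal - control` (as in subtracting a histone-H3 control
#' from a mark track); the result may be negative. Both tracks must share
#' chromosome and bin grid — no implicit resampling.
#'
#' @param signal,control [genomic_track()] objects on the same grid.
#' @return a `GenomicTrack` of the differences.
#' @export
subtract_control <- function(signal, control) {
  stopifnot(inherits(signal, "GenomicTrack"), inherits(control, "GenomicTrack"))
  if (!same_grid(signal, control)) {
    stop("signal and control are on different bin grids; resample explicitly")
  }
  genomic_track(signal$values - control$values, chrom = signal$chrom,
                bin_size_bp = signal$bin_size_bp, start_bp = signal$start_bp)
}

#' Moving-average smoothing of a coverage track
#'
#' Centered moving average over `ceiling(window_bp / bin_size_bp)` bins,
#' forced odd so the window is centered; near the track ends the mean is
#' taken over the available bins only (truncated window), or over a
#' reflected extension with `edge = "reflect"`.
#'
#' @param track a [genomic_track()].
#' @param window_bp smoothing window in bp (default 500).
#' @param edge `"truncate"` (default) or `"reflect"`.
#' @return the smoothed `GenomicTrack`.
#' @export
smooth_track <- function(track, window_bp = 500,
                         edge = c("truncate", "reflect")) {
  stopifnot(inherits(track, "GenomicTrack"))
  edge <- match.arg(edge)
  if (window_bp < track$bin_size_bp) {
    warning("window smaller than one bin; returning track unchanged")
    return(track)
  }
  k <- ceiling(window_bp / track$bin_size_bp)
  if (k %% 2 == 0) k <- k + 1L
  v <- track$values
  sm <- if (edge == "truncate") {
    runmean_centered(v, k)
  } else {
    h <- (k - 1L) %/% 2L
    n <- length(v)
    ext <- c(rev(v[seq_len(min(h, n))]), v, rev(v[seq.int(max(1, n - h + 1), n)]))
    runmean_centered(ext, k)[seq.int(h + 1L, h + n)]
  }
  genomic_track(sm, chrom = track$chrom, bin_size_bp = track$bin_size_bp,
                start_bp = track$start_bp)
}

#' Average replicate tracks and report pairwise Pearson correlations
#'
#' @param tracks list of [genomic_track()] objects on a shared grid.
#' @return list with `average` (per-bin arithmetic mean as a
#'   `GenomicTrack`) and `pearson` (pairwise correlation matrix over
#'   bins; `NA` where a track has zero variance).
#' @export
average_replicates <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  for (tr in tracks) stopifnot(inherits(tr, "GenomicTrack"))
  for (tr in tracks[-1]) {
    if (!same_grid(tracks[[1]], tr)) stop("replicate tracks on different grids")
  }
  m <- vapply(tracks, function(tr) tr$values, tracks[[1]]$values)
  m <- matrix(m, ncol = length(tracks))
  avg <- rowMeans(m)
  n <- length(tracks)
  pearson <- matrix(NA_real_, n, n)
  sds <- apply(m, 2, stats::sd)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (sds[i] > 0 && sds[j] > 0) {
        pearson[i, j] <- stats::cor(m[, i], m[, j])
      }
    }
  }
  nm <- names(tracks)
  if (is.null(nm)) nm <- paste0("rep", seq_len(n))
  dimnames(pearson) <- list(nm, nm)
  list(
    average = genomic_track(avg, chrom = tracks[[1]]$chrom,
                            bin_size_bp = tracks[[1]]$bin_size_bp,
                            start_bp = tracks[[1]]$start_bp),
    pearson = pearson
  )
}

#' Read / write a single-chromosome bedGraph coverage track
#'
#' Uses rtracklayer for parsing/serialization. Reading requires the file
#' to describe one chromosome in contiguous, uniform bins (the canonical
#' on-disk form of a `GenomicTrack`).
#'
#' @param path bedGraph file path.
#' @return `read_bedgraph`: a [genomic_track()].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) != 1) {
    stop("bedGraph must cover exactly one chromosome")
  }
  gr <- GenomicRanges::sort(gr)
  starts <- GenomicRanges::start(gr) - 1L   # back to 0-based
  ends <- GenomicRanges::end(gr)
  widths <- ends - starts
  if (length(unique(widths)) != 1) stop("bedGraph bins are not uniform")
  if (length(starts) > 1 && any(diff(starts) != widths[1])) {
    stop("bedGraph bins are not contiguous")
  }
  genomic_track(gr$score,
                chrom = as.character(GenomicRanges::seqnames(gr))[1],
                bin_size_bp = widths[1], start_bp = starts[1])
}

#' @rdname read_bedgraph
#' @param track a [genomic_track()] to serialize.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "GenomicTrack"))
  n <- length(track$values)
  starts0 <- track$start_bp + (seq_len(n) - 1L) * track$bin_size_bp
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = starts0 + 1L,
                              end = starts0 + track$bin_size_bp),
    score = track$values
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
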