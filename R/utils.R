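# Internal numerical helpers shared across modules.
#
# Array convention: 3D volumes are indexed [z, y, x] with dim = c(nz, ny, nx);
# voxel sizes are given as c(dz, dy, dx) in micrometres. User-facing voxel
# coordinates are 0-based; the physical position of voxel (z, y, x) is
# (z, y, x) * voxel_size_um, i.e. voxel centres sit on a regular grid
# anchored at the origin.

#' Evaluate code with a temporary RNG state
#'
#' Seeds the RNG, runs `code`, and restores the caller's `.Random.seed`, so
#' generators are pure functions of their config and never perturb the
#' session RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a root seed
#'
#' Each generated artifact draws from its own substream, keyed by name, so
#' adding one generator call to a script never shifts the randomness of the
#' others. Plain polynomial string hash folded into the positive 32-bit range.
#' @noRd
substream_seed <- function(seed, name) {
  h <- as.double(seed) %% 2147483647
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

#' Truncated Gaussian kernel, unit sum
#' @noRd
gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Shift a 3D array by (dz, dy, dx), filling vacated entries with `fill`.
shift3 <- function(a, dz, dy, dx, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) {
    if (s >= 0) seq_len(n - s) else seq.int(1 - s, n)
  }
  dst <- function(n, s) {
    if (s >= 0) seq.int(1 + s, n) else seq_len(n + s)
  }
  out[dst(d[1], dz), dst(d[2], dy), dst(d[3], dx)] <-
    a[src(d[1], dz), src(d[2], dy), src(d[3], dx)]
  out
}

# Convolve a 3D array along one axis with a symmetric kernel; edges are
# renormalized over the in-bounds taps so constant fields are preserved.
conv_axis3 <- function(a, kernel, axis) {
  if (length(kernel) == 1) return(a)
  r <- (length(kernel) - 1L) %/% 2L
  acc <- array(0, dim(a))
  wsum <- array(0, dim(a))
  ones <- array(1, dim(a))
  for (j in seq_along(kernel)) {
    s <- j - r - 1L
    off <- c(0L, 0L, 0L)
    off[axis] <- s
    acc <- acc + kernel[j] * shift3(a, off[1], off[2], off[3], fill = 0)
    wsum <- wsum + kernel[j] * shift3(ones, off[1], off[2], off[3], fill = 0)
  }
  acc / wsum
}

#' Separable Gaussian blur of a 3D array
#'
#' @param a 3D array indexed `[z, y, x]`.
#' @param sigma_vox per-axis standard deviation in voxels, `c(z, y, x)`.
#' @noRd
blur3 <- function(a, sigma_vox) {
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      a <- conv_axis3(a, gaussian_kernel1d(sigma_vox[axis]), axis)
    }
  }
  a
}

# 2D Gaussian blur via the 3D path (singleton z).
blur2 <- function(m, sigma_px) {
  a <- array(m, c(1L, nrow(m), ncol(m)))
  matrix(blur3(a, c(0, sigma_px, sigma_px)), nrow(m), ncol(m))
}

#' Centered running mean with truncated edges
#'
#' Window of `k` samples (k odd); near the edges the mean is taken over the
#' available samples only, so constants are preserved everywhere.
#' Cumulative-sum formulation, O(n).
#' @noRd
runmean_centered <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 0) return(x)
  h <- (k - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Offsets of the 26-neighborhood, split by lexicographic (z, y, x) order.
# A voxel is a local maximum iff it is strictly greater than every earlier
# neighbor and >= every later neighbor; on an equal-intensity plateau this
# keeps exactly the lexicographically earliest voxel.
neighbor_offsets3 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  earlier <- (g$dz < 0) |
    (g$dz == 0 & g$dy < 0) |
    (g$dz == 0 & g$dy == 0 & g$dx < 0)
  list(
    earlier = as.matrix(g[earlier, c("dz", "dy", "dx")]),
    later   = as.matrix(g[!earlier, c("dz", "dy", "dx")])
  )
}

#' Logical mask of 26-neighborhood local maxima of a 3D array
#' @noRd
local_maxima3 <- function(a) {
  offs <- neighbor_offsets3()
  is_max <- array(TRUE, dim(a))
  for (i in seq_len(nrow(offs$earlier))) {
    o <- offs$earlier[i, ]
    is_max <- is_max & (a > shift3(a, o[1], o[2], o[3], fill = -Inf))
    if (!any(is_max)) return(is_max)
  }
  for (i in seq_len(nrow(offs$later))) {
    o <- offs$later[i, ]
    is_max <- is_max & (a >= shift3(a, o[1], o[2], o[3], fill = -Inf))
    if (!any(is_max)) return(is_max)
  }
  is_max
}

#' Greedy non-maximum suppression on points
#'
#' Keeps points in decreasing order of `value`, discarding any point closer
#' than `min_sep` (Euclidean, in the units of `coords`) to an already kept
#' point. Ties are broken by original order.
#' @param coords numeric matrix, one point per row.
#' @return integer indices (into rows of `coords`) of the kept points.
#' @noRd
nms_points <- function(coords, value, min_sep) {
  if (nrow(coords) == 0) return(integer(0))
  ord <- order(-value, seq_along(value))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0) {
      kept <- i
      next
    }
    d2 <- colSums((t(coords[kept, , drop = FALSE]) - coords[i, ])^2)
    if (all(d2 >= min_sep^2)) kept <- c(kept, i)
  }
  sort(kept)
}

# Wrap angles (degrees) to (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Shared argument checks -------------------------------------------------

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", what), call. = FALSE)
  }
  invisible(x)
}
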