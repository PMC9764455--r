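#' Multi-channel 3D intensity volume with physical voxel sizes
#'
#' A `VolumeStack` is the substrate of all confocal statistics: a list of
#' named channels (3D arrays indexed `[z, y, x]`, arbitrary units,
#' non-negative) that share a common shape, plus the physical voxel size in
#' micrometres. Physical positions are voxel index (0-based) times voxel
#' size, so all distances computed downstream are in micrometres, never in
#' voxels — confocal z-spacing typically exceeds the xy pixel size and
#' voxel-space distances would be anisotropic.
#'
#' @param channels named list of 3D numeric arrays, all of identical
#'   dimension `c(nz, ny, nx)`.
#' @param voxel_size_um numeric length-3, `c(dz, dy, dx)` in micrometres.
#' @return An object of class `VolumeStack`.
#' @examples
#' vs <- volume_stack(list(rna = array(0, c(4, 8, 8))), c(0.2, 0.1, 0.1))
#' dim_volume(vs)
#' @export
volume_stack <- function(channels, voxel_size_um) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of 3D arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3)) {
    stop("every channel must be a 3D array [z, y, x]")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("all channels must share the same shape")
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stop("`voxel_size_um` must be three positive numbers (dz, dy, dx)")
  }
  structure(
    list(channels = channels, voxel_size_um = voxel_size_um),
    class = "VolumeStack"
  )
}

#' @return `dim_volume`: the shape `c(nz, ny, nx)` of the stack.
#' @rdname volume_stack
#' @param x a `VolumeStack`.
#' @export
dim_volume <- function(x) {
  stopifnot(inherits(x, "VolumeStack"))
  dim(x$channels[[1]])
}

get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "VolumeStack"))
  if (!channel %in% names(stack$channels)) {
    stop(sprintf("unknown channel '%s'; stack has: %s", channel,
                 paste(names(stack$channels), collapse = ", ")))
  }
  stack$channels[[channel]]
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim_volume(x)
  cat(sprintf(
    "VolumeStack: %d channel(s) [%s], %d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    d[1], d[2], d[3],
    x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]
  ))
  invisible(x)
}

#' Read and write volume stacks as multi-page TIFF
#'
#' Each channel is written to `<prefix>_<channel>.tif` as one 32-bit float
#' page per z-slice, with a sidecar JSON (`<prefix>.json`) holding the
#' channel names and voxel size. `read_volume_tiff()` reverses this.
#'
#' @param stack a [volume_stack()].
#' @param prefix path prefix for the output files.
#' @return `write_volume_tiff` returns the sidecar path invisibly;
#'   `read_volume_tiff` returns a `VolumeStack`.
#' @export
write_volume_tiff <- function(stack, prefix) {
  stopifnot(inherits(stack, "VolumeStack"))
  d <- dim_volume(stack)
  scale <- max(1, vapply(stack$channels, max, 0))
  for (ch in names(stack$channels)) {
    pages <- lapply(seq_len(d[1]), function(z) {
      stack$channels[[ch]][z, , ] / scale
    })
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", prefix, ch),
                    bits.per.sample = 32L)
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(channels = names(stack$channels),
         voxel_size_um = stack$voxel_size_um,
         intensity_scale = scale),
    sidecar, auto_unbox = FALSE, digits = NA
  )
  invisible(sidecar)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(ch) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE)
    a <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
    a * meta$intensity_scale
  })
  names(channels) <- meta$channels
  volume_stack(channels, meta$voxel_size_um)
}
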