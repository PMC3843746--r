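#' A single-channel fluorescence z-stack
#'
#' Light container for one acquisition channel of a cell: a 3-D grid of
#' camera counts plus the lateral pixel size and axial step that calibrate
#' it. Coordinates throughout the package are 1-based `(x, y, z)` with pixel
#' centers at integer positions; the voxel array is stored `[y, x, z]` so a
#' single plane is an ordinary `matrix[row = y, col = x]` as returned by
#' [tiff::readTIFF()].
#'
#' @param voxels numeric array of non-negative intensities; a matrix is
#'   promoted to a single-plane stack.
#' @param pixel_size_nm lateral pixel size in nm (default 160).
#' @param z_step_nm spacing between successive planes in nm (default 200).
#' @param channel one of `"donor"`, `"acceptor"`, `"fret"`.
#' @return An object of class `channel_stack`.
#' @examples
#' st <- channel_stack(array(1, dim = c(16, 16, 5)), channel = "donor")
#' dim(st$voxels)
#' @export
channel_stack <- function(voxels, pixel_size_nm = 160, z_step_nm = 200,
                          channel = c("donor", "acceptor", "fret")) {
  channel <- match.arg(channel)
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(dim(voxels), 1L))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a matrix or a 3-D array.", class = "fretcal_input_error")
  }
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    abort("All voxel intensities must be finite.", class = "fretcal_input_error")
  }
  if (any(voxels < 0)) {
    abort("Voxel intensities must be non-negative.", class = "fretcal_input_error")
  }
  d <- dim(voxels)
  if (d[1] < 8L || d[2] < 8L) {
    abort("Stack must be at least 8 x 8 pixels in x and y.",
      class = "fretcal_input_error")
  }
  stopifnot(pixel_size_nm > 0, z_step_nm > 0)
  structure(
    list(voxels = voxels, pixel_size_nm = pixel_size_nm,
         z_step_nm = z_step_nm, channel = channel),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<channel_stack: %s, %d x %d px (%g nm), %d plane%s (%g nm step)>\n",
    x$channel, d[2], d[1], x$pixel_size_nm, d[3],
    if (d[3] == 1) "" else "s", x$z_step_nm
  ))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$voxels)

n_planes <- function(stack) dim(stack$voxels)[3]

#' Extract one plane of a stack as a matrix
#'
#' @param stack a [channel_stack()].
#' @param z 1-based plane index.
#' @return A numeric matrix `[y, x]`.
#' @export
stack_plane <- function(stack, z) {
  stopifnot(inherits(stack, "channel_stack"))
  if (z < 1L || z > n_planes(stack)) {
    abort(sprintf("Plane %d outside stack (1..%d).", z, n_planes(stack)),
      class = "fretcal_input_error")
  }
  stack$voxels[, , z]
}
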