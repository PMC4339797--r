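#' Physical voxel size
#'
#' Records the physical size of one voxel in micrometres along each axis.
#' Confocal stacks are strongly anisotropic (e.g. 0.04 x 0.04 um laterally at
#' 0.3 um slice spacing), and every physical-space computation in the package
#' (filter kernels, centroid coordinates, matching radii) goes through this
#' record rather than assuming cubic voxels.
#'
#' @param dx,dy,dz micrometres per voxel along X, Y and Z; all strictly
#'   positive.
#' @return An object of class `voxel_size` with fields `dx`, `dy`, `dz` and
#'   the recorded `anisotropy` ratio `dz/dx`.
#' @examples
#' voxel_size(0.04, 0.04, 0.3)
#' @export
voxel_size <- function(dx = 0.04, dy = 0.04, dz = 0.3) {
  vals <- c(dx = dx, dy = dy, dz = dz)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("voxel dimensions must be strictly positive and finite")
  structure(list(dx = dx, dy = dy, dz = dz, anisotropy = dz / dx),
            class = "voxel_size")
}

#' @export
print.voxel_size <- function(x, ...) {
  cat(sprintf("voxel size: %g x %g x %g um (x, y, z); anisotropy dz/dx = %g\n",
              x$dx, x$dy, x$dz, x$anisotropy))
  invisible(x)
}

#' 3D image stack
#'
#' The carrier type for raw, filtered and normalized images. Voxels are held
#' in a numeric array indexed `(z, y, x)` — page index equals z, matching
#' slice-by-slice confocal acquisition — with intensities as doubles
#' regardless of the on-disk bit depth.
#'
#' @param voxels 3D numeric array indexed `(z, y, x)`.
#' @param voxel_size a [voxel_size()].
#' @param channel free-text channel name.
#' @param normalized logical; `TRUE` once intensities have been rescaled to
#'   `[0, 1]` by [normalize_filtered()].
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size = smfishq::voxel_size(),
                        channel = "", normalized = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D (z, y, x) array")
  if (dim(voxels)[1] < 1L) stop("stack needs at least one slice")
  if (!inherits(voxel_size, "voxel_size"))
    stop("voxel_size must be a voxel_size object")
  storage.mode(voxels) <- "double"
  if (isTRUE(normalized)) {
    rng <- range(voxels)
    if (rng[1] < 0 || rng[2] > 1)
      stop("normalized stack must have voxel values in [0, 1]")
  }
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 channel = as.character(channel),
                 normalized = isTRUE(normalized)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_stack: %d x %d x %d (z, y, x)%s%s; range [%g, %g]\n",
    d[1], d[2], d[3],
    if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else "",
    if (x$normalized) ", normalized" else "",
    min(x$voxels), max(x$voxels)))
  print(x$voxel_size)
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Read a multi-page TIFF stack
#'
#' Reads a multi-page grayscale TIFF into an [image_stack()], promoting 8/16
#' bit pages to doubles. The voxel size comes from the `voxel_size` argument
#' if given, otherwise from the JSON sidecar `<path>.meta.json` written by
#' [write_stack()]; it is an error if neither source provides it.
#'
#' @param path TIFF file path.
#' @param voxel_size optional [voxel_size()] overriding any sidecar.
#' @return An [image_stack()] with `Z` equal to the page count.
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # 8/16-bit pages are integer data: take the raw counts. 32-bit pages are
  # float: readTIFF already returns the stored values (as.is would corrupt
  # them by rescaling as if integer).
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits < 32L) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent page shape across TIFF pages")
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(voxel_size)) {
    if (is.null(meta))
      stop("voxel size not supplied and no sidecar found at ", sp)
    voxel_size <- voxel_size(meta$dx_um, meta$dy_um, meta$dz_um)
  }
  z <- length(pages)
  vox <- array(0, dim = c(z, shapes[1, 1], shapes[2, 1]))
  for (k in seq_len(z)) vox[k, , ] <- pages[[k]]
  # float pages were written min/max scaled into [0,1]; undo via sidecar range
  if (!is.null(meta) && identical(meta$storage, "float32"))
    vox <- vox * (meta$vmax - meta$vmin) + meta$vmin
  image_stack(vox, voxel_size,
              channel = if (!is.null(meta)) meta$channel else "",
              normalized = !is.null(meta) && isTRUE(meta$normalized))
}

#' Write a stack as multi-page TIFF plus JSON sidecar
#'
#' Non-negative integer-valued stacks up to 65535 are stored as 16-bit
#' integer pages (bit-exact round trip); anything else is min/max scaled into
#' `[0, 1]` and stored as 32-bit float pages, with the original range kept in
#' the sidecar (round trip to single precision). The sidecar
#' `<path>.meta.json` records `dx_um`, `dy_um`, `dz_um`, `channel`,
#' `normalized` and the storage scheme.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  is_int <- min(v) >= 0 && max(v) <= 65535 && all(v == round(v))
  meta <- list(dx_um = stack$voxel_size$dx, dy_um = stack$voxel_size$dy,
               dz_um = stack$voxel_size$dz, channel = stack$channel,
               normalized = stack$normalized)
  if (is_int) {
    pages <- lapply(seq_len(d[1]), function(k) v[k, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    meta$storage <- "uint16"
  } else {
    vmin <- min(v); vmax <- max(v)
    den <- if (vmax > vmin) vmax - vmin else 1
    pages <- lapply(seq_len(d[1]), function(k) (v[k, , ] - vmin) / den)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    meta$storage <- "float32"
    meta$vmin <- vmin
    meta$vmax <- vmin + den
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
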