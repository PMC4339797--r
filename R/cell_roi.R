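#' Per-cell border polygons
#'
#' A cell border is drawn slice by slice, so a ROI is a map from z-index to a
#' closed polygon in the `(y, x)` pixel plane. All coordinates are 0-based:
#' voxel centers sit at integer `(y, x)` positions and z indexes pages from
#' 0, matching the on-disk `rois.json` schema. There is no interpolation
#' between slices; a slice without a polygon contributes nothing to the mask.
#'
#' @param cell_id identifier (coerced to character).
#' @param slices named list mapping z-index (name, 0-based) to an `n x 2`
#'   matrix of `(y, x)` vertices (0-based pixel coordinates, implicitly
#'   closed, at least 3 vertices, non-self-intersecting).
#' @return An object of class `cell_roi`.
#' @export
cell_roi <- function(cell_id, slices) {
  stopifnot(is.list(slices))
  if (length(slices) && is.null(names(slices)))
    stop("slices must be named by 0-based z-index")
  slices <- lapply(slices, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("polygon needs an n x 2 (y, x) matrix with >= 3 vertices")
    storage.mode(p) <- "double"
    p
  })
  structure(list(cell_id = as.character(cell_id), slices = slices),
            class = "cell_roi")
}

#' Read / write ROI interchange files
#'
#' `rois.json` holds a list of `{cell_id, slices: {"<z>": [[y, x], ...]}}`
#' objects with 0-based coordinates — the file format that replaces
#' interactive border drawing and lets external annotation tools supply cell
#' outlines.
#'
#' @param path JSON file path.
#' @return `read_rois()`: a list of [cell_roi()] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("no such ROI file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    slices <- lapply(r$slices, function(vs)
      do.call(rbind, lapply(vs, function(v) c(v[[1]], v[[2]]))))
    cell_roi(r$cell_id, slices)
  })
}

#' @rdname read_rois
#' @param rois list of [cell_roi()] objects.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r) {
    list(cell_id = r$cell_id,
         slices = lapply(r$slices, function(p)
           lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd (crossing-number) point-in-polygon, vectorized over points.
# Points exactly on an edge count as inside (boundary-inclusive), detected
# via collinearity within eps before the parity test.
point_in_polygon <- function(py, px, poly, eps = 1e-9) {
  ny <- poly[, 1]; nx <- poly[, 2]
  n <- length(ny)
  jj <- c(n, seq_len(n - 1L))
  inside <- logical(length(py))
  onedge <- logical(length(py))
  for (i in seq_len(n)) {
    y1 <- ny[i]; x1 <- nx[i]; y2 <- ny[jj[i]]; x2 <- nx[jj[i]]
    # boundary: point within the segment's bounding box and collinear
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg <- abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps
    onedge <- onedge | seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' Rasterize a cell ROI to a 3D mask
#'
#' A voxel `(z, y, x)` is inside the mask iff slice `z` carries a polygon and
#' the voxel center — at integer 0-based `(y, x)` — lies inside it under the
#' even-odd rule; points exactly on the border count as inside. Slices with
#' no polygon are all-false, as are polygon parts outside the frame.
#'
#' @param roi a [cell_roi()].
#' @param shape integer `(Z, Y, X)` of the target stack.
#' @return An object of class `mask_volume`: list with logical 3D `mask` and
#'   `cell_id`.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "cell_roi"), length(shape) == 3L)
  zi <- as.integer(names(roi$slices))
  if (length(zi) && any(zi < 0 | zi >= shape[1]))
    stop("ROI z-index outside stack range")
  mask <- array(FALSE, dim = shape)
  for (k in seq_along(roi$slices)) {
    poly <- roi$slices[[k]]
    if (abs(polygon_area(poly)) < .Machine$double.eps)
      stop("degenerate (zero-area) polygon in cell ", roi$cell_id)
    ylo <- max(0L, floor(min(poly[, 1]))); yhi <- min(shape[2] - 1L, ceiling(max(poly[, 1])))
    xlo <- max(0L, floor(min(poly[, 2]))); xhi <- min(shape[3] - 1L, ceiling(max(poly[, 2])))
    if (ylo > yhi || xlo > xhi) next          # polygon entirely out of frame
    ys <- ylo:yhi; xs <- xlo:xhi
    grid <- expand.grid(y = ys, x = xs)
    inside <- point_in_polygon(grid$y, grid$x, poly)
    sl <- matrix(FALSE, shape[2], shape[3])
    sl[cbind(grid$y + 1L, grid$x + 1L)] <- inside
    mask[zi[k] + 1L, , ] <- sl
  }
  structure(list(mask = mask, cell_id = roi$cell_id), class = "mask_volume")
}

polygon_area <- function(poly) {
  y <- poly[, 1]; x <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Mask a stack with a cell's 3D border image
#'
#' Voxels inside the mask are unchanged; voxels outside are set to exactly 0.
#' Idempotent: masking twice equals masking once.
#'
#' @param stack an [image_stack()].
#' @param mask a `mask_volume` from [rasterize_roi()] (or a logical array of
#'   matching shape).
#' @return The masked [image_stack()].
#' @export
apply_mask <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"))
  m <- if (inherits(mask, "mask_volume")) mask$mask else mask
  if (!identical(dim(m), dim(stack$voxels)))
    stop("mask shape does not match stack shape")
  out <- stack$voxels
  out[!m] <- 0
  image_stack(out, stack$voxel_size, channel = stack$channel,
              normalized = stack$normalized)
}
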