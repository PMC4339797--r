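#' Label connected components in a 3D binary image
#'
#' Maximal connected sets of `TRUE` voxels under 6-, 18- or 26-neighbor
#' adjacency. The default used throughout the package is 26: with 0.3 um
#' slices over 0.04 um pixels, the voxels of one diffraction-limited dot
#' commonly touch only diagonally between z slices.
#'
#' @param binary 3D logical array `(z, y, x)`.
#' @param connectivity 6, 18 or 26.
#' @return `list(labels = integer array with 0 background and components
#'   numbered 1..count, count = number of components)`.
#' @export
label_components <- function(binary, connectivity = 26L) {
  if (!is.array(binary) || length(dim(binary)) != 3L)
    stop("binary must be a 3D array")
  res <- label_components_cpp(as.logical(binary), dim(binary),
                              as.integer(connectivity))
  res$labels <- array(res$labels, dim = dim(binary))
  res
}

#' Threshold sweep: component counts over a uniform threshold grid
#'
#' Counts connected components of `filtered > t` for the uniform grid
#' `t_k = k / n_thresholds`, `k = 1..n_thresholds`, on the normalized
#' `[0, 1]` scale — the 100-point curve from which a counting threshold is
#' selected. If a mask is given it is applied before thresholding.
#'
#' @param filtered a normalized [image_stack()] (see [normalize_filtered()]).
#' @param mask optional `mask_volume` or logical array.
#' @param n_thresholds number of grid points (default 100).
#' @param connectivity voxel adjacency for [label_components()].
#' @return An object of class `threshold_sweep`: data-frame-like list with
#'   `thresholds`, `counts`, and unset selection fields (see
#'   [select_threshold()]).
#' @export
threshold_sweep <- function(filtered, mask = NULL, n_thresholds = 100L,
                            connectivity = 26L) {
  stopifnot(inherits(filtered, "image_stack"))
  if (!filtered$normalized)
    stop("threshold_sweep requires a normalized stack")
  if (n_thresholds < 1L) stop("n_thresholds must be >= 1")
  if (!is.null(mask)) filtered <- apply_mask(filtered, mask)
  th <- seq_len(n_thresholds) / n_thresholds
  counts <- sweep_counts_cpp(as.numeric(filtered$voxels),
                             dim(filtered$voxels), th,
                             as.integer(connectivity))
  structure(list(thresholds = th, counts = counts,
                 selected_threshold = NA_real_, selected_count = NA_integer_,
                 selection_mode = NA_character_,
                 connectivity = as.integer(connectivity)),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("threshold sweep: %d thresholds, counts %d..%d\n",
              length(x$thresholds), min(x$counts), max(x$counts)))
  if (!is.na(x$selected_threshold))
    cat(sprintf("  selected (%s): threshold %.3f -> %d components\n",
                x$selection_mode, x$selected_threshold, x$selected_count))
  invisible(x)
}

#' Select the counting threshold from a sweep
#'
#' `"plateau"` mode automates the by-eye choice of the threshold whose dot
#' count is stable. Candidate plateaus are runs of at least `min_plateau`
#' consecutive thresholds with identical nonzero component count; among
#' them, the run maximizing `run length x count` is chosen (ties toward the
#' lower threshold) and its midpoint returned. Scoring by length alone is
#' not enough: whenever one dot is about twice as bright as the rest (a
#' conglomerate, which also sets the normalization ceiling), the interval
#' where only that dot survives is a long flat run at count 1 that would
#' beat the true counting plateau; weighting by the supported count restores
#' the plateau where the dots actually live, while noise-dominated regions
#' change count at almost every grid step and never form qualifying runs.
#' If no run qualifies, the modal nonzero count is used and the midpoint of
#' its first run returned. If every count is zero the result is the explicit
#' "no spots" outcome with count 0. `"manual"` mode takes `manual_value`,
#' which must be one of the grid thresholds.
#'
#' @param sweep a [threshold_sweep()].
#' @param mode `"plateau"` or `"manual"`.
#' @param manual_value the threshold to use in manual mode.
#' @param min_plateau minimum run length that counts as a plateau.
#' @return The sweep with `selected_threshold`, `selected_count` and
#'   `selection_mode` filled.
#' @export
select_threshold <- function(sweep, mode = c("plateau", "manual"),
                             manual_value = NULL, min_plateau = 3L) {
  stopifnot(inherits(sweep, "threshold_sweep"))
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(manual_value) ||
        !any(abs(sweep$thresholds - manual_value) < 1e-12))
      stop("manual_value must be one of the sweep thresholds")
    k <- which.min(abs(sweep$thresholds - manual_value))
    sweep$selected_threshold <- sweep$thresholds[k]
    sweep$selected_count <- sweep$counts[k]
    sweep$selection_mode <- "manual"
    return(sweep)
  }
  counts <- sweep$counts
  if (all(counts == 0L)) {
    sweep$selected_threshold <- NA_real_
    sweep$selected_count <- 0L
    sweep$selection_mode <- "plateau"
    return(sweep)
  }
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values > 0L
  best <- NULL
  if (any(ok & r$lengths >= min_plateau)) {
    cand <- which(ok & r$lengths >= min_plateau)
    score <- as.numeric(r$lengths[cand]) * r$values[cand]
    best <- cand[which.max(score)]             # ties: first = lowest threshold
  } else {
    tab <- tapply(r$lengths[ok], r$values[ok], sum)
    modal <- as.integer(names(tab)[which.max(tab)])
    best <- which(ok & r$values == modal)[1L]
  }
  mid <- (starts[best] + ends[best]) %/% 2L
  sweep$selected_threshold <- sweep$thresholds[mid]
  sweep$selected_count <- sweep$counts[mid]
  sweep$selection_mode <- "plateau"
  sweep
}

# Per-component centroids / sizes / mean intensities from a label array.
# `origin` is the 0-based (z, y, x) offset of the cropped array in the full
# stack; centroids are intensity-weighted.
component_table <- function(labels, values, count, origin, vs) {
  if (count == 0L)
    return(data.frame(spot_id = integer(0), cell_id = character(0),
                      z = numeric(0), y = numeric(0), x = numeric(0),
                      z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                      voxel_count = integer(0), mean_intensity = numeric(0),
                      conglomerate = logical(0)))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  v <- values[idx]
  d <- dim(labels)
  z0 <- (idx - 1L) %% d[1]
  rest <- (idx - 1L) %/% d[1]
  y0 <- rest %% d[2]
  x0 <- rest %/% d[2]
  wsum <- rowsum(v, lab)
  zc <- rowsum(v * z0, lab) / wsum + origin[1]
  yc <- rowsum(v * y0, lab) / wsum + origin[2]
  xc <- rowsum(v * x0, lab) / wsum + origin[3]
  nvox <- as.integer(rowsum(rep(1L, length(lab)), lab))
  data.frame(spot_id = seq_len(count), cell_id = NA_character_,
             z = as.numeric(zc), y = as.numeric(yc), x = as.numeric(xc),
             z_um = as.numeric(zc) * vs$dz, y_um = as.numeric(yc) * vs$dy,
             x_um = as.numeric(xc) * vs$dx,
             voxel_count = nvox,
             mean_intensity = as.numeric(wsum) / nvox,
             conglomerate = FALSE)
}

# Tight 0-based bounding box of a logical array, NULL when empty.
mask_bbox <- function(m) {
  w <- which(m)
  if (!length(w)) return(NULL)
  d <- dim(m)
  z <- (w - 1L) %% d[1]
  rest <- (w - 1L) %/% d[1]
  y <- rest %% d[2]
  x <- rest %/% d[2]
  rbind(lo = c(min(z), min(y), min(x)), hi = c(max(z), max(y), max(x)))
}

#' Count transcripts per cell via mask, sweep and plateau selection
#'
#' For each cell: mask the normalized filtered stack with the cell's
#' rasterized border, run the threshold sweep inside it, select the counting
#' threshold, and label components at that threshold. Each component is one
#' transcript dot; the spot table records intensity-weighted centroids in
#' voxel and physical (um) coordinates, voxel counts and mean normalized
#' intensities. Overlapping ROIs are reported and resolved first-come: a
#' voxel belongs to the first cell that claims it.
#'
#' @param filtered a normalized [image_stack()].
#' @param rois list of [cell_roi()].
#' @param mode,manual_value,min_plateau see [select_threshold()].
#' @param n_thresholds,connectivity see [threshold_sweep()].
#' @param min_voxels drop components smaller than this many voxels; the
#'   default 1 keeps everything (no size filter).
#' @param embryo_id identifier copied into the results.
#' @return `list(cell_counts = data.frame(embryo_id, cell_id, threshold,
#'   transcript_count), spots = spot table, sweeps = named list of
#'   threshold_sweep)`.
#' @export
count_per_cell <- function(filtered, rois, mode = "plateau",
                           manual_value = NULL, n_thresholds = 100L,
                           connectivity = 26L, min_plateau = 3L,
                           min_voxels = 1L, embryo_id = "embryo1") {
  stopifnot(inherits(filtered, "image_stack"))
  if (!filtered$normalized) stop("count_per_cell requires a normalized stack")
  shp <- dim(filtered$voxels)
  claimed <- array(FALSE, dim = shp)
  cell_counts <- NULL; spots <- NULL; sweeps <- list()
  next_id <- 1L
  for (roi in rois) {
    m <- rasterize_roi(roi, shp)$mask
    if (any(m & claimed)) {
      warning("ROI '", roi$cell_id,
              "' overlaps a previous cell; first-come ownership applied")
      m <- m & !claimed
    }
    claimed <- claimed | m
    bb <- mask_bbox(m)
    if (is.null(bb)) {
      sw <- NULL
      sel_count <- 0L; sel_thresh <- NA_real_
      tab <- component_table(array(0L, c(1, 1, 1)), array(0, c(1, 1, 1)),
                             0L, c(0, 0, 0), filtered$voxel_size)
    } else {
      sub <- filtered$voxels[(bb[1, 1]:bb[2, 1]) + 1L,
                             (bb[1, 2]:bb[2, 2]) + 1L,
                             (bb[1, 3]:bb[2, 3]) + 1L, drop = FALSE]
      msub <- m[(bb[1, 1]:bb[2, 1]) + 1L, (bb[1, 2]:bb[2, 2]) + 1L,
                (bb[1, 3]:bb[2, 3]) + 1L, drop = FALSE]
      sub[!msub] <- 0
      substack <- image_stack(sub, filtered$voxel_size,
                              channel = filtered$channel, normalized = TRUE)
      sw <- threshold_sweep(substack, n_thresholds = n_thresholds,
                            connectivity = connectivity)
      sw <- select_threshold(sw, mode = mode, manual_value = manual_value,
                             min_plateau = min_plateau)
      sel_thresh <- sw$selected_threshold
      if (is.na(sel_thresh)) {
        sel_count <- 0L
        tab <- component_table(array(0L, c(1, 1, 1)), array(0, c(1, 1, 1)),
                               0L, c(0, 0, 0), filtered$voxel_size)
      } else {
        lab <- label_components(sub > sel_thresh, connectivity)
        tab <- component_table(lab$labels, sub, lab$count, bb[1, ],
                               filtered$voxel_size)
        if (min_voxels > 1L) tab <- tab[tab$voxel_count >= min_voxels, ]
        sel_count <- nrow(tab)
      }
    }
    if (nrow(tab)) {
      tab$cell_id <- roi$cell_id
      tab$spot_id <- seq.int(next_id, length.out = nrow(tab))
      next_id <- next_id + nrow(tab)
    }
    spots <- rbind(spots, tab)
    sweeps[[roi$cell_id]] <- sw
    cell_counts <- rbind(cell_counts, data.frame(
      embryo_id = embryo_id, cell_id = roi$cell_id,
      threshold = sel_thresh, transcript_count = as.integer(sel_count)))
  }
  if (is.null(spots))
    spots <- component_table(array(0L, c(1, 1, 1)), array(0, c(1, 1, 1)),
                             0L, c(0, 0, 0), filtered$voxel_size)
  list(cell_counts = cell_counts, spots = spots, sweeps = sweeps)
}

#' Measure dot intensities at a fixed threshold
#'
#' Applies one fixed threshold (default 0.25) to a normalized filtered stack
#' — the same threshold for all equally filtered images — labels the
#' components, and reports each dot's mean normalized voxel intensity. This
#' is the input to [classify_conglomerates()].
#'
#' @inheritParams count_per_cell
#' @param fixed_threshold threshold on the normalized `[0, 1]` scale.
#' @param mask optional `mask_volume` or logical array.
#' @return A spot table (see [count_per_cell()]).
#' @export
measure_dot_intensities <- function(filtered, fixed_threshold = 0.25,
                                    mask = NULL, connectivity = 26L) {
  stopifnot(inherits(filtered, "image_stack"))
  if (!filtered$normalized)
    stop("measure_dot_intensities requires a normalized stack")
  if (!is.null(mask)) filtered <- apply_mask(filtered, mask)
  v <- filtered$voxels
  lab <- label_components(v > fixed_threshold, connectivity)
  tab <- component_table(lab$labels, v, lab$count, c(0, 0, 0),
                         filtered$voxel_size)
  if (inherits(mask, "mask_volume") && nrow(tab)) tab$cell_id <- mask$cell_id
  tab
}

#' Flag conglomerate dots at twice the modal intensity
#'
#' Bins the dots' mean intensities (bin width 0.05), takes the modal bin
#' center `m` as the single-transcript intensity, and flags every dot whose
#' mean intensity reaches `fold * m * (1 - tol)` or more as a conglomerate —
#' an unresolved pair of transcripts appearing as one dot of about twice the
#' unit brightness.
#'
#' @param spots a spot table with a `mean_intensity` column.
#' @param bin_width intensity histogram bin width.
#' @param fold intensity fold-change defining a conglomerate.
#' @param tol relative tolerance around `fold * m`.
#' @return `list(spots = table with `conglomerate` flags set,
#'   modal_intensity, n, n_flagged, pct_flagged)` with `pct_flagged` in
#'   percent, rounded to one decimal.
#' @export
classify_conglomerates <- function(spots, bin_width = 0.05, fold = 2.0,
                                   tol = 0.15) {
  if (is.null(spots) || nrow(spots) == 0L) stop("empty spot table")
  mi <- spots$mean_intensity
  bins <- pmin(floor(mi / bin_width), ceiling(1 / bin_width) - 1L)
  tab <- table(bins)
  modal_bin <- as.numeric(names(tab)[which.max(tab)])  # ties: lowest bin
  m <- (modal_bin + 0.5) * bin_width
  flagged <- mi >= fold * m * (1 - tol)
  spots$conglomerate <- flagged
  list(spots = spots, modal_intensity = m, n = length(mi),
       n_flagged = sum(flagged),
       pct_flagged = round(100 * mean(flagged), 1))
}

#' Two-channel colocalization efficiency
#'
#' Matches dots across channels one-to-one, greedily by ascending pairwise
#' physical distance (equivalently, repeatedly pairing mutual nearest
#' neighbors), accepting pairs within `radius`. The detection efficiency in
#' each direction is the fraction of one channel's dots that found a partner
#' in the other.
#'
#' @param spots_a,spots_b spot tables with `z_um`, `y_um`, `x_um` columns
#'   from the same voxel grid.
#' @param radius matching radius in um (about 3x the lateral PSF sigma by
#'   default).
#' @return `list(efficiency_a_to_b, efficiency_b_to_a, matches =
#'   data.frame(a, b, dist_um), n_a, n_b)`. With an empty reference table the
#'   corresponding efficiency is `NA` ("no reference dots").
#' @export
colocalize <- function(spots_a, spots_b, radius = 0.3) {
  n_a <- if (is.null(spots_a)) 0L else nrow(spots_a)
  n_b <- if (is.null(spots_b)) 0L else nrow(spots_b)
  matches <- data.frame(a = integer(0), b = integer(0), dist_um = numeric(0))
  if (n_a > 0L && n_b > 0L) {
    d2 <- outer(spots_a$z_um, spots_b$z_um, `-`)^2 +
          outer(spots_a$y_um, spots_b$y_um, `-`)^2 +
          outer(spots_a$x_um, spots_b$x_um, `-`)^2
    cand <- which(d2 <= radius^2)
    if (length(cand)) {
      ord <- cand[order(d2[cand])]
      used_a <- logical(n_a); used_b <- logical(n_b)
      ai <- (ord - 1L) %% n_a + 1L
      bi <- (ord - 1L) %/% n_a + 1L
      keep_a <- integer(0); keep_b <- integer(0); keep_d <- numeric(0)
      for (k in seq_along(ord)) {
        if (used_a[ai[k]] || used_b[bi[k]]) next
        used_a[ai[k]] <- TRUE; used_b[bi[k]] <- TRUE
        keep_a <- c(keep_a, ai[k]); keep_b <- c(keep_b, bi[k])
        keep_d <- c(keep_d, sqrt(d2[ord[k]]))
      }
      matches <- data.frame(a = keep_a, b = keep_b, dist_um = keep_d)
    }
  }
  list(efficiency_a_to_b = if (n_a) nrow(matches) / n_a else NA_real_,
       efficiency_b_to_a = if (n_b) nrow(matches) / n_b else NA_real_,
       matches = matches, n_a = n_a, n_b = n_b)
}
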