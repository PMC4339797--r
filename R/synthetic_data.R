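#' Simulation parameters for synthetic smFISH stacks
#'
#' Describes a synthetic whole-mount imaging experiment: cells tiled on the
#' XY plane, each containing diffraction-limited dots rendered as anisotropic
#' 3D Gaussians over an autofluorescent background with shot and read noise.
#' Defaults emulate a high-NA confocal acquisition (0.04 x 0.04 x 0.3 um
#' voxels) at a signal level where single dots are clearly resolvable.
#'
#' @param image_shape integer `(Z, Y, X)` in voxels.
#' @param voxel_size a [voxel_size()].
#' @param n_cells number of cells tiled (non-overlapping) in XY.
#' @param spots_per_cell either a fixed count, or
#'   `list(family = <name>, params = list(...))` with `family` one of
#'   `"normal"`, `"gamma"`, `"logistic"`, `"weibull"`, `"poisson"` — per-cell
#'   counts are then drawn via [sample_cell_counts()].
#' @param psf_sigma_xy,psf_sigma_z Gaussian point-spread sigmas, um. The
#'   axial default exceeds the 0.3 um slice spacing so every dot spans more
#'   than one z slice.
#' @param spot_amplitude mean photon amplitude at a dot's peak.
#' @param amplitude_jitter_sdlog lognormal sdlog of per-dot amplitude jitter
#'   (0.1 gives roughly +/-10%, producing the tight modal intensity peak seen
#'   in well-behaved smFISH data).
#' @param conglomerate_fraction probability that a dot is a conglomerate of
#'   two transcripts and is rendered at twice the amplitude.
#' @param background_level mean autofluorescence (photons).
#' @param background_gradient fractional linear ramp of the background across
#'   X (0.2 = +/-10% end to end), emulating uneven illumination.
#' @param read_noise_sd additive Gaussian camera noise, photons.
#' @param shot_noise logical; Poisson-resample the expected photon image.
#' @param channel_dropout probability that a true dot is absent from channel
#'   B in a two-channel experiment.
#' @param min_separation_um minimum pairwise distance between dot centers
#'   within a cell, measured in a resolution-normalized metric: axial
#'   distances are scaled by `psf_sigma_xy / psf_sigma_z` before combining
#'   with the lateral ones, so 0.6 um lateral and 2.1 um axial are equally
#'   "separated". This keeps simulated dots individually resolvable in the
#'   anisotropic optics (a plain Euclidean minimum would let dots sit one
#'   slice apart in z and merge into single components).
#' @param seed RNG seed; the same seed gives bit-identical output.
#' @return An object of class `sim_params`.
#' @section Random draw order: one global RNG stream seeded once, consumed in
#'   a fixed order so individual draws can be replayed: per-cell counts (only
#'   if `spots_per_cell` is distributional), conglomerate flags
#'   (`runif(N) < conglomerate_fraction`), channel-B presence flags
#'   (`runif(N) < 1 - channel_dropout`), cell polygons, dot positions (dart
#'   throwing), amplitude jitter, then shot noise / read noise for channel A
#'   and (two-channel only) channel B.
#' @export
sim_params <- function(image_shape = c(24L, 384L, 384L),
                       voxel_size = smfishq::voxel_size(0.04, 0.04, 0.3),
                       n_cells = 4L,
                       spots_per_cell = 50L,
                       psf_sigma_xy = 0.1,
                       psf_sigma_z = 0.35,
                       spot_amplitude = 150,
                       amplitude_jitter_sdlog = 0.1,
                       conglomerate_fraction = 0.004,
                       background_level = 20,
                       background_gradient = 0.2,
                       read_noise_sd = 2,
                       shot_noise = TRUE,
                       channel_dropout = 0.2,
                       min_separation_um = 0.6,
                       seed = 1L) {
  p <- list(image_shape = as.integer(image_shape), voxel_size = voxel_size,
            n_cells = as.integer(n_cells), spots_per_cell = spots_per_cell,
            psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
            spot_amplitude = spot_amplitude,
            amplitude_jitter_sdlog = amplitude_jitter_sdlog,
            conglomerate_fraction = conglomerate_fraction,
            background_level = background_level,
            background_gradient = background_gradient,
            read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
            channel_dropout = channel_dropout,
            min_separation_um = min_separation_um, seed = as.integer(seed))
  probs <- c(p$conglomerate_fraction, p$channel_dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$psf_sigma_xy <= 0 || p$psf_sigma_z <= 0) stop("PSF sigmas must be positive")
  if (p$spot_amplitude <= 0) stop("spot amplitude must be positive")
  if (p$background_level < 0 || p$read_noise_sd < 0)
    stop("background and read noise must be non-negative")
  if (length(p$image_shape) != 3L || any(p$image_shape < 1L))
    stop("image_shape must be positive (Z, Y, X)")
  structure(p, class = "sim_params")
}

# Perturbed regular 12-gons tiled on a ceiling(sqrt(n)) grid, replicated over
# a z interval that leaves room for the axial PSF support. Consumes RNG.
generate_cell_rois <- function(p) {
  shp <- p$image_shape
  mz <- as.integer(ceiling(4 * p$psf_sigma_z / p$voxel_size$dz))
  zlo <- mz; zhi <- shp[1] - 1L - mz
  if (zhi < zlo) stop("stack too shallow for the axial PSF support")
  gx <- ceiling(sqrt(p$n_cells)); gy <- ceiling(p$n_cells / gx)
  tw <- (shp[3] - 1) / gx; th <- (shp[2] - 1) / gy
  mxy <- ceiling(4 * p$psf_sigma_xy / p$voxel_size$dx)
  r <- 0.40 * min(tw, th)
  if (min(tw, th) / 2 - r < mxy)
    stop("cells cannot fit in the frame with the lateral PSF margin")
  nv <- 12L
  rois <- vector("list", p$n_cells)
  for (i in seq_len(p$n_cells)) {
    cx <- ((i - 1) %% gx + 0.5) * tw
    cy <- ((i - 1) %/% gx + 0.5) * th
    rot <- runif(1, 0, 2 * pi / nv)
    rad <- r * runif(nv, 0.85, 1.0)
    ang <- rot + 2 * pi * (0:(nv - 1)) / nv
    poly <- cbind(cy + rad * sin(ang), cx + rad * cos(ang))
    slices <- rep(list(poly), zhi - zlo + 1L)
    names(slices) <- as.character(zlo:zhi)
    rois[[i]] <- cell_roi(paste0("cell", i), slices)
  }
  rois
}

# Dart-throwing placement inside a shrunken polygon with a pairwise physical
# minimum distance; consumes a data-dependent number of RNG draws.
place_spots <- function(poly, zlo, zhi, n, p, mask) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  ctr <- colMeans(poly)
  shrunk <- sweep(sweep(poly, 2, ctr) * 0.85, 2, ctr, `+`)
  vs <- p$voxel_size
  pos <- matrix(NA_real_, n, 3)
  got <- 0L; tries <- 0L
  ylim <- range(shrunk[, 1]); xlim <- range(shrunk[, 2])
  while (got < n) {
    tries <- tries + 1L
    if (tries > 50000L)
      stop("could not place ", n, " spots at the requested separation")
    zc <- runif(1, zlo + 0.2, zhi - 0.2)
    yc <- runif(1, ylim[1], ylim[2])
    xc <- runif(1, xlim[1], xlim[2])
    if (!point_in_polygon(yc, xc, shrunk)) next
    if (!mask[round(zc) + 1L, round(yc) + 1L, round(xc) + 1L]) next
    if (got > 0L) {
      zscale <- p$psf_sigma_xy / p$psf_sigma_z
      d2 <- ((pos[seq_len(got), 1] - zc) * vs$dz * zscale)^2 +
            ((pos[seq_len(got), 2] - yc) * vs$dy)^2 +
            ((pos[seq_len(got), 3] - xc) * vs$dx)^2
      if (min(d2) < p$min_separation_um^2) next
    }
    got <- got + 1L
    pos[got, ] <- c(zc, yc, xc)
  }
  pos
}

simulate_core <- function(p) {
  set.seed(p$seed)
  shp <- p$image_shape
  # per-cell true dot counts
  if (is.list(p$spots_per_cell)) {
    counts <- sample_cell_counts(p$spots_per_cell$family,
                                 p$spots_per_cell$params, p$n_cells)
  } else {
    counts <- rep(as.integer(p$spots_per_cell), p$n_cells)
  }
  ntot <- sum(counts)
  conglomerate <- runif(ntot) < p$conglomerate_fraction
  present_in_b <- runif(ntot) < 1 - p$channel_dropout
  rois <- generate_cell_rois(p)
  masks <- lapply(rois, rasterize_roi, shape = shp)
  zidx <- as.integer(names(rois[[1]]$slices))
  zlo <- min(zidx); zhi <- max(zidx)
  pos <- matrix(numeric(0), 0, 3); cell_of <- integer(0)
  for (i in seq_len(p$n_cells)) {
    pos <- rbind(pos, place_spots(rois[[i]]$slices[[1]], zlo, zhi, counts[i],
                                  p, masks[[i]]$mask))
    cell_of <- c(cell_of, rep(i, counts[i]))
  }
  amp <- p$spot_amplitude * rlnorm(ntot, 0, p$amplitude_jitter_sdlog)
  amp <- amp * ifelse(conglomerate, 2, 1)
  spots <- data.frame(
    spot_id = seq_len(ntot),
    cell_id = if (ntot) vapply(cell_of, function(i) rois[[i]]$cell_id, "") else character(0),
    z = pos[, 1], y = pos[, 2], x = pos[, 3],
    amplitude = amp, conglomerate = conglomerate,
    present_in_b = present_in_b)
  per_cell <- data.frame(
    cell_id = vapply(rois, `[[`, "", "cell_id"),
    true_count = as.integer(counts))
  list(p = p, spots = spots, rois = rois, masks = masks, per_cell = per_cell)
}

# Expected photon image: ramped background plus one anisotropic Gaussian per
# dot. Dots are accumulated on a flat vector through linear indices so each
# spot touches only its own ~4*sigma window rather than copying the stack.
expected_image <- function(core, which_spots) {
  p <- core$p; shp <- p$image_shape
  nz <- shp[1]; ny <- shp[2]; nx <- shp[3]
  xramp <- p$background_level * p$background_gradient *
    ((seq_len(nx) - 1) / max(1, nx - 1) - 0.5)
  v <- rep(p$background_level + xramp, each = nz * ny)
  sp <- core$spots[which_spots, , drop = FALSE]
  vs <- p$voxel_size
  sz <- p$psf_sigma_z / vs$dz; sy <- p$psf_sigma_xy / vs$dy
  sx <- p$psf_sigma_xy / vs$dx
  for (i in seq_len(nrow(sp))) {
    zc <- sp$z[i]; yc <- sp$y[i]; xc <- sp$x[i]
    zr <- max(0, floor(zc - 4 * sz)):min(nz - 1, ceiling(zc + 4 * sz))
    yr <- max(0, floor(yc - 4 * sy)):min(ny - 1, ceiling(yc + 4 * sy))
    xr <- max(0, floor(xc - 4 * sx)):min(nx - 1, ceiling(xc + 4 * sx))
    gz <- exp(-(zr - zc)^2 / (2 * sz^2))
    gy <- exp(-(yr - yc)^2 / (2 * sy^2))
    gx <- exp(-(xr - xc)^2 / (2 * sx^2))
    idx <- outer(outer(zr + 1, nz * yr, `+`), nz * ny * xr, `+`)
    v[idx] <- v[idx] + sp$amplitude[i] * outer(outer(gz, gy), gx)
  }
  array(v, dim = shp)
}

add_noise <- function(img, p) {
  v <- as.numeric(img)
  if (p$shot_noise) v <- rpois(length(v), v)
  if (p$read_noise_sd > 0) v <- v + rnorm(length(v), 0, p$read_noise_sd)
  array(pmax(v, 0), dim = dim(img))
}

ground_truth <- function(core) {
  list(spots = core$spots, cell_rois = core$rois,
       per_cell_counts = core$per_cell)
}

#' Simulate a single-channel smFISH stack with ground truth
#'
#' Renders every true dot as an anisotropic 3D Gaussian inside its cell's
#' polygon mask, adds an autofluorescent background with a linear ramp across
#' X, then Poisson shot noise and Gaussian read noise. The returned ground
#' truth carries every dot's cell, sub-voxel centroid, amplitude,
#' conglomerate flag and channel-B presence flag, plus the generating ROIs
#' and per-cell true counts.
#'
#' @param params a [sim_params()].
#' @return `list(stack = image_stack, truth = list(spots, cell_rois,
#'   per_cell_counts))`.
#' @export
simulate_stack <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  core <- simulate_core(params)
  img <- add_noise(expected_image(core, seq_len(nrow(core$spots))), params)
  list(stack = image_stack(img, params$voxel_size, channel = "A"),
       truth = ground_truth(core))
}

#' Simulate a two-channel double-labeling experiment
#'
#' Channel A renders all true dots; channel B independently drops each dot
#' with probability `channel_dropout`, emulating incomplete probe binding in
#' the second color. Both channels share geometry and amplitudes and receive
#' independent noise.
#'
#' @inheritParams simulate_stack
#' @return `list(stack_a, stack_b, truth)`; `truth$spots$present_in_b` marks
#'   the dots rendered in channel B.
#' @export
simulate_two_channel <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  core <- simulate_core(params)
  all_i <- seq_len(nrow(core$spots))
  img_a <- add_noise(expected_image(core, all_i), params)
  img_b <- add_noise(expected_image(core, which(core$spots$present_in_b)),
                     params)
  list(stack_a = image_stack(img_a, params$voxel_size, channel = "A"),
       stack_b = image_stack(img_b, params$voxel_size, channel = "B"),
       truth = ground_truth(core))
}

#' Draw per-cell transcript counts from a named reference family
#'
#' Continuous draws are rounded to the nearest integer and clipped at zero,
#' since transcript counts are non-negative integers; the statistics stage
#' then fits the continuous families to these integers.
#'
#' @param family one of `"normal"`, `"gamma"`, `"logistic"`, `"weibull"`,
#'   `"poisson"`.
#' @param params named list of family parameters: normal `mean`, `sd`; gamma
#'   `shape`, `rate`; logistic `location`, `scale`; weibull `shape`, `scale`;
#'   poisson `lambda`.
#' @param n number of cells to draw.
#' @param seed optional seed; omit to consume the current RNG stream.
#' @return Integer vector of length `n`.
#' @export
sample_cell_counts <- function(family, params, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  family <- match.arg(family,
    c("normal", "gamma", "logistic", "weibull", "poisson"))
  pq <- function(nm) {
    v <- params[[nm]]
    if (is.null(v)) stop("missing parameter '", nm, "' for ", family)
    v
  }
  pos <- function(nm) {
    v <- pq(nm)
    if (v <= 0) stop("parameter '", nm, "' must be positive for ", family)
    v
  }
  x <- switch(family,
    normal   = rnorm(n, pq("mean"), pos("sd")),
    gamma    = rgamma(n, shape = pos("shape"), rate = pos("rate")),
    logistic = rlogis(n, pq("location"), pos("scale")),
    weibull  = rweibull(n, shape = pos("shape"), scale = pos("scale")),
    poisson  = rpois(n, pos("lambda")))
  as.integer(pmax(0, round(x)))
}
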