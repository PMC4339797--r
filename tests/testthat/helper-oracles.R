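# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (queue-based search, direct convolution sums, grid
# scans) and never call the code paths they check.

# Breadth-first-search connected-component count on a 3D logical array.
bfs_label_count <- function(binary, connectivity) {
  d <- dim(binary)
  offs <- list()
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    manh <- abs(a) + abs(b) + abs(c)
    if (manh == 0) next
    if (connectivity == 6 && manh > 1) next
    if (connectivity == 18 && manh > 2) next
    offs[[length(offs) + 1]] <- c(a, b, c)
  }
  visited <- array(FALSE, d)
  count <- 0L
  coords <- which(binary, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    start <- coords[r, ]
    if (visited[start[1], start[2], start[3]]) next
    count <- count + 1L
    queue <- list(start)
    visited[start[1], start[2], start[3]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        nb <- cur + o
        if (any(nb < 1) || any(nb > d)) next
        if (binary[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
          visited[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  count
}

# Direct (non-separable) 3D convolution with half-sample-symmetric reflect
# boundaries: one shift-multiply-accumulate per kernel tap.
direct_conv3d <- function(img, kernel) {
  d <- dim(img); kd <- dim(kernel)
  h <- (kd - 1) %/% 2
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- array(0, d)
  for (kz in seq_len(kd[1])) for (ky in seq_len(kd[2]))
    for (kx in seq_len(kd[3])) {
      w <- kernel[kz, ky, kx]
      if (w == 0) next
      zi <- reflect(seq_len(d[1]) + (kz - 1 - h[1]), d[1])
      yi <- reflect(seq_len(d[2]) + (ky - 1 - h[2]), d[2])
      xi <- reflect(seq_len(d[3]) + (kx - 1 - h[3]), d[3])
      out <- out + w * img[zi, yi, xi, drop = FALSE]
    }
  out
}

# Brute-force KS sup over a fine grid plus all sample points.
bf_ks_D <- function(x, cdf, grid_n = 20000) {
  pts <- sort(unique(c(x, seq(min(x) - 1, max(x) + 1, length.out = grid_n))))
  ec <- ecdf(x)
  eps <- 1e-9 * max(1, diff(range(x)))
  max(abs(ec(pts) - cdf(pts)), abs(ec(pts - eps) - cdf(pts - eps)))
}

# Exhaustive dynamic-programming optimum for probe interval packing:
# f(i) = best count using positions i..L-1.
dp_max_tiling <- function(L, p, g) {
  if (L < p) return(0L)
  f <- integer(L + p + g + 1)          # f[i+1] = best from 0-based pos i
  for (i in (L - p):0) {
    skip <- f[i + 2]
    place <- 1L + f[min(L + p + g, i + p + g) + 1]
    f[i + 1] <- max(skip, place)
  }
  f[1]
}

# Coarse grid scan of a family log-likelihood; returns the argmax.
grid_loglik_argmax <- function(x, family, p1_grid, p2_grid) {
  best <- c(NA, NA); best_ll <- -Inf
  for (p1 in p1_grid) for (p2 in p2_grid) {
    ll <- switch(family,
      gamma    = sum(dgamma(x, shape = p1, rate = p2, log = TRUE)),
      weibull  = sum(dweibull(x, shape = p1, scale = p2, log = TRUE)),
      logistic = sum(dlogis(x, location = p1, scale = p2, log = TRUE)))
    if (ll > best_ll) { best_ll <- ll; best <- c(p1, p2) }
  }
  list(par = best, loglik = best_ll)
}

# Small-frame simulation parameters shared by pipeline-level tests: one
# roomy cell so dart-throwing stays fast at reduced resolution.
small_sim_params <- function(seed = 1L, n_spots = 12L, ...) {
  sim_params(image_shape = c(16L, 128L, 128L), n_cells = 1L,
             spots_per_cell = n_spots, seed = seed, ...)
}

# Independent CDF reconstruction for a fit (by family name and parameters),
# used to check ks_gof without reusing its internals.
fitted_cdf_for_test <- function(fit) {
  p <- fit$params
  switch(fit$family,
    normal   = function(q) pnorm(q, p[["mean"]], p[["sd"]]),
    gamma    = function(q) pgamma(q, shape = p[["shape"]], rate = p[["rate"]]),
    logistic = function(q) plogis(q, p[["location"]], p[["scale"]]),
    weibull  = function(q) pweibull(q, p[["shape"]], p[["scale"]]),
    poisson  = function(q) ppois(q, p[["lambda"]]))
}
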