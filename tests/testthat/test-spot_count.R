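test_that("component labeling matches a BFS oracle across connectivities", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_identical(label_components(one, 6)$count, 1L)
  corner <- array(FALSE, c(2, 2, 2))
  corner[1, 1, 1] <- TRUE; corner[2, 2, 2] <- TRUE   # touch only at a corner
  expect_identical(label_components(corner, 26)$count, 1L)
  expect_identical(label_components(corner, 18)$count, 2L)
  expect_identical(label_components(corner, 6)$count, 2L)
  edge <- array(FALSE, c(2, 2, 1))
  edge[1, 1, 1] <- TRUE; edge[2, 2, 1] <- TRUE        # share an edge in 3D
  expect_identical(label_components(edge, 18)$count, 1L)
  expect_identical(label_components(edge, 6)$count, 2L)
  set.seed(31)
  for (rep in 1:20) {
    b <- array(runif(8^3) < 0.2, c(8, 8, 8))
    for (conn in c(6L, 18L, 26L))
      expect_identical(label_components(b, conn)$count,
                       bfs_label_count(b, conn))
  }
  expect_error(label_components(one, 4), "connectivity")
})

test_that("labels partition the foreground into consistent components", {
  set.seed(5)
  b <- array(runif(6 * 6 * 6) < 0.3, c(6, 6, 6))
  res <- label_components(b, 26)
  expect_identical(sort(unique(as.integer(res$labels[b]))),
                   seq_len(res$count))
  expect_true(all(res$labels[!b] == 0L))
})

test_that("threshold sweep produces the full uniform grid of counts", {
  zero <- image_stack(array(0, c(3, 10, 10)), voxel_size(), normalized = TRUE)
  sw0 <- threshold_sweep(zero)
  expect_identical(length(sw0$thresholds), 100L)
  expect_identical(sw0$thresholds, (1:100) / 100)
  expect_true(all(sw0$counts == 0L))
  # five disjoint equal blobs: a contiguous run counts exactly 5
  vox <- array(0, c(3, 20, 20))
  for (at in list(c(2, 3, 3), c(2, 3, 16), c(2, 16, 3), c(2, 16, 16),
                  c(2, 10, 10)))
    vox[at[1], at[2], at[3]] <- 0.8
  vox[1, 1, 1] <- 1  # normalizing voxel so blobs sit below 1
  st <- image_stack(vox, voxel_size(), normalized = TRUE)
  sw <- threshold_sweep(st)
  expect_true(all(sw$counts[sw$thresholds < 0.8] == 6L))
  expect_identical(sw$counts[50], 6L)   # 5 blobs + the normalizing voxel
  expect_true(all(sw$counts[sw$thresholds >= 0.8 & sw$thresholds < 1] == 1L))
  expect_identical(sw$counts[100], 0L)  # nothing strictly above the max
  expect_error(threshold_sweep(image_stack(vox, voxel_size())), "normalized")
})

test_that("plateau selection picks the longest stable nonzero run", {
  mk <- function(counts) {
    n <- length(counts)
    structure(list(thresholds = seq_len(n) / n, counts = as.integer(counts),
                   selected_threshold = NA_real_,
                   selected_count = NA_integer_,
                   selection_mode = NA_character_, connectivity = 26L),
              class = "threshold_sweep")
  }
  sw <- select_threshold(mk(c(9, 7, 7, 7, 7, 2, 1, rep(0, 93))))
  expect_identical(sw$selected_count, 7L)
  expect_equal(sw$selected_threshold, 3 / 100)  # midpoint of run 2..5
  # equal-length plateaus: the lower-threshold one wins
  tie <- select_threshold(mk(c(5, 5, 5, 3, 3, 3, rep(0, 4))))
  expect_identical(tie$selected_count, 5L)
  # all zero: explicit no-spots outcome
  none <- select_threshold(mk(rep(0, 10)))
  expect_identical(none$selected_count, 0L)
  expect_true(is.na(none$selected_threshold))
  # no run reaches min_plateau: modal nonzero count fallback
  modal <- select_threshold(mk(c(4, 6, 4, 6, 4, 9, rep(0, 4))))
  expect_identical(modal$selected_count, 4L)
  # manual mode
  man <- select_threshold(mk(c(9, 7, 7, 7, 7, 2, 1, rep(0, 93))),
                          mode = "manual", manual_value = 0.05)
  expect_identical(man$selected_count, 7L)
  expect_equal(man$selected_threshold, 0.05)
  expect_error(select_threshold(mk(rep(1, 10)), mode = "manual",
                                manual_value = 0.123), "thresholds")
})

blob_stack <- function(centers, peak = 0.8) {
  vox <- array(0, c(5, 24, 24))
  for (ct in centers) {
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
      vox[ct[1] + dz, ct[2] + dy, ct[3] + dx] <-
        peak * exp(-(dz^2 + dy^2 + dx^2) / 2)
  }
  vox / max(vox)
}

test_that("count_per_cell counts constructed spots inside their cell only", {
  vox <- blob_stack(list(c(3, 5, 5), c(3, 5, 18), c(3, 18, 11)))
  st <- image_stack(vox, voxel_size(), normalized = TRUE)
  cover <- rbind(c(-1, -1), c(-1, 24), c(24, 24), c(24, -1))
  slices <- rep(list(cover), 5); names(slices) <- as.character(0:4)
  all_roi <- cell_roi("all", slices)
  res <- count_per_cell(st, list(all_roi))
  expect_identical(res$cell_counts$transcript_count, 3L)
  expect_identical(nrow(res$spots), 3L)
  expect_identical(sum(res$cell_counts$transcript_count), nrow(res$spots))
  # a cell whose mask misses every spot counts zero
  corner <- rbind(c(20, 0), c(20, 3), c(23, 3), c(23, 0))
  sl2 <- list("0" = corner)
  res0 <- count_per_cell(st, list(cell_roi("off", sl2)))
  expect_identical(res0$cell_counts$transcript_count, 0L)
  # spot table geometry: centroids in um use the anisotropic voxel pitch
  expect_equal(res$spots$z_um, res$spots$z * 0.3, tolerance = 1e-12)
  expect_equal(res$spots$x_um, res$spots$x * 0.04, tolerance = 1e-12)
  expect_true(all(res$spots$mean_intensity >= res$cell_counts$threshold))
})

test_that("overlapping ROIs warn and apply first-come ownership", {
  vox <- blob_stack(list(c(3, 5, 5)))
  st <- image_stack(vox, voxel_size(), normalized = TRUE)
  sq <- function(id) {
    poly <- rbind(c(2, 2), c(2, 9), c(9, 9), c(9, 2))
    slices <- rep(list(poly), 5); names(slices) <- as.character(0:4)
    cell_roi(id, slices)
  }
  expect_warning(res <- count_per_cell(st, list(sq("a"), sq("b"))),
                 "first-come")
  expect_identical(res$cell_counts$transcript_count, c(1L, 0L))
})

test_that("plateau counts are invariant to joint amplitude rescaling", {
  p1 <- small_sim_params(seed = 17, shot_noise = FALSE, read_noise_sd = 0)
  p2 <- small_sim_params(seed = 17, shot_noise = FALSE, read_noise_sd = 0,
                         spot_amplitude = 150 * 7, background_level = 20 * 7)
  count_of <- function(p) {
    sim <- simulate_stack(p)
    norm <- normalize_filtered(log_filter(sim$stack))
    count_per_cell(norm, sim$truth$cell_rois)$cell_counts$transcript_count
  }
  expect_identical(count_of(p1), count_of(p2))
})

test_that("fixed-threshold intensities report member-voxel means", {
  vox <- array(0, c(3, 10, 10))
  vox[2, 3:4, 3:4] <- 0.6          # flat component of four voxels
  vox[2, 8, 8] <- 1
  st <- image_stack(vox, voxel_size(), normalized = TRUE)
  tab <- measure_dot_intensities(st, fixed_threshold = 0.25)
  tab <- tab[order(tab$mean_intensity), ]
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$mean_intensity, c(0.6, 1.0))
  expect_identical(tab$voxel_count, c(4L, 1L))
  empty <- measure_dot_intensities(
    image_stack(array(0, c(2, 4, 4)), voxel_size(), normalized = TRUE))
  expect_identical(nrow(empty), 0L)
})

test_that("component voxel counts shrink monotonically as the threshold rises", {
  set.seed(23)
  p <- small_sim_params(seed = 23, n_spots = 6L)
  sim <- simulate_stack(p)
  norm <- normalize_filtered(log_filter(sim$stack))
  sizes <- vapply(c(0.2, 0.3, 0.4, 0.5), function(t) {
    tab <- measure_dot_intensities(norm, fixed_threshold = t)
    sum(tab$voxel_count)
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("conglomerate classification reproduces tallies and edge cases", {
  spots <- data.frame(mean_intensity = c(rep(0.275, 501), 0.55, 0.55))
  cl <- classify_conglomerates(spots)
  expect_identical(cl$n, 503L)
  expect_identical(cl$n_flagged, 2L)
  expect_equal(cl$pct_flagged, 0.4)
  expect_equal(cl$modal_intensity, 0.275)
  expect_identical(sum(cl$spots$conglomerate), 2L)
  allsame <- classify_conglomerates(data.frame(mean_intensity = rep(0.31, 40)))
  expect_equal(allsame$pct_flagged, 0)
  expect_error(classify_conglomerates(data.frame(mean_intensity = numeric(0))),
               "empty")
})

test_that("colocalization matches one-to-one within the radius", {
  pts <- data.frame(z_um = c(1, 2, 3), y_um = c(1, 1, 1), x_um = c(0, 0, 0))
  same <- colocalize(pts, pts, radius = 0.1)
  expect_equal(same$efficiency_a_to_b, 1)
  expect_equal(same$efficiency_b_to_a, 1)
  far <- colocalize(pts, pts + 10, radius = 0.5)
  expect_equal(far$efficiency_a_to_b, 0)
  none <- colocalize(pts[0, ], pts, radius = 0.5)
  expect_true(is.na(none$efficiency_a_to_b))
  # one B dot between two A dots can only match once
  a <- data.frame(z_um = c(0, 0.4), y_um = 0, x_um = 0)
  b <- data.frame(z_um = 0.1, y_um = 0, x_um = 0)
  m <- colocalize(a, b, radius = 0.5)
  expect_identical(nrow(m$matches), 1L)
  expect_identical(m$matches$a, 1L)    # nearer A dot wins
  expect_equal(m$efficiency_a_to_b, 0.5)
  expect_equal(m$efficiency_b_to_a, 1)
})
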