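#' Pipeline run configuration
#'
#' Collects every tunable of the counting pipeline with defaults that
#' reproduce the standard workflow constants: 100 sweep thresholds, the
#' fixed 0.25 intensity threshold, 26-connectivity, alpha = 0.05.
#'
#' @param stack path to the input TIFF (with sidecar or `voxel_*`
#'   overrides).
#' @param rois path to `rois.json`.
#' @param out_dir output directory.
#' @param sigma_xy,sigma_z,truncation LoG scales, um (see
#'   [filter_params()]).
#' @param n_thresholds,connectivity,mode,manual_value,min_plateau,min_voxels
#'   sweep/selection settings (see [count_per_cell()]).
#' @param fixed_threshold dot-intensity threshold (see
#'   [measure_dot_intensities()]).
#' @param bin_width,fold,tol conglomerate settings (see
#'   [classify_conglomerates()]).
#' @param coloc_radius matching radius, um (see [colocalize()]).
#' @param alpha,bootstrap,pooling statistics settings (see
#'   [model_selection_table()]); `pooling` is `"pooled"` or `"per_embryo"`.
#' @param seed RNG seed recorded in every output header.
#' @param embryo_id identifier for the output tables.
#' @return A `run_config` list.
#' @export
run_config <- function(stack = NULL, rois = NULL, out_dir = ".",
                       sigma_xy = 0.13, sigma_z = 0.4, truncation = 4,
                       n_thresholds = 100L, connectivity = 26L,
                       mode = "plateau", manual_value = NULL,
                       min_plateau = 3L, min_voxels = 1L,
                       fixed_threshold = 0.25, bin_width = 0.05, fold = 2.0,
                       tol = 0.15, coloc_radius = 0.3, alpha = 0.05,
                       bootstrap = FALSE, pooling = "pooled", seed = 1L,
                       embryo_id = "embryo1") {
  structure(as.list(environment()), class = "run_config")
}

#' Read a YAML run configuration
#'
#' The file holds the [run_config()] fields either flat or grouped in
#' sections (`filter:`, `sweep:`, `intensity:`, `coloc:`, `stats:`, `io:`);
#' section names are organizational only and are flattened away. Unknown
#' keys are an error. Precedence is command line > file > defaults.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    raw <- yaml::read_yaml(path)
    for (k in names(raw)) {
      if (is.list(raw[[k]])) vals[names(raw[[k]])] <- raw[[k]]
      else vals[[k]] <- raw[[k]]
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

provenance_header <- function(config) {
  keep <- c("sigma_xy", "sigma_z", "n_thresholds", "connectivity", "mode",
            "min_plateau", "min_voxels", "fixed_threshold", "bin_width",
            "fold", "tol", "coloc_radius", "alpha", "seed", "embryo_id")
  vals <- vapply(keep, function(k)
    paste0(k, "=", paste(format(config[[k]]), collapse = ",")), "")
  c(paste0("# smfishq ", as.character(packageVersion("smfishq"))),
    paste0("# ", paste(vals, collapse = " ")))
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output CSV, skipping provenance comment lines
#' @param path CSV written by [run_pipeline()] or the CLI.
#' @return data.frame.
#' @export
read_output_csv <- function(path) read.csv(path, comment.char = "#")

#' Run the full counting pipeline on one stack
#'
#' filter -> normalize -> per-cell mask/sweep/select/count -> fixed-threshold
#' dot intensities -> conglomerate classification, writing
#' `cell_counts.csv`, `spots.csv`, `sweep.csv` and `intensity_summary.json`
#' into `out_dir`. Every CSV starts with a commented provenance header
#' (package version, all parameters, seed), and identical config plus inputs
#' give byte-identical outputs.
#'
#' @param config a [run_config()] with `stack` and `rois` set.
#' @param stack optionally, an [image_stack()] already in memory (skips
#'   reading `config$stack`).
#' @param rois optionally, a list of [cell_roi()] already in memory.
#' @return Invisibly, `list(cell_counts, spots, sweeps, intensity_spots,
#'   conglomerates, files)`.
#' @export
run_pipeline <- function(config, stack = NULL, rois = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(stack)) {
    if (is.null(config$stack)) stop("config$stack is not set")
    if (!file.exists(config$stack))
      stop("stage image_io: no such stack: ", config$stack)
    stack <- read_stack(config$stack)
  }
  if (is.null(rois)) {
    if (is.null(config$rois)) stop("config$rois is not set")
    if (!file.exists(config$rois))
      stop("stage cell_roi: no such ROI file: ", config$rois)
    rois <- read_rois(config$rois)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- filter_params(config$sigma_xy, config$sigma_z, config$truncation)
  filtered <- log_filter(stack, fp)
  norm <- tryCatch(normalize_filtered(filtered),
                   smfishq_no_signal = function(e) NULL)
  hdr <- provenance_header(config)
  files <- character(0)
  if (is.null(norm)) {
    cc <- data.frame(embryo_id = config$embryo_id,
                     cell_id = vapply(rois, `[[`, "", "cell_id"),
                     threshold = NA_real_, transcript_count = 0L)
    res <- list(cell_counts = cc, spots = NULL, sweeps = list())
    intens <- NULL; congl <- NULL
  } else {
    res <- count_per_cell(norm, rois, mode = config$mode,
                          manual_value = config$manual_value,
                          n_thresholds = config$n_thresholds,
                          connectivity = config$connectivity,
                          min_plateau = config$min_plateau,
                          min_voxels = config$min_voxels,
                          embryo_id = config$embryo_id)
    intens <- measure_dot_intensities(norm, config$fixed_threshold,
                                      connectivity = config$connectivity)
    congl <- if (nrow(intens))
      classify_conglomerates(intens, config$bin_width, config$fold,
                             config$tol) else NULL
  }
  f <- file.path(config$out_dir, "cell_counts.csv")
  write_csv_with_header(res$cell_counts, f, hdr); files <- c(files, f)
  if (!is.null(res$spots)) {
    f <- file.path(config$out_dir, "spots.csv")
    write_csv_with_header(res$spots, f, hdr); files <- c(files, f)
  }
  if (length(res$sweeps)) {
    sw <- do.call(rbind, lapply(names(res$sweeps), function(cid) {
      s <- res$sweeps[[cid]]
      if (is.null(s)) return(NULL)
      data.frame(cell_id = cid, threshold = s$thresholds, count = s$counts)
    }))
    f <- file.path(config$out_dir, "sweep.csv")
    write_csv_with_header(sw, f, hdr); files <- c(files, f)
  }
  if (!is.null(congl)) {
    f <- file.path(config$out_dir, "intensity_summary.json")
    jsonlite::write_json(
      list(fixed_threshold = config$fixed_threshold,
           n_dots = congl$n, modal_intensity = congl$modal_intensity,
           n_flagged = congl$n_flagged, pct_flagged = congl$pct_flagged),
      f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(list(cell_counts = res$cell_counts, spots = res$spots,
                 sweeps = res$sweeps, intensity_spots = intens,
                 conglomerates = congl, files = files))
}

#' Write a simulated experiment to disk
#'
#' Materializes [simulate_stack()] / [simulate_two_channel()] output in the
#' on-disk formats the CLI consumes: channel TIFFs with sidecars,
#' `rois.json`, `ground_truth.csv` (one row per true dot) and
#' `cell_counts.csv` (true per-cell counts).
#'
#' @param params a [sim_params()].
#' @param out_dir output directory.
#' @param two_channel write channels A and B instead of A alone.
#' @return Invisibly, the simulation result with `$files` added.
#' @export
simulate_to_files <- function(params, out_dir, two_channel = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (two_channel) simulate_two_channel(params) else
    simulate_stack(params)
  files <- character(0)
  if (two_channel) {
    fa <- file.path(out_dir, "channel_a.tif")
    fb <- file.path(out_dir, "channel_b.tif")
    write_stack(sim$stack_a, fa); write_stack(sim$stack_b, fb)
    files <- c(files, fa, fb)
  } else {
    fa <- file.path(out_dir, "channel_a.tif")
    write_stack(sim$stack, fa); files <- c(files, fa)
  }
  fr <- file.path(out_dir, "rois.json")
  write_rois(sim$truth$cell_rois, fr); files <- c(files, fr)
  fg <- file.path(out_dir, "ground_truth.csv")
  write.csv(sim$truth$spots, fg, row.names = FALSE); files <- c(files, fg)
  fc <- file.path(out_dir, "cell_counts.csv")
  write.csv(sim$truth$per_cell_counts, fc, row.names = FALSE)
  files <- c(files, fc)
  sim$files <- files
  invisible(sim)
}
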