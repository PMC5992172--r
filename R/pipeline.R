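#' Pipeline drivers
#'
#' Function-level equivalents of the analysis workflow's steps: simulate a
#' batch of assays to files, analyse a directory of trace/scan files into
#' one results table, and summarise stopping forces per assay geometry.
#' The numbered scripts under `analysis/` are thin narrative wrappers
#' around these functions.
#'
#' @name pipeline
NULL

#' Geometry presets for the four anchorage modes
#'
#' Simulation configurations whose force scales match the four measured
#' regimes: statically surface-anchored motor domains ("gliding", tens of
#' pN), diffusively anchored full-length motors between aligned
#' microtubules ("sliding", sub-pN), full-length motors between
#' non-aligned microtubules ("non_aligned", several pN), and motor domains
#' statically anchored on a microtubule ("mt_anchored", several to tens of
#' pN). Unloaded velocities are the measured population means; team
#' frictions are set so the plateau force `team_friction * v0` falls in
#' the observed range.
#'
#' @param seed Base RNG seed; each geometry gets a distinct derived seed.
#' @return Named list of [sim_config()] objects.
#' @export
geometry_presets <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    gliding = sim_config(geometry = "gliding", unloaded_velocity = 270,
                         team_friction = 0.05, trap_stiffness = 0.05,
                         duration = 40, binding_time = 8, seed = seed),
    sliding = sim_config(geometry = "sliding", unloaded_velocity = 57,
                         team_friction = 0.0123, trap_stiffness = 0.05,
                         duration = 40, binding_time = 8, seed = seed + 1L),
    non_aligned = sim_config(geometry = "non_aligned",
                             unloaded_velocity = 180, team_friction = 0.033,
                             trap_stiffness = 0.05, duration = 40,
                             binding_time = 8, seed = seed + 2L),
    mt_anchored = sim_config(geometry = "mt_anchored",
                             unloaded_velocity = 205, team_friction = 0.054,
                             trap_stiffness = 0.05, duration = 40,
                             binding_time = 8, seed = seed + 3L))
}

#' Simulate a batch of assays to files
#'
#' Writes `n` force traces (and, for the sliding geometry where plateau
#' forces drown in noise, `n` force-velocity scans) plus the resolved
#' configuration as a YAML sidecar. Trace `i` uses seed `config$seed + i`,
#' so the whole batch is reproducible from the config file alone.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param n Number of traces/scans.
#' @param scans Also write force-velocity scans (default: only for the
#'   sliding geometry).
#' @param setpoints Scan force set-points, pN.
#' @return Invisibly, the vector of written file paths.
#' @export
run_simulation <- function(config, out_dir, n = 1L,
                           scans = config$geometry == "sliding",
                           setpoints = seq(-5, 5, length.out = 11)) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sim_config(config, file.path(out_dir, "config.yaml"))
  paths <- character(0)
  for (i in seq_len(n)) {
    ci <- config
    ci$seed <- config$seed + i
    if (scans) {
      scan <- simulate_fv_scan(ci, setpoints = setpoints, seed = ci$seed)
      scan$pair_id <- sprintf("%s-%03d", config$geometry, i)
      p <- file.path(out_dir, sprintf("scan_%03d.tsv", i))
      write_fv_scan(scan, p)
    } else {
      tr <- simulate_trap_trace(ci)
      p <- file.path(out_dir, sprintf("trace_%03d.tsv", i))
      write_force_trace(tr, p)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}

# decide whether a file holds a trace or a scan from its header columns
classify_input <- function(path) {
  header <- grep("^#", readLines(path, n = 3L), invert = TRUE, value = TRUE)[1]
  if (grepl("fx_pN", header)) "trace"
  else if (grepl("setpoint", header)) "scan"
  else NA_character_
}

#' Analyse a batch of trace and scan files
#'
#' Routes each file to the matching estimator: force traces go through
#' binding detection, plateau detection and the plateau stopping force;
#' force-velocity scans through the weighted linear fit. Per-file failures
#' are logged (as warnings) and skipped; the call errors only when no file
#' yields a result.
#'
#' @param paths Files to analyse (trace or scan TSVs), or a directory.
#' @param ... Passed to [analyze_trace()].
#' @return `data.frame` with one row per successful input: `file`, `kind`,
#'   `geometry`, `stopping_force` (pN), `uncertainty` (plateau sd or fit
#'   se, pN), `binding_time` (s, traces only). The number of failed files
#'   is attached as attribute `n_failed`.
#' @export
analyze_traces <- function(paths, ...) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no input files", call. = FALSE)
  rows <- list()
  n_failed <- 0L
  for (p in paths) {
    row <- tryCatch({
      kind <- classify_input(p)
      if (is.na(kind)) stop("unrecognised file format")
      if (kind == "trace") {
        tr <- read_force_trace(p)
        geom <- tr$metadata$config$geometry
        an <- analyze_trace(tr, ...)
        if (is.null(an$result)) stop("no stopping-force plateau found")
        data.frame(file = basename(p), kind = kind,
                   geometry = if (is.null(geom)) NA_character_ else geom,
                   stopping_force = an$result$stopping_force,
                   uncertainty = an$result$plateau_sd,
                   binding_time = an$binding_time)
      } else {
        scan <- read_fv_scan(p)
        fit <- fit_force_velocity(scan)
        geom <- sub("-[0-9]+$", "", scan$pair_id)
        data.frame(file = basename(p), kind = kind,
                   geometry = if (geom %in% GEOMETRIES) geom else NA_character_,
                   stopping_force = fit$stopping_force,
                   uncertainty = fit$stopping_force_se,
                   binding_time = NA_real_)
      }
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", basename(p), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(row)) n_failed <- n_failed + 1L else rows <- c(rows, list(row))
  }
  if (length(rows) == 0L) {
    stop("all input files failed to analyse", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}

#' Summarise stopping forces per assay geometry
#'
#' Boxplot statistics of the stopping force for each geometry plus
#' pairwise two-sample Kolmogorov-Smirnov comparisons between geometries.
#'
#' @param results Results table from [analyze_traces()] (or any data.frame
#'   with `geometry` and `stopping_force` columns).
#' @return List with `stats` (named list of [boxplot_stats()] per
#'   geometry), `medians` (named vector) and `comparisons` (data.frame of
#'   pairwise KS D and p, empty for a single geometry).
#' @export
geometry_report <- function(results) {
  need <- c("geometry", "stopping_force")
  if (!all(need %in% names(results))) {
    stop("`results` must have geometry and stopping_force columns",
         call. = FALSE)
  }
  geoms <- unique(results$geometry)
  unknown <- setdiff(geoms, GEOMETRIES)
  if (length(unknown) > 0) {
    stop("unknown geometry labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(results$stopping_force, results$geometry)
  stats <- lapply(groups, boxplot_stats)
  medians <- vapply(stats, `[[`, numeric(1), "median")
  comparisons <- data.frame(geometry_a = character(0),
                            geometry_b = character(0),
                            ks_d = numeric(0), p_value = numeric(0))
  gn <- names(groups)
  if (length(gn) > 1L) {
    for (i in seq_len(length(gn) - 1L)) {
      for (j in (i + 1L):length(gn)) {
        if (length(groups[[i]]) < 2L || length(groups[[j]]) < 2L) next
        kt <- suppressWarnings(stats::ks.test(groups[[i]], groups[[j]]))
        comparisons <- rbind(comparisons,
          data.frame(geometry_a = gn[i], geometry_b = gn[j],
                     ks_d = unname(kt$statistic), p_value = kt$p.value))
      }
    }
  }
  list(stats = stats, medians = medians, comparisons = comparisons)
}
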