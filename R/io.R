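#' Delimited-text I/O
#'
#' All artefacts are flat files: tab-separated tables with a header row,
#' preceded by `#`-prefixed metadata lines (JSON payload) carrying the
#' trap stiffness, seed and any simulation truth; configurations are flat
#' YAML key-value files. Physical quantities are serialised in pN, nm, s
#' and K.
#'
#' @name slideforce_io
NULL

write_meta_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta) > 0) {
    writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA)), con)
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta_table <- function(path) {
  lines <- readLines(path, n = 5L)
  meta_lines <- grep("^#", lines)
  meta <- if (length(meta_lines) > 0) {
    jsonlite::fromJSON(sub("^#\\s*", "", lines[meta_lines[1]]))
  } else list()
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(data = df, meta = meta)
}

#' Write / read a force trace
#'
#' Tab-separated columns `time_s`, `fx_pN`, `fy_pN`, `stage_x_nm`,
#' `stage_y_nm`, with trap stiffness, seed and metadata in a `#` JSON
#' header line.
#'
#' @param trace A [force_trace()].
#' @param path File path.
#' @return `path` (write) or a [force_trace()] (read).
#' @export
write_force_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  df <- data.frame(time_s = trace$time, fx_pN = trace$force_x,
                   fy_pN = trace$force_y,
                   stage_x_nm = if (is.null(trace$stage_x)) 0 else trace$stage_x,
                   stage_y_nm = if (is.null(trace$stage_y)) 0 else trace$stage_y)
  meta <- c(list(trap_stiffness = trace$trap_stiffness), trace$metadata)
  meta$events <- NULL   # data frame; ground truth travels in `config`
  write_meta_table(df, path, meta)
}

#' @rdname write_force_trace
#' @export
read_force_trace <- function(path) {
  x <- read_meta_table(path)
  k <- x$meta$trap_stiffness
  if (is.null(k)) stop("trace file lacks trap_stiffness metadata", call. = FALSE)
  force_trace(time = x$data$time_s, force_x = x$data$fx_pN,
              force_y = x$data$fy_pN, stage_x = x$data$stage_x_nm,
              stage_y = x$data$stage_y_nm, trap_stiffness = k,
              metadata = x$meta[setdiff(names(x$meta), "trap_stiffness")])
}

#' Write / read a force-velocity scan
#'
#' One segment per row (`mode`, `setpoint`, `response`, `quality_weight`,
#' `duration`); unloaded velocity and pair id in the JSON header line.
#'
#' @param scan An [fv_scan()].
#' @param path File path.
#' @return `path` (write) or an [fv_scan()] (read).
#' @export
write_fv_scan <- function(scan, path) {
  stopifnot(inherits(scan, "fv_scan"))
  write_meta_table(scan$segments, path,
                   list(unloaded_velocity = scan$unloaded_velocity,
                        pair_id = scan$pair_id))
}

#' @rdname write_fv_scan
#' @export
read_fv_scan <- function(path) {
  x <- read_meta_table(path)
  fv_scan(x$data, unloaded_velocity = x$meta$unloaded_velocity,
          pair_id = x$meta$pair_id)
}

#' Write / read a filament track table
#'
#' Long-format table (`filament_id`, `frame_time_s`, `position_nm`,
#' `length_nm`, `mode`), one row per frame, possibly holding many
#' filaments.
#'
#' @param tracks A [filament_track()] or list of them.
#' @param path File path.
#' @return `path` (write) or a list of [filament_track()] (read).
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "filament_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    data.frame(filament_id = tr$filament_id, frame_time_s = tr$frame_times,
               position_nm = tr$positions, length_nm = tr$filament_length,
               mode = tr$mode)
  })
  write_meta_table(do.call(rbind, rows), path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- read_meta_table(path)$data
  lapply(split(df, df$filament_id), function(d) {
    filament_track(frame_times = d$frame_time_s, positions = d$position_nm,
                   filament_length = d$length_nm[1], mode = d$mode[1],
                   filament_id = as.character(d$filament_id[1]))
  })
}

#' Write / read a simulation configuration
#'
#' Flat YAML key-value file; the seed is mandatory.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `path` (write) or a [sim_config()] (read).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(vals$seed)) stop("config lacks a seed", call. = FALSE)
  if (!is.null(vals$offset_force)) {
    vals$offset_force <- as.numeric(unlist(vals$offset_force))
  }
  do.call(sim_config, vals)
}

#' Write a stopping-force result
#'
#' One-row tab-separated summary plus a JSON sidecar (`<path>.json`)
#' holding the analysis windows and settings.
#'
#' @param result A `stopping_force_result`.
#' @param path File path for the table; the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_stopping_force <- function(result, path) {
  stopifnot(inherits(result, "stopping_force_result"))
  df <- data.frame(stopping_force_pN = result$stopping_force,
                   offset_x_pN = result$offset_x,
                   offset_y_pN = result$offset_y,
                   plateau_mean_x_pN = result$plateau_mean_x,
                   plateau_mean_y_pN = result$plateau_mean_y,
                   plateau_sd_pN = result$plateau_sd,
                   n_baseline = result$n_baseline,
                   n_plateau = result$n_plateau)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(result), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
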