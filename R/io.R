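#' Default configuration values
#'
#' The defaults follow the standard measurement protocol: a 100 x 100
#' lattice, fluctuation tolerance 0.01 sustained over 500 steps, a 500-step
#' averaging window and 10 replicates.
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(L = 100L, f = 0.5, init_behavior1_prob = 0.5, seed = 1L,
       params = c(2, 2, -1, -1, 1, 1, 2, 2),
       fluct_tol = 0.01, window = 500L, average_window = 500L,
       max_steps = 20000L, n_reps = 10L)
}

.config_keys <- c("L", "f", "init_behavior1_prob", "seed", "params",
                  "fluct_tol", "window", "average_window", "max_steps",
                  "n_reps")

#' Load a plain-text key = value configuration file
#'
#' Lines have the form `key = value`; blank lines and `#` comments are
#' ignored. `params` takes eight comma-separated numbers in the order
#' `B1,B2,B3,B4,C1,C2,C3,C4`. Missing keys fall back to [default_config()];
#' unknown keys and out-of-range values are errors.
#'
#' @param path file path.
#' @return A validated named list of configuration values.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% .config_keys)
      stop("unknown config key: '", key, "' (known: ",
           paste(.config_keys, collapse = ", "), ")")
    cfg[[key]] <- if (key == "params") {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    } else as.numeric(val)
  }
  validate_config(cfg)
}

#' Validate a configuration list
#'
#' @param cfg named list as returned by [load_config()] / [default_config()].
#' @return The validated list (integer-valued fields coerced).
#' @export
validate_config <- function(cfg) {
  # delegate range checks to the constructors
  lc <- lattice_config(cfg$L, cfg$f, cfg$init_behavior1_prob, cfg$seed)
  cs <- convergence_spec(cfg$fluct_tol, cfg$window, cfg$average_window,
                         cfg$max_steps)
  gs <- game_set(cfg$params)
  n_reps <- as.integer(cfg$n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be a positive integer")
  list(L = lc$L, f = lc$f, init_behavior1_prob = lc$init_behavior1_prob,
       seed = lc$seed, params = as.numeric(unlist(gs)),
       fluct_tol = cs$fluct_tol, window = cs$window,
       average_window = cs$average_window, max_steps = cs$max_steps,
       n_reps = n_reps)
}

#' Save a configuration as a key = value file
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  fmt <- function(v) paste(format(v, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = ",")
  writeLines(sprintf("%s = %s", names(cfg), vapply(cfg, fmt, character(1))),
             path)
  invisible(path)
}

manifest_list <- function(...) {
  extra <- list(...)
  c(list(package = "groupgames",
         version = as.character(utils::packageVersion("groupgames"))),
    extra)
}

write_manifest <- function(path, ...) {
  jsonlite::write_json(manifest_list(...), paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a trajectory to CSV
#'
#' One row per step with the population and per-group behavior-1 fractions;
#' a JSON manifest with the full run configuration is written alongside
#' (`<path>.manifest.json`).
#'
#' @param traj a [trajectory()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(step = seq_along(traj$rho1) - 1L,
                   rho1 = traj$rho1,
                   rho1_g1 = traj$rho1_g1,
                   rho1_g2 = traj$rho1_g2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  write_manifest(path,
                 kind = "timeseries",
                 games = if (!is.null(traj$games)) unclass(traj$games),
                 config = if (!is.null(traj$config)) unclass(traj$config),
                 conv = if (!is.null(traj$conv)) unclass(traj$conv),
                 converged_at = traj$converged_at,
                 steady_rho1 = traj$steady_rho1,
                 realized_f = traj$realized_f)
  invisible(path)
}

#' Write a sweep result to CSV
#'
#' @param result a `sweep_result` data.frame.
#' @param path output CSV path.
#' @param manifest optional named list of extra manifest fields (parameter
#'   grids, protocol settings).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path, manifest = list()) {
  stopifnot(inherits(result, "sweep_result"))
  utils::write.csv(result, path, row.names = FALSE, quote = FALSE)
  do.call(write_manifest, c(list(path, kind = "sweep"), manifest))
  invisible(path)
}

#' Read a sweep result back from CSV
#'
#' @param path CSV written by [write_sweep()].
#' @return A `sweep_result` data.frame.
#' @export
read_sweep <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("sweep_result", "data.frame"))
}

#' Snapshot color mapping
#'
#' The four agent states and their colors: blue = behavior 1 in group 1,
#' yellow = behavior 2 in group 1, green = behavior 1 in group 2, red =
#' behavior 2 in group 2 (codes 0..3 in [encode_states()] order).
#' @return Named character vector of hex colors.
#' @export
snapshot_palette <- function() {
  c(`behavior1_group1` = "#0000FF",  # blue
    `behavior2_group1` = "#FFFF00",  # yellow
    `behavior1_group2` = "#00FF00",  # green
    `behavior2_group2` = "#FF0000")  # red
}

#' Export a 4-state snapshot grid
#'
#' Writes a PNG with the standard color mapping (see [snapshot_palette()])
#' and a plain-text sidecar (`<path>.txt`) holding the integer grid (0..3,
#' space-separated, one lattice row per line).
#'
#' @param grid integer matrix with entries in 0..3, as from
#'   [encode_states()].
#' @param path output PNG path.
#' @param scale integer pixel size per lattice site.
#' @return `path`, invisibly.
#' @export
export_snapshot <- function(grid, path, scale = 1L) {
  grid <- as.matrix(grid)
  if (!all(grid %in% 0:3)) stop("snapshot grid entries must be in 0..3")
  pal <- grDevices::col2rgb(snapshot_palette()) / 255
  img <- array(0, dim = c(nrow(grid), ncol(grid), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(pal[ch, grid + 1L], nrow(grid), ncol(grid))
  if (scale > 1L) {
    idx_r <- rep(seq_len(nrow(grid)), each = scale)
    idx_c <- rep(seq_len(ncol(grid)), each = scale)
    img <- img[idx_r, idx_c, , drop = FALSE]
  }
  png::writePNG(img, path)
  writeLines(apply(grid, 1, paste, collapse = " "), paste0(path, ".txt"))
  invisible(path)
}
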