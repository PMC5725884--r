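#' Read a model configuration file
#'
#' Loads a flat key/value JSON or YAML document whose keys mirror the
#' [ha_params()] field names, and returns the validated parameter set.
#' Missing keys keep their defaults; unknown keys and constraint
#' violations are rejected with an error naming the offending key.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [ha_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  if (length(cfg) == 0) return(ha_params())
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == "")) {
    stop("config must be a flat named mapping", call. = FALSE)
  }
  ha_params(cfg)
}

traj_header <- function() c("time_hr", STATE_VARS)

#' Write / read a trajectory as CSV
#'
#' The on-disk format is a plain CSV with the fixed header
#' `time_hr,cHA,vHA,eHA,gHA,bHT,cHT,HTpool,Gstar,Tstar,bHA` and one row
#' per grid point. Values are written with 17 significant digits
#' (`%.17g`, locale-independent '.' decimal separator), so a write/read
#' round trip reproduces every double bit-for-bit.
#'
#' @param trajectory An `ha_trajectory` (or any data frame with the
#'   trajectory columns).
#' @param path Output / input file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a trajectory tibble.
#' @export
write_trajectory <- function(trajectory, path) {
  hdr <- traj_header()
  df <- as.data.frame(trajectory)
  if (!all(hdr %in% names(df))) {
    stop("trajectory lacks required columns", call. = FALSE)
  }
  df <- df[hdr]
  lines <- c(paste(hdr, collapse = ","),
             apply(df, 1, function(r) {
               paste(sprintf("%.17g", r), collapse = ",")
             }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- traj_header()
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1 || lines[1] != paste(hdr, collapse = ",")) {
    stop("line 1: unexpected header", call. = FALSE)
  }
  if (length(lines) < 2) stop("trajectory file has no data rows",
                              call. = FALSE)
  fields <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(fields) != length(hdr))
  if (length(bad) > 0) {
    stop("line ", bad[1] + 1, ": expected ", length(hdr),
         " fields", call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = length(hdr), byrow = TRUE)
  if (any(is.na(m))) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("line ", bad + 1, ": non-numeric field", call. = FALSE)
  }
  colnames(m) <- hdr
  tibble::as_tibble(as.data.frame(m))
}

#' Synthetic baseline-subtracted voltammetry-style trace
#'
#' Generates a pseudo-measurement from a simulated trajectory:
#' extracellular histamine is resampled to the voltammetry sampling rate
#' (10 Hz), the baseline is subtracted (measurements report only changes
#' from baseline), and zero-mean Gaussian noise of the given standard
#' deviation is added under an explicit seed. Deterministic given
#' `(trajectory, noise_sd, seed)`. Intended as a synthetic test fixture
#' for trace-comparison code, not as a model of electrode physics.
#'
#' @param trajectory An `ha_trajectory` (must contain `time_hr`, `eHA`).
#' @param noise_sd Noise standard deviation (uM), `>= 0`.
#' @param seed RNG seed.
#' @param hz Sampling rate.
#' @param baseline Baseline to subtract; defaults to `eHA` at the first
#'   time point.
#' @param window_s Optional length-2 window (seconds) to resample;
#'   defaults to the full trajectory span.
#' @return A tibble with columns `time_s`, `eha_rel` (noisy,
#'   baseline-relative) and `eha_clean`.
#' @export
generate_pseudo_fscv <- function(trajectory, noise_sd = 0.1, seed = 1L,
                                 hz = 10, baseline = NULL,
                                 window_s = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  t_s <- trajectory$time_hr * 3600
  if (is.null(window_s)) window_s <- range(t_s)
  if (window_s[1] < min(t_s) - 1e-9 || window_s[2] > max(t_s) + 1e-9) {
    stop("trajectory does not span the requested window", call. = FALSE)
  }
  grid <- seq(window_s[1], window_s[2], by = 1 / hz)
  clean <- stats::approx(t_s, trajectory$eHA, xout = grid)$y
  if (is.null(baseline)) baseline <- trajectory$eHA[1]
  rel <- baseline_relative(clean, baseline)
  noise <- withr::with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  tibble::tibble(time_s = grid, eha_rel = rel + noise, eha_clean = rel)
}
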