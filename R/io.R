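## Persistence: versioned native containers for streams and channel
## counts, plain-text interchange (CSV/JSON), and run configuration.

STREAM_FORMAT_VERSION <- 1L

#' Write a stream or channel-counts object to its native container
#'
#' The native container is a versioned single-file payload holding the
#' named datasets (`waveform`, `laser_clock`, `hsync1`, `hsync2`,
#' `vsync` for streams; `counts`, `clock`, `pulse_index` plus the sync
#' tables for channel counts). Write-read round trips are lossless.
#'
#' @param x A `raw_stream` or [channel_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(x, path) {
  if (!inherits(x, c("raw_stream", "channel_counts")))
    stop_invalid("`x` must be a raw_stream or channel_counts")
  payload <- list(format = "mux2p-stream", version = STREAM_FORMAT_VERSION,
                  kind = class(x)[1], data = unclass(x))
  saveRDS(payload, path)
  invisible(path)
}

#' Read a stream or channel-counts object written by [write_stream()]
#'
#' @param path Input path.
#' @return The stored `raw_stream` or [channel_counts()].
#' @export
read_stream <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop_invalid("corrupt or unreadable stream file: ", conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "mux2p-stream"))
    stop_invalid("not a mux2p stream container: ", path)
  if (!identical(payload$version, STREAM_FORMAT_VERSION))
    stop_invalid("unsupported stream container version ", payload$version)
  structure(payload$data, class = payload$kind)
}

#' Export channel counts as CSV (plain-text interchange)
#'
#' @param counts A [channel_counts()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  stopifnot(inherits(counts, "channel_counts"))
  df <- data.frame(pulse_index = counts$pulse_index,
                   clock = if (is.null(counts$clock)) NA_integer_ else counts$clock,
                   ch1 = counts$values[, 1], ch2 = counts$values[, 2],
                   ch3 = counts$values[, 3], ch4 = counts$values[, 4])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read channel counts from CSV written by [write_counts_csv()]
#'
#' @param path CSV path.
#' @return A [channel_counts()].
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path)
  need <- c("pulse_index", "clock", "ch1", "ch2", "ch3", "ch4")
  if (!all(need %in% names(df)))
    stop_invalid("counts CSV must have columns ", paste(need, collapse = ", "))
  channel_counts(unname(as.matrix(df[, c("ch1", "ch2", "ch3", "ch4")])),
                 pulse_index = df$pulse_index,
                 clock = if (all(is.na(df$clock))) NULL else df$clock)
}

#' Bundle a full run configuration
#'
#' @param scope A [scope_config()].
#' @param gates A [gate_set()].
#' @param accumulation Accumulation factor (1, 2 or 4).
#' @param mixing Optional [mixing_matrix()].
#' @param flim Optional named list of FLIM options.
#' @param seed Integer seed.
#' @return Object of class `run_config` (schema-versioned).
#' @export
run_config <- function(scope = scope_config(), gates = default_gate_set(),
                       accumulation = 1L, mixing = NULL, flim = list(),
                       seed = 1L) {
  if (!accumulation %in% c(1L, 2L, 4L))
    stop_invalid("`accumulation` must be 1, 2 or 4")
  structure(list(schema = "mux2p-config", version = 1L,
                 scope = scope, gates = gates,
                 accumulation = as.integer(accumulation),
                 mixing = mixing, flim = flim, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize a run configuration to JSON
#'
#' @param config A [run_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(schema = config$schema, version = config$version,
            scope = unclass(config$scope)[setdiff(names(config$scope),
                                                  "seed")],
            gates = list(gates = config$gates$gates,
                         record_len = config$gates$record_len),
            accumulation = config$accumulation,
            mixing = if (is.null(config$mixing)) NULL else
              list(a = config$mixing$a, b = config$mixing$b,
                   c = config$mixing$c),
            flim = config$flim, seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' @param path JSON path written by [write_config()].
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "mux2p-config"))
    stop_invalid("not a mux2p config: ", path)
  if (!identical(as.integer(x$version), 1L))
    stop_invalid("unsupported config schema version ", x$version)
  sc <- x$scope
  scope <- scope_config(sample_rate = sc$sample_rate, rep_rate = sc$rep_rate,
                        n_paths = sc$n_paths,
                        resonant_freq = sc$resonant_freq,
                        fill_fraction = sc$fill_fraction,
                        lines_per_frame = sc$lines_per_frame,
                        pixels_per_line = sc$pixels_per_line,
                        scanner_phases = sc$scanner_phases,
                        noise_sd = sc$noise_sd,
                        trigger_delay_ns = sc$trigger_delay_ns,
                        photon_amp = sc$photon_amp)
  gates <- gate_set(matrix(unlist(x$gates$gates), ncol = 2),
                    record_len = x$gates$record_len)
  mixing <- if (is.null(x$mixing)) NULL else
    mixing_matrix(x$mixing$a, x$mixing$b, x$mixing$c)
  run_config(scope = scope, gates = gates, accumulation = x$accumulation,
             mixing = mixing, flim = as.list(x$flim), seed = x$seed)
}
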