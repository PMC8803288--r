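# File dialects
#
# accelerometer CSV : timestamp_gmt (ISO-8601, milliseconds), accel_z_g
# GPS CSV           : timestamp_gmt, lat, lon (WGS84 decimal degrees)
# recorders CSV     : recorder_id, lat, lon
# bout TSV          : recorder_id, begin_s, end_s (GMT epoch seconds),
#                     tab-separated with header, in the spirit of a Raven
#                     selection table
# labels CSV        : timestamp_gmt, behavior
# model TXT         : key/value lines with full-precision decimals
#
# Timestamps are serialized as ISO-8601 UTC with millisecond precision
# (25 Hz needs sub-second resolution); internally times are numeric GMT
# epoch seconds.

fmt_gmt <- function(time_s) {
  t <- .POSIXct(time_s, tz = "GMT")
  paste0(format(t, "%Y-%m-%dT%H:%M:", tz = "GMT"),
         sprintf("%06.3f", as.numeric(time_s) %% 60), "Z")
}

# parse ISO timestamp to epoch seconds; seconds-with-milliseconds are taken
# from the printed field to avoid strptime fractional-second drift
parse_gmt <- function(x, file = "<input>") {
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?Z$", x)
  if (any(!ok))
    stop(sprintf("%s: unparseable timestamp on data line %d: '%s'",
                 file, which(!ok)[1], x[which(!ok)[1]]))
  base <- as.numeric(as.POSIXct(substr(x, 1, 16), format = "%Y-%m-%dT%H:%M",
                                tz = "GMT"))
  secs <- as.numeric(substring(x, 18, nchar(x) - 1))
  base + secs
}

check_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", file, paste(miss, collapse = ", ")))
}

check_sorted <- function(time_s, file) {
  bad <- which(diff(time_s) <= 0)
  if (length(bad) > 0)
    stop(sprintf("%s: timestamps not strictly increasing at data line %d",
                 file, bad[1] + 1))
}

check_numeric <- function(x, col, file) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0)
    stop(sprintf("%s: non-numeric value in '%s' on data line %d: '%s'",
                 file, col, bad[1], x[bad[1]]))
  v
}

#' Read and write the accelerometer CSV dialect
#'
#' Columns `timestamp_gmt` (ISO-8601 UTC with milliseconds) and `accel_z_g`.
#' Writing then reading restores the trace to millisecond/1e-6 g precision,
#' and re-writing a read file is byte-identical (canonical form).
#'
#' @param trace An [accel_trace()].
#' @param path File path.
#' @param kind Trace kind to stamp on the result of reading.
#' @return `read_accel_csv` returns an `accel_trace`; the writer returns
#'   `path` invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- data.frame(timestamp_gmt = fmt_gmt(trace$time_s),
                   accel_z_g = sprintf("%.6f", trace$accel_g))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path, kind = "raw") {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_cols(df, c("timestamp_gmt", "accel_z_g"), path)
  t <- parse_gmt(df$timestamp_gmt, path)
  check_sorted(t, path)
  accel_trace(t, check_numeric(df$accel_z_g, "accel_z_g", path), kind = kind)
}

#' Read and write the GPS CSV dialect
#'
#' Columns `timestamp_gmt`, `lat`, `lon` (WGS84 decimal degrees).
#'
#' @param track A `gps_track` data.frame.
#' @param path File path.
#' @return `read_gps_csv` returns a `gps_track`; the writer returns `path`
#'   invisibly.
#' @export
write_gps_csv <- function(track, path) {
  df <- data.frame(timestamp_gmt = fmt_gmt(track$time_s),
                   lat = sprintf("%.7f", track$lat),
                   lon = sprintf("%.7f", track$lon))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gps_csv
#' @export
read_gps_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_cols(df, c("timestamp_gmt", "lat", "lon"), path)
  t <- parse_gmt(df$timestamp_gmt, path)
  check_sorted(t, path)
  structure(data.frame(time_s = t,
                       lat = check_numeric(df$lat, "lat", path),
                       lon = check_numeric(df$lon, "lon", path)),
            class = c("gps_track", "data.frame"))
}

#' Read and write the recorder-position CSV
#'
#' Columns `recorder_id`, `lat`, `lon`.
#'
#' @param recorders data.frame with `id`, `lat`, `lon`.
#' @param path File path.
#' @return `read_recorders_csv` returns a data.frame `id`, `lat`, `lon`.
#' @export
write_recorders_csv <- function(recorders, path) {
  df <- data.frame(recorder_id = recorders$id,
                   lat = sprintf("%.7f", recorders$lat),
                   lon = sprintf("%.7f", recorders$lon))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recorders_csv
#' @export
read_recorders_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_cols(df, c("recorder_id", "lat", "lon"), path)
  data.frame(id = df$recorder_id,
             lat = check_numeric(df$lat, "lat", path),
             lon = check_numeric(df$lon, "lon", path))
}

#' Read and write the song-bout annotation TSV
#'
#' Tab-separated with header, columns `recorder_id`, `begin_s`, `end_s` (GMT
#' epoch seconds) — a minimal Raven-selection-table-like dialect. When read
#' as audio ground truth (`check_min_s = 10`), rows shorter than the
#' annotation convention's minimum trigger a warning with their line number.
#'
#' @param bouts data.frame with `recorder_id` (or `behavior` for model
#'   bouts), `begin_s`/`start_s`, `end_s`.
#' @param path File path.
#' @param check_min_s Warn about rows shorter than this duration (`NULL` to
#'   skip).
#' @return `read_bout_tsv` returns an `audio_bouts` data.frame.
#' @export
write_bout_tsv <- function(bouts, path) {
  id <- if ("recorder_id" %in% names(bouts)) bouts$recorder_id
        else rep("model", nrow(bouts))
  b <- if ("begin_s" %in% names(bouts)) bouts$begin_s else bouts$start_s
  e <- bouts$end_s
  df <- data.frame(recorder_id = id,
                   begin_s = sprintf("%.3f", b), end_s = sprintf("%.3f", e))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bout_tsv
#' @export
read_bout_tsv <- function(path, check_min_s = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  check_cols(df, c("recorder_id", "begin_s", "end_s"), path)
  out <- data.frame(recorder_id = df$recorder_id,
                    begin_s = check_numeric(df$begin_s, "begin_s", path),
                    end_s = check_numeric(df$end_s, "end_s", path))
  if (any(out$end_s <= out$begin_s))
    stop(sprintf("%s: end_s <= begin_s on data line %d", path,
                 which(out$end_s <= out$begin_s)[1]))
  if (!is.null(check_min_s)) {
    short <- which(out$end_s - out$begin_s < check_min_s)
    if (length(short) > 0)
      warning(sprintf("%s: %d row(s) shorter than %g s (first at data line %d); the annotation convention records only bouts of at least %g s",
                      path, length(short), check_min_s, short[1], check_min_s))
  }
  structure(out, class = c("audio_bouts", "data.frame"))
}

#' Write per-second behavior labels
#'
#' Columns `timestamp_gmt`, `behavior`.
#'
#' @param labels `behavior_labels` data.frame.
#' @param path File path.
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(timestamp_gmt = fmt_gmt(labels$time_s),
                   behavior = labels$behavior)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_cols(df, c("timestamp_gmt", "behavior"), path)
  structure(data.frame(time_s = parse_gmt(df$timestamp_gmt, path),
                       behavior = df$behavior),
            class = c("behavior_labels", "data.frame"))
}

#' Serialize a fitted Gaussian HMM as human-readable text
#'
#' Key/value lines (`K`, `pi`, one `A` row per line, `mu`, `sigma`,
#' optionally `seed` and `loglik`) with 17-significant-digit decimals, which
#' round-trip doubles exactly.
#'
#' @param model A `gaussian_hmm`.
#' @param path File path.
#' @param seed,loglik Optional provenance recorded alongside the parameters.
#' @return `read_model` returns a `gaussian_hmm` with attributes `seed` and
#'   `loglik` when present.
#' @export
write_model <- function(model, path, seed = NULL, loglik = NULL) {
  stopifnot(inherits(model, "gaussian_hmm"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(paste("K", model$K),
             paste("pi", num(model$pi)),
             vapply(seq_len(model$K),
                    function(i) paste0("A", i, " ", num(model$A[i, ])), ""),
             paste("mu", num(model$mu)),
             paste("sigma", num(model$sigma)),
             paste("sigma_floor", num(model$sigma_floor)))
  if (!is.null(seed)) lines <- c(lines, paste("seed", seed))
  if (!is.null(loglik)) lines <- c(lines, paste("loglik", num(loglik)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " +")
  key <- vapply(kv, `[`, "", 1)
  val <- lapply(kv, function(x) as.numeric(x[-1]))
  names(val) <- key
  K <- as.integer(val$K)
  A <- do.call(rbind, val[paste0("A", seq_len(K))])
  m <- gaussian_hmm(val$pi, A, val$mu, val$sigma,
                    sigma_floor = val$sigma_floor %||% 1e-4)
  if (!is.null(val$seed)) attr(m, "seed") <- as.integer(val$seed)
  if (!is.null(val$loglik)) attr(m, "loglik") <- val$loglik
  m
}

#' Read a pipeline configuration file
#'
#' A single human-readable YAML file holding the pipeline constants, the
#' emission spec, site geometry and duration distributions. Only keys present
#' in the file override the defaults from [pipeline_config()],
#' [emission_spec()] and [night_config()].
#'
#' @param path YAML file path.
#' @return A list with elements `pipeline`, `night`, `emission`, `geometry`
#'   (the latter `NULL` unless given in the file).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pl <- do.call(pipeline_config, y$pipeline %||% list())
  ncfg <- do.call(night_config, y$night %||% list())
  em <- do.call(emission_spec, y$emission %||% list())
  geom <- if (!is.null(y$geometry)) {
    site_geometry(as.data.frame(y$geometry$song_posts),
                  as.data.frame(y$geometry$foraging_patches),
                  as.data.frame(y$geometry$recorders),
                  gps_error_sd = y$geometry$gps_error_sd %||% (20 / 1.96))
  } else NULL
  list(pipeline = pl, night = ncfg, emission = em, geometry = geom)
}
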