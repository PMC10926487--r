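#' @title Detection ingest and quality filtering
#' @description Readers for detector exports and capture logs, the
#'   quality filters applied to automated annotations, and aggregation of
#'   detections into per-evening counts with image-count exposure.
#' @name ingest
NULL

# Parse ISO-8601 timestamps with an explicit UTC offset ("+11:00" or
# "+1100") into POSIXct UTC, keeping the offset (hours) alongside.
parse_timestamp <- function(x) {
  x <- as.character(x)
  bad <- !grepl("[+-][0-9]{2}:?[0-9]{2}$", x)
  if (any(bad))
    stop("timestamp without UTC offset: ", x[which(bad)[1]],
         " (row ", which(bad)[1], ")")
  off_str <- sub("^.*([+-][0-9]{2}):?([0-9]{2})$", "\\1.\\2", x)
  offset <- ifelse(substr(off_str, 1, 1) == "-", -1, 1) *
    (abs(as.numeric(substr(off_str, 1, 3))) +
       as.numeric(substr(off_str, 5, 6)) / 60)
  core <- sub("([+-][0-9]{2}):?([0-9]{2})$", "", x)
  t <- as.POSIXct(core, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(t)) {
    i <- which(is.na(t))[1]
    stop("malformed timestamp '", x[i], "' (row ", i, ")")
  }
  list(utc = t - offset * 3600, offset = offset)
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a detection table
#'
#' One record per detected flying insect. Two dialects are supported: a
#' flat CSV (columns `site_id`, `timestamp` with explicit UTC offset,
#' `score`, `wingbeat_snr`, `wingbeat_freq`, `track_dx`, `track_dy`,
#' `source`) and a VIA-style per-image annotation JSON export, where each
#' image entry carries `regions` whose `region_attributes` hold `score`,
#' `snr` and `wbf` and whose file-level attributes hold site and
#' timestamp.
#'
#' Missing quality fields stay missing (`NA`), never zero: a record with
#' no wingbeat measurement cannot be shown to pass the wingbeat filters.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"annotation_json"`.
#' @return Data frame of detection records: `site_id`, `timestamp`
#'   (POSIXct UTC), `utc_offset_hours`, `score`, `wingbeat_snr`,
#'   `wingbeat_freq`, `track_dx`, `track_dy`, `source`.
#' @export
read_detections <- function(path, dialect = c("csv", "annotation_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    raw <- utils::read.csv(path, colClasses = "character")
    need <- c("site_id", "timestamp", "score", "wingbeat_snr",
              "wingbeat_freq", "track_dx", "track_dy", "source")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("detection CSV missing columns: ",
                           paste(miss, collapse = ", "))
    ts <- parse_timestamp(raw$timestamp)
    score <- .num_or_na(raw$score)
    if (anyNA(score)) {
      i <- which(is.na(score))[1]
      stop("malformed score at row ", i, ": '", raw$score[i], "'")
    }
    if (any(score < 0 | score > 1))
      stop("score outside [0,1] at row ", which(score < 0 | score > 1)[1])
    out <- data.frame(
      site_id = raw$site_id,
      timestamp = ts$utc,
      utc_offset_hours = ts$offset,
      score = score,
      wingbeat_snr = .num_or_na(raw$wingbeat_snr),
      wingbeat_freq = .num_or_na(raw$wingbeat_freq),
      track_dx = .num_or_na(raw$track_dx),
      track_dy = .num_or_na(raw$track_dy),
      source = raw$source,
      stringsAsFactors = FALSE)
  } else {
    ann <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- list()
    for (img in ann) {
      fa <- img$file_attributes
      for (reg in img$regions) {
        ra <- reg$region_attributes
        rows[[length(rows) + 1]] <- data.frame(
          site_id = as.character(fa$site_id),
          raw_ts = as.character(fa$timestamp),
          score = as.numeric(ra$score),
          wingbeat_snr = if (is.null(ra$snr)) NA_real_ else as.numeric(ra$snr),
          wingbeat_freq = if (is.null(ra$wbf)) NA_real_ else as.numeric(ra$wbf),
          track_dx = if (is.null(ra$dx)) NA_real_ else as.numeric(ra$dx),
          track_dy = if (is.null(ra$dy)) NA_real_ else as.numeric(ra$dy),
          source = if (is.null(fa$source)) "still" else as.character(fa$source),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(empty_detections())
    ts <- parse_timestamp(out$raw_ts)
    out$timestamp <- ts$utc
    out$utc_offset_hours <- ts$offset
    out$raw_ts <- NULL
    out <- out[, c("site_id", "timestamp", "utc_offset_hours", "score",
                   "wingbeat_snr", "wingbeat_freq", "track_dx", "track_dy",
                   "source")]
  }
  both <- is.na(out$track_dx) == is.na(out$track_dy)
  if (!all(both))
    stop("track_dx/track_dy must be both present or both missing (row ",
         which(!both)[1], ")")
  out
}

empty_detections <- function() {
  data.frame(site_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
             utc_offset_hours = numeric(), score = numeric(),
             wingbeat_snr = numeric(), wingbeat_freq = numeric(),
             track_dx = numeric(), track_dy = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

#' Read a capture log
#'
#' Per-image capture records (`site_id`, `timestamp` with UTC offset),
#' used as the exposure denominator: the number of images taken inside an
#' evening window is the Poisson exposure for that site-evening.
#'
#' @param path CSV path.
#' @return Data frame `site_id`, `timestamp` (POSIXct UTC),
#'   `utc_offset_hours`, sorted within site.
#' @export
read_capture_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character")
  if (!all(c("site_id", "timestamp") %in% names(raw)))
    stop("capture log needs columns site_id, timestamp")
  ts <- parse_timestamp(raw$timestamp)
  out <- data.frame(site_id = raw$site_id, timestamp = ts$utc,
                    utc_offset_hours = ts$offset, stringsAsFactors = FALSE)
  out <- out[order(out$site_id, out$timestamp), ]
  dup <- stats::ave(as.numeric(out$timestamp), out$site_id,
                    FUN = function(z) c(1, diff(z)))
  if (any(dup <= 0)) stop("capture timestamps not strictly increasing within site")
  rownames(out) <- NULL
  out
}

#' Quality-filter thresholds
#'
#' Defaults follow the automated-annotation screen used for the field
#' data: prediction score at least 0.8, wingbeat signal-to-noise ratio in
#' the closed interval \[1, 50\], and wingbeat frequency in the closed
#' interval \[27, 78\] Hz. All bounds are inclusive; the score cut keeps
#' 0.8 exactly (scores *less than* 0.8 are excluded).
#'
#' @param min_score Minimum retained prediction score, in \[0, 1\].
#' @param snr_range Closed interval of retained wingbeat SNR.
#' @param freq_range_hz Closed interval of retained wingbeat frequency (Hz).
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_score = 0.8, snr_range = c(1, 50),
                              freq_range_hz = c(27, 78)) {
  stopifnot(min_score >= 0, min_score <= 1,
            length(snr_range) == 2, snr_range[1] <= snr_range[2],
            length(freq_range_hz) == 2, freq_range_hz[1] <= freq_range_hz[2])
  structure(list(min_score = min_score, snr_range = snr_range,
                 freq_range_hz = freq_range_hz), class = "filter_thresholds")
}

#' Apply detection quality filters
#'
#' Retains exactly the records whose prediction score is at least
#' `min_score`, whose wingbeat SNR lies inside `snr_range`, and whose
#' wingbeat frequency lies inside `freq_range_hz` (all closed intervals).
#' Records with a missing SNR or frequency are excluded: a missing value
#' cannot be shown to lie inside the accepted range. Order is preserved
#' and the operation is idempotent.
#'
#' @param records Detection data frame from [read_detections()].
#' @param thresholds A [filter_thresholds()] object.
#' @return The retained subset, original order.
#' @export
apply_quality_filters <- function(records, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (nrow(records) == 0) return(records)
  keep <- records$score >= thresholds$min_score &
    !is.na(records$wingbeat_snr) &
    records$wingbeat_snr >= thresholds$snr_range[1] &
    records$wingbeat_snr <= thresholds$snr_range[2] &
    !is.na(records$wingbeat_freq) &
    records$wingbeat_freq >= thresholds$freq_range_hz[1] &
    records$wingbeat_freq <= thresholds$freq_range_hz[2]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-evening detection counts with exposure
#'
#' For each evening window, counts the quality-filtered detections whose
#' timestamp falls inside the half-open interval `[start, end)` and the
#' capture-log images inside the same interval (the exposure). Evenings
#' with zero exposure are omitted — the camera was off, and exposure is
#' the Poisson offset, so a zero cannot be carried. Records that fall in
#' no window of their site raise a warning and are ignored.
#'
#' @param records Filtered detection data frame.
#' @param captures Capture log from [read_capture_log()].
#' @param windows Data frame of evening windows: `site_id`,
#'   `evening_date` (or `date`), `window_start`/`start`,
#'   `window_end`/`end` (POSIXct UTC). [solar_table()] produces one.
#' @return Data frame `site_id`, `evening_date`, `count`, `exposure`.
#' @export
evening_counts <- function(records, captures, windows) {
  w <- windows
  if (!"evening_date" %in% names(w)) w$evening_date <- w$date
  if (!"window_start" %in% names(w)) w$window_start <- w$start
  if (!"window_end" %in% names(w)) w$window_end <- w$end
  stopifnot(all(c("site_id", "evening_date", "window_start", "window_end")
                %in% names(w)))
  in_window <- function(times, sites, i) {
    sites == w$site_id[i] & times >= w$window_start[i] & times < w$window_end[i]
  }
  count <- integer(nrow(w))
  exposure <- integer(nrow(w))
  matched <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(w))) {
    m <- in_window(records$timestamp, records$site_id, i)
    matched <- matched | m
    count[i] <- sum(m)
    exposure[i] <- sum(in_window(captures$timestamp, captures$site_id, i))
  }
  if (nrow(records) > 0 && any(!matched))
    warning(sum(!matched), " detection(s) outside all evening windows; ignored")
  out <- data.frame(site_id = w$site_id,
                    evening_date = as.Date(w$evening_date),
                    count = count, exposure = exposure,
                    stringsAsFactors = FALSE)
  out <- out[out$exposure >= 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}
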