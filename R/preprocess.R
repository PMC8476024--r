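#' Filter raw GPS fixes on quality
#'
#' Removes fixes obtained with fewer than `min_sats` satellites or with a
#' horizontal dilution of precision above `max_hdop`; retained fixes satisfy
#' `nsats >= min_sats` and `hdop <= max_hdop` (boundary values kept).
#'
#' @param fixes Tibble with at least `nsats` and `hdop` columns.
#' @param min_sats Minimum satellite count retained.
#' @param max_hdop Maximum HDOP retained.
#' @return List with `fixes` (retained rows) and `report` (one-row tibble:
#'   `n_in, n_removed, pct_removed, n_low_sats, n_high_hdop`).
#' @export
filter_fixes <- function(fixes, min_sats = 4, max_hdop = 5) {
  for (col in c("nsats", "hdop")) {
    if (!col %in% names(fixes)) {
      stop("missing quality column '", col, "' in fix table")
    }
  }
  n <- nrow(fixes)
  low_sats <- !is.na(fixes$nsats) & fixes$nsats < min_sats
  high_hdop <- !is.na(fixes$hdop) & fixes$hdop > max_hdop
  keep <- !(low_sats | high_hdop)
  report <- tibble::tibble(
    n_in = n, n_removed = sum(!keep),
    pct_removed = if (n == 0) 0 else 100 * sum(!keep) / n,
    n_low_sats = sum(low_sats), n_high_hdop = sum(high_hdop)
  )
  list(fixes = fixes[keep, , drop = FALSE], report = report)
}

## Seconds since local midnight.
time_of_day <- function(ts) {
  as.numeric(ts) - as.numeric(as.POSIXct(format(ts, "%Y-%m-%d"), tz = owl_tz()))
}

parse_clock <- function(s) {
  p <- as.integer(strsplit(s, ":")[[1]])
  3600 * p[1] + 60 * ifelse(length(p) > 1, p[2], 0)
}

#' Segment cleaned fixes into individual-nights
#'
#' Assigns every fix to the night whose recording window contains it
#' (post-midnight hours belong to the previous evening's `night_date`),
#' then builds one segment per individual-night. An individual's final
#' night is dropped when recording stopped more than `truncation_tol_min`
#' minutes before the window end (battery ran out mid-night). Nights with
#' fewer than `min_fixes` positions remain available for distance and
#' displacement analyses but are flagged out of the space-use (KDE) set.
#'
#' @param fixes Cleaned fix tibble (`id, timestamp, x_m, y_m`, sorted in
#'   time within each individual).
#' @param window Clock window `c(start, end)`, end past midnight.
#' @param min_fixes Minimum positions for the space-use pathway.
#' @param drop_truncated_last Drop an individual's truncated final night.
#' @param truncation_tol_min Allowed shortfall (minutes) at the window end.
#' @return List with `segments` (list of `night_segment`: individual_id,
#'   night_date, fixes, complete, n_fixes, include_kde) and `exclusions`
#'   (tibble `id, night_date, reason, n_fixes`).
#' @export
segment_nights <- function(fixes, window = c("21:00", "04:00"),
                           min_fixes = 100, drop_truncated_last = TRUE,
                           truncation_tol_min = 10) {
  w0 <- parse_clock(window[1]); w1 <- parse_clock(window[2])
  if (w0 == w1) stop("window start equals end")
  if (w1 >= w0) stop("window must span midnight (end before start on the clock)")
  tod <- time_of_day(fixes$timestamp)
  in_evening <- tod >= w0
  in_morning <- tod <= w1
  night_date <- as.Date(format(fixes$timestamp, "%Y-%m-%d"))
  night_date[in_morning] <- night_date[in_morning] - 1
  outside <- !(in_evening | in_morning)

  exclusions <- list()
  if (any(outside)) {
    out_tab <- fixes[outside, , drop = FALSE]
    agg <- aggregate(list(n_fixes = out_tab$id),
                     by = list(id = out_tab$id,
                               night_date = as.Date(format(out_tab$timestamp,
                                                           "%Y-%m-%d"))),
                     FUN = length)
    agg$reason <- "outside_window"
    exclusions[[length(exclusions) + 1]] <- agg
  }
  keep <- !outside
  fixes <- fixes[keep, , drop = FALSE]
  night_date <- night_date[keep]

  segments <- list()
  for (ind in unique(fixes$id)) {
    sel <- fixes$id == ind
    nd_all <- night_date[sel]
    f_ind <- fixes[sel, , drop = FALSE]
    nights <- sort(unique(nd_all))
    for (nd in as.list(nights)) {
      fx <- f_ind[nd_all == nd, , drop = FALSE]
      fx <- fx[order(fx$timestamp), , drop = FALSE]
      win_start <- as.POSIXct(paste(nd, window[1]), tz = owl_tz())
      win_end <- as.POSIXct(paste(nd + 1, window[2]), tz = owl_tz())
      shortfall <- as.numeric(difftime(win_end, max(fx$timestamp), units = "mins"))
      late_start <- as.numeric(difftime(min(fx$timestamp), win_start, units = "mins"))
      complete <- shortfall <= truncation_tol_min && late_start <= truncation_tol_min
      truncated_last <- drop_truncated_last && nd == max(nights) &&
        shortfall > truncation_tol_min
      if (truncated_last) {
        exclusions[[length(exclusions) + 1]] <- data.frame(
          id = ind, night_date = nd, reason = "truncated_final_night",
          n_fixes = nrow(fx))
        next
      }
      if (nrow(fx) < min_fixes) {
        exclusions[[length(exclusions) + 1]] <- data.frame(
          id = ind, night_date = nd, reason = "below_min_fixes_kde",
          n_fixes = nrow(fx))
      }
      segments[[length(segments) + 1]] <- structure(
        list(individual_id = ind, night_date = nd, fixes = fx,
             complete = complete, n_fixes = nrow(fx),
             include_kde = nrow(fx) >= min_fixes),
        class = "night_segment")
    }
  }
  excl <- if (length(exclusions)) {
    tibble::as_tibble(do.call(rbind, lapply(exclusions, function(d)
      d[, c("id", "night_date", "reason", "n_fixes")])))
  } else {
    tibble::tibble(id = character(), night_date = as.Date(character()),
                   reason = character(), n_fixes = integer())
  }
  list(segments = segments, exclusions = excl)
}

#' @exportS3Method base::print
print.night_segment <- function(x, ...) {
  cat("<night_segment> ", x$individual_id, " ", format(x$night_date),
      ": ", x$n_fixes, " fixes",
      if (x$complete) " (complete)" else " (incomplete)",
      if (!x$include_kde) " [excluded from KDE set]", "\n", sep = "")
  invisible(x)
}

#' Attach hourly weather to night segments
#'
#' Joins temperature and precipitation onto every fix by (night_date,
#' clock hour). Hours without a weather record get `NA` values and a
#' `weather_missing` flag; nothing is interpolated. Duplicate weather keys
#' are an error.
#'
#' @param segmented Output of [segment_nights()] (or a bare segment list).
#' @param weather Tibble from [generate_weather()] / [read_weather()].
#' @return Same structure with `temp_c`, `precip`, `weather_missing`
#'   columns added to each segment's fixes.
#' @export
attach_weather <- function(segmented, weather) {
  segs <- if (!is.null(segmented$segments)) segmented$segments else segmented
  key <- paste(weather$night_date, weather$hour)
  if (anyDuplicated(key)) {
    stop("duplicate weather records for night-hour key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  idx <- setNames(seq_along(key), key)
  segs <- lapply(segs, function(s) {
    hr <- as.integer(format(s$fixes$timestamp, "%H"))
    k <- paste(s$night_date, hr)
    j <- idx[k]
    s$fixes$temp_c <- weather$temp_c[j]
    s$fixes$precip <- weather$precip[j]
    s$fixes$weather_missing <- is.na(j)
    s
  })
  if (!is.null(segmented$segments)) {
    segmented$segments <- segs
    segmented
  } else {
    segs
  }
}
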