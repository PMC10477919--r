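iso_week_start <- function(ts) {
  lubridate::as_date(lubridate::floor_date(ts, unit = "week", week_start = 1))
}

#' Weekly volume series per group
#'
#' Buckets classified (and optionally segmented) posts into ISO weeks
#' (Monday start, UTC) and counts volumes per group. `NOISE` posts are
#' excluded. Missing weeks inside the corpus span are zero-filled so every
#' series is contiguous.
#'
#' @param posts_labeled tibble with `post_id`, `timestamp`, `country` and a
#'   `category` column (e.g. classification labels joined onto posts);
#'   optional `segment` and `is_question` columns.
#' @param by grouping columns among `country`, `category`, `segment`,
#'   `is_question`.
#' @return tibble: grouping columns, `week` (Date, Monday), `volume`.
#' @export
aggregate_weekly <- function(posts_labeled,
                             by = c("country", "category")) {
  stopifnot(all(by %in% names(posts_labeled)))
  df <- posts_labeled[posts_labeled$category != NOISE_LABEL, , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble(week = as.Date(character(0)), volume = integer(0)))
  }
  df$week <- iso_week_start(df$timestamp)
  all_weeks <- seq(min(df$week), max(df$week), by = "7 days")
  out <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), .data$week, name = "volume") |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(by)),
                    week = all_weeks,
                    fill = list(volume = 0L)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(by, "week"))))
  out
}

#' Velocity values and alerts for one weekly series
#'
#' The velocity for week i is the relative difference between the current
#' weekly volume and the trailing mean over the previous `window` weeks:
#' `V_i = (Vol_i - m_i) / m_i` with `m_i = mean(Vol_{i-window} ..
#' Vol_{i-1})`. A week is flagged when `V_i >= threshold` (a volume change
#' at least 15% above the trailing mean, by default) and `Vol_i >=
#' min_volume`. Velocities exist only from week `window + 1` on. When the
#' trailing mean is zero the velocity is undefined; the week is flagged iff
#' the volume clears `min_volume` and is recorded distinctly as a new
#' topic.
#'
#' @param series tibble with `week` and `volume` (one group), or a numeric
#'   volume vector.
#' @param window trailing-mean window in weeks (default 4).
#' @param threshold alert threshold on relative change (default 0.15).
#' @param min_volume minimum weekly volume for an alert (default 10; set 0
#'   for the strict textbook rule).
#' @return tibble: `week`, `volume`, `baseline_mean`, `velocity`,
#'   `flagged`, `new_topic`.
#' @export
velocity_series <- function(series, window = 4, threshold = 0.15,
                            min_volume = 10) {
  if (window < 1) stop("window must be >= 1")
  if (is.data.frame(series)) {
    vol <- as.numeric(series$volume)
    weeks <- series$week
  } else {
    vol <- as.numeric(series)
    weeks <- seq_along(vol)
  }
  n <- length(vol)
  baseline <- rep(NA_real_, n)
  velocity <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  new_topic <- rep(FALSE, n)
  if (n >= window + 1) {
    for (i in seq(window + 1, n)) {
      m <- mean(vol[(i - window):(i - 1)])
      baseline[i] <- m
      if (m > 0) {
        velocity[i] <- (vol[i] - m) / m
        flagged[i] <- velocity[i] >= threshold && vol[i] >= min_volume
      } else {
        new_topic[i] <- TRUE
        flagged[i] <- vol[i] >= min_volume
      }
    }
  }
  tibble::tibble(week = weeks, volume = vol, baseline_mean = baseline,
                 velocity = velocity, flagged = flagged, new_topic = new_topic)
}

#' Velocity alerts for every weekly series in a grouped table
#'
#' @param weekly tibble from [aggregate_weekly()].
#' @param by grouping columns identifying each series.
#' @inheritParams velocity_series
#' @return tibble: grouping columns plus the [velocity_series()] columns.
#' @export
velocity_alerts <- function(weekly, by = setdiff(names(weekly), c("week", "volume")),
                            window = 4, threshold = 0.15, min_volume = 10) {
  weekly |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(g, key) {
      velocity_series(g, window = window, threshold = threshold,
                      min_volume = min_volume)
    }) |>
    dplyr::ungroup()
}

#' Count flagged alert weeks per group
#'
#' Supports the reporting layouts "alerts by category and gender" and
#' "alerts by category question rate and gender" over a period.
#'
#' @param alerts tibble from [velocity_alerts()].
#' @param by grouping columns (default: everything but the per-week
#'   columns).
#' @param period optional length-2 Date vector restricting weeks
#'   (inclusive).
#' @return tibble: grouping columns, `n_alerts`.
#' @export
count_alerts <- function(alerts,
                         by = setdiff(names(alerts),
                                      c("week", "volume", "baseline_mean",
                                        "velocity", "flagged", "new_topic")),
                         period = NULL) {
  df <- alerts
  if (!is.null(period)) {
    df <- df[df$week >= period[1] & df$week <= period[2], , drop = FALSE]
  }
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_alerts = sum(.data$flagged), .groups = "drop")
}

#' Export velocity alerts as CSV
#' @param alerts tibble from [velocity_alerts()].
#' @param path destination CSV.
#' @export
write_alerts <- function(alerts, path) {
  readr::write_csv(alerts, path, progress = FALSE)
  invisible(path)
}
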