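test_that("velocity on printed toy series matches hand arithmetic", {
  v <- velocity_series(c(100, 100, 100, 100, 120))
  expect_equal(v$velocity[5], 0.20)
  expect_equal(v$baseline_mean[5], 100)
  expect_true(v$flagged[5])
  expect_true(all(is.na(v$velocity[1:4])))

  # constant series: zero velocity everywhere, no alerts
  v2 <- velocity_series(rep(50, 10))
  expect_true(all(v2$velocity[5:10] == 0))
  expect_false(any(v2$flagged))

  # trailing mean 25, velocity (23 - 25)/25 = -0.08
  v3 <- velocity_series(c(10, 20, 30, 40, 23))
  expect_equal(v3$baseline_mean[5], 25)
  expect_equal(v3$velocity[5], -0.08)
  expect_false(v3$flagged[5])
})

test_that("zero-baseline weeks follow the new-topic rule and min_volume gates alerts", {
  v <- velocity_series(c(0, 0, 0, 0, 12), min_volume = 10)
  expect_true(is.na(v$velocity[5]))
  expect_true(v$new_topic[5])
  expect_true(v$flagged[5])
  v2 <- velocity_series(c(0, 0, 0, 0, 5), min_volume = 10)
  expect_false(v2$flagged[5])
  # a large relative jump below the volume floor is suppressed
  v3 <- velocity_series(c(2, 2, 2, 2, 4), min_volume = 10)
  expect_equal(v3$velocity[5], 1)
  expect_false(v3$flagged[5])
  expect_true(velocity_series(c(2, 2, 2, 2, 4), min_volume = 0)$flagged[5])
  expect_error(velocity_series(1:10, window = 0), "window")
})

test_that("velocity agrees with a brute-force loop recomputation to 1e-12", {
  set.seed(33)
  for (rep in 1:50) {
    vol <- rpois(sample(6:20, 1), lambda = sample(c(5, 50, 500), 1))
    got <- velocity_series(vol, min_volume = 0)
    for (i in seq_along(vol)) {
      if (i <= 4) {
        expect_true(is.na(got$velocity[i]))
      } else {
        m <- (vol[i - 4] + vol[i - 3] + vol[i - 2] + vol[i - 1]) / 4
        if (m > 0) {
          expect_equal(got$velocity[i], (vol[i] - m) / m, tolerance = 1e-12)
          expect_equal(got$flagged[i], (vol[i] - m) / m >= 0.15)
        }
      }
    }
  }
})

test_that("velocity is scale invariant and damped by a constant baseline shift", {
  vol <- c(30, 35, 28, 32, 60, 31, 30, 29, 33, 58)
  v1 <- velocity_series(vol, min_volume = 0)
  v2 <- velocity_series(vol * 7, min_volume = 0)
  expect_equal(v1$velocity, v2$velocity, tolerance = 1e-12)
  v3 <- velocity_series(vol + 100, min_volume = 0)
  spikes <- which(v1$velocity > 0.15)
  expect_true(all(abs(v3$velocity[spikes]) < abs(v1$velocity[spikes])))
})

test_that("weekly aggregation buckets by ISO week, zero-fills gaps and drops noise", {
  base <- as.POSIXct("2021-01-04 00:00:00", tz = "UTC")  # a Monday
  df <- tibble::tibble(
    post_id = sprintf("p%d", 1:10),
    timestamp = c(rep(base + 3600, 7), rep(base + 15 * 86400, 2), base),
    country = "GB",
    category = c(rep("cat01", 7), rep("cat01", 2), NOISE_LABEL)
  )
  wk <- aggregate_weekly(df, by = c("country", "category"))
  expect_equal(nrow(wk), 3)                       # weeks 1..3, gap filled
  expect_equal(wk$volume, c(7L, 0L, 2L))
  expect_equal(as.integer(diff(wk$week)), c(7L, 7L))
  expect_equal(unique(wk$category), "cat01")      # noise excluded
  expect_equal(nrow(aggregate_weekly(df[0, ], by = c("country", "category"))), 0)
})

test_that("alert counts on a spiked synthetic timeline exactly match the spike ledger", {
  b <- generate_corpus(synthetic_spec(seed = 11))
  labeled <- dplyr::inner_join(
    b$posts,
    tibble::tibble(post_id = b$gold$post_id,
                   category = vapply(b$gold$categories,
                                     function(x) if (length(x)) x else NOISE_LABEL,
                                     character(1))),
    by = c(id = "post_id"))
  labeled$post_id <- labeled$id
  wk <- aggregate_weekly(labeled, by = c("country", "category"))
  # weekly volumes reproduce the generator's ground-truth ledger of counts
  truth <- b$weekly_counts
  joined <- dplyr::inner_join(wk, truth, by = c("category", "week"))
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$volume.x, joined$volume.y)

  alerts <- velocity_alerts(wk)
  flagged <- alerts[alerts$flagged, c("category", "week")]
  expect_equal(nrow(flagged), nrow(b$ledger))
  expect_equal(flagged$category, b$ledger$category)
  expect_equal(flagged$week, b$ledger$week)

  counts <- count_alerts(alerts, by = c("country", "category"))
  for (cat in unique(truth$category)) {
    expect_equal(counts$n_alerts[counts$category == cat],
                 sum(b$ledger$category == cat))
  }
})

test_that("gender-split alert series partition the combined series on synthetic data", {
  b <- generate_corpus(synthetic_spec(seed = 13))
  labeled <- dplyr::inner_join(
    b$posts,
    tibble::tibble(post_id = b$gold$post_id,
                   category = vapply(b$gold$categories,
                                     function(x) if (length(x)) x else NOISE_LABEL,
                                     character(1))),
    by = c(id = "post_id"))
  labeled$post_id <- labeled$id
  labeled <- dplyr::inner_join(labeled, b$segments, by = "post_id")
  combined <- aggregate_weekly(labeled, by = c("country", "category"))
  split <- aggregate_weekly(labeled, by = c("country", "category", "segment"))
  resum <- split |>
    dplyr::group_by(.data$country, .data$category, .data$week) |>
    dplyr::summarise(volume = sum(.data$volume), .groups = "drop")
  j <- dplyr::inner_join(combined, resum, by = c("country", "category", "week"))
  expect_equal(j$volume.x, j$volume.y)
})
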