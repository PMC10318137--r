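test_that("familiarity filtering drops flagged traces and empty songs", {
  co <- toy_cohort(list(list(1:3, 4:6, 7:9), list(2:4, 5:7, 8:10)),
                   c("hit", "flop"))
  # identity when nothing is familiar
  out <- filter_unfamiliar(co$traces, co$surveys)
  expect_equal(nrow(out), nrow(co$traces))

  # one familiar listener: song averaged over the remaining two
  co2 <- toy_cohort(list(list(rep(2, 4), rep(4, 4), rep(9, 4))), "hit",
                    familiar = list(c("p03", "s01")))
  flt <- filter_unfamiliar(co2$traces, co2$surveys)
  ser <- song_average_series(flt)
  expect_equal(ser$n_participants, 2L)
  expect_equal(unname(ser$avg_series), rep(3, 4))

  # all listeners familiar: song excluded with a warning
  co3 <- toy_cohort(list(list(1:4, 1:4), list(2:5, 2:5)), c("hit", "flop"),
                    familiar = list(c("p01", "s02"), c("p02", "s02")))
  expect_warning(flt3 <- filter_unfamiliar(co3$traces, co3$surveys,
                                           min_participants = 2L),
                 "s02")
  expect_setequal(unique(flt3$song_id), "s01")

  # trace with no survey row is an error
  expect_error(filter_unfamiliar(co$traces, co$surveys[-1, ]),
               "without survey row")
})

test_that("song averaging truncates to the shortest trace", {
  ser <- series_from(c(1, 2, 3), c(3, 2, 1))
  expect_equal(unname(ser$avg_series), c(2, 2, 2))
  # single participant: identity
  ser1 <- series_from(c(5, 6, 7))
  expect_equal(unname(ser1$avg_series), c(5, 6, 7))
  # unequal lengths: both cut to the shortest, then averaged
  ser2 <- series_from(rep(2, 8), rep(4, 5))
  expect_length(ser2$avg_series, 5L)
  expect_equal(unname(ser2$avg_series), rep(3, 5))
  expect_error(song_average_series(data.table::data.table(
    participant_id = character(0), song_id = character(0),
    t_sec = integer(0), immersion = numeric(0))), "no traces")
})

test_that("threshold statistics match hand-computed values", {
  # constant series across equal participants
  serc <- series_from(rep(3, 6), rep(3, 6))
  st <- compute_threshold(serc)
  expect_equal(st$median_avg, 3)
  expect_equal(st$sample_sd, 0)
  expect_equal(st$threshold, 3)

  # single participant 1..5: median 3, sample SD sqrt(2.5)
  st2 <- compute_threshold(series_from(1:5))
  expect_equal(st2$median_avg, 3)
  expect_equal(st2$sample_sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(st2$threshold, 3 + sqrt(2.5), tolerance = 1e-12)
  expect_equal(st2$total_immersion, 15)

  # two participants, constant 0 and constant 2: all-sample SD sqrt(1.2)
  st3 <- compute_threshold(series_from(rep(0, 3), rep(2, 3)))
  expect_equal(st3$median_avg, 1)
  expect_equal(st3$sample_sd, sqrt(1.2), tolerance = 1e-12)
  expect_equal(st3$threshold, 1 + sqrt(1.2), tolerance = 1e-12)
})

test_that("peak immersion matches the worked single-participant example", {
  ser <- series_from(c(1, 1, 1, 10))
  st <- compute_threshold(ser)
  expect_equal(st$threshold, 5.5)  # median 1 + all-sample SD 4.5
  expect_equal(peak_immersion(ser, st), 10 / 13, tolerance = 1e-12)
  # constant series: nothing strictly exceeds the threshold
  expect_equal(peak_immersion(series_from(rep(4, 10))), 0)
  # all-zero song: undefined
  expect_error(peak_immersion(series_from(rep(0, 5))), "total immersion")
})

test_that("retreat follows the sorted-quintile rule", {
  expect_equal(retreat(series_from(rep(7, 10))), 0.2)     # k = 2, 2c/10c
  expect_equal(retreat(series_from(1:10)), 3 / 55, tolerance = 1e-12)
  expect_equal(retreat(series_from(rep(1, 4))), 0.25)     # floor rule: k = 1
  expect_error(retreat(series_from(rep(0, 5))), "total immersion")
  # raw (unnormalized) variant returns the plain quintile sum
  expect_equal(retreat(series_from(1:10), normalize = FALSE), 3)
})

test_that("peak and retreat equal brute-force oracles on random series", {
  set.seed(42)
  for (i in 1:250) {
    ser <- random_series()
    expect_equal(peak_immersion(ser), oracle_peak(ser), tolerance = 1e-12)
    expect_equal(retreat(ser), oracle_retreat(ser), tolerance = 1e-12)
    expect_equal(compute_threshold(ser)$threshold, oracle_threshold(ser),
                 tolerance = 1e-12)
  }
})

test_that("feature bounds, scale invariance and quintile monotonicity hold", {
  set.seed(11)
  for (i in 1:50) {
    ser <- random_series(t_len = sample(5:30, 1))
    p <- peak_immersion(ser)
    r <- retreat(ser)
    t_len <- length(ser$avg_series)
    k <- max(1, floor(0.2 * t_len))
    expect_gte(p, 0); expect_lte(p, 1)
    expect_lte(r, k / t_len + 1e-12)
    if (t_len >= 5) expect_lte(r, 0.2 + 1e-12)
    # scale invariance: both statistics are ratios
    ser_scaled <- ser
    ser_scaled$avg_series <- ser$avg_series * 3.7
    ser_scaled$sample_matrix <- ser$sample_matrix * 3.7
    expect_equal(peak_immersion(ser_scaled), p, tolerance = 1e-12)
    expect_equal(retreat(ser_scaled), r, tolerance = 1e-12)
  }
  # raising the lowest-quintile values weakly increases the raw quintile sum
  ser <- random_series(t_len = 20, n_p = 1)
  k <- 4L
  ord <- order(ser$avg_series)
  bumped <- ser
  bumped$avg_series[ord[1:k]] <- bumped$avg_series[ord[1:k]] +
    0.5 * (bumped$avg_series[ord[k + 1]] - bumped$avg_series[ord[1:k]])
  expect_gte(retreat(bumped, normalize = FALSE),
             retreat(ser, normalize = FALSE))
  expect_lte(retreat(bumped), k / 20 + 1e-12)
})

test_that("featurize matches independent recomputation on a toy cohort", {
  co <- toy_cohort(list(list(c(1, 1, 1, 10), c(2, 2, 2, 8)),
                        list(c(5, 4, 3, 2), c(1, 2, 3, 4))),
                   c("hit", "flop"))
  f <- featurize(co$traces, co$surveys, co$songs)
  expect_equal(nrow(f), 2L)
  for (s in c("s01", "s02")) {
    ser <- song_average_series(co$traces[co$traces$song_id == s, ])
    row <- f[f$song_id == s, ]
    expect_equal(row$avg_immersion, mean(ser$avg_series))
    expect_equal(row$peak_immersion, peak_immersion(ser))
    expect_equal(row$retreat, retreat(ser))
    expect_equal(row$n_participants, 2L)
  }
  expect_equal(f$label, c("hit", "flop"))

  # 60-second traces: first-minute window is the identity
  co60 <- toy_cohort(list(list(runif(60, 2, 6), runif(60, 2, 6))), "hit")
  f_full <- featurize(co60$traces, co60$surveys, co60$songs, window = "full")
  f_min <- featurize(co60$traces, co60$surveys, co60$songs,
                     window = "first_minute")
  expect_equal(f_full$avg_immersion, f_min$avg_immersion)
  expect_equal(f_full$retreat, f_min$retreat)

  # missing label is an error
  expect_error(featurize(co$traces, co$surveys, co$songs[-1, ]), "label")
})

test_that("first-minute window truncates longer traces", {
  set.seed(5)
  vals <- runif(100, 2, 6)
  co <- toy_cohort(list(list(vals)), "hit")
  f_min <- featurize(co$traces, co$surveys, co$songs, window = "first_minute",
                     min_participants = 1L)
  ser60 <- series_from(vals[1:60])
  expect_equal(f_min$avg_immersion, mean(vals[1:60]))
  expect_equal(f_min$retreat, retreat(ser60))
})
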