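# shared fixtures, built in code

# song_series from explicit per-participant value vectors
series_from <- function(..., song_id = "sX") {
  vecs <- list(...)
  traces <- data.table::rbindlist(lapply(seq_along(vecs), function(i) {
    data.table::data.table(participant_id = sprintf("p%02d", i),
                           song_id = song_id,
                           t_sec = seq_along(vecs[[i]]) - 1L,
                           immersion = vecs[[i]])
  }))
  song_average_series(traces)
}

# minimal trace/survey/song tables for n participants x given song labels
toy_cohort <- function(values, labels, familiar = NULL) {
  # values: list over songs of list over participants of numeric vectors
  stopifnot(length(values) == length(labels))
  traces <- data.table::rbindlist(lapply(seq_along(values), function(s) {
    data.table::rbindlist(lapply(seq_along(values[[s]]), function(p) {
      data.table::data.table(participant_id = sprintf("p%02d", p),
                             song_id = sprintf("s%02d", s),
                             t_sec = seq_along(values[[s]][[p]]) - 1L,
                             immersion = values[[s]][[p]])
    }))
  }))
  pairs <- unique(traces[, c("participant_id", "song_id")])
  surveys <- data.table::data.table(
    pairs, liking = 5L, replay = 0L, recommend = 0L, familiar = 0L,
    offensive = 0L, lyric_memory = 0L)
  if (!is.null(familiar)) {
    for (fm in familiar) {
      surveys[surveys$participant_id == fm[1] & surveys$song_id == fm[2],
              "familiar"] <- 1L
    }
  }
  songs <- data.table::data.table(
    song_id = sprintf("s%02d", seq_along(labels)), label = labels,
    duration_sec = vapply(values, function(v) length(v[[1]]), integer(1)),
    streams = ifelse(labels == "hit", 1e6, 1e4),
    stations = 5L, likes = 100L)
  list(traces = traces, surveys = surveys, songs = songs)
}

# brute-force oracles for the song-level statistics (kept deliberately
# naive and loop-based, independent of the package implementation)
oracle_threshold <- function(series) {
  n <- length(series$avg_series)
  vals <- sort(series$avg_series)
  med <- if (n %% 2 == 1) vals[(n + 1) / 2] else
    (vals[n / 2] + vals[n / 2 + 1]) / 2
  samp <- as.vector(series$sample_matrix)
  s <- if (length(samp) > 1) sqrt(sum((samp - mean(samp))^2) / (length(samp) - 1)) else 0
  med + s
}

oracle_peak <- function(series) {
  m <- oracle_threshold(series)
  total <- 0; above <- 0
  for (v in series$avg_series) {
    total <- total + v
    if (v > m) above <- above + v
  }
  above / total
}

oracle_retreat <- function(series) {
  a <- series$avg_series
  k <- max(1, floor(0.2 * length(a)))
  picked <- a[order(a)][1:k]
  sum(picked) / sum(a)
}

# random multi-participant series for property tests
random_series <- function(t_len = sample(5:40, 1), n_p = sample(1:5, 1)) {
  vecs <- lapply(seq_len(n_p), function(i) round(runif(t_len, 0, 10), 3))
  do.call(series_from, vecs)
}

# simplex grid search oracle for ensemble weights (resolution res)
grid_search_weights <- function(Z, y, res = 0.001) {
  p <- ncol(Z)
  stopifnot(p %in% c(2L, 3L))
  b1 <- seq(0, 1, by = res)
  if (p == 2L) {
    W <- cbind(b1, 1 - b1)
  } else {
    g <- expand.grid(b1 = b1, b2 = b1)
    g <- g[g$b1 + g$b2 <= 1 + 1e-12, ]
    W <- cbind(g$b1, g$b2, 1 - g$b1 - g$b2)
  }
  risks <- colMeans((Z %*% t(W) - y)^2)
  list(beta = W[which.min(risks), ], risk = min(risks))
}
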