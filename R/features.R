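#' Drop traces from participants familiar with a song
#'
#' Self-reported liking is anchored to familiarity, so song-level analysis
#' uses only listeners who did not already know the song. Each
#' participant-song trace whose survey row has `familiar == 1` is removed;
#' songs left with fewer than `min_participants` listeners are excluded
#' entirely with a warning.
#'
#' @param traces long-format trace table (`participant_id`, `song_id`,
#'   `t_sec`, `immersion`).
#' @param surveys survey table with at least `participant_id`, `song_id`,
#'   `familiar`. Every trace must have a matching survey row.
#' @param min_participants minimum listeners a song must retain (default 2).
#' @return the filtered trace table; excluded song ids are attached as
#'   `attr(, "excluded_songs")`.
#' @export
filter_unfamiliar <- function(traces, surveys, min_participants = 2L) {
  traces <- as.data.table(traces)
  surveys <- as.data.table(surveys)
  pairs <- unique(traces[, .(participant_id, song_id)])
  m <- surveys[pairs, on = c("participant_id", "song_id")]
  if (anyNA(m$familiar)) {
    miss <- m[is.na(familiar)][1L]
    stop(sprintf("trace without survey row: participant %s, song %s",
                 miss$participant_id, miss$song_id), call. = FALSE)
  }
  keep_pairs <- m[familiar == 0, .(participant_id, song_id)]
  out <- traces[keep_pairs, on = c("participant_id", "song_id")]
  counts <- keep_pairs[, .(n_p = .N), by = song_id]
  all_songs <- unique(traces$song_id)
  low <- union(setdiff(all_songs, counts$song_id),
               counts[n_p < min_participants, song_id])
  if (length(low) > 0) {
    warning("excluding songs with fewer than ", min_participants,
            " unfamiliar listeners: ", paste(low, collapse = ", "),
            call. = FALSE)
    out <- out[!song_id %in% low]
  }
  setattr(out, "excluded_songs", low)
  out[]
}

#' Cross-participant average immersion series for one song
#'
#' Truncates all of a song's traces to their shortest common length, then
#' averages across participants at each second. The per-participant sample
#' matrix is retained because the peak-immersion threshold needs the SD
#' over all participant-second samples.
#'
#' @param traces long-format traces for a single song.
#' @return a `song_series` list: `song_id`, `avg_series`, `sample_matrix`
#'   (seconds x participants) and `n_participants`.
#' @export
song_average_series <- function(traces) {
  traces <- as.data.table(traces)
  if (nrow(traces) == 0L) stop("no traces supplied", call. = FALSE)
  sid <- unique(traces$song_id)
  if (length(sid) != 1L) {
    stop("song_average_series() expects traces for exactly one song",
         call. = FALSE)
  }
  lens <- traces[, .(len = .N), by = participant_id]
  t_min <- min(lens$len)
  tr <- traces[t_sec < t_min]
  setorder(tr, participant_id, t_sec)
  m <- matrix(tr$immersion, nrow = t_min,
              dimnames = list(NULL, lens$participant_id[order(lens$participant_id)]))
  structure(list(song_id = sid, avg_series = rowMeans(m), sample_matrix = m,
                 n_participants = ncol(m)),
            class = "song_series")
}

#' Threshold statistics for peak immersion
#'
#' The peak threshold is the median of the cross-participant average series
#' plus the sample SD taken over *all* participant-second samples of the
#' song (not over participant means: that is the only reading that uses
#' every participant and the full duration at once). Total immersion is the
#' sum of the average series.
#'
#' @param series a [song_average_series()] result.
#' @return list with `median_avg`, `sample_sd`, `threshold`
#'   (`median_avg + sample_sd`) and `total_immersion`.
#' @export
compute_threshold <- function(series) {
  stopifnot(inherits(series, "song_series"))
  avg <- series$avg_series
  if (length(avg) == 0L) stop("empty series", call. = FALSE)
  samples <- as.vector(series$sample_matrix)
  s <- if (length(samples) >= 2L) sd(samples) else 0
  list(median_avg = median(avg), sample_sd = s,
       threshold = median(avg) + s, total_immersion = sum(avg))
}

#' Peak immersion of a song
#'
#' Fraction of the song's total immersion contributed by seconds whose
#' average immersion strictly exceeds the median-plus-SD threshold. The
#' `"value"` mode cumulates the above-threshold values themselves (the
#' default: only a value sum forms a meaningful ratio to total immersion);
#' `"indicator"` counts above-threshold seconds instead and divides the
#' time by total immersion.
#'
#' @param series a [song_average_series()] result.
#' @param stats optional precomputed [compute_threshold()] result.
#' @param mode `"value"` (default) or `"indicator"`.
#' @return a fraction in `[0, 1]` (`"value"` mode).
#' @export
peak_immersion <- function(series, stats = compute_threshold(series),
                           mode = c("value", "indicator")) {
  mode <- match.arg(mode)
  avg <- series$avg_series
  if (stats$total_immersion <= 0) {
    stop("total immersion is zero; peak immersion undefined", call. = FALSE)
  }
  above <- avg > stats$threshold
  num <- if (mode == "value") sum(avg[above]) else sum(above)
  num / stats$total_immersion
}

#' Neurologic retreat of a song
#'
#' Cumulated mass of the lowest 20% of the cross-participant average
#' immersion values. The quintile holds `k = max(1, floor(0.2 T))` seconds,
#' selected by a stable ascending sort (ties keep time order). By default
#' the sum is expressed relative to total immersion, giving a fraction that
#' is at most `k/T` (and at most 0.2 once `T >= 5`); `normalize = FALSE`
#' returns the raw unit-second sum.
#'
#' @param series a [song_average_series()] result.
#' @param normalize divide by total immersion (default `TRUE`).
#' @return retreat fraction (or raw sum).
#' @export
retreat <- function(series, normalize = TRUE) {
  avg <- series$avg_series
  t_len <- length(avg)
  if (t_len == 0L) stop("empty series", call. = FALSE)
  im <- sum(avg)
  if (normalize && im <= 0) {
    stop("total immersion is zero; retreat undefined", call. = FALSE)
  }
  k <- max(1L, floor(0.2 * t_len))
  low_sum <- sum(sort(avg, method = "radix")[seq_len(k)])
  if (normalize) low_sum / im else low_sum
}

#' Song-level neural feature table
#'
#' The full featurization path: familiarity filtering, optional truncation
#' to the first minute, cross-participant averaging, and the three
#' song-level statistics (average immersion, peak immersion, retreat), one
#' row per retained song with its hit/flop label.
#'
#' @param traces,surveys,songs cohort tables as produced by
#'   [simulate_cohort()] or [read_cohort_tables()]. `songs` must map every
#'   `song_id` to a `label`.
#' @param window `"full"` or `"first_minute"` (truncates each trace to
#'   `t_sec < 60` before averaging).
#' @param min_participants passed to [filter_unfamiliar()].
#' @param peak_mode passed to [peak_immersion()].
#' @param normalize_retreat passed to [retreat()].
#' @return a `data.table` with columns `song_id`, `label`, `avg_immersion`,
#'   `peak_immersion`, `retreat`, `n_participants`, `window`.
#' @export
featurize <- function(traces, surveys, songs,
                      window = c("full", "first_minute"),
                      min_participants = 2L,
                      peak_mode = c("value", "indicator"),
                      normalize_retreat = TRUE) {
  window <- match.arg(window)
  peak_mode <- match.arg(peak_mode)
  songs <- as.data.table(songs)
  if (!all(c("song_id", "label") %in% names(songs))) {
    stop("`songs` must contain song_id and label", call. = FALSE)
  }
  tr <- filter_unfamiliar(traces, surveys, min_participants)
  if (nrow(tr) == 0L) stop("no traces remain after familiarity filtering",
                           call. = FALSE)
  if (window == "first_minute") tr <- tr[t_sec < 60L]

  labmap <- setNames(normalize_label(songs$label), songs$song_id)
  present <- unique(tr$song_id)
  if (anyNA(labmap[present])) {
    stop("missing label for song(s): ",
         paste(setdiff(present, names(labmap)), collapse = ", "),
         call. = FALSE)
  }

  # truncate each song to its shortest retained trace, then aggregate
  lens <- tr[, .(len = .N), by = .(song_id, participant_id)]
  tmin <- lens[, .(minlen = min(len), n_p = .N), by = song_id]
  tr <- tr[tmin, on = "song_id"][t_sec < minlen]

  avg_tab <- tr[, .(avg = mean(immersion)), by = .(song_id, t_sec)]
  sd_tab <- tr[, .(sample_sd = if (.N >= 2L) sd(immersion) else 0),
               by = song_id]

  feat <- avg_tab[, {
    a <- avg[order(t_sec)]
    im <- sum(a)
    if (im <= 0) stop("song ", .BY$song_id, " has zero total immersion",
                      call. = FALSE)
    k <- max(1L, floor(0.2 * length(a)))
    list(avg_immersion = mean(a), total_immersion = im, med = median(a),
         retreat = sum(sort(a, method = "radix")[seq_len(k)]) /
           (if (normalize_retreat) im else 1),
         t_len = length(a))
  }, by = song_id]
  feat <- feat[sd_tab, on = "song_id"]
  thr <- feat$med + feat$sample_sd
  peak <- avg_tab[feat, on = "song_id"][
    , .(peak_immersion = {
      a <- avg[order(t_sec)]
      above <- a > (med + sample_sd)[1]
      num <- if (peak_mode == "value") sum(a[above]) else sum(above)
      num / total_immersion[1]
    }), by = song_id]
  out <- feat[peak, on = "song_id"][tmin, on = "song_id"]
  out <- out[, .(song_id, label = unname(labmap[song_id]),
                 avg_immersion, peak_immersion, retreat,
                 n_participants = n_p, window = window)]
  setorder(out, song_id)
  out[]
}
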