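#' Call sleep bouts from a minute-binned activity trace
#'
#' Applies the standard larval-zebrafish criterion: sleep is any period of
#' one or more consecutive minutes of immobility. A minute is immobile iff
#' its activity is at or below `epsilon` (default 0, i.e. strictly no
#' recorded movement); bouts are the maximal runs of immobile minutes.
#'
#' @param activity numeric vector of per-minute activity values (>= 0).
#' @param epsilon immobility threshold (default 0); expose a small positive
#'   value for noisy trackers.
#' @return data.frame with one row per bout: `start_minute` (0-based),
#'   `length_min`; empty for an empty or fully active trace.
#' @export
call_sleep_bouts <- function(activity, epsilon = 0) {
  empty <- data.frame(start_minute = integer(0), length_min = integer(0))
  if (!length(activity)) return(empty)
  if (any(activity < 0)) stop("activity must be non-negative")
  r <- rle(activity <= epsilon)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  data.frame(
    start_minute = starts[keep] - 1L,
    length_min = as.integer(r$lengths[keep])
  )
}

# hour-of-recording (0-based) and phase per minute for a given photoperiod
.minute_phase <- function(n_min, photoperiod = c(light = 14, dark = 10),
                          start_minute = 0) {
  cycle <- sum(photoperiod) * 60
  m <- (seq_len(n_min) - 1 + start_minute) %% cycle
  ifelse(m < photoperiod[["light"]] * 60, "light", "dark")
}

#' Summarize sleep architecture of one trace
#'
#' Per clock hour of the recording: minutes asleep, number of wake-to-sleep
#' transitions (bout onsets; equal to the number of bouts, so the transition
#' count and the bout-length summary describe the same events), mean length
#' of the bouts *starting* in that hour (a bout spanning an hour or phase
#' boundary counts wholly toward its onset hour, keeping counts additive),
#' and mean activity. Day/night aggregates are the means of the per-hour
#' values over light and dark hours, classified by the phase at the start of
#' each hour.
#'
#' @param bouts data.frame from [call_sleep_bouts()] on the same trace.
#' @param activity the trace's per-minute activity vector.
#' @param photoperiod named numeric, hours of `light` and `dark`.
#' @param epsilon immobility threshold used for per-minute sleep tallies
#'   (must match the bout call).
#' @param start_minute clock offset of the first minute relative to
#'   lights-on (default 0).
#' @return list with `hourly` (data.frame: `hour`, `phase`, `sleep_min`,
#'   `n_transitions`, `mean_bout_len`, `mean_activity`) and `phase`
#'   (data.frame with one row per phase: per-hour means of the same metrics).
#' @export
summarize_sleep <- function(bouts, activity,
                            photoperiod = c(light = 14, dark = 10),
                            epsilon = 0, start_minute = 0) {
  n_min <- length(activity)
  cycle_h <- sum(photoperiod)
  hour_of <- ((seq_len(n_min) - 1 + start_minute) %/% 60) %% cycle_h
  hours <- sort(unique(hour_of))
  phase_min <- .minute_phase(n_min, photoperiod, start_minute)
  asleep <- activity <= epsilon

  minutes_per_hour <- as.integer(rowsum(rep(1, n_min), hour_of))
  sleep_min <- as.integer(rowsum(as.integer(asleep), hour_of))
  mean_activity <- as.numeric(rowsum(activity, hour_of)) / minutes_per_hour
  phase_h <- phase_min[!duplicated(hour_of)][match(hours, hour_of[!duplicated(hour_of)])]
  if (nrow(bouts)) {
    bout_hour <- ((bouts$start_minute + start_minute) %/% 60) %% cycle_h
    pos <- match(bout_hour, hours)
    n_transitions <- tabulate(pos, length(hours))
    len_sum <- numeric(length(hours))
    agg <- rowsum(as.numeric(bouts$length_min), pos)
    len_sum[as.integer(rownames(agg))] <- agg[, 1]
    mean_bout_len <- ifelse(n_transitions > 0, len_sum / n_transitions,
                            NA_real_)
  } else {
    n_transitions <- integer(length(hours))
    mean_bout_len <- rep(NA_real_, length(hours))
  }
  hourly <- data.frame(
    hour = hours, phase = phase_h, sleep_min = sleep_min,
    n_transitions = n_transitions, mean_bout_len = mean_bout_len,
    mean_activity = mean_activity, stringsAsFactors = FALSE
  )
  phase_tbl <- do.call(rbind, lapply(unique(hourly$phase), function(ph) {
    sub <- hourly[hourly$phase == ph, , drop = FALSE]
    data.frame(
      phase = ph,
      sleep_min_per_h = mean(sub$sleep_min),
      transitions_per_h = mean(sub$n_transitions),
      mean_bout_len = if (all(is.na(sub$mean_bout_len))) NA_real_ else
        mean(sub$mean_bout_len, na.rm = TRUE),
      mean_activity = mean(sub$mean_activity),
      stringsAsFactors = FALSE
    )
  }))
  list(hourly = hourly, phase = phase_tbl)
}

#' Score every larva of a cohort
#'
#' Runs [call_sleep_bouts()] and [summarize_sleep()] per larva and stacks the
#' per-phase aggregates.
#'
#' @param cohort long data.frame as produced by [simulate_activity_cohort()]
#'   (`larva_id`, `genotype`, `minute_index`, `activity`, and optionally
#'   `light_phase` — the photoperiod argument is authoritative).
#' @param photoperiod,epsilon passed through.
#' @return data.frame, one row per larva x phase: `larva_id`, `genotype`,
#'   `phase`, `sleep_min_per_h`, `transitions_per_h`, `mean_bout_len`,
#'   `mean_activity`.
#' @export
score_cohort <- function(cohort, photoperiod = c(light = 14, dark = 10),
                         epsilon = 0) {
  stopifnot(all(c("larva_id", "genotype", "minute_index", "activity") %in%
                  names(cohort)))
  ord <- order(cohort$larva_id, cohort$minute_index)
  act_by <- split(cohort$activity[ord], cohort$larva_id[ord])
  geno_by <- vapply(split(cohort$genotype[ord], cohort$larva_id[ord]),
                    `[`, character(1), 1)
  res <- lapply(names(act_by), function(id) {
    act <- act_by[[id]]
    bouts <- call_sleep_bouts(act, epsilon)
    ph <- summarize_sleep(bouts, act, photoperiod, epsilon)$phase
    cbind(
      data.frame(larva_id = id, genotype = geno_by[[id]],
                 stringsAsFactors = FALSE),
      ph
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# two-group mean-difference permutation machinery shared by the comparisons
.perm_test <- function(values, labels, group_a, group_b,
                       n_permutations = 999, seed = 1L, exact = NULL) {
  ina <- labels == group_a
  inb <- labels == group_b
  if (sum(ina) < 2 || sum(inb) < 2) {
    stop("each group needs at least two larvae")
  }
  x <- values[ina | inb]
  lab <- ina[ina | inb]  # TRUE = group_a
  n <- length(x)
  n_a <- sum(lab)
  obs <- mean(x[lab]) - mean(x[!lab])
  total <- choose(n, n_a)
  if (is.null(exact)) exact <- total <= 20000
  tol <- 1e-12 * (1 + abs(obs))
  if (exact) {
    idx <- combn(n, n_a)
    stats <- apply(idx, 2, function(i) mean(x[i]) - mean(x[-i]))
    p <- mean(abs(stats) >= abs(obs) - tol)
    method <- "exact"
    n_used <- total
  } else {
    set.seed(as.integer(seed))
    cnt <- 0L
    for (b in seq_len(n_permutations)) {
      i <- sample.int(n, n_a)
      s <- mean(x[i]) - mean(x[-i])
      if (abs(s) >= abs(obs) - tol) cnt <- cnt + 1L
    }
    p <- (1 + cnt) / (n_permutations + 1)
    method <- "sampled"
    n_used <- n_permutations
  }
  list(effect = obs, p = p, method = method, n_permutations = n_used)
}

#' Permutation comparison of a sleep metric between two genotypes
#'
#' Tests whether a per-larva phase aggregate (e.g. night sleep minutes per
#' hour) differs between two genotype groups. The statistic is the
#' difference of group means; its null distribution comes from relabeling
#' larvae — exhaustively when the number of distinct assignments is small
#' (<= 20000 by default), otherwise by Monte-Carlo sampling. This
#' distribution-free comparison replaces parametric repeated-measures
#' modelling and is testable against exact enumeration.
#'
#' @param scores data.frame from [score_cohort()].
#' @param groups length-2 character vector: the genotypes to compare (effect
#'   = first minus second).
#' @param phase `"dark"` or `"light"`.
#' @param metric column of `scores` to compare.
#' @param n_permutations Monte-Carlo permutations when not exhaustive.
#' @param seed seed for the Monte-Carlo draw.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   `NULL` decides by the number of assignments.
#' @return list: `effect`, `p`, `method` (`"exact"`/`"sampled"`),
#'   `n_permutations`.
#' @export
compare_genotypes <- function(scores, groups, phase = "dark",
                              metric = "sleep_min_per_h",
                              n_permutations = 999, seed = 1L, exact = NULL) {
  stopifnot(length(groups) == 2, metric %in% names(scores))
  sub <- scores[scores$phase == phase & scores$genotype %in% groups, ]
  sub <- sub[!is.na(sub[[metric]]), ]
  .perm_test(sub[[metric]], sub$genotype, groups[1], groups[2],
             n_permutations, seed, exact)
}

#' Sleep rebound after deprivation
#'
#' Compares post-deprivation sleep time between sleep-deprived and control
#' larvae scored over matched recording windows. The statistic is the mean
#' post-window sleep-time difference (deprived minus control); a positive
#' value is homeostatic rebound. Significance by label permutation as in
#' [compare_genotypes()].
#'
#' @param summaries data.frame with columns `larva_id`, `group` (values
#'   `deprived` / `control`), `post_sleep_min` and `window_min` (length of
#'   the post-deprivation scoring window, identical for all larvae).
#' @param n_permutations,seed,exact as in [compare_genotypes()].
#' @return list: `effect` (minutes), `p`, `method`, `n_permutations`.
#' @export
rebound_analysis <- function(summaries, n_permutations = 999, seed = 1L,
                             exact = NULL) {
  stopifnot(all(c("larva_id", "group", "post_sleep_min", "window_min") %in%
                  names(summaries)))
  if (length(unique(summaries$window_min)) != 1) {
    stop("recording-window mismatch between larvae")
  }
  .perm_test(summaries$post_sleep_min, summaries$group, "deprived", "control",
             n_permutations, seed, exact)
}
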