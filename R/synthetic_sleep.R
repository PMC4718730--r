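#' Default genotype-specific sleep parameters of the simulator
#'
#' Night sleep time and bout length per genotype calibrated to the published
#' means of the mutant line (hom 13.08, het 14.78, wt 15.46 min/h; night bout
#' length 2.21 vs 2.43 min); day sleep times 2.76/2.80/2.87 min/h with a
#' common nominal day bout length of 1.2 min (day bout length is not
#' independently identifiable at minute resolution).
#'
#' @return nested list: `genotype$phase` with elements `sleep_min_per_hour`
#'   and `mean_bout_len`.
#' @export
default_sleep_params <- function() {
  list(
    hom = list(night = list(sleep_min_per_hour = 13.08, mean_bout_len = 2.21),
               day = list(sleep_min_per_hour = 2.76, mean_bout_len = 1.2)),
    het = list(night = list(sleep_min_per_hour = 14.78, mean_bout_len = 2.32),
               day = list(sleep_min_per_hour = 2.80, mean_bout_len = 1.2)),
    wt = list(night = list(sleep_min_per_hour = 15.46, mean_bout_len = 2.43),
              day = list(sleep_min_per_hour = 2.87, mean_bout_len = 1.2))
  )
}

#' Configuration of the activity-trace simulator
#'
#' Describes a 24-h video-tracking cohort under a light/dark cycle. Each
#' larva's minute-binned trace follows a two-state (wake/sleep) alternating
#' renewal process with geometric bout lengths, parameterized per genotype
#' and phase by the stationary sleep time (minutes per hour) and the mean
#' sleep-bout length (minutes); the wake-to-sleep transition rate is implied
#' by the two (rate = sleep fraction / bout length, in the stationary
#' regime). Wake minutes receive gamma-distributed activity in arbitrary
#' tracker units; sleep minutes are exactly 0.
#'
#' @param n_larvae_per_genotype larvae per genotype.
#' @param photoperiod named numeric, hours of `light` then `dark` (default
#'   14:10, lights-on at minute 0).
#' @param params nested list as in [default_sleep_params()]; genotype names
#'   are free labels (defaults `hom`, `het`, `wt`).
#' @param activity_mean mean wake-minute activity (arbitrary units).
#' @param activity_shape gamma shape of wake-minute activity.
#' @param between_larva_sd named numeric, between-larva standard deviation of
#'   the individual sleep level (min/h) per phase. Individual larvae differ
#'   well beyond the renewal process's own sampling noise; each larva's
#'   target sleep time is drawn from a gamma distribution around the
#'   genotype mean with this sd (degenerate at 0 when the mean is 0). The
#'   defaults (day 2.0, night 1.5) combine with the within-larva chain
#'   variance to match the dispersion of published cohorts.
#' @param hours recording duration (default 24).
#' @param seed integer seed.
#' @return list of class `sleep_sim_config`.
#' @export
sleep_sim_config <- function(n_larvae_per_genotype = 90,
                             photoperiod = c(light = 14, dark = 10),
                             params = default_sleep_params(),
                             activity_mean = 10, activity_shape = 2,
                             between_larva_sd = c(day = 2.0, night = 1.5),
                             hours = 24, seed = 1L) {
  if (n_larvae_per_genotype < 1) stop("need at least one larva per genotype")
  if (length(photoperiod) != 2 || any(photoperiod < 0)) {
    stop("photoperiod must give light and dark hours")
  }
  for (g in names(params)) {
    for (ph in c("day", "night")) {
      s <- params[[g]][[ph]]$sleep_min_per_hour
      b <- params[[g]][[ph]]$mean_bout_len
      if (is.null(s) || s < 0 || s > 60) {
        stop("sleep minutes per hour must lie in [0, 60] (", g, "/", ph, ")")
      }
      if (is.null(b) || b < 1) {
        stop("mean bout length must be >= 1 minute (", g, "/", ph, ")")
      }
    }
  }
  if (any(between_larva_sd < 0)) stop("between_larva_sd must be >= 0")
  structure(
    list(
      n_larvae_per_genotype = as.integer(n_larvae_per_genotype),
      photoperiod = photoperiod, params = params,
      activity_mean = activity_mean, activity_shape = activity_shape,
      between_larva_sd = between_larva_sd,
      hours = hours, seed = as.integer(seed)
    ),
    class = "sleep_sim_config"
  )
}

# Minute-wise transition probabilities implied by (sleep min/h, bout length);
# vectorized over per-larva sleep levels.
.chain_rates <- function(sleep_min_per_hour, mean_bout_len) {
  f <- pmin(sleep_min_per_hour, 60) / 60
  p_sw <- rep(1 / mean_bout_len, length(f))
  p_ws <- ifelse(f >= 1, 1, pmin(1, f / (1 - f) * p_sw))
  p_sw[f >= 1] <- 0
  list(p_ws = p_ws, p_sw = p_sw)
}

# Per-larva sleep levels: gamma around the genotype mean with the configured
# between-larva sd (point mass at 0 when the mean is 0), capped at 60 min/h.
.larva_levels <- function(n, mean_sleep, sd_sleep) {
  if (mean_sleep <= 0 || sd_sleep == 0) return(rep(mean_sleep, n))
  shape <- (mean_sleep / sd_sleep)^2
  pmin(60, rgamma(n, shape = shape, rate = shape / mean_sleep))
}

#' Simulate a cohort of minute-binned larval activity traces
#'
#' Runs the two-state wake/sleep Markov chain of [sleep_sim_config()] for
#' each larva (initial state drawn from the day-phase stationary
#' distribution; parameters switch at the light/dark boundary) and overlays
#' gamma activity on wake minutes.
#'
#' @param config a [sleep_sim_config()].
#' @return list with `cohort` (long data.frame: `larva_id`, `genotype`,
#'   `minute_index` 0-based, `activity`, `light_phase`) and `truth` (the
#'   per-genotype generative parameters, one row per genotype x phase, with
#'   the implied transition rate per hour).
#' @export
simulate_activity_cohort <- function(config = sleep_sim_config()) {
  stopifnot(inherits(config, "sleep_sim_config"))
  set.seed(config$seed)
  n_min <- as.integer(round(config$hours * 60))
  light_min <- as.integer(round(config$photoperiod[["light"]] * 60))
  phase <- ifelse(seq_len(n_min) - 1 < light_min, "light", "dark")

  out <- list()
  truth <- list()
  for (g in names(config$params)) {
    pars <- config$params[[g]]
    n <- config$n_larvae_per_genotype
    lev_day <- .larva_levels(n, pars$day$sleep_min_per_hour,
                             config$between_larva_sd[["day"]])
    lev_night <- .larva_levels(n, pars$night$sleep_min_per_hour,
                               config$between_larva_sd[["night"]])
    r_day <- .chain_rates(lev_day, pars$day$mean_bout_len)
    r_night <- .chain_rates(lev_night, pars$night$mean_bout_len)
    state <- matrix(0L, nrow = n, ncol = n_min)  # 1 = asleep
    cur <- as.integer(runif(n) < lev_day / 60)
    for (t in seq_len(n_min)) {
      r <- if (phase[t] == "light") r_day else r_night
      u <- runif(n)
      cur <- ifelse(cur == 1L,
                    as.integer(u >= r$p_sw),  # stay asleep w.p. 1 - p_sw
                    as.integer(u < r$p_ws))
      state[, t] <- cur
    }
    n_wake <- sum(state == 0L)
    act <- matrix(0, nrow = n, ncol = n_min)
    act[state == 0L] <- rgamma(n_wake, shape = config$activity_shape,
                               rate = config$activity_shape / config$activity_mean)
    ids <- sprintf("%s_%03d", g, seq_len(n))
    out[[g]] <- data.frame(
      larva_id = rep(ids, each = n_min),
      genotype = g,
      minute_index = rep(seq_len(n_min) - 1L, times = n),
      activity = as.vector(t(act)),
      light_phase = rep(phase, times = n),
      stringsAsFactors = FALSE
    )
    for (ph in c("day", "night")) {
      truth[[paste(g, ph)]] <- data.frame(
        genotype = g, phase = ifelse(ph == "day", "light", "dark"),
        sleep_min_per_hour = pars[[ph]]$sleep_min_per_hour,
        mean_bout_len = pars[[ph]]$mean_bout_len,
        transitions_per_hour = pars[[ph]]$sleep_min_per_hour /
          pars[[ph]]$mean_bout_len,
        stringsAsFactors = FALSE
      )
    }
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  attr(truth, "config") <- config
  list(cohort = cohort, truth = truth)
}
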