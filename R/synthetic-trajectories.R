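# Larval trajectory generator: correlated random walks with injected
# pause-and-reorient (head-cast) events, plus still (non-mover) larvae that
# only show tracking jitter.

#' Configuration for the trajectory generator
#'
#' Defaults reproduce the recording conditions of the study: two-minute
#' recordings at 30 Hz, cohorts of 26 larvae, a mean crawling speed of
#' 0.190 mm/s (the control-group value on apple food) and 1.45 head casts
#' per minute. Per-step heading noise (2 degrees/step at 30 Hz, ~11
#' degrees/sqrt(s)) and a 15% still fraction are modelling choices for
#' values the source data do not pin down.
#'
#' @param duration_s recording length, seconds.
#' @param rate_hz sampling rate, Hz.
#' @param mean_speed_mm_s mean crawling speed of movers, mm/s.
#' @param speed_sd_mm_s between-larva SD of crawling speed, mm/s.
#' @param turn_sd_deg per-step SD of the heading increment, degrees.
#' @param head_cast_rate_per_min injected head-cast rate per mover, 1/min.
#' @param head_cast_angle_deg magnitude of the heading jump at each head
#'   cast (sign random), degrees.
#' @param head_cast_pause_s pause duration at each head cast, seconds.
#' @param still_fraction fraction of larvae generated as non-movers.
#' @param still_jitter_mm per-frame tracking jitter SD of still larvae, mm.
#' @param n_larvae cohort size.
#' @param seed integer root seed.
#' @return a `trajectory_config` list.
#' @export
trajectory_config <- function(duration_s = 120,
                              rate_hz = 30,
                              mean_speed_mm_s = 0.190,
                              speed_sd_mm_s = 0.04,
                              turn_sd_deg = 2,
                              head_cast_rate_per_min = 1.45,
                              head_cast_angle_deg = 90,
                              head_cast_pause_s = 1,
                              still_fraction = 0.15,
                              still_jitter_mm = 0.01,
                              n_larvae = 26,
                              seed = 1) {
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(rate_hz, "rate_hz")
  if (still_fraction < 0 || still_fraction > 1) {
    stop("`still_fraction` must be in [0, 1]")
  }
  if (head_cast_rate_per_min < 0) stop("head-cast rate must be >= 0")
  structure(
    list(duration_s = duration_s, rate_hz = rate_hz,
         mean_speed_mm_s = mean_speed_mm_s, speed_sd_mm_s = speed_sd_mm_s,
         turn_sd_deg = turn_sd_deg,
         head_cast_rate_per_min = head_cast_rate_per_min,
         head_cast_angle_deg = head_cast_angle_deg,
         head_cast_pause_s = head_cast_pause_s,
         still_fraction = still_fraction, still_jitter_mm = still_jitter_mm,
         n_larvae = as.integer(n_larvae), seed = as.integer(seed)),
    class = "trajectory_config"
  )
}

# Draw a Poisson number of event times over [margin, T - margin] with a
# minimum gap; the count is drawn first and kept while the times are
# resampled, so the expected number of events stays exactly rate * T.
draw_event_times <- function(rate_per_s, duration_s, min_gap_s, margin_s) {
  n <- stats::rpois(1, rate_per_s * duration_s)
  if (n == 0) return(numeric(0))
  lo <- margin_s; hi <- duration_s - margin_s
  if (hi - lo < (n - 1) * min_gap_s) {
    stop("injected events cannot fit the recording at the requested gap")
  }
  for (tr in 1:200) {
    tt <- sort(stats::runif(n, lo, hi))
    if (n == 1 || all(diff(tt) >= min_gap_s)) return(tt)
  }
  stop("failed to draw separated event times; rate too high for duration")
}

#' Generate a cohort of larval trajectories with ground truth
#'
#' Movers follow a correlated random walk at their per-larva base speed;
#' head casts are injected as a pause of `head_cast_pause_s` followed by a
#' heading jump of +-`head_cast_angle_deg`, with times recorded in the
#' ground truth (timestamped at mid-pause). Still larvae jitter around a
#' fixed point with zero mean displacement.
#'
#' @param config a [trajectory_config()].
#' @return list with `table` (data frame `larva_id`, `t_s`, `x_mm`,
#'   `y_mm`) and `truth` (`larvae`: per-larva mover flag and base speed;
#'   `events`: injected head casts with `larva_id`, `time_s`,
#'   `angle_deg`).
#' @export
gen_trajectories <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  cf <- config
  n_steps <- round(cf$duration_s * cf$rate_hz)
  t_s <- (0:n_steps) / cf$rate_hz

  with_seed(substream_seed(cf$seed, "trajectories"), {
    n_still <- round(cf$still_fraction * cf$n_larvae)
    still_ids <- sample.int(cf$n_larvae, n_still)

    tabs <- vector("list", cf$n_larvae)
    ev_list <- list()
    larvae <- data.frame(larva_id = seq_len(cf$n_larvae),
                         mover = !(seq_len(cf$n_larvae) %in% still_ids),
                         base_speed_mm_s = NA_real_)
    for (i in seq_len(cf$n_larvae)) {
      x0 <- stats::runif(1, -20, 20)
      y0 <- stats::runif(1, -20, 20)
      if (!larvae$mover[i]) {
        x <- x0 + stats::rnorm(n_steps + 1, 0, cf$still_jitter_mm)
        y <- y0 + stats::rnorm(n_steps + 1, 0, cf$still_jitter_mm)
        larvae$base_speed_mm_s[i] <- 0
      } else {
        speed <- max(stats::rnorm(1, cf$mean_speed_mm_s, cf$speed_sd_mm_s),
                     0.01)
        larvae$base_speed_mm_s[i] <- speed
        step_len <- rep(speed / cf$rate_hz, n_steps)
        dtheta <- stats::rnorm(n_steps, 0, cf$turn_sd_deg)

        pause_steps <- max(1L, round(cf$head_cast_pause_s * cf$rate_hz))
        times <- if (cf$head_cast_rate_per_min > 0) {
          draw_event_times(
            cf$head_cast_rate_per_min / 60, cf$duration_s,
            min_gap_s = max(3, 2 * cf$head_cast_pause_s + 1),
            margin_s = cf$head_cast_pause_s + 1
          )
        } else {
          numeric(0)
        }
        angles <- cf$head_cast_angle_deg *
          sample(c(-1, 1), length(times), replace = TRUE)
        for (k in seq_along(times)) {
          s0 <- round(times[k] * cf$rate_hz) + 1L        # first paused step
          span <- s0:min(s0 + pause_steps - 1L, n_steps)
          step_len[span] <- 0
          dtheta[span] <- 0
          jump_at <- min(s0 + pause_steps, n_steps)
          dtheta[jump_at] <- dtheta[jump_at] + angles[k]
        }
        if (length(times) > 0) {
          ev_list[[length(ev_list) + 1L]] <- data.frame(
            larva_id = i,
            time_s = times + cf$head_cast_pause_s / 2,
            angle_deg = angles
          )
        }
        theta <- (stats::runif(1, 0, 360) + cumsum(dtheta)) * pi / 180
        x <- x0 + c(0, cumsum(step_len * cos(theta)))
        y <- y0 + c(0, cumsum(step_len * sin(theta)))
      }
      tabs[[i]] <- data.frame(larva_id = i, t_s = t_s, x_mm = x, y_mm = y)
    }
    events <- if (length(ev_list) > 0) {
      do.call(rbind, ev_list)
    } else {
      data.frame(larva_id = integer(0), time_s = numeric(0),
                 angle_deg = numeric(0))
    }
    list(
      table = do.call(rbind, tabs),
      truth = list(larvae = larvae, events = events, config = cf)
    )
  })
}

#' Write / read trajectory tables as CSV
#'
#' Plain CSV with columns `larva_id`, `t_s`, `x_mm`, `y_mm`.
#' @param table trajectory table as returned by [gen_trajectories()].
#' @param path file path.
#' @export
write_trajectories_csv <- function(table, path) {
  utils::write.csv(table[, c("larva_id", "t_s", "x_mm", "y_mm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("larva_id", "t_s", "x_mm", "y_mm")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  }
  df[, need]
}
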