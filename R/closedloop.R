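# Closed-loop Y-maze: maze geometry and zones, turn evaluation, the trial
# controller state machine (settle -> haptic signal -> turn evaluation ->
# reward), and exact cumulative binomial success statistics.

#' Y-maze geometry
#'
#' Three identical arms joined at 120 degrees. Each arm is a rectangle of
#' `arm_length_m` x `arm_width_m` starting at the central junction; per arm
#' a mid-arm evaluation zone (where the turn decision is scored) and a
#' distal arm-end zone (where the bird settles and feeders sit) are
#' defined as radial bands.
#'
#' @param arm_length_m arm length (m), default 0.92.
#' @param arm_width_m arm width (m), default 0.27.
#' @param center_radius_m radius of the central junction zone (m).
#' @param arm_angles_deg outward axis direction of each arm (degrees,
#'   counter-clockwise from +x); the default labels the arms clockwise.
#' @param eval_band radial fraction band of the evaluation zone.
#' @param end_band radial fraction band of the arm-end zone.
#' @return object of class `maze_geometry`.
#' @export
maze_geometry <- function(arm_length_m = 0.92, arm_width_m = 0.27,
                          center_radius_m = arm_width_m,
                          arm_angles_deg = c(90, -30, -150),
                          eval_band = c(0.35, 0.65),
                          end_band = c(0.75, 1.0)) {
  if (length(arm_angles_deg) != 3L) stop("a Y maze has three arms",
                                         call. = FALSE)
  structure(list(arm_length_m = arm_length_m, arm_width_m = arm_width_m,
                 center_radius_m = center_radius_m,
                 arm_angles_rad = deg2rad(arm_angles_deg),
                 eval_band = eval_band, end_band = end_band),
            class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf("<maze_geometry> 3 arms %0.2f x %0.2f m at (%s) deg\n",
              x$arm_length_m, x$arm_width_m,
              paste(round(rad2deg(x$arm_angles_rad)), collapse = ", ")))
  invisible(x)
}

#' Locate a 2D position within the maze
#'
#' @param position length-2 (x, y) position (m, maze frame, junction at the
#'   origin).
#' @param maze a [maze_geometry()].
#' @return list with `zone` (`"center"`, `"arm"`, `"outside"`), `arm`
#'   (1-3 or NA) and `region` (`"approach"`, `"evaluation"`, `"end"` or NA).
#' @export
locate_zone <- function(position, maze) {
  x <- position[1]; y <- position[2]
  if (sqrt(x^2 + y^2) <= maze$center_radius_m) {
    return(list(zone = "center", arm = NA_integer_, region = NA_character_))
  }
  r0 <- maze$center_radius_m
  for (a in 1:3) {
    th <- maze$arm_angles_rad[a]
    # arm-local coordinates: u along the outward axis, v across
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    if (abs(v) <= maze$arm_width_m / 2 && u >= r0 &&
        u <= r0 + maze$arm_length_m) {
      f <- (u - r0) / maze$arm_length_m
      region <- if (f >= maze$end_band[1]) "end"
                else if (f >= maze$eval_band[1] && f <= maze$eval_band[2]) {
                  "evaluation"
                } else "approach"
      return(list(zone = "arm", arm = a, region = region))
    }
  }
  list(zone = "outside", arm = NA_integer_, region = NA_character_)
}

#' Side of a turn between two arms
#'
#' From the heading of a bird walking from `entry_arm` into the junction,
#' decides whether `exit_arm` lies to its left or right (pure geometry, so
#' consistent relabeling of arms leaves outcomes unchanged).
#'
#' @param entry_arm,exit_arm arm indices (1-3), distinct.
#' @param maze a [maze_geometry()].
#' @return `"left"` or `"right"`.
#' @export
turn_side <- function(entry_arm, exit_arm, maze) {
  if (entry_arm == exit_arm) stop("entry and exit arm coincide: not a turn",
                                  call. = FALSE)
  te <- maze$arm_angles_rad[entry_arm]
  tx <- maze$arm_angles_rad[exit_arm]
  h <- c(-cos(te), -sin(te))            # heading: inward along entry arm
  e <- c(cos(tx), sin(tx))              # outward along exit arm
  if (h[1] * e[2] - h[2] * e[1] > 0) "left" else "right"
}

#' Evaluate a turn against the signaled side
#'
#' @inheritParams turn_side
#' @param signal_side `"left"` or `"right"`.
#' @return `"correct"` or `"incorrect"`.
#' @export
evaluate_turn <- function(entry_arm, exit_arm, signal_side, maze) {
  side <- turn_side(entry_arm, exit_arm, maze)
  if (identical(side, signal_side)) "correct" else "incorrect"
}

# balanced-block (size 4: two lefts, two rights) signal schedule
signal_schedule <- function(n) {
  blocks <- ceiling(n / 4)
  out <- character(0)
  for (b in seq_len(blocks)) {
    out <- c(out, sample(c("left", "left", "right", "right")))
  }
  out[seq_len(n)]
}

new_controller <- function(maze, settle_s = 0.5, detour_s = 5,
                           timeout_s = 30) {
  env <- new.env(parent = emptyenv())
  env$maze <- maze
  env$settle_s <- settle_s
  env$detour_s <- detour_s
  env$timeout_s <- timeout_s
  env$state <- "idle"
  env$dwell_arm <- NA_integer_
  env$dwell_since <- NA_real_
  env$signal_arm <- NA_integer_
  env$signal_side <- NA_character_
  env$signal_time <- NA_real_
  env$left_signal_arm_at <- NA_real_
  env$last_time <- -Inf
  env$schedule <- character(0)
  env$sig_count <- 0L
  env$log <- list()
  env
}

ctrl_emit <- function(env, time, event, pos, arm = NA_integer_) {
  env$log[[length(env$log) + 1L]] <-
    data.frame(time_s = time, event = event, x = pos[1], y = pos[2],
               arm = arm, stringsAsFactors = FALSE)
}

controller_step <- function(env, time, pos) {
  if (time < env$last_time) {
    stop("position stream is not time-ordered", call. = FALSE)
  }
  env$last_time <- time
  z <- locate_zone(pos, env$maze)
  if (env$state == "idle") {
    if (z$zone == "arm" && z$region == "end") {
      if (is.na(env$dwell_arm) || env$dwell_arm != z$arm) {
        env$dwell_arm <- z$arm
        env$dwell_since <- time
      } else if (time - env$dwell_since >= env$settle_s) {
        env$sig_count <- env$sig_count + 1L
        if (env$sig_count > length(env$schedule)) {
          env$schedule <- c(env$schedule, signal_schedule(16L))
        }
        env$signal_side <- env$schedule[env$sig_count]
        env$signal_arm <- z$arm
        env$signal_time <- time
        env$left_signal_arm_at <- NA_real_
        env$state <- "signaled"
        ctrl_emit(env, time, paste0("signal_", env$signal_side), pos, z$arm)
      }
    } else {
      env$dwell_arm <- NA_integer_
    }
  } else if (env$state == "signaled") {
    if (z$zone == "arm" && z$arm == env$signal_arm) {
      # back in the signal arm: a detour, never a new signal; if the bird
      # stays away longer than detour_s the pending trial is abandoned
      if (!is.na(env$left_signal_arm_at) &&
          time - env$left_signal_arm_at >= env$detour_s) {
        ctrl_emit(env, time, "missed", pos, env$signal_arm)
        env$state <- "idle"
        env$dwell_arm <- NA_integer_
      } else {
        env$left_signal_arm_at <- NA_real_
      }
    } else {
      if (is.na(env$left_signal_arm_at)) env$left_signal_arm_at <- time
      if (time - env$signal_time > env$timeout_s) {
        ctrl_emit(env, time, "missed", pos, env$signal_arm)
        env$state <- "idle"
        env$dwell_arm <- NA_integer_
      } else if (z$zone == "arm" && z$arm != env$signal_arm &&
                 z$region %in% c("evaluation", "end")) {
        verdict <- evaluate_turn(env$signal_arm, z$arm, env$signal_side,
                                 env$maze)
        ctrl_emit(env, time, paste0("turn_", verdict), pos, z$arm)
        if (verdict == "correct") ctrl_emit(env, time, "reward", pos, z$arm)
        env$state <- "idle"
        env$dwell_arm <- NA_integer_
      }
    }
  }
  invisible(env)
}

#' Run the closed-loop trial controller over a position stream
#'
#' State machine mirroring the live system: when the bird settles in an
#' arm end for `settle_s`, a haptic left/right signal is issued (balanced
#' pseudo-random blocks); the next crossing of another arm's evaluation
#' zone scores the turn and, if correct, triggers a reward. Returning to
#' the signal arm within `detour_s` of having left it issues no new signal
#' and the detour is ignored; staying away longer, or exceeding
#' `timeout_s`, logs the signal as missed.
#'
#' @param stream data.frame with `time_s`, `x`, `y` (time-ordered).
#' @param maze a [maze_geometry()].
#' @param settle_s dwell time required before a signal (s).
#' @param detour_s detour-forgiveness window (s).
#' @param timeout_s trial timeout (s).
#' @param seed RNG seed for the signal schedule.
#' @return `trial_log`: data.frame of events (`time_s`, `event`, `x`, `y`,
#'   `arm`) with attribute `pending` (1 if a signal is unresolved at the
#'   end of the stream).
#' @export
run_controller <- function(stream, maze, settle_s = 0.5, detour_s = 5,
                           timeout_s = 30, seed = 1L) {
  if (is.unsorted(stream$time_s)) {
    stop("position stream is not time-ordered", call. = FALSE)
  }
  with_seed(seed, {
    env <- new_controller(maze, settle_s, detour_s, timeout_s)
    env$schedule <- signal_schedule(max(64L, nrow(stream) %/% 10L))
    for (i in seq_len(nrow(stream))) {
      controller_step(env, stream$time_s[i],
                      c(stream$x[i], stream$y[i]))
    }
    log <- if (length(env$log)) do.call(rbind, env$log) else
      data.frame(time_s = numeric(0), event = character(0), x = numeric(0),
                 y = numeric(0), arm = integer(0), stringsAsFactors = FALSE)
    attr(log, "pending") <- as.integer(env$state == "signaled")
    class(log) <- c("trial_log", "data.frame")
    log
  })
}

#' Simulate an agent in the closed-loop Y maze
#'
#' Co-simulates a point agent and the trial controller. The `"obedient"`
#' agent always walks to the arm on the signaled side; the `"random"` agent
#' picks either side with equal probability (long-run success 0.5). Useful
#' as an end-to-end oracle for the controller.
#'
#' @param maze a [maze_geometry()].
#' @param agent `"random"` or `"obedient"`.
#' @param n_trials number of signaled trials to run.
#' @param seed RNG seed (drives both the schedule and the agent).
#' @param speed_m_s agent walking speed.
#' @param dt_s simulation step.
#' @return a `trial_log` (see [run_controller()]) with attribute `stream`.
#' @export
simulate_maze_agent <- function(maze, agent = c("random", "obedient"),
                                n_trials = 20L, seed = 1L, speed_m_s = 0.4,
                                dt_s = 0.02) {
  agent <- match.arg(agent)
  with_seed(seed, {
    env <- new_controller(maze)
    env$schedule <- signal_schedule(n_trials + 8L)
    r0 <- maze$center_radius_m
    arm_point <- function(a, frac) {
      th <- maze$arm_angles_rad[a]
      (r0 + frac * maze$arm_length_m) * c(cos(th), sin(th))
    }
    cur_arm <- 1L
    pos <- arm_point(cur_arm, 0.9)
    t <- 0
    goal <- NULL
    stream <- list()
    n_signals <- 0L
    mode <- "dwell"
    dwell_until <- t + env$settle_s + 0.3
    while (n_signals < n_trials || env$state == "signaled") {
      n_before <- length(env$log)
      controller_step(env, t, pos)
      if (length(env$log) > n_before) {
        ev <- env$log[[length(env$log)]]$event
        if (startsWith(ev, "signal_")) {
          n_signals <- n_signals + 1L
          side <- sub("signal_", "", ev)
          target_side <- if (agent == "obedient") side else
            sample(c("left", "right"), 1L)
          tgt <- setdiff(1:3, cur_arm)
          tgt <- tgt[vapply(tgt, function(a) {
            turn_side(cur_arm, a, maze) == target_side
          }, logical(1))][1]
          goal <- list(arm = tgt, frac = 0.9)
          mode <- "walk_center"
        }
      }
      stream[[length(stream) + 1L]] <- c(t, pos)
      if (mode == "dwell") {
        if (t >= dwell_until && n_signals >= n_trials) break
      } else if (mode == "walk_center") {
        step <- speed_m_s * dt_s
        d <- sqrt(sum(pos^2))
        if (d <= step) {
          pos <- c(0, 0)
          mode <- "walk_out"
        } else {
          pos <- pos * (d - step) / d
        }
      } else if (mode == "walk_out") {
        tgt <- arm_point(goal$arm, goal$frac)
        d <- sqrt(sum((tgt - pos)^2))
        step <- speed_m_s * dt_s
        if (d <= step) {
          pos <- tgt
          cur_arm <- goal$arm
          mode <- "dwell"
          dwell_until <- t + env$settle_s + 0.3
        } else {
          pos <- pos + (tgt - pos) / d * step
        }
      }
      t <- t + dt_s
      if (t > 3600) break                 # safety net
    }
    log <- if (length(env$log)) do.call(rbind, env$log) else
      data.frame(time_s = numeric(0), event = character(0), x = numeric(0),
                 y = numeric(0), arm = integer(0), stringsAsFactors = FALSE)
    attr(log, "pending") <- as.integer(env$state == "signaled")
    sm <- do.call(rbind, stream)
    attr(log, "stream") <- data.frame(time_s = sm[, 1], x = sm[, 2],
                                      y = sm[, 3])
    class(log) <- c("trial_log", "data.frame")
    log
  })
}

#' Exact upper-tail cumulative binomial test
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, by exact summation. Used to ask
#' whether a success rate in `n` trials exceeds chance `p0`.
#'
#' @param k_correct number of correct trials.
#' @param n_trials total trials (> 0).
#' @param p0 chance level, default 0.5.
#' @return upper-tail p-value.
#' @export
binomial_success <- function(k_correct, n_trials, p0 = 0.5) {
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  if (k_correct < 0 || k_correct > n_trials) {
    stop("need 0 <= k_correct <= n_trials", call. = FALSE)
  }
  if (k_correct == 0) return(1)
  sum(stats::dbinom(k_correct:n_trials, n_trials, p0))
}

#' Summarize a trial log
#'
#' @param log a `trial_log`.
#' @return list with counts of signals, correct/incorrect turns, rewards,
#'   missed trials, the success rate, and the cumulative binomial p-value.
#' @export
trial_summary <- function(log) {
  n_signal <- sum(startsWith(log$event, "signal_"))
  n_correct <- sum(log$event == "turn_correct")
  n_incorrect <- sum(log$event == "turn_incorrect")
  n_reward <- sum(log$event == "reward")
  n_missed <- sum(log$event == "missed")
  n_eval <- n_correct + n_incorrect
  list(n_signals = n_signal, n_correct = n_correct,
       n_incorrect = n_incorrect, n_rewards = n_reward,
       n_missed = n_missed, pending = attr(log, "pending") %||% 0L,
       success_rate = if (n_eval > 0) n_correct / n_eval else NA_real_,
       p_value = if (n_eval > 0) binomial_success(n_correct, n_eval)
                 else NA_real_)
}

#' Write a trial log as JSON lines
#'
#' @param log a `trial_log`.
#' @param path output path (one JSON object per event).
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
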