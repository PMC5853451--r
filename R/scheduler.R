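# Stimulation scheduling: trains of at most two phase-locked pulses, at least
# 9 s between trains, 50-ms pulses, per-train stim/sham randomization, and a
# 30-s pause whenever a movement or alpha burst follows a pulse within 6 s.

#' Scheduler configuration
#'
#' @param target_phase_deg Phase target, degrees (45 = mid-ascending).
#' @param pulse_duration_ms Nominal pulse duration (metadata; no audio is
#'   synthesized).
#' @param max_pulses_per_train Maximum pulses per train (default 2).
#' @param min_gap_after_train_s Minimum silence between the last pulse of a
#'   train and the first of the next (default 9 s).
#' @param post_stim_watch_s Window after each pulse watched for movement or
#'   alpha activity (default 6 s).
#' @param post_stim_pause_s Pause initiated when the watch triggers (default
#'   30 s).
#' @param sham_probability Probability that a train is sham (drawn per train
#'   so both pulses share an arm; default 0.5).
#' @param second_pulse_timeout_s If no target crossing occurs within this time
#'   of the first pulse the train closes with one pulse (default 3 s).
#' @param volume_db Nominal stimulus level (metadata only).
#' @param target_phase_list Optional vector of targets sampled uniformly per
#'   train (the "random condition": ascending 45, peak 90, descending 135,
#'   trough 270); `NULL` uses `target_phase_deg` throughout.
#' @return A `scheduler_config` list.
#' @export
scheduler_config <- function(target_phase_deg = 45, pulse_duration_ms = 50,
                             max_pulses_per_train = 2, min_gap_after_train_s = 9,
                             post_stim_watch_s = 6, post_stim_pause_s = 30,
                             sham_probability = 0.5, second_pulse_timeout_s = 3,
                             volume_db = 40, target_phase_list = NULL) {
  stopifnot(sham_probability >= 0, sham_probability <= 1,
            min_gap_after_train_s > 0, max_pulses_per_train >= 1)
  structure(as.list(environment()), class = "scheduler_config")
}

#' @rdname scheduler_step
#' @export
new_scheduler_state <- function() {
  list(last_time_s = -Inf, pause_until_s = -Inf, train_index = 0L,
       pulses_in_train = 0L, first_pulse_time_s = NA_real_,
       last_pulse_time_s = -Inf, last_train_end_s = -Inf,
       current_arm = NA_character_, current_target = NA_real_)
}

#' One step of the stimulation scheduler
#'
#' Emits a pulse iff a target crossing occurs while the N3 gate allows
#' stimulation, no pause is active, and the pacing rules hold: at most
#' `max_pulses_per_train` pulses per train, at least `min_gap_after_train_s`
#' between the last pulse of a train and the first of the next. A
#' `post_stim_alarm` (movement or alpha within the watch window after a
#' pulse) starts a pause and closes the current train.
#'
#' @param now_s Current time, seconds (monotone).
#' @param crossing Did the phase cross the target at this step?
#' @param gate_allow Do the N3 gate and hard conditions allow stimulation?
#' @param post_stim_alarm Alarm raised at this step?
#' @param state Scheduler state from [new_scheduler_state()].
#' @param config A [scheduler_config()].
#' @param est_phase_deg Estimated phase at this step (logged on the event).
#' @return `list(event = NULL or one-row tibble, state = updated state)`.
#' @export
scheduler_step <- function(now_s, crossing, gate_allow, post_stim_alarm,
                           state, config = scheduler_config(),
                           est_phase_deg = NA_real_) {
  if (now_s < state$last_time_s) stop("time must be non-decreasing")
  state$last_time_s <- now_s
  # close a dangling train whose second-pulse window expired
  if (state$pulses_in_train > 0 &&
      (now_s - state$first_pulse_time_s > config$second_pulse_timeout_s ||
       state$pulses_in_train >= config$max_pulses_per_train)) {
    state$last_train_end_s <- state$last_pulse_time_s
    state$pulses_in_train <- 0L
  }
  if (post_stim_alarm) {
    state$pause_until_s <- max(state$pause_until_s, now_s + config$post_stim_pause_s)
    if (state$pulses_in_train > 0) {
      state$last_train_end_s <- state$last_pulse_time_s
      state$pulses_in_train <- 0L
    }
  }
  event <- NULL
  if (isTRUE(crossing) && isTRUE(gate_allow) && now_s >= state$pause_until_s) {
    if (state$pulses_in_train > 0) {
      # second pulse of the open train, on the following slow oscillation
      state$pulses_in_train <- state$pulses_in_train + 1L
      state$last_pulse_time_s <- now_s
      event <- tibble::tibble(time_s = now_s, arm = state$current_arm,
                              train_index = state$train_index,
                              pulse_index = state$pulses_in_train,
                              target_deg = state$current_target,
                              est_phase_deg = est_phase_deg)
      if (state$pulses_in_train >= config$max_pulses_per_train) {
        state$last_train_end_s <- now_s
        state$pulses_in_train <- 0L
      }
    } else if (now_s - state$last_train_end_s >= config$min_gap_after_train_s) {
      state$train_index <- state$train_index + 1L
      state$pulses_in_train <- 1L
      state$first_pulse_time_s <- now_s
      state$last_pulse_time_s <- now_s
      state$current_arm <- if (runif(1) < config$sham_probability) "sham" else "stim"
      state$current_target <- if (is.null(config$target_phase_list))
        config$target_phase_deg else sample(config$target_phase_list, 1)
      event <- tibble::tibble(time_s = now_s, arm = state$current_arm,
                              train_index = state$train_index, pulse_index = 1L,
                              target_deg = state$current_target,
                              est_phase_deg = est_phase_deg)
    }
  }
  list(event = event, state = state)
}

alpha_burst_at <- function(alpha_ratio, fs, t0, t1, threshold = 0.35) {
  i0 <- max(1, floor(t0 * fs) + 1); i1 <- min(length(alpha_ratio), floor(t1 * fs))
  if (i1 <= i0) return(NA_real_)
  seg <- alpha_ratio[i0:i1]
  hit <- which(seg > threshold)
  if (!length(hit)) NA_real_ else t0 + (hit[1] - 1) / fs
}

#' Run the full closed loop on a recording
#'
#' Single chronological pass over a night: causal filtering, quality gating
#' and channel switching, epoch-wise N3 detection (decisions update only at
#' 30-s epoch ends), hard safety conditions, slow-oscillation phase tracking
#' on the gate-open segments, and the pacing scheduler. Deterministic for a
#' fixed seed.
#'
#' @param recording An `mc_recording`.
#' @param quality_model A `quality_model`.
#' @param n3_model An `n3_model`.
#' @param config A [scheduler_config()].
#' @param quality_threshold,theta Quality gate parameters.
#' @param seed Seed for the stim/sham draws.
#' @param trace_every Keep one phase-trace row per this many samples in the
#'   returned trace (crossing samples are always kept).
#' @return A `closed_loop_result`: list with `events` (stim log tibble),
#'   `predicted` (per-epoch tibble with N3 probability and decision),
#'   `quality`, `phase` (downsampled trace), `movements`, `virtual`.
#' @export
run_closed_loop <- function(recording, quality_model, n3_model,
                            config = scheduler_config(),
                            quality_threshold = 0.5, theta = 0.2,
                            seed = 1, trace_every = 25) {
  stopifnot(inherits(recording, "mc_recording"))
  fs <- recording$fs_eeg
  vc <- gate_and_select(recording, quality_model, threshold = quality_threshold,
                        theta = theta)
  feats <- epoch_features_for_night(vc, recording$accel, recording$fs_accel)
  p_n3 <- predict_n3(feats, n3_model)
  predicted <- dplyr::mutate(
    dplyr::select(feats, "epoch", "onset_s", "unscorable"),
    p_n3 = p_n3, is_n3 = p_n3 >= n3_model$threshold & !.data$unscorable)

  movements <- detect_movements(recording$accel, recording$fs_accel)

  # hard-condition gate evaluated on the epoch timeline; a decision made at
  # the end of epoch e governs samples of epoch e+1
  gs <- new_gate_state()
  n_ep <- nrow(predicted)
  allow_ep <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    t_dec <- predicted$onset_s[e] + 30
    mv <- movements$time_s[movements$time_s <= t_dec]
    if (length(mv)) gs <- note_movement(gs, max(mv))
    r <- hard_conditions(gs, t_dec, predicted$is_n3[e])
    gs <- r$state
    allow_ep[e] <- r$allow
  }
  predicted$gate_allow <- allow_ep

  # sample-resolution gate: epoch e's decision applies over epoch e+1, and
  # movement lockout is re-checked at sample resolution inside the loop below
  n <- length(vc$samples)
  gate <- rep(FALSE, n)
  for (e in which(allow_ep)) {
    i0 <- round((predicted$onset_s[e] + 30) * fs) + 1
    i1 <- min(n, round((predicted$onset_s[e] + 60) * fs))
    if (i0 <= i1) gate[i0:i1] <- TRUE
  }
  # the 4-h cutoff also binds at sample resolution (an epoch decision taken
  # just before the cutoff must not license pulses past it)
  first_n3_idx <- which(predicted$is_n3)[1]
  if (!is.na(first_n3_idx)) {
    first_n3_t <- predicted$onset_s[first_n3_idx] + 30
    cut <- round((first_n3_t + 14400) * fs)
    if (cut < n) gate[(cut + 1):n] <- FALSE
  }

  bank <- build_fit_bank(fs)
  # the sinusoid is fitted on the causally delta-filtered virtual channel
  # (0.4--4 Hz, 2nd order), the band the slow-oscillation fit targets
  bt <- signal::butter(1, c(0.4, 4) * 2 / fs, type = "pass")
  delta_vc <- iir_df2t(bt$b, bt$a, vc$samples, NULL)$y
  alpha_env <- NULL
  trace_keep <- list(); events <- list(); ev_i <- 0
  pending_alarms <- numeric(0)
  st <- new_scheduler_state()
  with_seed(seed, {
    segs <- contiguous_runs(gate)
    for (g in seq_len(nrow(segs))) {
      i0 <- max(1, segs$start[g] - bank$n + 1); i1 <- segs$end[g]
      x <- delta_vc[i0:i1]
      tr <- phase_trace(bank, x)
      tr$idx <- tr$idx + i0 - 1
      tr$time_s <- (tr$idx - 1) / fs
      tr <- tr[tr$idx >= segs$start[g], ]
      cross <- crossing_vector(tr$phase_now, tr$valid, config$target_phase_deg)
      cand <- which(cross)
      if (is.null(alpha_env) && length(cand)) {
        bp <- apply_zero_phase(ifelse(is.na(vc$samples), 0, vc$samples), fs,
                               band = c(8, 12), order = 4)
        tot <- ifelse(is.na(vc$samples), 0, vc$samples)
        sm <- function(z) as.numeric(data.table::frollmean(z, round(fs), align = "right", fill = 0))
        alpha_env <<- sm(bp^2) / pmax(sm(tot^2), 1e-9)
      }
      for (ci in cand) {
        now <- tr$time_s[ci]
        # apply any pending post-stimulation alarms that precede this crossing
        while (length(pending_alarms) && pending_alarms[1] <= now) {
          st <- scheduler_step(pending_alarms[1], crossing = FALSE,
                               gate_allow = FALSE, post_stim_alarm = TRUE,
                               state = st, config = config)$state
          pending_alarms <- pending_alarms[-1]
        }
        # movement lockout re-check at event resolution
        recent_mv <- movements$time_s[movements$time_s <= now & now - movements$time_s < 180]
        if (length(recent_mv)) next
        r <- scheduler_step(now, crossing = TRUE, gate_allow = TRUE,
                            post_stim_alarm = FALSE, state = st, config = config,
                            est_phase_deg = tr$phase_now[ci])
        st <- r$state
        if (!is.null(r$event)) {
          ev_i <- ev_i + 1; events[[ev_i]] <- r$event
          # schedule the post-stimulation watch: movement or alpha burst
          # within 6 s of the pulse triggers a 30-s pause
          t_watch1 <- now + config$post_stim_watch_s
          mv_hit <- movements$time_s[movements$time_s > now & movements$time_s <= t_watch1]
          al_hit <- alpha_burst_at(alpha_env, fs, now + 0.2, t_watch1)
          t_alarm <- suppressWarnings(min(c(mv_hit, al_hit), na.rm = TRUE))
          if (is.finite(t_alarm))
            pending_alarms <- sort(c(pending_alarms, t_alarm))
        }
      }
      keep <- tr$idx %% trace_every == 0 | cross
      trace_keep[[g]] <- tr[keep, ]
    }
  })
  events <- if (ev_i > 0) dplyr::bind_rows(events) else
    tibble::tibble(time_s = numeric(), arm = character(), train_index = integer(),
                   pulse_index = integer(), target_deg = numeric(),
                   est_phase_deg = numeric())
  structure(list(events = events,
                 predicted = predicted,
                 quality = vc$quality,
                 phase = if (length(trace_keep)) dplyr::bind_rows(trace_keep) else
                   tibble::tibble(),
                 movements = movements,
                 virtual = vc),
            class = "closed_loop_result")
}

contiguous_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' Audit a stimulation log against the pacing and safety rules
#'
#' Checks, from the log and gate information alone: at most two pulses per
#' train, within-train times ascending, at least the minimum gap between the
#' last pulse of a train and the first of the next, no pulse before the
#' 15-min onset delay or after the 4-h cutoff (relative to the first N3
#' detection), and no pulse within 3 min after a large movement.
#'
#' @param events Stim log tibble from [run_closed_loop()].
#' @param predicted Per-epoch tibble from the same run (for first-N3 timing).
#' @param movements Movement tibble.
#' @param config The [scheduler_config()] used.
#' @return Tibble of violations (zero rows when compliant).
#' @export
audit_stim_log <- function(events, predicted, movements,
                           config = scheduler_config()) {
  viol <- list(); vi <- 0
  add <- function(rule, detail) {
    vi <<- vi + 1
    viol[[vi]] <<- tibble::tibble(rule = rule, detail = detail)
  }
  if (nrow(events)) {
    by_train <- split(events, events$train_index)
    for (tr in by_train) {
      if (nrow(tr) > config$max_pulses_per_train)
        add("max_pulses", sprintf("train %d has %d pulses", tr$train_index[1], nrow(tr)))
      if (is.unsorted(tr$time_s, strictly = TRUE) && nrow(tr) > 1)
        add("ascending", sprintf("train %d times not ascending", tr$train_index[1]))
    }
    trains <- dplyr::summarise(dplyr::group_by(events, .data$train_index),
                               first = min(.data$time_s), last = max(.data$time_s),
                               .groups = "drop")
    trains <- dplyr::arrange(trains, .data$first)
    if (nrow(trains) > 1) {
      gaps <- trains$first[-1] - trains$last[-nrow(trains)]
      bad <- which(gaps < config$min_gap_after_train_s)
      for (b in bad) add("train_gap", sprintf("gap %.2f s before train %d",
                                              gaps[b], trains$train_index[b + 1]))
    }
    first_n3 <- predicted$onset_s[which(predicted$is_n3)[1]] + 30
    if (!is.na(first_n3)) {
      early <- events$time_s < first_n3 + 900
      late <- events$time_s > first_n3 + 14400
      if (any(early)) add("onset_delay", sprintf("%d pulse(s) before first N3 + 15 min", sum(early)))
      if (any(late)) add("cutoff_4h", sprintf("%d pulse(s) after first N3 + 4 h", sum(late)))
    }
    for (i in seq_len(nrow(events))) {
      dmv <- events$time_s[i] - movements$time_s
      if (any(dmv > 0 & dmv < 180))
        add("movement_lockout", sprintf("pulse at %.1f s within 3 min of movement", events$time_s[i]))
    }
  }
  if (vi == 0) tibble::tibble(rule = character(), detail = character())
  else dplyr::bind_rows(viol)
}
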