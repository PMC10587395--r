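#' Experiment design parameters
#'
#' Describes the two-session slow event-related design: each session holds six
#' runs of 160 volumes (TR 3 s); every run is split into an auditory half
#' (voice clips) and a visual half (body clips in session 1, face clips in
#' session 2); each half presents 18 one-second trials -- 16 regular trials
#' (four per emotion: anger, happy, neutral, fear) plus two catch trials of the
#' orthogonal change-detection task -- separated by inter-stimulus intervals
#' jittered between 10.7 and 11.3 s.
#'
#' @param n_sessions number of scan sessions.
#' @param runs_per_session runs in each session.
#' @param volumes_per_run volumes acquired per run.
#' @param tr repetition time in seconds.
#' @param stim_duration stimulus clip length in seconds.
#' @param isi_range length-2 numeric, inter-stimulus interval bounds (s).
#' @param trials_per_run_half total trials in one run half.
#' @param regular_trials_per_run_half non-catch trials in one run half; must be
#'   a multiple of the number of emotions.
#' @param catch_trials_per_run_half catch trials in one run half.
#' @param emotions ordered emotion labels.
#' @param stimulus_types stimulus category labels.
#' @param visual_type_by_session which visual category each session's visual
#'   run halves present (auditory halves are always voice).
#' @param n_actors actor identities assigned round-robin.
#' @param lead_in seconds between a half's start and its first onset.
#' @return an `experiment_design` list.
#' @export
experiment_design <- function(n_sessions = 2L,
                              runs_per_session = 6L,
                              volumes_per_run = 160L,
                              tr = 3,
                              stim_duration = 1,
                              isi_range = c(10.7, 11.3),
                              trials_per_run_half = 18L,
                              regular_trials_per_run_half = 16L,
                              catch_trials_per_run_half = 2L,
                              emotions = c("anger", "happy", "neutral", "fear"),
                              stimulus_types = c("face", "body", "voice"),
                              visual_type_by_session = c("body", "face"),
                              n_actors = 4L,
                              lead_in = 2) {
  design <- list(
    n_sessions = as.integer(n_sessions),
    runs_per_session = as.integer(runs_per_session),
    volumes_per_run = as.integer(volumes_per_run),
    tr = tr, stim_duration = stim_duration,
    isi_range = as.numeric(isi_range),
    trials_per_run_half = as.integer(trials_per_run_half),
    regular_trials_per_run_half = as.integer(regular_trials_per_run_half),
    catch_trials_per_run_half = as.integer(catch_trials_per_run_half),
    emotions = emotions, stimulus_types = stimulus_types,
    visual_type_by_session = visual_type_by_session,
    n_actors = as.integer(n_actors), lead_in = lead_in
  )
  class(design) <- "experiment_design"
  validate_experiment_design(design)
  design
}

validate_experiment_design <- function(d) {
  stopifnot(inherits(d, "experiment_design"))
  if (d$regular_trials_per_run_half + d$catch_trials_per_run_half !=
      d$trials_per_run_half) {
    stop("regular + catch trials must equal trials_per_run_half", call. = FALSE)
  }
  if (d$regular_trials_per_run_half %% length(d$emotions) != 0) {
    stop("regular trials per run half must balance across emotions",
         call. = FALSE)
  }
  if (length(d$visual_type_by_session) != d$n_sessions ||
      !all(d$visual_type_by_session %in% d$stimulus_types)) {
    stop("visual_type_by_session must name one stimulus type per session",
         call. = FALSE)
  }
  if (!"voice" %in% d$stimulus_types) {
    stop("stimulus_types must include 'voice' for the auditory halves",
         call. = FALSE)
  }
  if (d$tr <= 0 || d$stim_duration <= 0) stop("tr and stim_duration must be positive", call. = FALSE)
  if (length(d$isi_range) != 2 || diff(d$isi_range) < 0 || d$isi_range[1] < 0) {
    stop("isi_range must be an increasing non-negative pair", call. = FALSE)
  }
  invisible(d)
}

#' Build the full two-session trial schedule
#'
#' Lays out every run as two halves (visual-first in odd runs, auditory-first
#' in even runs, so half order is counterbalanced), draws a random emotion
#' order for the regular trials of each half, interleaves the catch trials at
#' random slots, and jitters inter-stimulus intervals uniformly within
#' `isi_range`. Identical seeds give identical schedules.
#'
#' @param design an [experiment_design()].
#' @param seed integer seed for the schedule.
#' @return a data frame (class `event_table`) with columns `onset`, `duration`,
#'   `trial_type`, `stimulus_type`, `emotion`, `session`, `run`, `run_half`,
#'   `actor`, `is_catch`. Onsets are seconds from run start.
#' @export
build_design <- function(design, seed) {
  validate_experiment_design(design)
  set.seed(seed)
  run_len <- design$volumes_per_run * design$tr
  half_len <- run_len / 2
  nt <- design$trials_per_run_half
  min_span <- design$lead_in + (nt - 1) * (design$stim_duration + design$isi_range[1]) +
    design$stim_duration
  if (min_span > half_len) {
    stop(sprintf(
      "schedule-infeasible: %d trials need %.1f s at minimal ISI but a run half is %.1f s",
      nt, min_span, half_len), call. = FALSE)
  }
  per_emotion <- design$regular_trials_per_run_half %/% length(design$emotions)
  n_runs <- design$n_sessions * design$runs_per_session
  out <- vector("list", n_runs * 2)
  for (run in seq_len(n_runs)) {
    session <- ceiling(run / design$runs_per_session)
    halves <- if (run %% 2 == 1) c("visual", "auditory") else c("auditory", "visual")
    for (h in 1:2) {
      half <- halves[h]
      half_start <- (h - 1) * half_len
      stype <- if (half == "visual") design$visual_type_by_session[session] else "voice"
      emo_order <- sample(rep(design$emotions, per_emotion))
      catch_pos <- sort(sample.int(nt, design$catch_trials_per_run_half))
      is_catch <- seq_len(nt) %in% catch_pos
      emotion <- rep(NA_character_, nt)
      emotion[!is_catch] <- emo_order
      isi <- stats::runif(nt - 1, design$isi_range[1], design$isi_range[2])
      onset <- half_start + design$lead_in +
        c(0, cumsum(design$stim_duration + isi))
      stopifnot(all(onset + design$stim_duration <= half_start + half_len))
      out[[(run - 1) * 2 + h]] <- data.frame(
        onset = onset,
        duration = design$stim_duration,
        trial_type = ifelse(is_catch, "catch", paste(stype, emotion, sep = "_")),
        stimulus_type = stype,
        emotion = emotion,
        session = session,
        run = run,
        run_half = half,
        actor = rep_len(seq_len(design$n_actors), nt),
        is_catch = is_catch,
        stringsAsFactors = FALSE
      )
    }
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  attr(ev, "design") <- design
  ev
}

#' Check an event table against the design invariants
#'
#' Verifies trial counts, per-half emotion balance, ISI bounds, run-length
#' fit, and the session/stimulus pairing. Used by the property tests and by
#' [read_events()] validation.
#'
#' @param events event table as returned by [build_design()].
#' @param design the [experiment_design()] the table should satisfy.
#' @return invisibly `TRUE`; stops with a message on the first violation.
#' @export
check_event_table <- function(events, design) {
  run_len <- design$volumes_per_run * design$tr
  if (any(events$onset + events$duration > run_len)) {
    stop("trial extends past end of run", call. = FALSE)
  }
  by_half <- split(events, list(events$run, events$run_half), drop = TRUE)
  for (hv in by_half) {
    if (nrow(hv) != design$trials_per_run_half) stop("wrong trial count in a run half", call. = FALSE)
    if (sum(!hv$is_catch) != design$regular_trials_per_run_half) stop("wrong regular-trial count", call. = FALSE)
    tab <- table(hv$emotion[!hv$is_catch])
    if (!all(sort(names(tab)) == sort(design$emotions)) ||
        length(unique(as.integer(tab))) != 1) {
      stop("emotions are not balanced within a run half", call. = FALSE)
    }
    o <- sort(hv$onset)
    isi <- diff(o) - design$stim_duration
    if (any(isi < design$isi_range[1] - 1e-9 | isi > design$isi_range[2] + 1e-9)) {
      stop("inter-stimulus interval outside the design bounds", call. = FALSE)
    }
    sess <- unique(hv$session)
    expected <- if (unique(hv$run_half) == "auditory") "voice" else design$visual_type_by_session[sess]
    if (!all(hv$stimulus_type == expected)) stop("stimulus type does not match session pairing", call. = FALSE)
  }
  invisible(TRUE)
}
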