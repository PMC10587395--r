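modality_of <- function(stimulus_type) {
  ifelse(stimulus_type == "voice", "auditory", "visual")
}

new_task <- function(name, kind, filter, label_fun, levels,
                     train_filter = NULL, test_filter = NULL) {
  structure(list(name = name, kind = kind, filter = filter,
                 label_fun = label_fun, levels = levels,
                 train_filter = train_filter, test_filter = test_filter,
                 chance_level = 1 / length(levels)),
            class = "decoding_task")
}

#' Decoding tasks
#'
#' Constructors for the four families of decoding problems. Each task carries
#' a trial filter (a predicate on the trial label table), a label extractor,
#' an ordered class set, and the analytic chance level (1 / number of
#' classes).
#'
#' * `task_modality(session)`: visual vs auditory. The classifier is trained
#'   per session pairing -- body vs voice in session 1, face vs voice in
#'   session 2 -- when `session` is given, or on all trials pooled otherwise.
#'   Chance 50%.
#' * `task_emotion_all()`: 4-way emotion from face, body and voice trials
#'   pooled across sessions. Chance 25%.
#' * `task_emotion_within(stimulus_types, session)`: 4-way emotion restricted
#'   to the given stimulus categories (e.g. `"voice"`, or
#'   `c("face", "body")` for the combined visual modality), optionally to one
#'   session (the per-session voice variants).
#' * `task_emotion_crossmodal(train, test)`: 4-way emotion, trained on one
#'   stimulus category and tested on another. Voice trials are taken from the
#'   session paired with the visual category (voice of the body session for
#'   body, of the face session for face), so train and test sets are disjoint
#'   by construction.
#'
#' @param session restrict to one session (1 or 2), or `NULL` for all.
#' @param stimulus_types stimulus categories to keep.
#' @param train,test stimulus category trained / tested on (one of them
#'   `"voice"`).
#' @param emotions ordered emotion class labels.
#' @return a `decoding_task`.
#' @name decoding_tasks
NULL

#' @rdname decoding_tasks
#' @export
task_modality <- function(session = NULL) {
  nm <- if (is.null(session)) "modality" else paste0("modality_s", session)
  new_task(
    name = nm, kind = "cv",
    filter = function(lab) {
      if (is.null(session)) rep(TRUE, nrow(lab)) else lab$session == session
    },
    label_fun = function(lab) modality_of(lab$stimulus_type),
    levels = c("visual", "auditory")
  )
}

#' @rdname decoding_tasks
#' @export
task_emotion_all <- function(emotions = c("anger", "happy", "neutral", "fear")) {
  new_task(
    name = "emotion_all", kind = "cv",
    filter = function(lab) rep(TRUE, nrow(lab)),
    label_fun = function(lab) lab$emotion,
    levels = emotions
  )
}

#' @rdname decoding_tasks
#' @export
task_emotion_within <- function(stimulus_types, session = NULL,
                                emotions = c("anger", "happy", "neutral", "fear")) {
  nm <- paste0("emotion_", paste(stimulus_types, collapse = "+"),
               if (!is.null(session)) paste0("_s", session) else "")
  new_task(
    name = nm, kind = "cv",
    filter = function(lab) {
      keep <- lab$stimulus_type %in% stimulus_types
      if (!is.null(session)) keep <- keep & lab$session == session
      keep
    },
    label_fun = function(lab) lab$emotion,
    levels = emotions
  )
}

voice_session_for <- function(visual_type) {
  # voice trials paired with a visual category come from that category's session
  switch(visual_type, body = 1L, face = 2L,
         stop("unknown visual category: ", visual_type, call. = FALSE))
}

#' @rdname decoding_tasks
#' @export
task_emotion_crossmodal <- function(train, test,
                                    emotions = c("anger", "happy", "neutral", "fear")) {
  if (sum(c(train, test) == "voice") != 1) {
    stop("cross-modal tasks pair voice with a visual category", call. = FALSE)
  }
  visual <- setdiff(c(train, test), "voice")
  sess <- voice_session_for(visual)
  part_filter <- function(stype) {
    function(lab) {
      if (stype == "voice") {
        lab$stimulus_type == "voice" & lab$session == sess
      } else {
        lab$stimulus_type == stype
      }
    }
  }
  new_task(
    name = paste0("emotion_", train, "_to_", test), kind = "crossmodal",
    filter = function(lab) part_filter(train)(lab) | part_filter(test)(lab),
    label_fun = function(lab) lab$emotion,
    levels = emotions,
    train_filter = part_filter(train),
    test_filter = part_filter(test)
  )
}

#' @rdname decoding_tasks
#' @export
crossmodal_task_set <- function(emotions = c("anger", "happy", "neutral", "fear")) {
  list(task_emotion_crossmodal("body", "voice", emotions),
       task_emotion_crossmodal("voice", "body", emotions),
       task_emotion_crossmodal("face", "voice", emotions),
       task_emotion_crossmodal("voice", "face", emotions))
}
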