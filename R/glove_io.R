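# Event-stream and cohort-table I/O.
#
# CSV dialects:
#   events: trial_id,subject_id,session,condition,hand,finger,t_on_ms,t_off_ms
#   tones : trial_id,t_tone_ms
#   cohort: subject_id,group,age,sex,edss,disease_duration_months,msfc,nhpt_s,
#           t25w_s,pasat,mfis_total,mfis_physical,mfis_cognitive,mfis_psychosocial
# Timestamps are integer milliseconds (1 kHz acquisition); fractional values are
# rejected, never rounded. Lines starting with '#' are provenance headers.

GLOVE_CONDITIONS <- c("SV", "MV", "2HZ", "2HZ_BIM")
GLOVE_HANDS <- c("L", "R")
GLOVE_FINGERS <- 2:5
PACED_CONDITIONS <- c("2HZ", "2HZ_BIM")

COHORT_COLUMNS <- c(
  "subject_id", "group", "age", "sex", "edss", "disease_duration_months",
  "msfc", "nhpt_s", "t25w_s", "pasat", "mfis_total", "mfis_physical",
  "mfis_cognitive", "mfis_psychosocial"
)

EVENT_COLUMNS <- c(
  "trial_id", "subject_id", "session", "condition",
  "hand", "finger", "t_on_ms", "t_off_ms"
)

.is_wholenumber <- function(x) {
  is.numeric(x) & is.finite(x) & x == floor(x)
}

#' Construct and validate a glove trial
#'
#' A trial is one 60-s recording of a repetitive thumb-to-finger opposition
#' sequence in one condition. Events are thumb contacts with fingers 2 (index)
#' to 5 (little); timestamps are integer milliseconds from trial start, contact
#' occupying the closed interval `[t_on, t_off]`.
#'
#' Validation is total: every malformed input raises a diagnostic error, never
#' a partially constructed object. Same-hand overlapping contacts (a physical
#' impossibility; sensor glitch) are rejected unless `repair = TRUE`, in which
#' case overlaps of at most `repair_max_ms` are resolved (same finger: merged
#' into one contact; different fingers: the earlier offset is truncated to the
#' later onset).
#'
#' @param trial_id,subject_id identifiers.
#' @param session session index, integer >= 1.
#' @param condition one of `"SV"`, `"MV"`, `"2HZ"`, `"2HZ_BIM"`. Unimanual
#'   conditions must contain right-hand events only; paced conditions must
#'   carry a metronome tone track at approximately 500 ms spacing.
#' @param events data.frame with columns `hand` (`"L"`/`"R"`), `finger`
#'   (2--5), `t_on`, `t_off` (integer ms, `t_off > t_on >= 0`).
#' @param tones integer ms vector of metronome tone times (empty for SV/MV).
#' @param duration trial length in ms (default 60000).
#' @param repair logical; attempt conservative repair of small same-hand
#'   overlaps instead of rejecting.
#' @param repair_max_ms largest overlap (ms) eligible for repair.
#' @return An object of class `glove_trial`.
#' @export
glove_trial <- function(trial_id, subject_id, session, condition, events,
                        tones = integer(), duration = 60000,
                        repair = FALSE, repair_max_ms = 5) {
  if (length(condition) != 1L || !condition %in% GLOVE_CONDITIONS) {
    stop("condition must be one of ", paste(GLOVE_CONDITIONS, collapse = ", "))
  }
  if (length(session) != 1L || !.is_wholenumber(session) || session < 1) {
    stop("session must be a single integer >= 1")
  }
  if (!.is_wholenumber(duration) || duration <= 0) {
    stop("duration must be a positive integer number of milliseconds")
  }
  events <- as.data.frame(events)
  needed <- c("hand", "finger", "t_on", "t_off")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols)) {
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  events <- events[needed]
  if (nrow(events)) {
    bad_hand <- which(!events$hand %in% GLOVE_HANDS)
    if (length(bad_hand)) {
      stop("invalid hand value in event row(s) ",
           paste(head(bad_hand, 5), collapse = ", "))
    }
    bad_finger <- which(!events$finger %in% GLOVE_FINGERS)
    if (length(bad_finger)) {
      stop("finger must be in 2..5; bad event row(s) ",
           paste(head(bad_finger, 5), collapse = ", "))
    }
    frac <- which(!(.is_wholenumber(events$t_on) & .is_wholenumber(events$t_off)))
    if (length(frac)) {
      stop("timestamps must be integer milliseconds (fractional values are ",
           "rejected, not rounded); bad event row(s) ",
           paste(head(frac, 5), collapse = ", "))
    }
    neg <- which(events$t_on < 0)
    if (length(neg)) {
      stop("t_on must be >= 0; bad event row(s) ",
           paste(head(neg, 5), collapse = ", "))
    }
    inv <- which(events$t_off <= events$t_on)
    if (length(inv)) {
      stop("t_off must exceed t_on; bad event row(s) ",
           paste(head(inv, 5), collapse = ", "))
    }
    events$t_on <- as.integer(events$t_on)
    events$t_off <- as.integer(events$t_off)
    events$finger <- as.integer(events$finger)
    events$hand <- as.character(events$hand)
    # stable sort by onset, hand as tiebreak (R before L is irrelevant, fixed)
    events <- events[order(events$t_on, events$hand, events$t_off), , drop = FALSE]
    rownames(events) <- NULL
    for (h in unique(events$hand)) {
      idx <- which(events$hand == h)
      if (length(idx) > 1L) {
        ev <- events[idx, ]
        overlap <- ev$t_off[-nrow(ev)] - ev$t_on[-1L]  # >0 means overlap
        bad <- which(overlap > 0)
        if (length(bad)) {
          if (!repair || any(overlap[bad] > repair_max_ms)) {
            stop("same-hand overlapping contacts on hand ", h,
                 " at event pair(s) ", paste(head(bad, 5), collapse = ", "),
                 if (!repair) " (set repair = TRUE to merge overlaps <= 5 ms)")
          }
          drop <- logical(nrow(ev))
          for (b in bad) {
            if (ev$finger[b] == ev$finger[b + 1L]) {
              # same finger: merge the two contacts
              ev$t_off[b] <- max(ev$t_off[b], ev$t_off[b + 1L])
              drop[b + 1L] <- TRUE
            } else {
              ev$t_off[b] <- ev$t_on[b + 1L]
            }
          }
          ev <- ev[!drop, , drop = FALSE]
          events <- rbind(events[-idx, , drop = FALSE], ev)
          events <- events[order(events$t_on, events$hand, events$t_off), ,
                           drop = FALSE]
          rownames(events) <- NULL
        }
      }
    }
  } else {
    events <- data.frame(hand = character(), finger = integer(),
                         t_on = integer(), t_off = integer())
  }
  if (!condition %in% "2HZ_BIM" && any(events$hand == "L")) {
    stop("condition ", condition, " is unimanual (dominant right hand); ",
         "left-hand events present")
  }
  tones <- as.numeric(tones)
  if (condition %in% PACED_CONDITIONS) {
    if (!length(tones)) {
      stop("paced condition ", condition, " requires a non-empty tone track")
    }
    if (any(!.is_wholenumber(tones))) stop("tone times must be integer ms")
    tones <- sort(as.integer(tones))
    if (length(tones) > 1L) {
      spacing <- median(diff(tones))
      if (spacing < 450 || spacing > 550) {
        warning("tone spacing (median ", spacing,
                " ms) far from the nominal 500 ms metronome period")
      }
    }
  } else if (length(tones)) {
    stop("self-paced condition ", condition, " must not carry tones")
  } else {
    tones <- integer()
  }
  structure(
    list(trial_id = as.character(trial_id),
         subject_id = as.character(subject_id),
         session = as.integer(session),
         condition = condition,
         duration = as.integer(duration),
         events = events,
         tones = as.integer(tones)),
    class = "glove_trial"
  )
}

#' @export
print.glove_trial <- function(x, ...) {
  cat(sprintf("<glove_trial %s> subject %s session %d condition %s: %d events",
              x$trial_id, x$subject_id, x$session, x$condition,
              nrow(x$events)),
      if (length(x$tones)) sprintf(", %d tones", length(x$tones)) else "",
      sprintf(", %d ms\n", x$duration), sep = "")
  invisible(x)
}

.read_glove_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

.write_glove_csv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one glove trial from an event CSV
#'
#' The event CSV must contain exactly one `trial_id`. For paced conditions a
#' tone CSV (columns `trial_id,t_tone_ms`) must be supplied.
#'
#' @param path event CSV path.
#' @param tones_path optional tone CSV path.
#' @param repair passed to [glove_trial()].
#' @param duration trial length in ms.
#' @return A validated [glove_trial()].
#' @export
read_trial <- function(path, tones_path = NULL, repair = FALSE,
                       duration = 60000) {
  df <- .read_glove_csv(path, EVENT_COLUMNS, "event")
  if (!nrow(df)) stop("event file ", path, " contains no data rows")
  ids <- unique(df$trial_id)
  if (length(ids) != 1L) {
    stop("read_trial expects exactly one trial_id per file; found ",
         length(ids), " (use read_trials for batches)")
  }
  tones <- integer()
  if (!is.null(tones_path)) {
    td <- .read_glove_csv(tones_path, c("trial_id", "t_tone_ms"), "tone")
    tones <- td$t_tone_ms[td$trial_id == ids]
  }
  glove_trial(
    trial_id = ids,
    subject_id = unique(df$subject_id)[1L],
    session = unique(df$session)[1L],
    condition = unique(df$condition)[1L],
    events = data.frame(hand = df$hand, finger = df$finger,
                        t_on = df$t_on_ms, t_off = df$t_off_ms),
    tones = tones, duration = duration, repair = repair
  )
}

#' Read a batch of glove trials
#'
#' @param events_path combined event CSV (many trial_ids).
#' @param tones_path optional combined tone CSV.
#' @inheritParams read_trial
#' @return Named list of [glove_trial()] objects, keyed by trial_id.
#' @export
read_trials <- function(events_path, tones_path = NULL, repair = FALSE,
                        duration = 60000) {
  df <- .read_glove_csv(events_path, EVENT_COLUMNS, "event")
  tones_df <- NULL
  if (!is.null(tones_path)) {
    tones_df <- .read_glove_csv(tones_path, c("trial_id", "t_tone_ms"), "tone")
  }
  out <- lapply(split(df, df$trial_id), function(d) {
    tones <- if (!is.null(tones_df)) {
      tones_df$t_tone_ms[tones_df$trial_id == d$trial_id[1L]]
    } else integer()
    glove_trial(
      trial_id = d$trial_id[1L], subject_id = d$subject_id[1L],
      session = d$session[1L], condition = d$condition[1L],
      events = data.frame(hand = d$hand, finger = d$finger,
                          t_on = d$t_on_ms, t_off = d$t_off_ms),
      tones = tones, duration = duration, repair = repair
    )
  })
  out[order(names(out))]
}

.trial_events_df <- function(trial) {
  ev <- trial$events
  data.frame(
    trial_id = rep(trial$trial_id, nrow(ev)),
    subject_id = rep(trial$subject_id, nrow(ev)),
    session = rep(trial$session, nrow(ev)),
    condition = rep(trial$condition, nrow(ev)),
    hand = ev$hand, finger = ev$finger,
    t_on_ms = ev$t_on, t_off_ms = ev$t_off,
    stringsAsFactors = FALSE
  )
}

.trial_tones_df <- function(trial) {
  data.frame(trial_id = rep(trial$trial_id, length(trial$tones)),
             t_tone_ms = trial$tones)
}

#' Write a glove trial to an event CSV
#'
#' Integer timestamps are preserved exactly; `read_trial(write_trial(x))`
#' round-trips field for field.
#'
#' @param trial a [glove_trial()].
#' @param path event CSV path.
#' @param tones_path optional tone CSV path (required to round-trip paced
#'   trials).
#' @param provenance optional character vector of provenance header lines.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, tones_path = NULL, provenance = NULL) {
  stopifnot(inherits(trial, "glove_trial"))
  .write_glove_csv(.trial_events_df(trial), path, provenance)
  if (!is.null(tones_path)) {
    .write_glove_csv(.trial_tones_df(trial), tones_path, provenance)
  }
  invisible(path)
}

#' Write a batch of glove trials
#'
#' @param trials list of [glove_trial()] objects.
#' @inheritParams write_trial
#' @param events_path combined event CSV path.
#' @export
write_trials <- function(trials, events_path, tones_path = NULL,
                         provenance = NULL) {
  ev <- do.call(rbind, lapply(trials, .trial_events_df))
  .write_glove_csv(ev, events_path, provenance)
  if (!is.null(tones_path)) {
    tn <- do.call(rbind, lapply(trials, .trial_tones_df))
    .write_glove_csv(tn, tones_path, provenance)
  }
  invisible(events_path)
}

#' Validate a cohort metadata table
#'
#' One row per subject. `group` is `"HC"` or `"MS"`; EDSS must be absent for
#' HC and lie on the 0--7 half-point grid for MS. Clinical fields are optional
#' (empty/NA), never sentinel numbers.
#'
#' @param df data.frame with the cohort columns (see [read_cohort()]).
#' @return The validated data.frame (class `glove_cohort` prepended).
#' @export
validate_cohort <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[COHORT_COLUMNS]
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad_group <- which(!df$group %in% c("HC", "MS"))
  if (length(bad_group)) {
    stop("group must be HC or MS; bad row(s) ",
         paste(head(bad_group, 5), collapse = ", "))
  }
  hc_edss <- which(df$group == "HC" & !is.na(df$edss))
  if (length(hc_edss)) {
    stop("EDSS must be absent for HC subjects; bad row(s) ",
         paste(head(hc_edss, 5), collapse = ", "))
  }
  edss <- df$edss[!is.na(df$edss)]
  if (length(edss)) {
    bad <- which(!is.na(df$edss) &
                 (df$edss < 0 | df$edss > 7 | df$edss * 2 != floor(df$edss * 2)))
    if (length(bad)) {
      stop("EDSS must lie on the 0..7 half-point grid; bad row(s) ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  if (any(!is.na(df$age) & df$age <= 0)) stop("age must be positive")
  class(df) <- c("glove_cohort", class(df))
  df
}

#' Read a cohort metadata CSV
#'
#' Columns: `subject_id,group,age,sex,edss,disease_duration_months,msfc,
#' nhpt_s,t25w_s,pasat,mfis_total,mfis_physical,mfis_cognitive,
#' mfis_psychosocial`. HC rows may leave clinical columns empty.
#'
#' @param path cohort CSV path.
#' @return Validated cohort data.frame, one row per subject.
#' @export
read_cohort <- function(path) {
  validate_cohort(.read_glove_csv(path, COHORT_COLUMNS, "cohort"))
}

#' Write a cohort metadata CSV
#'
#' @param cohort cohort data.frame (validated on the way out).
#' @param path output CSV path.
#' @param provenance optional provenance header lines.
#' @export
write_cohort <- function(cohort, path, provenance = NULL) {
  cohort <- validate_cohort(cohort)
  class(cohort) <- "data.frame"
  .write_glove_csv(cohort, path, provenance)
}
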