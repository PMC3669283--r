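# Kinematic parameter extraction.
#
# TD   touch duration: thumb-finger contact time, t_off - t_on, per touch.
# ITI  inter-tapping interval: gap between the end of one contact and the
#      start of the next on the same hand.
# RATE movement rate: 1000 / (mean TD + mean ITI), Hz.
# IHI  inter-hand interval (bimanual trials): mean absolute difference
#      between corresponding left- and right-hand touch onsets; larger IHI
#      means worse bimanual coordination.

.hand_events <- function(trial, hand) {
  ev <- trial$events[trial$events$hand == hand, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Per-touch contact durations
#'
#' @param trial a validated [glove_trial()].
#' @param hand `"R"` (default) or `"L"`.
#' @return Numeric vector of per-event `t_off - t_on` in ms, in event order.
#' @export
touch_durations <- function(trial, hand = "R") {
  stopifnot(inherits(trial, "glove_trial"), hand %in% GLOVE_HANDS)
  ev <- .hand_events(trial, hand)
  as.numeric(ev$t_off - ev$t_on)
}

#' Inter-tapping intervals
#'
#' Gap between the end of each contact and the start of the next contact on
#' the same hand: `t_on[i+1] - t_off[i]`, length `n_touches - 1`.
#'
#' @inheritParams touch_durations
#' @return Numeric vector of gaps in ms (empty, with a warning, when the hand
#'   has fewer than 2 events).
#' @export
inter_tap_intervals <- function(trial, hand = "R") {
  stopifnot(inherits(trial, "glove_trial"), hand %in% GLOVE_HANDS)
  ev <- .hand_events(trial, hand)
  n <- nrow(ev)
  if (n < 2L) {
    warning("fewer than 2 events on hand ", hand,
            "; no inter-tapping intervals")
    return(numeric())
  }
  as.numeric(ev$t_on[-1L] - ev$t_off[-n])
}

#' Movement rate
#'
#' `1000 / (mean TD + mean ITI)` in Hz. The default follows the defining
#' formula literally (trial-mean TD plus trial-mean ITI); `method = "count"`
#' instead divides the touch count by elapsed time, which differs under
#' timing jitter and is provided for sensitivity checks only.
#'
#' @inheritParams touch_durations
#' @param method `"formula"` (default) or `"count"`.
#' @return Rate in Hz.
#' @export
movement_rate <- function(trial, hand = "R", method = c("formula", "count")) {
  method <- match.arg(method)
  ev <- .hand_events(trial, hand)
  if (nrow(ev) < 2L) {
    stop("movement rate undefined: fewer than 2 events on hand ", hand)
  }
  if (method == "count") {
    span <- ev$t_on[nrow(ev)] - ev$t_on[1L]
    if (span <= 0) stop("movement rate undefined: zero elapsed time")
    return(1000 * (nrow(ev) - 1L) / span)
  }
  td <- mean(touch_durations(trial, hand))
  iti <- mean(pmax(inter_tap_intervals(trial, hand), 0))
  denom <- td + iti
  if (denom <= 0) stop("movement rate undefined: non-positive mean cycle")
  1000 / denom
}

# Deterministic pairing of left/right touches for the inter-hand interval.
# Walks both hands' event lists; a pair is emitted when the current fingers
# match (cycle position alignment on finger identity). On a mismatch the
# pointer with the earlier onset advances and that touch is excluded, which
# re-aligns the hands after a dropped touch.
.pair_hands <- function(ev_l, ev_r) {
  i <- 1L; j <- 1L
  nl <- nrow(ev_l); nr <- nrow(ev_r)
  left <- integer(); right <- integer(); excluded <- 0L
  while (i <= nl && j <= nr) {
    if (ev_l$finger[i] == ev_r$finger[j]) {
      left <- c(left, i); right <- c(right, j)
      i <- i + 1L; j <- j + 1L
    } else if (ev_l$t_on[i] <= ev_r$t_on[j]) {
      i <- i + 1L; excluded <- excluded + 1L
    } else {
      j <- j + 1L; excluded <- excluded + 1L
    }
  }
  excluded <- excluded + (nl - i + 1L) + (nr - j + 1L)
  list(left = left, right = right, excluded = excluded)
}

#' Inter-hand interval (bimanual asynchrony)
#'
#' Pairs left- and right-hand touches by cycle position after alignment on
#' finger identity and returns the mean absolute onset difference in ms.
#' Unpaired touches (dropped contacts, trailing partial cycles) are excluded
#' and counted in the `n_excluded` attribute.
#'
#' @param trial a validated bimanual (`2HZ_BIM`) [glove_trial()].
#' @return IHI in ms with attributes `n_pairs` and `n_excluded`. A warning is
#'   raised when fewer than 3 pairs support the estimate.
#' @export
inter_hand_interval <- function(trial) {
  stopifnot(inherits(trial, "glove_trial"))
  if (trial$condition != "2HZ_BIM") {
    stop("inter-hand interval is defined for the 2HZ_BIM condition only")
  }
  ev_l <- .hand_events(trial, "L")
  ev_r <- .hand_events(trial, "R")
  if (!nrow(ev_l) || !nrow(ev_r)) {
    stop("both hands must have events to compute the inter-hand interval")
  }
  p <- .pair_hands(ev_l, ev_r)
  if (length(p$left) < 3L) {
    warning("fewer than 3 left/right touch pairs; IHI estimate is unstable")
  }
  if (!length(p$left)) {
    stop("no alignable left/right touch pairs")
  }
  ihi <- mean(abs(ev_l$t_on[p$left] - ev_r$t_on[p$right]))
  structure(ihi, n_pairs = length(p$left), n_excluded = p$excluded)
}

#' Summarize one trial into its motor performance parameters
#'
#' For bimanual trials the right (dominant) hand supplies TD/ITI/RATE and the
#' left-right onset pairing supplies IHI. Negative gaps surviving validation
#' repair are clamped to 0 and counted in `n_excluded`.
#'
#' @param trial a validated [glove_trial()].
#' @return One-row data.frame: `trial_id, subject_id, session, condition,
#'   mean_td, mean_iti, rate, ihi, n_touches, n_excluded`. `ihi` is `NA`
#'   except in the `2HZ_BIM` condition.
#' @export
summarize_trial <- function(trial) {
  stopifnot(inherits(trial, "glove_trial"))
  td <- touch_durations(trial, "R")
  if (length(td) < 2L) {
    stop("trial ", trial$trial_id,
         ": fewer than 2 right-hand touches; parameters undefined")
  }
  iti_raw <- inter_tap_intervals(trial, "R")
  n_clamped <- sum(iti_raw < 0)
  iti <- pmax(iti_raw, 0)
  mean_td <- mean(td)
  mean_iti <- mean(iti)
  rate <- 1000 / (mean_td + mean_iti)
  ihi <- NA_real_
  n_excluded <- n_clamped
  if (trial$condition == "2HZ_BIM") {
    v <- inter_hand_interval(trial)
    ihi <- as.numeric(v)
    n_excluded <- n_excluded + attr(v, "n_excluded")
  }
  data.frame(
    trial_id = trial$trial_id, subject_id = trial$subject_id,
    session = trial$session, condition = trial$condition,
    mean_td = mean_td, mean_iti = mean_iti, rate = rate, ihi = ihi,
    n_touches = length(td), n_excluded = as.integer(n_excluded),
    stringsAsFactors = FALSE
  )
}

#' Batch kinematic extraction
#'
#' @param trials list of validated [glove_trial()] objects.
#' @return data.frame with one [summarize_trial()] row per trial.
#' @export
extract_params <- function(trials) {
  do.call(rbind, c(lapply(trials, summarize_trial),
                   list(make.row.names = FALSE)))
}

#' Pivot extracted parameters to one row per subject/session
#'
#' Produces the feature layout used by the discrimination and correlation
#' stages: `rate_sv` (SV), `rate_mv` (MV), `td_hz2`/`iti_hz2` (2HZ) and `ihi`
#' plus `log_ihi` (2HZ_BIM; natural log).
#'
#' @param params long data.frame from [extract_params()].
#' @return Wide data.frame keyed by `subject_id` and `session`.
#' @export
params_wide <- function(params) {
  key <- interaction(params$subject_id, params$session, drop = TRUE)
  rows <- lapply(split(params, key), function(d) {
    pick <- function(cond, col) {
      v <- d[[col]][d$condition == cond]
      if (length(v)) v[1L] else NA_real_
    }
    data.frame(
      subject_id = d$subject_id[1L], session = d$session[1L],
      rate_sv = pick("SV", "rate"), rate_mv = pick("MV", "rate"),
      td_hz2 = pick("2HZ", "mean_td"), iti_hz2 = pick("2HZ", "mean_iti"),
      ihi = pick("2HZ_BIM", "ihi"),
      stringsAsFactors = FALSE
    )
  })
  wide <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  wide$log_ihi <- ifelse(!is.na(wide$ihi) & wide$ihi > 0, log(wide$ihi),
                         NA_real_)
  if (any(!is.na(wide$ihi) & wide$ihi <= 0)) {
    warning("non-positive IHI cannot be log-transformed; set to NA")
  }
  wide[order(wide$subject_id, wide$session), , drop = FALSE]
}
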