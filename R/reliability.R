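# Test-retest agreement: two-way random-effects absolute-agreement ICC
# (McGraw & Wong ICC(A,1) / ICC(A,k)), standard error of measurement and the
# smallest real difference SRD = 1.96 * sqrt(2) * SEM.

#' Absolute-agreement intraclass correlation
#'
#' Two-way random-effects, absolute-agreement ICC from the ANOVA mean squares
#' of a subjects-by-sessions matrix: single-measure ICC(A,1) and
#' average-measure ICC(A,k). Negative estimates are reported as computed, not
#' truncated.
#'
#' @param data numeric matrix, rows = subjects (>= 3), columns = sessions
#'   (>= 2), no missing cells.
#' @return Named numeric vector `c(single = , average = )`.
#' @export
icc_agreement <- function(data) {
  m <- as.matrix(data)
  if (any(is.na(m))) stop("ICC requires a complete matrix (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop("ICC requires >= 3 subjects and >= 2 sessions")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0 && msc <= 0 && mse <= 0) {
    stop("ICC undefined: the matrix is constant (zero variance everywhere)")
  }
  single <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  average <- (msr - mse) / (msr + (msc - mse) / n)
  c(single = single, average = average)
}

#' Spearman-Brown step-up
#'
#' Reliability of the average of `k` measurements given the single-measure
#' reliability: `k * icc / (1 + (k - 1) * icc)`.
#'
#' @param icc_single single-measure reliability in (-1, 1].
#' @param k number of averaged measurements (>= 1).
#' @return Average-measure reliability.
#' @export
spearman_brown <- function(icc_single, k = 2) {
  stopifnot(k >= 1, icc_single > -1, icc_single <= 1)
  k * icc_single / (1 + (k - 1) * icc_single)
}

#' Standard error of measurement and smallest real difference
#'
#' `SEM = pooled_sd * sqrt(1 - icc_single)`; `SRD = 1.96 * sqrt(2) * SEM`,
#' the smallest longitudinal change exceeding measurement noise at 95%
#' confidence.
#'
#' @param pooled_sd pooled between-subject SD (root-mean-square of the
#'   session SDs), in parameter units.
#' @param icc_single single-measure absolute-agreement ICC (<= 1).
#' @return Named numeric vector `c(sem = , srd = )`.
#' @export
sem_srd <- function(pooled_sd, icc_single) {
  if (icc_single > 1) stop("icc_single must not exceed 1")
  if (pooled_sd < 0) stop("pooled_sd must be non-negative")
  sem <- pooled_sd * sqrt(1 - icc_single)
  c(sem = sem, srd = 1.96 * sqrt(2) * sem)
}

#' Smallest real difference as a percentage of the grand mean
#'
#' @param srd smallest real difference, parameter units.
#' @param grand_mean grand mean over sessions (> 0).
#' @return Raw percentage (report tables round it to integer).
#' @export
srd_percent <- function(srd, grand_mean) {
  if (grand_mean <= 0) stop("grand_mean must be positive")
  100 * srd / grand_mean
}

.pooled_sd <- function(sds) sqrt(mean(sds^2))

RELIABILITY_PARAMS <- c("rate_sv", "rate_mv", "td_hz2", "iti_hz2", "log_ihi")

PARAM_LABELS <- c(
  rate_sv = "RATE (SV) [Hz]",
  rate_mv = "RATE (MV) [Hz]",
  td_hz2 = "TD (2 Hz) [ms]",
  iti_hz2 = "ITI (2 Hz) [ms]",
  ihi = "IHI (2 Hz_bim) [ms]",
  log_ihi = "IHI (2 Hz_bim) (log-transformed)"
)

#' Test-retest reliability report
#'
#' Builds the standard reliability table (per-session mean and SD, SRD, SRD%,
#' single- and average-measure absolute-agreement ICC) for each motor
#' parameter over a two-session design. The inter-hand interval enters on the
#' natural-log scale. Subjects missing either session are dropped with a
#' warning.
#'
#' @param params long parameter table from [extract_params()] covering two
#'   sessions per subject.
#' @param parameters which parameters to report (default all five).
#' @return data.frame, one row per parameter, mirroring the reliability table
#'   layout.
#' @export
reliability_report <- function(params, parameters = RELIABILITY_PARAMS) {
  wide <- params_wide(params)
  sessions <- sort(unique(wide$session))
  if (length(sessions) != 2L) {
    stop("reliability report requires exactly 2 sessions; found ",
         length(sessions))
  }
  out <- lapply(parameters, function(p) {
    v <- wide[[p]]
    s1 <- wide[wide$session == sessions[1L], c("subject_id", p)]
    s2 <- wide[wide$session == sessions[2L], c("subject_id", p)]
    merged <- merge(s1, s2, by = "subject_id", suffixes = c("_1", "_2"))
    merged <- merged[complete.cases(merged), , drop = FALSE]
    n_dropped <- length(unique(wide$subject_id)) - nrow(merged)
    if (n_dropped > 0) {
      warning(p, ": ", n_dropped,
              " subject(s) missing a session or value; dropped")
    }
    m <- as.matrix(merged[, -1L, drop = FALSE])
    icc <- icc_agreement(m)
    sds <- apply(m, 2L, sd)
    means <- colMeans(m)
    ss <- sem_srd(.pooled_sd(sds), icc[["single"]])
    grand <- mean(means)
    data.frame(
      parameter = p, label = unname(PARAM_LABELS[p]), n = nrow(m),
      mean_s1 = means[1L], sd_s1 = sds[1L],
      mean_s2 = means[2L], sd_s2 = sds[2L],
      sem = ss[["sem"]], srd = ss[["srd"]],
      srd_pct = srd_percent(ss[["srd"]], grand),
      srd_pct_rounded = round(srd_percent(ss[["srd"]], grand)),
      icc_single = icc[["single"]], icc_average = icc[["average"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
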