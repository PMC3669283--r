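# Group comparison and clinical-correlation statistics: Mann-Whitney U
# (exact enumeration for small samples, tie-corrected normal approximation
# otherwise), age-adjusted partial Spearman correlations, and an
# ANOVA linear-trend analysis across disability strata.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. `U` counts pairs
#' where a value of `a` exceeds a value of `b` (ties count 1/2). For
#' `n1 + n2 <= 12` the two-sided p value is computed by exact enumeration of
#' all rank assignments (tie-aware); otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact_max enumerate exactly when `length(a) + length(b)` is at most
#'   this (default 12).
#' @return List with `u`, `p`, per-sample `mean`/`sem`, `direction`
#'   (`"a>b"`, `"a<b"` or `"none"`) and a `degenerate` flag (all values
#'   identical across both samples).
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) {
    p <- 1
  } else if (n1 + n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
  } else {
    nn <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- (n1 * n2 / 12) * (nn + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
  }
  direction <- if (u > mu) "a>b" else if (u < mu) "a<b" else "none"
  list(u = u, p = p, n1 = n1, n2 = n2,
       mean_a = mean(a), sem_a = sd(a) / sqrt(n1),
       mean_b = mean(b), sem_b = sd(b) / sqrt(n2),
       direction = direction, degenerate = degenerate)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and the covariate, then computes the partial
#' Pearson correlation of the ranked `x` and `y` given the ranked covariate,
#' with a t-based p value on `n - 3` degrees of freedom. With a constant
#' covariate this degenerates to the plain Spearman correlation (p on `n - 2`
#' df).
#'
#' @param x,y numeric vectors of equal length (n >= 5 complete triples).
#' @param covariate numeric adjustment variable (e.g. age).
#' @return List with `r`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariate) {
  if (length(x) != length(y) || length(x) != length(covariate)) {
    stop("x, y and covariate must have equal length")
  }
  keep <- complete.cases(x, y, covariate)
  x <- x[keep]; y <- y[keep]; z <- covariate[keep]
  n <- length(x)
  if (n < 5L) stop("partial Spearman requires at least 5 complete triples")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: constant x or y")
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (sd(rz) == 0) {
    r <- cor(rx, ry)
    df <- n - 2L
  } else {
    rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
    denom <- sqrt((1 - rxz^2) * (1 - ryz^2))
    if (denom == 0) stop("correlation undefined: covariate collinear with x or y")
    r <- (rxy - rxz * ryz) / denom
    df <- n - 3L
  }
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  }
  list(r = r, p = p, n = n)
}

CLINICAL_SCALES <- c("edss", "msfc", "nhpt_s", "t25w_s", "pasat",
                     "mfis_total", "mfis_physical", "mfis_cognitive",
                     "mfis_psychosocial")

MOTOR_FEATURES <- c("rate_sv", "rate_mv", "td_hz2", "iti_hz2", "ihi")

#' Motor-parameter / clinical-scale correlation grid
#'
#' Age-adjusted partial Spearman correlations between each motor performance
#' parameter and each clinical scale, restricted to the MS group
#' (pairwise-complete). Cells with fewer than 5 complete triples are marked
#' unavailable. Significance is flagged at unadjusted p < 0.05; no
#' multiplicity correction is applied (flagged in the output attribute
#' `note`).
#'
#' @param features wide per-subject feature table ([params_wide()], single
#'   session) for MS subjects.
#' @param cohort cohort table with clinical columns and `age`.
#' @param scales clinical columns to include.
#' @return data.frame with one row per parameter-scale pair: `parameter,
#'   scale, r, p, n, significant, available`.
#' @export
correlation_table <- function(features, cohort,
                              scales = CLINICAL_SCALES) {
  cohort <- as.data.frame(cohort)
  ms <- cohort[cohort$group == "MS", , drop = FALSE]
  features <- as.data.frame(features)
  dup <- setdiff(intersect(names(features), names(ms)), "subject_id")
  features[dup] <- NULL
  d <- merge(features, ms, by = "subject_id")
  rows <- list()
  for (par in MOTOR_FEATURES) {
    for (sc in scales) {
      keep <- complete.cases(d[[par]], d[[sc]], d$age)
      if (sum(keep) < 5L) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = par, scale = sc, r = NA_real_, p = NA_real_,
          n = sum(keep), significant = NA, available = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      pc <- partial_spearman(d[[par]], d[[sc]], d$age)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, scale = sc, r = pc$r, p = pc$p, n = pc$n,
        significant = pc$p < 0.05, available = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "note") <-
    "unadjusted p values; no multiple-testing correction applied"
  out
}

#' Group comparison table
#'
#' Mann-Whitney comparison of each motor parameter between HC and MS, with
#' per-group mean and SEM.
#'
#' @param features wide per-subject feature table ([params_wide()]).
#' @param cohort cohort table supplying the `group` column.
#' @return data.frame, one row per parameter.
#' @export
group_comparison <- function(features, cohort) {
  features <- as.data.frame(features)
  features$group <- NULL
  d <- merge(features, as.data.frame(cohort)[, c("subject_id", "group")],
             by = "subject_id")
  rows <- lapply(MOTOR_FEATURES, function(par) {
    hc <- d[[par]][d$group == "HC"]
    ms <- d[[par]][d$group == "MS"]
    hc <- hc[!is.na(hc)]; ms <- ms[!is.na(ms)]
    mw <- mann_whitney(hc, ms)
    data.frame(parameter = par, label = unname(PARAM_LABELS[par]),
               mean_hc = mw$mean_a, sem_hc = mw$sem_a, n_hc = mw$n1,
               mean_ms = mw$mean_b, sem_ms = mw$sem_b, n_ms = mw$n2,
               u = mw$u, p = mw$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

EDSS_STRATA_LEVELS <- c("HC", "EDSS 0", "EDSS 1-2", "EDSS 2.5-4", "EDSS >4")

#' Assign disability strata
#'
#' HC form their own stratum; MS subjects are binned on EDSS as `{0}`,
#' `[1, 2]`, `[2.5, 4]`, `(4, 7]`. MS subjects whose EDSS falls outside those
#' bins (e.g. 0.5) or is missing get `NA`.
#'
#' @param group character vector, `"HC"`/`"MS"`.
#' @param edss numeric EDSS (NA for HC).
#' @return Ordered factor with levels HC < EDSS 0 < 1-2 < 2.5-4 < >4.
#' @export
edss_strata <- function(group, edss) {
  out <- rep(NA_character_, length(group))
  out[group == "HC"] <- "HC"
  ms <- group == "MS" & !is.na(edss)
  out[ms & edss == 0] <- "EDSS 0"
  out[ms & edss >= 1 & edss <= 2] <- "EDSS 1-2"
  out[ms & edss >= 2.5 & edss <= 4] <- "EDSS 2.5-4"
  out[ms & edss > 4] <- "EDSS >4"
  factor(out, levels = EDSS_STRATA_LEVELS, ordered = TRUE)
}

#' Linear trend across ordered disability strata
#'
#' One-way ANOVA across the ordered strata with a linear contrast over
#' equally spaced stratum scores (0, 1, 2, ...), plus pairwise comparisons of
#' each MS stratum against HC using the pooled ANOVA error (unadjusted for
#' multiplicity). Empty strata are dropped with a warning; with two strata
#' the trend reduces to a two-sample contrast.
#'
#' @param scores numeric outcome (e.g. the finger motor impairment score).
#' @param strata ordered factor from [edss_strata()].
#' @return List with `strata` (per-stratum n, mean, sem), `trend_p`
#'   (two-sided), `trend_estimate`, and `pairwise_vs_first` (data.frame).
#' @export
edss_strata_trend <- function(scores, strata) {
  keep <- !is.na(scores) & !is.na(strata)
  scores <- scores[keep]; strata <- droplevels(strata[keep])
  lv <- levels(strata)
  counts <- table(strata)
  if (any(counts == 0)) {
    warning("empty stratum(s) dropped: ",
            paste(lv[counts == 0], collapse = ", "))
    strata <- droplevels(strata)
    lv <- levels(strata)
    counts <- table(strata)
  }
  j <- length(lv)
  if (j < 2L) stop("at least 2 non-empty strata are required")
  nn <- as.numeric(counts)
  means <- tapply(scores, strata, mean)
  sds <- tapply(scores, strata, sd)
  n_total <- length(scores)
  ss_within <- sum((nn - 1) * ifelse(is.na(sds), 0, sds)^2)
  df_err <- n_total - j
  if (df_err <= 0) stop("no residual degrees of freedom for the trend test")
  mse <- ss_within / df_err
  w <- seq_len(j) - 1
  w <- w - mean(w)  # centered equally spaced scores
  est <- sum(w * means)
  se <- sqrt(mse * sum(w^2 / nn))
  tstat <- est / se
  trend_p <- 2 * pt(-abs(tstat), df_err)
  pairwise <- NULL
  if (j > 1L) {
    ref <- 1L
    pw <- lapply(seq.int(2L, j), function(s) {
      diff <- means[s] - means[ref]
      se_d <- sqrt(mse * (1 / nn[s] + 1 / nn[ref]))
      t_d <- diff / se_d
      data.frame(stratum = lv[s], reference = lv[ref], diff = unname(diff),
                 p = 2 * pt(-abs(t_d), df_err), stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, c(pw, list(make.row.names = FALSE)))
  }
  list(
    strata = data.frame(stratum = lv, n = nn, mean = as.numeric(means),
                        sem = as.numeric(sds) / sqrt(nn),
                        stringsAsFactors = FALSE),
    trend_estimate = est, trend_t = tstat, trend_df = df_err,
    trend_p = trend_p, pairwise_vs_first = pairwise
  )
}
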