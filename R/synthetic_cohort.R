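# Synthetic cohort generator.
#
# World model: each subject carries stable latent motor traits (spontaneous
# and maximal movement rate; paced touch duration and inter-tap gap; a signed
# inter-hand asynchrony scale sigma). Observed per-session values add a
# between-session random effect so that the TOTAL cross-sectional law matches
# the configured group mean/SD while single-measure test-retest ICCs match
# the configured between/within split. Clinical covariates are linked to the
# latent traits through a Gaussian copula whose targets are OBSERVED-scale
# Spearman correlations; the latent correlation is calibrated for (a)
# measurement attenuation (factor sqrt(ICC)) and (b) EDSS half-point
# discretization (numeric-integration solve).
#
# Signed inter-hand asynchrony is zero-mean Gaussian per cycle, so the
# extracted IHI (mean |delta|) is half-normal with mean sigma * sqrt(2/pi).

`%||%` <- function(a, b) if (is.null(a)) b else a

MOTOR_TRAITS <- c("rate_sv", "rate_mv", "td_hz2", "iti_hz2", "ihi")

#' Default simulation profile
#'
#' Group distributions are parameterized from the published group means and
#' SEMs (SEM scaled to SD by the square root of the group size: 80 HC, 40
#' MS); the between/within variance split uses the published single-measure
#' ICCs; clinical covariate marginals and the copula rank-correlation targets
#' follow the published cohort description and correlation grid (significant
#' cells; plausible clinical-scale inter-correlations close the matrix).
#'
#' @param n_hc,n_ms group sizes for the discrimination cohort.
#' @param n_retest_hc healthy controls in the two-session reliability
#'   sub-study.
#' @return A nested configuration list (class `sim_config`).
#' @export
paper_defaults <- function(n_hc = 80, n_ms = 40, n_retest_hc = 27) {
  edss_grid <- seq(0, 7, by = 0.5)
  edss_probs <- c(0.12, 0.00, 0.12, 0.13, 0.15, 0.10, 0.08, 0.07,
                  0.06, 0.05, 0.04, 0.03, 0.03, 0.01, 0.01)
  names(edss_probs) <- edss_grid
  cop <- rbind(
    # motor trait vs clinical scale (observed-scale Spearman targets)
    c("rate_mv", "edss", -0.39),
    c("rate_mv", "msfc", 0.47),
    c("rate_mv", "nhpt_s", -0.45),
    c("rate_mv", "mfis_physical", -0.38),
    c("td_hz2", "msfc", -0.40),
    c("td_hz2", "nhpt_s", 0.45),
    c("iti_hz2", "nhpt_s", -0.37),
    c("ihi", "edss", 0.56),
    c("ihi", "msfc", -0.40),
    c("ihi", "pasat", -0.38),
    # clinical-scale block (plausible values; keeps the matrix coherent)
    c("edss", "msfc", -0.65),
    c("edss", "nhpt_s", 0.45),
    c("edss", "t25w_s", 0.60),
    c("edss", "pasat", -0.30),
    c("edss", "mfis_physical", 0.30),
    c("edss", "age", 0.15),
    c("msfc", "nhpt_s", -0.70),
    c("msfc", "t25w_s", -0.65),
    c("msfc", "pasat", 0.60),
    c("nhpt_s", "t25w_s", 0.40),
    c("nhpt_s", "pasat", -0.30),
    c("pasat", "mfis_cognitive", -0.30),
    c("mfis_physical", "mfis_cognitive", 0.45),
    c("mfis_physical", "mfis_psychosocial", 0.45),
    c("mfis_cognitive", "mfis_psychosocial", 0.45)
  )
  copula <- data.frame(var1 = cop[, 1], var2 = cop[, 2],
                       spearman = as.numeric(cop[, 3]),
                       stringsAsFactors = FALSE)
  structure(list(
    n_hc = n_hc, n_ms = n_ms, n_retest_hc = n_retest_hc,
    groups = list(
      HC = list(
        rate_sv = c(mean = 2.40, sd = 0.05 * sqrt(80)),
        rate_mv = c(mean = 3.25, sd = 0.06 * sqrt(80)),
        td_hz2 = c(mean = 213.82, sd = 4.68 * sqrt(80)),
        iti_hz2 = c(mean = 279.63, sd = 5.10 * sqrt(80)),
        ihi = c(mean = 18.87, sd = 0.87 * sqrt(80)),
        age = c(mean = 41, sd = 10),
        p_female = 0.61
      ),
      MS = list(
        rate_sv = c(mean = 1.93, sd = 0.09 * sqrt(40)),
        rate_mv = c(mean = 2.67, sd = 0.10 * sqrt(40)),
        td_hz2 = c(mean = 246.67, sd = 10.30 * sqrt(40)),
        iti_hz2 = c(mean = 269.24, sd = 10.92 * sqrt(40)),
        ihi = c(mean = 41.92, sd = 4.48 * sqrt(40)),
        age = c(mean = 42, sd = 9),
        p_female = 0.67,
        edss_probs = edss_probs,
        disease_duration_months = c(meanlog = log(132), sdlog = 0.85),
        msfc = c(mean = -0.71, sd = 1.4),
        nhpt_s = c(mean = 24, sd = 9),
        t25w_s = c(mean = 6.5, sd = 3.0),
        pasat = c(mean = 44, sd = 10),
        mfis_physical = c(mean = 13.5, sd = 7),
        mfis_cognitive = c(mean = 10, sd = 6.5),
        mfis_psychosocial = c(mean = 3.3, sd = 2.2)
      )
    ),
    # single-measure ICC targets: between-subject variance share of the total
    icc_split = c(rate_sv = 0.46, rate_mv = 0.71, td_hz2 = 0.53,
                  iti_hz2 = 0.39, ihi = 0.75),
    trial = list(duration = 60000, tone_period = 500, td_frac = 0.433,
                 cycle_jitter_sd = 25, td_jitter_sd = 12,
                 tone_jitter_sd = 20),
    copula = copula
  ), class = "sim_config")
}

# ---- copula calibration ------------------------------------------------

# Expected sample Spearman (midrank) correlation between a continuous
# variable and a discretized one when their normal scores are bivariate
# normal with correlation rho. probs: category probabilities of the discrete
# margin. Uses E[Phi(Z1) | Z2 = z] = Phi(rho * z / sqrt(2 - rho^2)).
.spearman_mixed <- function(rho, probs) {
  probs <- probs[probs > 0]
  cum <- cumsum(probs)
  cuts <- qnorm(c(0, cum))
  cuts[1] <- -9; cuts[length(cuts)] <- 9
  grade <- c(0, head(cum, -1)) + probs / 2  # midrank CDF per category
  scale <- rho / sqrt(2 - rho^2)
  e_fg <- 0
  for (k in seq_along(probs)) {
    ik <- integrate(function(z) dnorm(z) * pnorm(scale * z),
                    cuts[k], cuts[k + 1], rel.tol = 1e-9)$value
    e_fg <- e_fg + grade[k] * ik
  }
  var_g <- sum(probs * grade^2) - 0.25
  (e_fg - 0.25) / sqrt(var_g / 12)
}

.solve_mixed_rho <- function(target, probs) {
  if (target == 0) return(0)
  f <- function(r) .spearman_mixed(r, probs) - target
  uniroot(f, c(-0.999, 0.999), tol = 1e-8)$root
}

# Completes a partially specified correlation matrix: cells named in the
# config are held fixed, free cells are filled by alternating projection
# between the PSD cone and the fixed-cell constraint. Deterministic.
.complete_corr <- function(target, fixed, max_iter = 500, floor_eig = 1e-3) {
  s <- target
  for (it in seq_len(max_iter)) {
    e <- eigen(s, symmetric = TRUE)
    if (min(e$values) >= 1e-8 && it > 1L) break
    s <- e$vectors %*% (pmax(e$values, floor_eig) * t(e$vectors))
    d <- sqrt(diag(s))
    s <- s / outer(d, d)
    s[fixed] <- target[fixed]
    s <- (s + t(s)) / 2
  }
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("configuration error: copula correlation targets are mutually ",
         "inconsistent (no positive semi-definite completion; min ",
         "eigenvalue ", format(min(ev)), ")")
  }
  dimnames(s) <- dimnames(target)
  s
}

# Latent-normal correlation matrix for the MS copula, calibrated so that the
# OBSERVED-scale Spearman correlations hit the configured targets.
.build_copula_sigma <- function(config) {
  vars <- c(MOTOR_TRAITS, "age", "edss", "msfc", "nhpt_s", "t25w_s",
            "pasat", "mfis_physical", "mfis_cognitive", "mfis_psychosocial")
  d <- length(vars)
  sigma <- diag(d)
  dimnames(sigma) <- list(vars, vars)
  fixed <- diag(d) == 1
  att <- setNames(rep(1, d), vars)
  att[MOTOR_TRAITS] <- sqrt(config$icc_split[MOTOR_TRAITS])
  probs <- config$groups$MS$edss_probs
  cp <- config$copula
  for (r in seq_len(nrow(cp))) {
    v1 <- cp$var1[r]; v2 <- cp$var2[r]; target <- cp$spearman[r]
    if (!v1 %in% vars || !v2 %in% vars) {
      stop("unknown copula variable: ", v1, " / ", v2)
    }
    rho <- if (v1 == "edss" || v2 == "edss") {
      other <- if (v1 == "edss") v2 else v1
      .solve_mixed_rho(target, probs) / att[other]
    } else {
      2 * sin(pi * target / 6) / (att[v1] * att[v2])
    }
    if (abs(rho) >= 1) {
      stop("copula target ", target, " for ", v1, "-", v2,
           " is unattainable after attenuation calibration (needs |rho| = ",
           round(abs(rho), 3), " >= 1)")
    }
    i1 <- match(v1, vars); i2 <- match(v2, vars)
    sigma[i1, i2] <- sigma[i2, i1] <- rho
    fixed[i1, i2] <- fixed[i2, i1] <- TRUE
  }
  .complete_corr(sigma, fixed)
}

.lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.draw_edss <- function(z, probs) {
  grid <- as.numeric(names(probs))
  cum <- cumsum(probs)
  idx <- findInterval(pnorm(z), c(0, cum), rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(grid)] <- length(grid)
  grid[idx]
}

#' Simulate latent subjects with clinical covariates
#'
#' Draws `n_hc + n_ms` subjects. MS clinical covariates and latent motor
#' traits are linked through the calibrated Gaussian copula; HC subjects have
#' independent traits and no clinical scores beyond age/sex. Reproducible
#' under a fixed RNG seed (`set.seed` before calling).
#'
#' @param config a `sim_config` (see [paper_defaults()]).
#' @return data.frame, one row per subject: identifiers, clinical covariates
#'   and `lat_*` latent trait columns (`lat_ihi_sigma` is the signed
#'   inter-hand asynchrony SD in ms).
#' @export
simulate_subjects <- function(config = paper_defaults()) {
  draw_group <- function(g, n, prefix) {
    if (n == 0L) return(NULL)
    gc <- config$groups[[g]]
    vars <- c(MOTOR_TRAITS, "age", "edss", "msfc", "nhpt_s", "t25w_s",
              "pasat", "mfis_physical", "mfis_cognitive", "mfis_psychosocial")
    if (g == "MS") {
      sigma <- .build_copula_sigma(config)
      z <- matrix(rnorm(n * length(vars)), n) %*% chol(sigma)
    } else {
      z <- matrix(rnorm(n * length(vars)), n)
    }
    colnames(z) <- vars
    lat <- function(p) {
      m <- gc[[p]][["mean"]]; s <- gc[[p]][["sd"]] * sqrt(config$icc_split[[p]])
      pmax(m + s * z[, p], 0.02 * m)
    }
    ihi_tot <- .lnorm_pars(gc$ihi[["mean"]], gc$ihi[["sd"]])
    mu_sigma <- ihi_tot[["meanlog"]] - log(sqrt(2 / pi))
    sd_b <- ihi_tot[["sdlog"]] * sqrt(config$icc_split[["ihi"]])
    out <- data.frame(
      subject_id = sprintf("%s%04d", prefix, seq_len(n)),
      group = g,
      age = round(pmax(gc$age[["mean"]] + gc$age[["sd"]] * z[, "age"], 18), 1),
      sex = ifelse(runif(n) < gc$p_female, "F", "M"),
      lat_rate_sv = lat("rate_sv"),
      lat_rate_mv = lat("rate_mv"),
      lat_td_hz2 = lat("td_hz2"),
      lat_iti_hz2 = lat("iti_hz2"),
      lat_ihi_sigma = exp(mu_sigma + sd_b * z[, "ihi"]),
      stringsAsFactors = FALSE
    )
    if (g == "MS") {
      nh <- .lnorm_pars(gc$nhpt_s[["mean"]], gc$nhpt_s[["sd"]])
      tw <- .lnorm_pars(gc$t25w_s[["mean"]], gc$t25w_s[["sd"]])
      out$edss <- .draw_edss(z[, "edss"], gc$edss_probs)
      out$disease_duration_months <- round(pmin(pmax(
        exp(gc$disease_duration_months[["meanlog"]] +
            gc$disease_duration_months[["sdlog"]] * rnorm(n)), 8), 528))
      out$msfc <- gc$msfc[["mean"]] + gc$msfc[["sd"]] * z[, "msfc"]
      out$nhpt_s <- qlnorm(pnorm(z[, "nhpt_s"]), nh[["meanlog"]], nh[["sdlog"]])
      out$t25w_s <- qlnorm(pnorm(z[, "t25w_s"]), tw[["meanlog"]], tw[["sdlog"]])
      out$pasat <- pmin(pmax(round(gc$pasat[["mean"]] +
                                   gc$pasat[["sd"]] * z[, "pasat"]), 0), 60)
      out$mfis_physical <- pmin(pmax(round(
        gc$mfis_physical[["mean"]] +
        gc$mfis_physical[["sd"]] * z[, "mfis_physical"]), 0), 36)
      out$mfis_cognitive <- pmin(pmax(round(
        gc$mfis_cognitive[["mean"]] +
        gc$mfis_cognitive[["sd"]] * z[, "mfis_cognitive"]), 0), 40)
      out$mfis_psychosocial <- pmin(pmax(round(
        gc$mfis_psychosocial[["mean"]] +
        gc$mfis_psychosocial[["sd"]] * z[, "mfis_psychosocial"]), 0), 8)
      out$mfis_total <- out$mfis_physical + out$mfis_cognitive +
        out$mfis_psychosocial
    } else {
      out$edss <- NA_real_
      out$disease_duration_months <- NA_real_
      out$msfc <- NA_real_
      out$nhpt_s <- NA_real_
      out$t25w_s <- NA_real_
      out$pasat <- NA_real_
      out$mfis_physical <- NA_real_
      out$mfis_cognitive <- NA_real_
      out$mfis_psychosocial <- NA_real_
      out$mfis_total <- NA_real_
    }
    out
  }
  rbind(draw_group("HC", config$n_hc, "HC"),
        draw_group("MS", config$n_ms, "MS"))
}

#' Extract the cohort metadata table from simulated subjects
#'
#' @param subjects output of [simulate_subjects()].
#' @return Validated cohort data.frame in the cohort-CSV column layout.
#' @export
subject_records <- function(subjects) {
  df <- subjects[, COHORT_COLUMNS]
  validate_cohort(df)
}

# per-session trait values: latent plus the between-session random effect
.session_traits <- function(subject, config, drift = TRUE) {
  g <- subject$group
  gc <- config$groups[[g]]
  icc <- config$icc_split
  w <- function(p) if (drift) gc[[p]][["sd"]] * sqrt(1 - icc[[p]]) else 0
  ihi_tot <- .lnorm_pars(gc$ihi[["mean"]], gc$ihi[["sd"]])
  sd_w_log <- if (drift) ihi_tot[["sdlog"]] * sqrt(1 - icc[["ihi"]]) else 0
  list(
    rate_sv = max(subject$lat_rate_sv + rnorm(1, 0, w("rate_sv")), 0.3),
    rate_mv = max(subject$lat_rate_mv + rnorm(1, 0, w("rate_mv")), 0.5),
    td_hz2 = max(subject$lat_td_hz2 + rnorm(1, 0, w("td_hz2")), 30),
    iti_hz2 = max(subject$lat_iti_hz2 + rnorm(1, 0, w("iti_hz2")), 10),
    ihi_sigma = exp(log(subject$lat_ihi_sigma) + rnorm(1, 0, sd_w_log))
  )
}

# clamp onsets to be strictly increasing (preserving cycle order), round to
# integer ms, clip contacts to the next onset and the trial end
.finalize_hand <- function(t_on, td, hand, duration) {
  n <- length(t_on)
  if (!n) return(NULL)
  t_on <- round(t_on)
  if (n > 1L) {
    for (i in 2:n) if (t_on[i] < t_on[i - 1] + 2) t_on[i] <- t_on[i - 1] + 2
  }
  t_off <- t_on + pmax(round(td), 1)
  if (n > 1L) t_off <- pmin(t_off, c(t_on[-1L], Inf))
  keep <- t_on >= 0 & t_off <= duration
  if (!any(keep)) return(NULL)
  data.frame(hand = hand, finger = rep(GLOVE_FINGERS, length.out = n)[keep],
             t_on = t_on[keep], t_off = t_off[keep],
             stringsAsFactors = FALSE)
}

#' Simulate one trial for a latent subject
#'
#' Self-paced conditions generate cycles of period `1000/rate` with lognormal
#' jitter; paced conditions lock onsets to the subject's own period lattice
#' (mean `TD + gap`, which need not equal the 500 ms metronome period — real
#' cohorts tap slightly fast) with Gaussian tone-locking jitter. The bimanual
#' condition adds left-hand onsets offset from the right hand by a signed
#' zero-mean Gaussian asynchrony with the subject's session-specific scale,
#' so the extracted IHI has expectation `sigma * sqrt(2/pi)`.
#'
#' @param subject one row of [simulate_subjects()] output (data.frame or
#'   list).
#' @param condition `"SV"`, `"MV"`, `"2HZ"` or `"2HZ_BIM"`.
#' @param session session index (>= 1); each call draws an independent
#'   between-session random effect when `drift = TRUE`.
#' @param config a `sim_config`.
#' @param drift include the between-session random effect (default TRUE).
#' @return A validated [glove_trial()]. Warns and returns an empty-event
#'   trial when the duration is shorter than one cycle.
#' @export
simulate_trial <- function(subject, condition, session = 1L,
                           config = paper_defaults(), drift = TRUE) {
  stopifnot(condition %in% GLOVE_CONDITIONS)
  subject <- as.list(subject)
  tc <- config$trial
  duration <- tc$duration
  tr <- .session_traits(subject, config, drift = drift)
  tones <- integer()
  if (condition %in% c("SV", "MV")) {
    rate <- if (condition == "SV") tr$rate_sv else tr$rate_mv
    period <- 1000 / rate
    td_mean <- tc$td_frac * period
    n_max <- ceiling(duration / period) + 5L
    jit <- if (tc$cycle_jitter_sd > 0) {
      sdlog <- sqrt(log(1 + (tc$cycle_jitter_sd / period)^2))
      rlnorm(n_max, -sdlog^2 / 2, sdlog)
    } else rep(1, n_max)
    t_on <- cumsum(c(0, period * jit))[seq_len(n_max)]
    td <- td_mean + if (tc$td_jitter_sd > 0) {
      rnorm(n_max, 0, tc$td_jitter_sd)
    } else 0
    ev <- .finalize_hand(t_on, pmax(td, 5), "R", duration)
  } else {
    tones <- as.integer(seq(tc$tone_period, max(duration, tc$tone_period),
                            by = tc$tone_period))
    period <- tr$td_hz2 + tr$iti_hz2
    n_max <- max(ceiling((duration - tc$tone_period) / period) + 2L, 1L)
    k <- seq_len(n_max) - 1L
    eps <- if (tc$tone_jitter_sd > 0) rnorm(n_max, 0, tc$tone_jitter_sd) else 0
    t_on_r <- tc$tone_period + k * period + eps
    td_r <- tr$td_hz2 + if (tc$td_jitter_sd > 0) {
      rnorm(n_max, 0, tc$td_jitter_sd)
    } else 0
    td_r <- pmax(pmin(td_r, period - 10), 5)
    ev <- .finalize_hand(t_on_r, td_r, "R", duration)
    if (condition == "2HZ_BIM") {
      delta <- rnorm(n_max, 0, tr$ihi_sigma)
      td_l <- tr$td_hz2 + if (tc$td_jitter_sd > 0) {
        rnorm(n_max, 0, tc$td_jitter_sd)
      } else 0
      td_l <- pmax(pmin(td_l, period - 10), 5)
      ev_l <- .finalize_hand(t_on_r + delta, td_l, "L", duration)
      ev <- rbind(ev, ev_l)
    }
  }
  if (is.null(ev) || !nrow(ev)) {
    warning("duration shorter than one cycle: empty trial for subject ",
            subject$subject_id, " condition ", condition)
    ev <- data.frame(hand = character(), finger = integer(),
                     t_on = integer(), t_off = integer())
  }
  glove_trial(
    trial_id = sprintf("%s_s%d_%s", subject$subject_id, session, condition),
    subject_id = subject$subject_id, session = session,
    condition = condition, events = ev, tones = tones, duration = duration
  )
}

#' Simulate a full cohort of glove trials
#'
#' One trial per subject, condition and session. With `dir` set, the cohort
#' table, combined event and tone CSVs and a JSON manifest are written
#' through the package's I/O layer; otherwise everything is returned in
#' memory. Fixing the RNG seed before the call fixes every output byte.
#'
#' @param config a `sim_config`.
#' @param sessions number of sessions per subject (default 1; use 2 for a
#'   test-retest design).
#' @param conditions conditions to simulate (default all four).
#' @param dir optional output directory.
#' @param subjects optionally reuse a previous [simulate_subjects()] draw.
#' @param provenance optional provenance header lines for written files.
#' @return List with `subjects`, `cohort` (metadata table), `trials` (list of
#'   [glove_trial()]), and `files` (manifest, when `dir` is set).
#' @export
simulate_cohort <- function(config = paper_defaults(), sessions = 1L,
                            conditions = GLOVE_CONDITIONS, dir = NULL,
                            subjects = NULL, provenance = NULL) {
  subjects <- subjects %||% simulate_subjects(config)
  trials <- vector("list", nrow(subjects) * sessions * length(conditions))
  idx <- 0L
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, , drop = FALSE]
    for (s in seq_len(sessions)) {
      for (cond in conditions) {
        idx <- idx + 1L
        trials[[idx]] <- simulate_trial(subj, cond, session = s,
                                        config = config)
      }
    }
  }
  names(trials) <- vapply(trials, `[[`, "", "trial_id")
  cohort <- subject_records(subjects)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      cohort = file.path(dir, "cohort.csv"),
      events = file.path(dir, "events.csv"),
      tones = file.path(dir, "tones.csv"),
      manifest = file.path(dir, "manifest.json")
    )
    write_cohort(cohort, files$cohort, provenance)
    write_trials(trials, files$events, files$tones, provenance)
    jsonlite::write_json(
      list(n_subjects = nrow(subjects), sessions = sessions,
           conditions = conditions, n_trials = length(trials),
           files = lapply(files[c("cohort", "events", "tones")], basename)),
      files$manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  list(subjects = subjects, cohort = cohort, trials = trials, files = files)
}

#' Desk-scale feature-level cohort draw
#'
#' Draws per-subject motor features directly from the configured group
#' cross-sectional laws, skipping event-stream simulation: Gaussian rates /
#' touch durations / gaps and a mean/SD-matched lognormal inter-hand
#' interval. Used for fast distribution-matched discrimination checks.
#'
#' @param n_hc,n_ms group sizes.
#' @param config a `sim_config` supplying the group laws.
#' @return data.frame: `subject_id, group, age, rate_sv, rate_mv, td_hz2,
#'   iti_hz2, ihi, log_ihi`.
#' @export
simulate_feature_cohort <- function(n_hc, n_ms, config = paper_defaults()) {
  draw <- function(g, n, prefix) {
    gc <- config$groups[[g]]
    ln <- .lnorm_pars(gc$ihi[["mean"]], gc$ihi[["sd"]])
    data.frame(
      subject_id = sprintf("%s%04d", prefix, seq_len(n)),
      group = g,
      age = round(pmax(gc$age[["mean"]] + gc$age[["sd"]] * rnorm(n), 18), 1),
      rate_sv = pmax(rnorm(n, gc$rate_sv[["mean"]], gc$rate_sv[["sd"]]), 0.3),
      rate_mv = pmax(rnorm(n, gc$rate_mv[["mean"]], gc$rate_mv[["sd"]]), 0.5),
      td_hz2 = pmax(rnorm(n, gc$td_hz2[["mean"]], gc$td_hz2[["sd"]]), 30),
      iti_hz2 = pmax(rnorm(n, gc$iti_hz2[["mean"]], gc$iti_hz2[["sd"]]), 10),
      ihi = rlnorm(n, ln[["meanlog"]], ln[["sdlog"]]),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(draw("HC", n_hc, "HC"), draw("MS", n_ms, "MS"))
  out$log_ihi <- log(out$ihi)
  out
}
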