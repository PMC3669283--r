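# Shared fixtures and independent oracles, built in code.

# Deterministic noise-free trial: regular cycle of `period` ms, contact time
# `td`, fingers cycling 2..5, starting at t = 0.
make_regular_trial <- function(n_touches = 120, td = 250, period = 500,
                               condition = "SV", hand = "R",
                               subject_id = "S1", session = 1,
                               duration = 60000, offset = 0) {
  t_on <- offset + (seq_len(n_touches) - 1) * period
  events <- data.frame(
    hand = hand,
    finger = rep(2:5, length.out = n_touches),
    t_on = t_on, t_off = t_on + td
  )
  tones <- if (condition %in% c("2HZ", "2HZ_BIM")) {
    seq(500, duration, by = 500)
  } else integer()
  glove_trial(paste0(subject_id, "_", condition), subject_id, session,
              condition, events, tones = tones, duration = duration)
}

# Bimanual trial with explicit signed left-right onset asynchronies.
make_bimanual_trial <- function(deltas, td = 200, period = 500,
                                subject_id = "S1") {
  n <- length(deltas)
  t_r <- 500 + (seq_len(n) - 1) * period
  fingers <- rep(2:5, length.out = n)
  events <- rbind(
    data.frame(hand = "R", finger = fingers, t_on = t_r, t_off = t_r + td),
    data.frame(hand = "L", finger = fingers, t_on = t_r + deltas,
               t_off = t_r + deltas + td)
  )
  glove_trial(paste0(subject_id, "_bim"), subject_id, 1, "2HZ_BIM", events,
              tones = seq(500, 60000, by = 500), duration = 60000)
}

# A small noise-reduced simulation profile for fast structural tests.
small_config <- function(n_hc = 6, n_ms = 4) {
  cfg <- paper_defaults(n_hc = n_hc, n_ms = n_ms, n_retest_hc = 0)
  cfg
}

# Independent ICC(A,1)/ICC(A,k) oracle via R's aov() mean squares.
icc_oracle_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(n), k)),
    sess = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subj + sess, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["sess", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  c(single = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    average = (msr - mse) / (msr + (msc - mse) / n))
}

# Exhaustive pair-counting AUC oracle (ties count 1/2).
auc_oracle_pairs <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# Partial Spearman oracle: residualize ranks on the ranked covariate.
partial_spearman_oracle <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::resid(stats::lm(rx ~ rz))
  ey <- stats::resid(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

# Table 1 printed values (session means/SDs, SRD, SRD%, ICC single/average).
table1 <- data.frame(
  parameter = c("rate_sv", "rate_mv", "td_hz2", "iti_hz2", "log_ihi"),
  mean_s1 = c(1.97, 2.86, 222.8, 274.9, 3.03),
  sd_s1 = c(0.29, 0.48, 37.0, 37.0, 0.45),
  mean_s2 = c(2.26, 2.98, 217.2, 293.2, 2.97),
  sd_s2 = c(0.33, 0.45, 29.4, 55.1, 0.42),
  srd = c(0.51, 0.69, 63.8, 100.1, 0.61),
  srd_pct = c(24, 24, 29, 35, 20),
  icc_single = c(0.46, 0.71, 0.53, 0.39, 0.75),
  icc_average = c(0.63, 0.83, 0.69, 0.55, 0.86)
)
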