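test_that("fixed seed fixes every output byte", {
  run <- function() {
    set.seed(801)
    d <- withr::local_tempdir()
    sim <- simulate_cohort(small_config(), dir = d)
    list(subjects = sim$subjects,
         bytes = lapply(list.files(d, full.names = TRUE), readLines))
  }
  a <- run(); b <- run()
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$bytes, b$bytes)
})

test_that("noise-free self-paced trial is exactly periodic", {
  cfg <- paper_defaults()
  cfg$trial$cycle_jitter_sd <- 0
  cfg$trial$td_jitter_sd <- 0
  cfg$trial$td_frac <- 0.5
  subj <- list(subject_id = "NF", group = "HC", lat_rate_sv = 2,
               lat_rate_mv = 3, lat_td_hz2 = 250, lat_iti_hz2 = 250,
               lat_ihi_sigma = 10)
  tr <- simulate_trial(subj, "SV", config = cfg, drift = FALSE)
  expect_equal(nrow(tr$events), 120L)
  expect_true(all(touch_durations(tr) == 250))
  expect_true(all(inter_tap_intervals(tr) == 250))
  s <- summarize_trial(tr)
  expect_equal(s$rate, 2.0)
})

test_that("zero asynchrony gives identical hands and IHI 0", {
  cfg <- paper_defaults()
  subj <- list(subject_id = "Z", group = "HC", lat_rate_sv = 2,
               lat_rate_mv = 3, lat_td_hz2 = 214, lat_iti_hz2 = 280,
               lat_ihi_sigma = 1e-9)
  set.seed(802)
  tr <- simulate_trial(subj, "2HZ_BIM", config = cfg, drift = FALSE)
  expect_equal(summarize_trial(tr)$ihi, 0)
  ev_l <- tr$events[tr$events$hand == "L", ]
  ev_r <- tr$events[tr$events$hand == "R", ]
  expect_equal(ev_l$t_on, ev_r$t_on)
})

test_that("half-normal identity: mean |asynchrony| = sigma * sqrt(2/pi)", {
  cfg <- paper_defaults()
  subj <- list(subject_id = "H", group = "HC", lat_rate_sv = 2,
               lat_rate_mv = 3, lat_td_hz2 = 214, lat_iti_hz2 = 280,
               lat_ihi_sigma = 23.65)
  set.seed(803)
  ihis <- replicate(60, summarize_trial(
    simulate_trial(subj, "2HZ_BIM", config = cfg, drift = FALSE))$ihi)
  # E[IHI] = 23.65 * sqrt(2/pi) = 18.87; MC SE ~ 0.17 at 60 trials x ~119 pairs
  expect_lt(abs(mean(ihis) - 18.87), 0.7)
})

test_that("paced trials carry ~2 Hz tones and ~120 touches", {
  set.seed(804)
  cfg <- paper_defaults()
  subjects <- simulate_subjects(paper_defaults(n_hc = 2, n_ms = 2))
  for (i in seq_len(4)) {
    tr <- simulate_trial(subjects[i, ], "2HZ", config = cfg)
    expect_equal(median(diff(tr$tones)), 500)
    expect_gt(sum(tr$events$hand == "R"), 90)
    expect_lt(sum(tr$events$hand == "R"), 150)
  }
})

test_that("independence copula leaves the asynchrony trait unlinked to EDSS", {
  cfg <- paper_defaults(n_hc = 0, n_ms = 200)
  cfg$copula <- cfg$copula[0, ]  # drop every dependence target
  set.seed(805)
  s <- simulate_subjects(cfg)
  expect_lt(abs(cor(rank(s$lat_ihi_sigma), rank(s$edss))), 0.15)
})

test_that("copula calibration recovers its internal latent target at n=2000", {
  cfg <- paper_defaults(n_hc = 0, n_ms = 2000)
  sigma <- glovekin:::.build_copula_sigma(cfg)
  # expected latent-trait/EDSS Spearman from the calibrated latent rho
  expected <- glovekin:::.spearman_mixed(sigma["ihi", "edss"],
                                         cfg$groups$MS$edss_probs)
  set.seed(806)
  s <- simulate_subjects(cfg)
  got <- cor(rank(s$lat_ihi_sigma), rank(s$edss))
  expect_lt(abs(got - expected), 0.05)
})

test_that("configuration errors are raised for invalid copulas", {
  cfg <- paper_defaults()
  cfg$copula <- rbind(cfg$copula,
                      data.frame(var1 = "rate_sv", var2 = "bogus",
                                 spearman = 0.5))
  expect_error(simulate_subjects(cfg), "unknown copula variable")
  cfg2 <- paper_defaults()
  # after sqrt(ICC) attenuation this target needs |rho| >= 1
  cfg2$copula <- rbind(cfg2$copula,
                       data.frame(var1 = "iti_hz2", var2 = "msfc",
                                  spearman = -0.75))
  expect_error(simulate_subjects(cfg2), "unattainable")
})

test_that("cohort sizes follow the requested design", {
  set.seed(807)
  rel <- simulate_cohort(paper_defaults(n_hc = 27, n_ms = 0), sessions = 2)
  expect_length(rel$trials, 27 * 4 * 2)
  set.seed(808)
  main <- simulate_cohort(small_config(n_hc = 8, n_ms = 4))
  expect_length(main$trials, 12 * 4)
  expect_equal(sum(main$cohort$group == "MS"), 4)
  expect_true(all(is.na(main$cohort$edss[main$cohort$group == "HC"])))
  ms_edss <- main$cohort$edss[main$cohort$group == "MS"]
  expect_true(all(ms_edss >= 0 & ms_edss <= 7))
})

test_that("generated trials always pass validation round-trips", {
  set.seed(809)
  sim <- simulate_cohort(small_config(n_hc = 3, n_ms = 3))
  for (tr in sim$trials) {
    ev <- tr$events
    for (h in unique(ev$hand)) {
      e <- ev[ev$hand == h, ]
      expect_true(all(e$t_off > e$t_on))
      if (nrow(e) > 1) expect_true(all(e$t_on[-1] >= e$t_off[-nrow(e)]))
    }
    # reconstruction through the validating constructor succeeds
    expect_s3_class(
      glove_trial(tr$trial_id, tr$subject_id, tr$session, tr$condition,
                  tr$events, tr$tones, tr$duration),
      "glove_trial")
  }
})

test_that("desk-scale feature cohort matches the configured laws", {
  set.seed(810)
  d <- simulate_feature_cohort(4000, 4000)
  cfg <- paper_defaults()
  hc <- d[d$group == "HC", ]; ms <- d[d$group == "MS", ]
  expect_lt(abs(mean(hc$rate_sv) - 2.40), 0.03)
  expect_lt(abs(sd(hc$rate_sv) - cfg$groups$HC$rate_sv[["sd"]]), 0.03)
  expect_lt(abs(mean(ms$ihi) - 41.92), 1.5)
  expect_lt(abs(sd(ms$ihi) - cfg$groups$MS$ihi[["sd"]]), 1.5)
  expect_equal(d$log_ihi, log(d$ihi))
})

test_that("too-short trials warn and come back empty", {
  cfg <- paper_defaults()
  cfg$trial$duration <- 300
  subj <- list(subject_id = "T", group = "HC", lat_rate_sv = 2,
               lat_rate_mv = 3, lat_td_hz2 = 250, lat_iti_hz2 = 250,
               lat_ihi_sigma = 10)
  expect_warning(tr <- simulate_trial(subj, "2HZ", config = cfg,
                                      drift = FALSE),
                 "shorter than one cycle")
  expect_equal(nrow(tr$events), 0L)
})
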