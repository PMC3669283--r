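test_that("trial construction validates and sorts events", {
  tr <- glove_trial("t1", "s1", 1, "SV",
                    data.frame(hand = c("R", "R"), finger = c(3, 2),
                               t_on = c(400, 0), t_off = c(650, 250)))
  expect_s3_class(tr, "glove_trial")
  expect_equal(tr$events$t_on, c(0L, 400L))
  expect_equal(tr$events$finger, c(2L, 3L))

  expect_error(
    glove_trial("t1", "s1", 1, "SV",
                data.frame(hand = "R", finger = 2, t_on = 500, t_off = 400)),
    "t_off must exceed t_on.*1")
  expect_error(
    glove_trial("t1", "s1", 1, "SV",
                data.frame(hand = "R", finger = 2, t_on = 0.5, t_off = 250)),
    "integer milliseconds")
  expect_error(
    glove_trial("t1", "s1", 1, "SV",
                data.frame(hand = "R", finger = 6, t_on = 0, t_off = 250)),
    "finger")
  expect_error(
    glove_trial("t1", "s1", 1, "SV",
                data.frame(hand = "L", finger = 2, t_on = 0, t_off = 250)),
    "unimanual")
  expect_error(
    glove_trial("t1", "s1", 1, "2HZ",
                data.frame(hand = "R", finger = 2, t_on = 0, t_off = 250)),
    "tone track")
  expect_error(
    glove_trial("t1", "s1", 1, "SV",
                data.frame(hand = "R", finger = 2, t_on = 0, t_off = 250),
                tones = c(500, 1000)),
    "must not carry tones")
})

test_that("same-hand overlaps are rejected or conservatively repaired", {
  ev <- data.frame(hand = "R", finger = c(2, 3),
                   t_on = c(0, 246), t_off = c(250, 500))
  expect_error(glove_trial("t", "s", 1, "SV", ev), "overlapping")
  tr <- glove_trial("t", "s", 1, "SV", ev, repair = TRUE)
  expect_equal(tr$events$t_off[1], 246L)  # truncated to the next onset
  # same finger: merged into one contact
  ev2 <- data.frame(hand = "R", finger = c(2, 2),
                    t_on = c(0, 246), t_off = c(250, 500))
  tr2 <- glove_trial("t", "s", 1, "SV", ev2, repair = TRUE)
  expect_equal(nrow(tr2$events), 1L)
  expect_equal(tr2$events$t_off, 500L)
  # overlap beyond the repair threshold still rejected
  ev3 <- data.frame(hand = "R", finger = c(2, 3),
                    t_on = c(0, 200), t_off = c(250, 500))
  expect_error(glove_trial("t", "s", 1, "SV", ev3, repair = TRUE),
               "overlapping")
})

test_that("trial round-trip through CSV is exact for random trials", {
  set.seed(401)
  cfg <- small_config()
  subjects <- simulate_subjects(cfg)
  conds <- c("SV", "MV", "2HZ", "2HZ_BIM")
  for (i in 1:4) {
    tr <- simulate_trial(subjects[i, ], conds[i], config = cfg)
    ep <- withr::local_tempfile(fileext = ".csv")
    tp <- withr::local_tempfile(fileext = ".csv")
    write_trial(tr, ep, tones_path = tp,
                provenance = c("roundtrip check", "seed=401"))
    back <- read_trial(ep, tones_path = if (length(tr$tones)) tp else NULL)
    expect_identical(back$events, tr$events)
    expect_identical(back$tones, tr$tones)
    expect_identical(back$condition, tr$condition)
    expect_identical(back$subject_id, tr$subject_id)
    expect_identical(back$session, tr$session)
  }
})

test_that("batch trial I/O round-trips and rejects multi-trial read_trial", {
  set.seed(402)
  cfg <- small_config()
  sim <- simulate_cohort(cfg, conditions = c("SV", "2HZ_BIM"))
  ep <- withr::local_tempfile(fileext = ".csv")
  tp <- withr::local_tempfile(fileext = ".csv")
  write_trials(sim$trials, ep, tp)
  back <- read_trials(ep, tp)
  expect_setequal(names(back), names(sim$trials))
  for (id in names(back)) {
    expect_identical(back[[id]]$events, sim$trials[[id]]$events)
    expect_identical(back[[id]]$tones, sim$trials[[id]]$tones)
  }
  expect_error(read_trial(ep), "exactly one trial_id")
})

test_that("empty-events trial writes a header-only file", {
  tr <- glove_trial("t0", "s0", 1, "SV",
                    data.frame(hand = character(), finger = integer(),
                               t_on = integer(), t_off = integer()))
  ep <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, ep)
  lines <- readLines(ep)
  expect_length(lines, 1L)  # header only
  expect_match(lines, "trial_id,subject_id")
})

test_that("cohort validation enforces the invariants", {
  base <- data.frame(
    subject_id = c("a", "b", "c"), group = c("HC", "MS", "MS"),
    age = c(40, 42, 50), sex = c("F", "M", "F"),
    edss = c(NA, 2, 6.5), disease_duration_months = c(NA, 120, 300),
    msfc = c(NA, -0.5, -2), nhpt_s = c(NA, 21, 40), t25w_s = c(NA, 5, 12),
    pasat = c(NA, 50, 30), mfis_total = c(NA, 20, 45),
    mfis_physical = c(NA, 10, 25), mfis_cognitive = c(NA, 8, 16),
    mfis_psychosocial = c(NA, 2, 4)
  )
  ok <- validate_cohort(base)
  expect_equal(ok$group, c("HC", "MS", "MS"))

  bad <- base; bad$edss[2] <- 7.5
  expect_error(validate_cohort(bad), "half-point grid")
  bad <- base; bad$edss[2] <- 2.3
  expect_error(validate_cohort(bad), "half-point grid")
  bad <- base; bad$subject_id[2] <- "a"
  expect_error(validate_cohort(bad), "duplicate")
  bad <- base; bad$edss[1] <- 1
  expect_error(validate_cohort(bad), "absent for HC")

  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(base, p, provenance = "cohort roundtrip")
  back <- read_cohort(p)
  expect_equal(back$edss, base$edss)
  expect_equal(back$msfc, base$msfc)
  expect_equal(back$subject_id, base$subject_id)
})

test_that("the shipped demonstration trial loads and summarizes", {
  ep <- system.file("extdata", "example_trial_events.csv",
                    package = "glovekin")
  tp <- system.file("extdata", "example_trial_tones.csv",
                    package = "glovekin")
  tr <- read_trial(ep, tones_path = tp, duration = 5000)
  expect_equal(tr$condition, "2HZ_BIM")
  expect_equal(nrow(tr$events), 16L)
  s <- summarize_trial(tr)
  expect_equal(s$n_touches, 8L)
  expect_gt(s$ihi, 0)
})
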