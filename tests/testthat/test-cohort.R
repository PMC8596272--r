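# Cohort design, subject recordings, protocol structure, effect encoding.

test_that("default design encodes the intended orderings in its targets", {
  ht <- default_hurst_table()
  expect_identical(nrow(ht), 3L * 7L * 4L)
  expect_true(all(ht$hurst > 0 & ht$hurst < 1))
  rest <- ht[ht$state == "rest", ]
  h <- function(g, b) rest$hurst[rest$group == g & rest$band == b]
  # lower Hurst target = higher complexity
  expect_lt(h("severe_dai", "broadband"), h("control", "broadband"))
  expect_identical(h("control", "broadband"), h("mild_dai", "broadband"))
  expect_lt(h("control", "alpha"), h("mild_dai", "alpha"))
  expect_lt(h("mild_dai", "alpha"), h("severe_dai", "alpha"))
  # stimulus response: H drops (complexity rises) for control/mild,
  # rises (complexity falls) for severe
  for (st in setdiff(unique(ht$state), "rest")) {
    hb <- function(g) ht$hurst[ht$group == g & ht$state == st &
                                 ht$band == "broadband"]
    expect_lt(hb("control"), h("control", "broadband"))
    expect_lt(hb("mild_dai"), h("mild_dai", "broadband"))
    expect_gt(hb("severe_dai"), h("severe_dai", "broadband"))
  }
})

test_that("design validation rejects malformed inputs", {
  expect_error(cohort_design(n_subjects = c(control = 1, mild_dai = 1)),
               class = "fe_param_error")
  bad <- default_hurst_table(); bad$hurst[5L] <- 1.2
  expect_error(cohort_design(hurst_table = bad), class = "fe_param_error")
  bad2 <- default_hurst_table(); bad2 <- bad2[bad2$state != "rest", ]
  expect_error(cohort_design(hurst_table = bad2), class = "fe_param_error")
  expect_error(cohort_design(hemisphere_asymmetry = -0.1),
               class = "fe_param_error")
  d <- cohort_design()
  expect_error(gen_subject_recording("patients", d, 1L),
               class = "fe_param_error")
})

test_that("subject recordings implement the stimulus protocol", {
  design <- cohort_design()
  rec <- gen_subject_recording("control", design, 7L)
  fs <- design$fs
  # 90 s rest + 6 stimuli x 12 reps x (2 s gap + 10 s stimulus)
  expect_identical(nrow(rec$data), as.integer((90 + 72 * 12) * fs))
  expect_identical(ncol(rec$data), 19L)
  expect_identical(rec$channel_labels, channels_1020())
  expect_identical(rec$fs, 250)
  sch <- rec$schedule
  expect_identical(nrow(sch), 73L)
  expect_identical(sch$state[1L], "rest")
  expect_identical(sch$duration[1L], 90)
  counts <- table(sch$state[-1L])
  expect_true(all(counts == 12L))
  expect_identical(length(counts), 6L)
  # stimulus intervals all 10 s, non-overlapping with 2 s gaps
  expect_true(all(sch$duration[-1L] == 10))
  expect_true(all(diff(sch$onset[-1L]) == 12))
  # reproducibility
  expect_identical(rec$data, gen_subject_recording("control", design, 7L)$data)
  expect_false(identical(rec$data,
                         gen_subject_recording("control", design, 8L)$data))
})

test_that("cohorts are reproducible and sized per group", {
  d3 <- small_design()
  c1 <- gen_cohort(d3)
  c2 <- gen_cohort(d3)
  expect_identical(length(c1), 3L)
  expect_identical(vapply(c1, `[[`, "", "group"),
                   c("control", "mild_dai", "severe_dai"))
  expect_identical(c1[[2L]]$recording$data, c2[[2L]]$recording$data)
  # study-sized manifest without materializing 41 recordings
  d41 <- cohort_design(seed = 5L)
  man <- gen_cohort(d41, keep_signals = FALSE)
  expect_identical(length(man), 41L)
  expect_identical(sum(vapply(man, `[[`, "", "group") == "severe_dai"), 15L)
  expect_error(gen_cohort(cohort_design(
    n_subjects = c(control = 0, mild_dai = 1, severe_dai = 1))),
    class = "fe_param_error")
})

test_that("zero asymmetry gives a symmetric hemisphere contrast", {
  d <- small_design(n = c(control = 5, mild_dai = 5, severe_dai = 5),
                    hemisphere_asymmetry = 0, seed = 31L)
  tab <- hfd_table(d, bands = list(band_spec("broadband", 2, 20)))
  hc <- hemisphere_contrast(tab[tab$state != "rest", ])
  # contrasts fluctuate around zero at the estimator-noise scale
  expect_lt(abs(mean(hc$contrast)), 0.0015)
})

test_that("severe injury shows higher broadband rest complexity than control", {
  d <- small_design(n = c(control = 5, mild_dai = 1, severe_dai = 5),
                    seed = 17L)
  tab <- hfd_table(d, bands = list(band_spec("broadband", 2, 20)))
  rest <- tab[tab$state == "rest", ]
  m <- tapply(rest$hfd, rest$group, mean)
  expect_gt(m[["severe_dai"]], m[["control"]])
})
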