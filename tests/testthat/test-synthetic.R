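test_that("arm profiles validate their rates and sizes", {
  expect_error(arm_profile("A", 0, 200, rep(0.2, 4), rep(0.8, 4)), "n_videos")
  expect_error(arm_profile("A", 5, 4, rep(0.2, 4), rep(0.8, 4)),
               "frames_per_video")
  expect_error(arm_profile("A", 5, 200, c(0.2, 0.2, 0.2, 1.2), rep(0.8, 4)),
               "fractions")
})

test_that("extreme abundant rates plant every or no frame above the criterion", {
  p1 <- arm_profile("A", 1, 40, rep(1, 4), rep(0.5, 4))
  v1 <- generate_video(p1, 1, seed = 5)
  sb <- v1$frames$segment == "sb"
  expect_true(all(v1$frames$coverage[sb] >= 0.10))
  p0 <- arm_profile("A", 1, 40, rep(0, 4), rep(0.5, 4))
  v0 <- generate_video(p0, 1, seed = 5)
  sb <- v0$frames$segment == "sb"
  expect_true(all(v0$frames$coverage[sb] < 0.10))
})

test_that("video generation is deterministic and arm streams are independent", {
  p <- paper_study_profiles(frames_per_video = 24L)$smt_minus
  a <- generate_video(p, 3, seed = 9)
  b <- generate_video(p, 3, seed = 9)
  expect_identical(a, b)
  d <- generate_video(p, 4, seed = 9)
  expect_false(identical(a$frames$coverage, d$frames$coverage))
})

test_that("planted Q4 abundance converges to the configured arm rate", {
  # pool 10,000 Q4 small-bowel frames from the no-simethicone profile
  p <- paper_study_profiles(frames_per_video = 200L)$smt_minus
  q4 <- unlist(lapply(1:200, function(i) {
    v <- generate_video(p, i, seed = 123)
    sb <- v$frames$segment == "sb"
    truth <- v$frames$abundant_truth[sb]
    truth[quartile_of(seq_len(sum(sb)) - 1, sum(sb)) == 4]
  }))
  expect_equal(length(q4), 10000)
  expect_gte(mean(q4), 0.295)
  expect_lte(mean(q4), 0.315)
})

test_that("the packaged cohort has the published arm sizes and planted counts", {
  coh <- generate_cohort(paper_study_profiles(frames_per_video = 8L), seed = 7)
  arms <- vapply(coh$videos, function(v) v$arm, character(1))
  expect_equal(sum(arms == "SMT-"), 48)
  expect_equal(sum(arms == "SMT+"), 57)
  expect_equal(nrow(coh$roster), 105)
  expect_false(anyDuplicated(coh$roster$patient_id) > 0)
  # exact-count planting of completion and findings
  smtm <- coh$videos[arms == "SMT-"]; smtp <- coh$videos[arms == "SMT+"]
  expect_equal(sum(vapply(smtm, function(v) v$complete, logical(1))), 42)
  expect_equal(sum(vapply(smtp, function(v) v$complete, logical(1))), 53)
  dy <- function(v) any(v$findings %in% c("P1", "P2"))
  expect_equal(sum(vapply(smtm, dy, logical(1))), 20)
  expect_equal(sum(vapply(smtp, dy, logical(1))), 24)
})

test_that("cohort metadata is reproducible under a fixed seed", {
  p <- paper_study_profiles(frames_per_video = 8L)
  p$smt_minus$n_videos <- 4L; p$smt_plus$n_videos <- 4L
  a <- generate_cohort(p, seed = 31)
  b <- generate_cohort(p, seed = 31)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("timestamps are ordered and transit times recoverable", {
  p <- paper_study_profiles(frames_per_video = 40L)$smt_plus
  v <- generate_video(p, 2, seed = 13)
  expect_true(all(diff(v$frames$t_sec) >= 0))
  s <- truth_summary(v)
  expect_equal(s$gastric_transit_min, v$gastric_min, tolerance = 1e-8)
  expect_equal(s$sb_transit_min, v$sb_min, tolerance = 1e-8)
})
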