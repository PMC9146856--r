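test_that("quartile boundaries follow floor(k*N/4)", {
  expect_equal(split_quartiles(8)$end - split_quartiles(8)$start, rep(2, 4))
  q10 <- split_quartiles(10)
  expect_equal(q10$start, c(0, 2, 5, 7))
  expect_equal(q10$end, c(2, 5, 7, 10))
  expect_equal(split_quartiles(4)$end - split_quartiles(4)$start, rep(1, 4))
  expect_error(split_quartiles(3), "too few SB frames")
})

test_that("quartile ranges always partition the small-bowel index set", {
  for (n in c(4:12, 101, 1037, 9999, 10000)) {
    q <- split_quartiles(n)
    expect_equal(q$start[1], 0)
    expect_equal(q$end[4], n)
    expect_equal(q$start[-1], q$end[-4])
    memb <- quartile_of(0:(n - 1), n)
    expect_equal(as.vector(table(memb)), q$end - q$start)
  }
})

make_scores <- function(abundant, adequate, offset = 0) {
  data.frame(frame_index = seq_along(abundant) - 1 + offset,
             bubble_class = ifelse(abundant, "abundant", "scarce"),
             cleanliness_class = ifelse(adequate, "adequate", "inadequate"),
             stringsAsFactors = FALSE)
}

make_sidecar <- function(n, findings = "P0", complete = TRUE) {
  list(video_id = "v1", arm = "A", t_sec = seq(0, by = 30, length.out = n),
       sb_first = 0, sb_last = n - 1,
       colonic_frame_present = complete, findings = findings)
}

test_that("per-quartile fractions summarize the planted pattern", {
  sc <- make_scores(c(1, 1, 0, 0, 0, 0, 0, 0) == 1, rep(TRUE, 8))
  s <- summarize_video(sc, make_sidecar(8))
  expect_equal(unlist(s[paste0("abundant_q", 1:4)], use.names = FALSE),
               c(1, 0, 0, 0))
  expect_equal(unlist(s[paste0("adequate_q", 1:4)], use.names = FALSE),
               rep(1, 4))
  expect_equal(unlist(s[paste0("n_q", 1:4)], use.names = FALSE), rep(2, 4))
})

test_that("weighted quartile fractions conserve the whole-sequence fraction", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:500, 1)
    ab <- runif(n) < runif(1)
    s <- summarize_video(make_scores(ab, ab), make_sidecar(n))
    nq <- unlist(s[paste0("n_q", 1:4)], use.names = FALSE)
    fr <- unlist(s[paste0("abundant_q", 1:4)], use.names = FALSE)
    expect_equal(sum(nq * fr) / sum(nq), mean(ab))
    expect_equal(sum(nq), n)
  }
})

test_that("outcomes derive from timestamps and findings", {
  sc <- make_scores(rep(FALSE, 10), rep(TRUE, 10), offset = 2)
  # two gastric frames before the SB segment
  gast <- make_scores(rep(FALSE, 2), rep(FALSE, 2))
  sc <- rbind(gast, sc)
  sidecar <- list(video_id = "v9", arm = "B",
                  t_sec = c(10, 50, seq(120, by = 60, length.out = 10)),
                  sb_first = 2, sb_last = 11,
                  colonic_frame_present = FALSE, findings = c("P0", "P2"))
  s <- summarize_video(sc, sidecar)
  expect_equal(s$gastric_transit_min, 2)
  expect_equal(s$sb_transit_min, 9)
  expect_equal(s$n_images, 12)
  expect_false(s$complete)
  expect_true(s$dy_positive)
  expect_true(s$p2_positive)
  expect_false(s$p1_positive)
})

test_that("P0-only findings leave the diagnostic yield negative", {
  s <- summarize_video(make_scores(rep(FALSE, 8), rep(FALSE, 8)),
                       make_sidecar(8, findings = "P0"))
  expect_false(s$dy_positive)
})

test_that("missing sidecar fields are reported by name", {
  sc <- make_scores(rep(FALSE, 8), rep(FALSE, 8))
  bad <- make_sidecar(8)
  bad$sb_first <- NULL; bad$findings <- NULL
  expect_error(summarize_video(sc, bad), "sb_first")
  expect_error(summarize_video(sc, bad), "findings")
})
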