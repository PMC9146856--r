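#' Split the small-bowel sequence into quartiles
#'
#' Partitions `[0, N)` (0-based small-bowel frame indices) into four
#' half-open ranges with boundaries at `floor(k * N / 4)`, `k = 0..4`, so
#' remainder frames fall into Q2 and Q4.
#'
#' @param n_sb_frames Number of small-bowel frames (>= 4).
#' @return data.frame with columns `quartile` (1..4), `start` (inclusive,
#'   0-based) and `end` (exclusive).
#' @export
split_quartiles <- function(n_sb_frames) {
  n <- n_sb_frames
  if (!is.numeric(n) || n < 4) stop("too few SB frames")
  b <- floor((0:4) * n / 4)
  data.frame(quartile = 1:4, start = b[1:4], end = b[2:5])
}

#' Quartile membership of small-bowel frame indices
#'
#' @param idx 0-based small-bowel frame indices.
#' @param n_sb_frames Total number of small-bowel frames.
#' @return Integer vector of quartiles (1..4).
#' @export
quartile_of <- function(idx, n_sb_frames) {
  q <- split_quartiles(n_sb_frames)
  findInterval(idx, q$start)
}

required_sidecar_fields <- c("video_id", "arm", "t_sec", "sb_first", "sb_last",
                             "colonic_frame_present", "findings")

check_sidecar <- function(sidecar) {
  miss <- setdiff(required_sidecar_fields, names(sidecar))
  if (length(miss))
    stop("missing sidecar fields: ", paste(miss, collapse = ", "))
  invisible(sidecar)
}

#' Summarize one scored video
#'
#' Aggregates per-frame scores over the small-bowel segment: the proportion
#' of abundant-in-bubbles and of adequately-cleansed frames in each quartile,
#' plus the reader-level outcomes (transit times in minutes, completion,
#' diagnostic-yield positivity from P1/P2 findings).
#'
#' @param scores data.frame with one row per frame of the whole video, in
#'   order, with columns `frame_index`, `bubble_class`, `cleanliness_class`.
#' @param sidecar List with fields `video_id`, `arm`, `t_sec` (per-frame
#'   timestamps in seconds, capsule ingestion at 0), `sb_first`/`sb_last`
#'   (0-based indices of the first and last small-bowel frame),
#'   `colonic_frame_present`, `findings` (character vector of P0/P1/P2).
#' @return One-row data.frame: identifiers, `abundant_q1..q4`,
#'   `adequate_q1..q4`, `n_q1..q4`, `gastric_transit_min`, `sb_transit_min`,
#'   `n_images`, `complete`, `p1_positive`, `p2_positive`, `dy_positive`.
#' @export
summarize_video <- function(scores, sidecar) {
  check_sidecar(sidecar)
  stopifnot(all(c("frame_index", "bubble_class", "cleanliness_class")
                %in% names(scores)))
  sb_first <- sidecar$sb_first; sb_last <- sidecar$sb_last
  sb_rows <- which(scores$frame_index >= sb_first & scores$frame_index <= sb_last)
  n_sb <- length(sb_rows)
  if (n_sb < 4) stop("too few SB frames")
  q <- quartile_of(seq_len(n_sb) - 1, n_sb)
  ab <- scores$bubble_class[sb_rows] == "abundant"
  ad <- scores$cleanliness_class[sb_rows] == "adequate"
  abundant <- vapply(1:4, function(k) mean(ab[q == k]), numeric(1))
  adequate <- vapply(1:4, function(k) mean(ad[q == k]), numeric(1))
  nq <- vapply(1:4, function(k) sum(q == k), numeric(1))
  t_sec <- sidecar$t_sec
  p1 <- any(sidecar$findings == "P1")
  p2 <- any(sidecar$findings == "P2")
  out <- data.frame(video_id = sidecar$video_id, arm = sidecar$arm,
                    stringsAsFactors = FALSE)
  for (k in 1:4) out[[paste0("abundant_q", k)]] <- abundant[k]
  for (k in 1:4) out[[paste0("adequate_q", k)]] <- adequate[k]
  for (k in 1:4) out[[paste0("n_q", k)]] <- nq[k]
  out$gastric_transit_min <- t_sec[sb_first + 1] / 60
  out$sb_transit_min <- (t_sec[sb_last + 1] - t_sec[sb_first + 1]) / 60
  out$n_images <- nrow(scores)
  out$complete <- isTRUE(sidecar$colonic_frame_present)
  out$p1_positive <- p1
  out$p2_positive <- p2
  out$dy_positive <- p1 || p2
  out
}
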