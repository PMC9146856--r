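#' Red-over-green cleanliness ratio
#'
#' Ratio of the mean red over the mean green channel intensity within the
#' FOV. Well-prepared mucosa is red-dominant; bile, faeces and debris raise
#' the green channel, lowering the ratio. The ratio-of-means form is used
#' (rather than a mean of per-pixel ratios) so individual zero-green pixels
#' cannot blow up the score.
#'
#' @param frame A `ce_frame`.
#' @return Positive ratio.
#' @export
rg_ratio <- function(frame) {
  stopifnot(inherits(frame, "ce_frame"))
  if (!any(frame$mask)) stop("undefined ratio: empty field of view")
  mr <- mean(frame$img[, , 1][frame$mask])
  mg <- mean(frame$img[, , 2][frame$mask])
  if (mg == 0) stop("undefined ratio")
  mr / mg
}

#' Classify frame cleanliness
#'
#' A frame is adequately cleansed when its red-over-green ratio is strictly
#' greater than the threshold (default 1.6); a frame exactly at the threshold
#' is inadequate.
#'
#' @param frame A `ce_frame`.
#' @param threshold Ratio cut-off, default 1.6.
#' @return `"adequate"` or `"inadequate"`.
#' @export
classify_cleanliness <- function(frame, threshold = 1.6) {
  if (rg_ratio(frame) > threshold) "adequate" else "inadequate"
}

#' Score a single frame
#'
#' Applies both per-frame scorers: GLCM contrast with the bubble-abundance
#' classification at `tau`, and the red-over-green ratio with the
#' cleanliness classification.
#'
#' @param frame A `ce_frame`.
#' @param params GLCM parameters.
#' @param tau Calibrated contrast threshold.
#' @param rg_threshold Cleanliness ratio cut-off.
#' @return One-row data.frame: `contrast`, `bubble_class`, `rg_ratio`,
#'   `cleanliness_class`.
#' @export
score_frame <- function(frame, params = glcm_params(), tau,
                        rg_threshold = 1.6) {
  ctr <- frame_contrast(frame, params)
  rg <- rg_ratio(frame)
  data.frame(contrast = ctr,
             bubble_class = if (ctr >= tau) "abundant" else "scarce",
             rg_ratio = rg,
             cleanliness_class = if (rg > rg_threshold) "adequate" else "inadequate",
             stringsAsFactors = FALSE)
}
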