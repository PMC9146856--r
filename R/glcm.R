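#' GLCM parameters
#'
#' Settings for the grey-level co-occurrence matrix: pairs of pixels at a
#' fixed offset are counted into a joint grey-level histogram. Defaults follow
#' the usual Haralick conventions (32 levels, distance 1, the four principal
#' orientations pooled, symmetric matrix).
#'
#' @param n_levels Number of equal-width grey bins over `[0, 255]` (>= 2).
#' @param distance Pixel offset distance (>= 1).
#' @param angles Orientations in degrees; any subset of 0, 45, 90, 135.
#' @param symmetric If `TRUE`, each pair is counted in both directions.
#' @return An object of class `glcm_params`.
#' @export
glcm_params <- function(n_levels = 32L, distance = 1L,
                        angles = c(0, 45, 90, 135), symmetric = TRUE) {
  stopifnot(n_levels >= 2, distance >= 1, length(angles) >= 1,
            all(angles %in% c(0, 45, 90, 135)))
  structure(list(n_levels = as.integer(n_levels),
                 distance = as.integer(distance),
                 angles = angles, symmetric = isTRUE(symmetric)),
            class = "glcm_params")
}

#' Grey-level quantization of a frame
#'
#' Converts RGB to luminance (`0.299 R + 0.587 G + 0.114 B`) and quantizes to
#' `n_levels` equal-width bins over `[0, 255]`.
#'
#' @param frame A `ce_frame`.
#' @param n_levels Number of grey bins.
#' @return Integer matrix of levels in `0 .. n_levels - 1`.
#' @export
quantize_grey <- function(frame, n_levels = 32L) {
  img <- frame$img
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  # the tiny offset absorbs float error in the luminance weights so values
  # sitting exactly on a bin boundary quantize predictably
  lev <- floor(lum * n_levels / 256 + 1e-9)
  lev[lev > n_levels - 1] <- n_levels - 1
  lev[lev < 0] <- 0
  storage.mode(lev) <- "integer"
  lev
}

glcm_offsets <- function(angles, d) {
  lapply(angles, function(a) switch(as.character(a),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d)))
}

#' Compute a grey-level co-occurrence matrix
#'
#' Counts, for every orientation, co-occurrences of grey levels of pixel
#' pairs separated by `distance`, restricted to pairs with both pixels inside
#' the FOV mask. Counts are symmetrized (pair counted both ways) when
#' `symmetric`, pooled over orientations, and normalized to sum to one.
#'
#' @param frame A `ce_frame`.
#' @param params A [glcm_params()].
#' @return A `glcm_matrix`: an `n_levels x n_levels` matrix of probabilities.
#' @export
compute_glcm <- function(frame, params = glcm_params()) {
  stopifnot(inherits(frame, "ce_frame"))
  n <- params$n_levels
  lev <- quantize_grey(frame, n)
  mask <- frame$mask
  h <- nrow(lev); w <- ncol(lev)
  d <- params$distance
  counts <- numeric(n * n)
  for (off in glcm_offsets(params$angles, d)) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(h, h - dr)
    c1 <- max(1, 1 - dc):min(w, w - dc)
    if (length(r1) < 1 || length(c1) < 1) next
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + dr, c1 + dc, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    code <- a[ok] * n + b[ok] + 1L
    counts <- counts + tabulate(code, nbins = n * n)
  }
  m <- matrix(counts, n, n, byrow = TRUE)  # code = i*n + j, row-major
  if (params$symmetric) m <- m + t(m)
  s <- sum(m)
  if (s < 2) stop("degenerate field of view")
  structure(m / s, class = "glcm_matrix", params = params)
}

#' GLCM contrast
#'
#' The Haralick contrast feature
#' \eqn{\sum_{i,j} (i - j)^2 \, p(i, j)}: zero for a constant image, large
#' when neighbouring pixels frequently sit in distant grey bins, as along the
#' bright rims of bubbles against the mucosa.
#'
#' @param m A normalized `glcm_matrix`.
#' @return Non-negative contrast value.
#' @export
glcm_contrast <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (abs(sum(m) - 1) > 1e-6) stop("GLCM must be normalized (sum to 1)")
  n <- nrow(m)
  idx <- seq_len(n) - 1
  d2 <- outer(idx, idx, "-")^2
  sum(d2 * m)
}

#' Contrast of a frame
#'
#' Convenience composition of [compute_glcm()] and [glcm_contrast()].
#' @inheritParams compute_glcm
#' @return Contrast value.
#' @export
frame_contrast <- function(frame, params = glcm_params()) {
  glcm_contrast(compute_glcm(frame, params))
}

#' Calibrate the bubble-abundance contrast threshold
#'
#' Given frames labelled by the ground-truth criterion (bubbles covering at
#' least 10% of the FOV), picks the contrast cut-off `tau` maximizing the
#' Youden index (sensitivity + specificity - 1). Candidate cut points are the
#' midpoints between consecutive distinct contrast values; ties are broken
#' toward higher specificity (the larger cut point).
#'
#' @param frames List of `ce_frame` objects, or `NULL` if `contrast` given.
#' @param abundant Logical vector of ground-truth labels (`TRUE` = abundant).
#' @param params GLCM parameters used to score the frames.
#' @param contrast Optional pre-computed contrast vector (skips scoring).
#' @return A `calibration_result` list: `tau`, `sensitivity`, `specificity`,
#'   `youden`, `n`.
#' @export
calibrate_threshold <- function(frames = NULL, abundant, params = glcm_params(),
                                contrast = NULL) {
  if (is.null(contrast)) {
    stopifnot(is.list(frames), length(frames) == length(abundant))
    contrast <- vapply(frames, frame_contrast, numeric(1), params = params)
  }
  abundant <- as.logical(abundant)
  stopifnot(length(contrast) == length(abundant), !anyNA(abundant))
  if (!any(abundant) || all(abundant))
    stop("calibration requires both classes (scarce and abundant)")
  u <- sort(unique(contrast))
  if (length(u) < 2) stop("calibration requires at least two distinct contrast values")
  cand <- (u[-1] + u[-length(u)]) / 2
  n_ab <- sum(abundant); n_sc <- sum(!abundant)
  sens <- vapply(cand, function(t) sum(contrast >= t & abundant) / n_ab, numeric(1))
  spec <- vapply(cand, function(t) sum(contrast < t & !abundant) / n_sc, numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[order(spec[best], cand[best], decreasing = TRUE)][1]
  structure(list(tau = cand[best], sensitivity = sens[best],
                 specificity = spec[best], youden = youden[best],
                 n = length(contrast)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Contrast threshold tau = %.3f (sens %.3f, spec %.3f, n = %d)\n",
              x$tau, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' Classify a frame as scarce or abundant in bubbles
#'
#' A frame is called abundant when its GLCM contrast is at or above the
#' calibrated threshold `tau`; the ground truth the threshold is calibrated
#' against is bubbles covering 10% or more of the FOV.
#'
#' @param frame A `ce_frame`.
#' @param params GLCM parameters.
#' @param tau Calibrated contrast threshold.
#' @return `"abundant"` or `"scarce"`.
#' @export
classify_bubbles <- function(frame, params = glcm_params(), tau) {
  stopifnot(is.numeric(tau), length(tau) == 1)
  if (frame_contrast(frame, params) >= tau) "abundant" else "scarce"
}
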