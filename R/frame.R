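#' Circular field-of-view mask
#'
#' Capsule endoscopes image through a circular optic: pixels outside the disc
#' are black and carry no information. All scoring in this package is
#' restricted to the field of view (FOV).
#'
#' @param width,height Image size in pixels.
#' @param radius_frac Disc radius as a fraction of `min(width, height)`.
#' @return A `height x width` logical matrix, `TRUE` inside the FOV.
#' @export
fov_mask <- function(width, height, radius_frac = 0.48) {
  fov_geometry(width, height, radius_frac)$mask
}

# Per-size geometry cache: the mask and coordinate grids are identical for
# every frame of a given size, and rendering touches them constantly.
.geom_cache <- new.env(parent = emptyenv())

fov_geometry <- function(width, height, radius_frac = 0.48) {
  stopifnot(width >= 4, height >= 4, radius_frac > 0)
  key <- sprintf("%d_%d_%g", width, height, radius_frac)
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  r <- radius_frac * min(width, height)
  x <- matrix(rep(seq_len(width), each = height), nrow = height)
  y <- matrix(rep(seq_len(height), times = width), nrow = height)
  g <- list(mask = (x - cx)^2 + (y - cy)^2 <= r^2,
            xs = x / width, ys = y / height, cx = cx, cy = cy, r_fov = r)
  .geom_cache[[key]] <- g
  g
}

#' Construct a frame object
#'
#' A frame is an 8-bit RGB still image together with its FOV mask. Channel
#' values are stored as doubles in `[0, 255]`.
#'
#' @param img `height x width x 3` numeric array, values in `[0, 255]`.
#' @param mask Logical `height x width` FOV mask; `NULL` derives the default
#'   circular mask from the image size.
#' @return An object of class `ce_frame` with elements `img` and `mask`.
#' @export
new_frame <- function(img, mask = NULL) {
  stopifnot(is.array(img), length(dim(img)) == 3, dim(img)[3] == 3)
  if (is.null(mask)) mask <- fov_mask(dim(img)[2], dim(img)[1])
  stopifnot(is.logical(mask), all(dim(mask) == dim(img)[1:2]))
  structure(list(img = img, mask = mask), class = "ce_frame")
}

#' @export
print.ce_frame <- function(x, ...) {
  d <- dim(x$img)
  cat(sprintf("<ce_frame %dx%d, FOV %d px (%.1f%%)>\n",
              d[2], d[1], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Specification of a synthetic frame
#'
#' Describes the planted ground truth of one synthetic endoscopic still:
#' the fraction of the FOV covered by bubbles and the target red-over-green
#' channel balance.
#'
#' @param width,height Image size in pixels.
#' @param true_bubble_coverage Fraction of the FOV area covered by bubbles,
#'   in `[0, 1]` (values above 0.95 are not renderable).
#' @param rg_balance Target ratio of mean red over mean green intensity
#'   within the FOV; must be positive.
#' @param noise_sd Standard deviation of the per-pixel grey-level noise.
#' @param seed Integer seed; rendering is fully deterministic given the spec.
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(width = 128L, height = 128L, true_bubble_coverage = 0,
                       rg_balance = 1.8, noise_sd = 8, seed = 1L) {
  stopifnot(width >= 16, height >= 16)
  if (!is.numeric(true_bubble_coverage) || true_bubble_coverage < 0 ||
      true_bubble_coverage > 1)
    stop("true_bubble_coverage must be in [0, 1]")
  if (!is.numeric(rg_balance) || rg_balance <= 0)
    stop("rg_balance must be positive")
  structure(list(width = as.integer(width), height = as.integer(height),
                 true_bubble_coverage = true_bubble_coverage,
                 rg_balance = rg_balance, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "frame_spec")
}

# Place non-overlapping bubble discs inside the FOV until the painted pixel
# fraction is within tol of the target. Candidate centers are sampled from
# still-uncovered FOV pixels; a proposed disc is shrunk until its painted
# pixels are disjoint from every earlier disc, so packing stays efficient
# up to very dense targets. Returns logical disc and rim masks.
place_bubbles <- function(mask, coverage, rim_width = 1.3, tol = 0.0015) {
  h <- nrow(mask); w <- ncol(mask)
  n_fov <- sum(mask)
  disc <- matrix(FALSE, h, w)
  rim <- matrix(FALSE, h, w)
  if (coverage <= 0) return(list(disc = disc, rim = rim))
  g <- fov_geometry(w, h)
  cx <- g$cx; cy <- g$cy; r_fov <- g$r_fov
  target_px <- coverage * n_fov
  tol_px <- max(4, tol * n_fov)
  r_hi <- min(7, r_fov / 3); r_lo <- 5
  covered <- 0
  fails <- 0
  free_idx <- which(mask)
  since_refresh <- 0
  while (target_px - covered > tol_px) {
    if (fails > 4000) stop("cannot reach requested bubble coverage")
    if (since_refresh > 25) {
      free_idx <- which(mask & !disc)
      since_refresh <- 0
    }
    p <- free_idx[sample.int(length(free_idx), 1)]
    y0 <- ((p - 1) %% h) + 1
    x0 <- ((p - 1) %/% h) + 1
    rem <- target_px - covered
    r_cap <- sqrt((rem + tol_px) / pi)
    # discs may spill at most ~2 px past the FOV edge; only in-mask pixels
    # count toward coverage
    r <- min(stats::runif(1, min(r_lo, r_cap), max(r_lo, min(r_hi, r_cap))),
             r_fov - sqrt((x0 - cx)^2 + (y0 - cy)^2) + 2, r_cap)
    placed <- FALSE
    while (r >= 0.6) {
      xr <- max(1, floor(x0 - r)):min(w, ceiling(x0 + r))
      yr <- max(1, floor(y0 - r)):min(h, ceiling(y0 + r))
      d2 <- outer((yr - y0)^2, (xr - x0)^2, "+")
      in_disc <- d2 <= r^2
      sub <- disc[yr, xr, drop = FALSE]
      if (!any(sub[in_disc])) {
        sub_rim <- rim[yr, xr, drop = FALSE]
        sub[in_disc] <- TRUE
        sub_rim[in_disc & d2 > (max(r - rim_width, 0))^2] <- TRUE
        disc[yr, xr] <- sub
        rim[yr, xr] <- sub_rim
        covered <- covered + sum(in_disc & mask[yr, xr, drop = FALSE])
        placed <- TRUE
        break
      }
      r <- r / 2
    }
    if (placed) {
      fails <- 0
      since_refresh <- since_refresh + 1
    } else {
      fails <- fails + 1
      if (fails %% 100 == 0) { free_idx <- which(mask & !disc); since_refresh <- 0 }
    }
  }
  list(disc = disc, rim = rim)
}

# Rescale the non-bubble background so the FOV-wide mean-R / mean-G ratio
# hits the target, preferring the solution that preserves the background
# luminance (so the texture signal seen by the GLCM detector is unaffected
# by the colour balance). Iterates because clipping at [0, 255] perturbs
# the means slightly.
adjust_rg_balance <- function(R, G, mask, bub, target, tol = 0.008,
                              max_iter = 15L) {
  bg <- mask & !bub
  if (!any(bg)) stop("unattainable red/green balance: no background pixels")
  f <- sum(bub & mask) / sum(mask)
  L0 <- 0.299 * mean(R[bg]) + 0.587 * mean(G[bg])
  for (i in seq_len(max_iter)) {
    mR <- mean(R[mask]); mG <- mean(G[mask])
    if (mG > 0 && abs(mR / mG / target - 1) < tol) return(list(R = R, G = G))
    Rb <- if (f > 0) mean(R[bub & mask]) else 0
    Gb <- if (f > 0) mean(G[bub & mask]) else 0
    Rg <- mean(R[bg]); Gg <- mean(G[bg])
    # solve for background means (Rp, Gp) with
    #   (f*Rb + (1-f)*Rp) / (f*Gb + (1-f)*Gp) = target
    #   0.299*Rp + 0.587*Gp = L0
    A <- (target * f * Gb - f * Rb) / (1 - f)
    Gp <- (L0 - 0.299 * A) / (0.299 * target + 0.587)
    Rp <- A + target * Gp
    if (!is.finite(Gp) || !is.finite(Rp) || Gp < 2 || Rp < 2) {
      # luminance cannot be held; fall back to scaling green alone
      Gp <- Gg * (mR / mG) / target
      Rp <- Rg
    }
    R[bg] <- pmin(255, pmax(0, R[bg] * (Rp / Rg)))
    G[bg] <- pmin(255, pmax(0, G[bg] * (Gp / Gg)))
  }
  # last resort for nearly bubble-filled frames: rescale the green channel
  # of the whole FOV (bubble film included)
  for (i in seq_len(max_iter)) {
    mR <- mean(R[mask]); mG <- mean(G[mask])
    if (mG > 0 && abs(mR / mG / target - 1) < tol) break
    G[mask] <- pmin(255, pmax(0, G[mask] * (mR / mG) / target))
  }
  mR <- mean(R[mask]); mG <- mean(G[mask])
  if (abs(mR / mG / target - 1) >= 0.02)
    stop("unattainable red/green balance for this frame")
  list(R = R, G = G)
}

#' Render a synthetic endoscopic frame
#'
#' Draws an 8-bit RGB still with the appearance the scorers target: a reddish
#' textured mucosa inside a circular FOV (black outside), non-overlapping
#' bright bubble annuli covering `true_bubble_coverage` of the FOV, and
#' greenish debris blotches, with the background rescaled so the FOV
#' mean-red over mean-green ratio matches `rg_balance` within 2%.
#'
#' Rendering is deterministic given the spec (including its seed). The painted
#' bubble-pixel fraction matches the requested coverage within \eqn{\pm 0.01}.
#'
#' @param spec A [frame_spec()].
#' @return A [new_frame()] object; attributes `bubble_px` (logical matrix of
#'   planted bubble pixels) and `coverage_rendered` carry the ground truth.
#' @export
render_frame <- function(spec) {
  stopifnot(inherits(spec, "frame_spec"))
  if (spec$true_bubble_coverage > 0.95)
    stop("bubble coverage above 0.95 is not renderable")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  invisible(stats::runif(64))  # decorrelate streams from nearby seeds
  h <- spec$height; w <- spec$width
  g <- fov_geometry(w, h)
  mask <- g$mask
  n <- h * w
  # low-frequency shading + iid grain gives the mucosa its texture
  xs <- g$xs; ys <- g$ys
  ph <- stats::runif(4, 0, 2 * pi)
  shade <- sin(2 * pi * (1.7 * xs + 0.9 * ys) + ph[1]) +
    0.6 * sin(2 * pi * (0.8 * xs - 1.9 * ys) + ph[2]) +
    0.4 * sin(2 * pi * (3.1 * xs + 2.3 * ys) + ph[3])
  R <- 168 + 9 * shade + stats::rnorm(n, 0, spec$noise_sd)
  G <- 86 + 5 * shade + stats::rnorm(n, 0, 0.7 * spec$noise_sd)
  B <- 66 + 4 * shade + stats::rnorm(n, 0, 0.7 * spec$noise_sd)
  dim(R) <- dim(G) <- dim(B) <- c(h, w)
  # greenish debris blotches (bile / residue)
  for (k in seq_len(3)) {
    bx <- stats::runif(1, 0.25 * w, 0.75 * w)
    by <- stats::runif(1, 0.25 * h, 0.75 * h)
    br <- stats::runif(1, 0.06, 0.14) * min(w, h)
    d2 <- outer((seq_len(h) - by)^2, (seq_len(w) - bx)^2, "+")
    a <- 0.35 * exp(-d2 / (2 * br^2))
    R <- R + a * (95 - R)
    G <- G + a * (128 - G)
    B <- B + a * (52 - B)
  }
  bub <- place_bubbles(mask, spec$true_bubble_coverage)
  disc <- bub$disc & mask
  rim <- bub$rim & mask
  interior <- disc & !rim
  # translucent interior carrying strong specular glints: the speckle makes
  # the texture signal scale with bubble area, not just rim length
  n_int <- sum(interior)
  glint <- 255 * stats::runif(n_int, 0.2, 1)
  R[interior] <- 0.45 * R[interior] + 0.55 * glint
  G[interior] <- 0.45 * G[interior] + 0.55 * glint
  B[interior] <- 0.45 * B[interior] + 0.55 * glint
  R[rim] <- 0.08 * R[rim] + 0.92 * 255
  G[rim] <- 0.08 * G[rim] + 0.92 * 255
  B[rim] <- 0.08 * B[rim] + 0.92 * 255
  adj <- adjust_rg_balance(R, G, mask, disc, spec$rg_balance)
  R <- adj$R; G <- adj$G
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- round(pmin(255, pmax(0, R)))
  img[, , 2] <- round(pmin(255, pmax(0, G)))
  img[, , 3] <- round(pmin(255, pmax(0, B)))
  img[, , 1][!mask] <- 0; img[, , 2][!mask] <- 0; img[, , 3][!mask] <- 0
  fr <- new_frame(img, mask)
  attr(fr, "bubble_px") <- disc
  attr(fr, "coverage_rendered") <- sum(disc) / sum(mask)
  fr
}
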