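# Independent oracles and small fixture builders used across the suite.

# Brute-force GLCM by explicit pair enumeration: loops over every pixel and
# offset, no shared code with compute_glcm.
brute_glcm <- function(frame, params) {
  n <- params$n_levels
  img <- frame$img
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  lev <- pmin(floor(lum * n / 256), n - 1)
  h <- nrow(lev); w <- ncol(lev)
  d <- params$distance
  offs <- list("0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
               "135" = c(-d, -d))
  m <- matrix(0, n, n)
  for (a in as.character(params$angles)) {
    dr <- offs[[a]][1]; dc <- offs[[a]][2]
    for (i in seq_len(h)) for (j in seq_len(w)) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 < 1 || i2 > h || j2 < 1 || j2 > w) next
      if (!frame$mask[i, j] || !frame$mask[i2, j2]) next
      m[lev[i, j] + 1, lev[i2, j2] + 1] <- m[lev[i, j] + 1, lev[i2, j2] + 1] + 1
      if (params$symmetric)
        m[lev[i2, j2] + 1, lev[i, j] + 1] <- m[lev[i2, j2] + 1, lev[i, j] + 1] + 1
    }
  }
  m / sum(m)
}

# Classical mean-decomposition sums of squares for the split-plot design
# (independent of the aov route used by mixed_anova).
brute_mixed_ss <- function(data) {
  y <- data$value
  grand <- mean(y)
  k <- length(unique(data$quartile))
  subj_means <- tapply(y, data$subject, mean)
  subj_group <- tapply(as.character(data$group), data$subject, `[`, 1)
  group_means <- tapply(y, data$group, mean)
  n_g <- table(subj_group)
  quart_means <- tapply(y, data$quartile, mean)
  cell_means <- tapply(y, list(data$group, data$quartile), mean)
  ss_total <- sum((y - grand)^2)
  ss_between <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_g * (group_means[names(n_g)] - grand)^2)
  ss_subj <- ss_between - ss_group
  n_subj <- length(subj_means)
  ss_quart <- n_subj * sum((quart_means - grand)^2)
  ss_inter <- 0
  for (g in rownames(cell_means)) for (q in colnames(cell_means))
    ss_inter <- ss_inter + n_g[[g]] *
      (cell_means[g, q] - group_means[[g]] - quart_means[[q]] + grand)^2
  ss_resid <- ss_total - ss_between - ss_quart - ss_inter
  list(group = ss_group, subjects_within = ss_subj, quartile = ss_quart,
       interaction = ss_inter, residual = ss_resid, total = ss_total)
}

# Constant-colour frame with a full (all-TRUE) mask.
uniform_frame <- function(r, g, b, w = 16, h = 16) {
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  new_frame(img, matrix(TRUE, h, w))
}

# Grey frame from a matrix of 8-bit values (all channels equal), full mask.
grey_frame <- function(vals, mask = NULL) {
  h <- nrow(vals); w <- ncol(vals)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- vals
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  new_frame(img, mask)
}

# n x n checkerboard of two grey levels lo_bin/hi_bin (given as bin indices
# for n_levels bins of width 256/n_levels).
checkerboard_frame <- function(n = 4, lo_bin = 0, hi_bin = 31, n_levels = 32) {
  wbin <- 256 / n_levels
  vals <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
  grey_frame(vals * (hi_bin - lo_bin) * wbin + lo_bin * wbin)
}

# Random small RGB frame, optionally with a random mask.
random_frame <- function(seed, w = 16, h = 16, masked = FALSE) {
  set.seed(seed)
  img <- array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
  mask <- if (masked) matrix(runif(h * w) < 0.8, h, w) else matrix(TRUE, h, w)
  new_frame(img, mask)
}
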