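#' Two-way mixed repeated-measures ANOVA
#'
#' Classical split-plot decomposition for a design with one between-subjects
#' factor (preparation group) and one within-subjects factor (small-bowel
#' quartile), one observation per subject x quartile cell. The group effect
#' is tested against subjects-within-groups; the quartile and
#' group-by-quartile effects against the subject-by-quartile residual.
#' No sphericity correction is applied by default; `gg = TRUE` adds
#' Greenhouse-Geisser-adjusted p-values for the within-subject effects.
#'
#' @param data Long data.frame with columns `subject`, `group`, `quartile`,
#'   `value`; every subject must have exactly one value per quartile.
#' @param gg If `TRUE`, also report Greenhouse-Geisser epsilon and adjusted
#'   p-values for the within-subject tests.
#' @return A `mixed_anova` object: a data.frame `table` with one row per
#'   effect (`group`, `subjects_within`, `quartile`, `group_by_quartile`,
#'   `residual`) and columns `ss`, `df`, `ms`, `F`, `p`; plus `ss_total` and
#'   optionally `gg_epsilon`, `p_quartile_gg`, `p_interaction_gg`.
#' @export
mixed_anova <- function(data, gg = FALSE) {
  stopifnot(all(c("subject", "group", "quartile", "value") %in% names(data)))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$quartile <- factor(data$quartile)
  if (nlevels(data$group) != 2) stop("exactly two groups are required")
  tab <- table(data$subject, data$quartile)
  if (any(tab != 1)) stop("missing cells: each subject needs one value per quartile")
  ns <- table(unique(data[, c("subject", "group")])$group)
  if (any(ns < 2)) stop("each group needs at least 2 subjects")
  k <- nlevels(data$quartile)

  fit <- stats::aov(value ~ group * quartile + Error(subject),
                    data = data)
  sm <- summary(fit)
  s_between <- sm[["Error: subject"]][[1]]
  s_within <- sm[["Error: Within"]][[1]]
  pick <- function(s, name) {
    i <- match(name, trimws(rownames(s)))
    c(ss = s[i, "Sum Sq"], df = s[i, "Df"])
  }
  g <- pick(s_between, "group")
  sw <- pick(s_between, "Residuals")
  qr <- pick(s_within, "quartile")
  gq <- pick(s_within, "group:quartile")
  rs <- pick(s_within, "Residuals")
  eff <- data.frame(
    effect = c("group", "subjects_within", "quartile", "group_by_quartile",
               "residual"),
    ss = c(g["ss"], sw["ss"], qr["ss"], gq["ss"], rs["ss"]),
    df = c(g["df"], sw["df"], qr["df"], gq["df"], rs["df"]),
    stringsAsFactors = FALSE)
  eff$ms <- eff$ss / eff$df
  ms_sw <- eff$ms[2]; ms_res <- eff$ms[5]
  eff$F <- c(eff$ms[1] / ms_sw, NA, eff$ms[3] / ms_res, eff$ms[4] / ms_res, NA)
  eff$p <- c(stats::pf(eff$F[1], eff$df[1], eff$df[2], lower.tail = FALSE), NA,
             stats::pf(eff$F[3], eff$df[3], eff$df[5], lower.tail = FALSE),
             stats::pf(eff$F[4], eff$df[4], eff$df[5], lower.tail = FALSE), NA)
  res <- list(table = eff, ss_total = sum(eff$ss),
              n_per_group = as.vector(ns), k = k)
  if (gg) {
    eps <- gg_epsilon(data)
    res$gg_epsilon <- eps
    res$p_quartile_gg <- stats::pf(eff$F[3], eps * eff$df[3], eps * eff$df[5],
                                   lower.tail = FALSE)
    res$p_interaction_gg <- stats::pf(eff$F[4], eps * eff$df[4], eps * eff$df[5],
                                      lower.tail = FALSE)
  }
  class(res) <- "mixed_anova"
  res
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Two-way mixed repeated-measures ANOVA\n")
  tab <- x$table
  tab$ss <- signif(tab$ss, 5); tab$ms <- signif(tab$ms, 5)
  tab$F <- signif(tab$F, 4); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$gg_epsilon))
    cat(sprintf("Greenhouse-Geisser epsilon = %.3f\n", x$gg_epsilon))
  invisible(x)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures.
gg_epsilon <- function(data) {
  wide <- stats::reshape(data[, c("subject", "group", "quartile", "value")],
                         idvar = c("subject", "group"),
                         timevar = "quartile", direction = "wide")
  y <- as.matrix(wide[, -(1:2), drop = FALSE])
  groups <- wide$group
  centered <- do.call(rbind, lapply(split(as.data.frame(y), groups), function(m) {
    m <- as.matrix(m)
    sweep(m, 2, colMeans(m))
  }))
  s <- crossprod(centered) / (nrow(y) - length(unique(groups)))
  k <- ncol(s)
  dbar <- mean(diag(s)); sbar <- mean(s)
  row_means <- rowMeans(s)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(s^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  eps <- num / den
  min(1, max(1 / (k - 1), eps))
}

#' Welch two-sample t-test
#'
#' @param x,y Numeric samples.
#' @param var_equal If `TRUE`, pooled-variance Student form instead of the
#'   default Welch unequal-variance form.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(x, y, var_equal = FALSE) {
  if (stats::sd(c(x, y)) == 0) return(list(t = 0, df = NA_real_, p = 1))
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = outcome
#'   (`a`,`b` = group 1; `c`,`d` = group 2).
#' @param correct Apply the Yates continuity correction (default off).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(m < 0) || any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
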