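#' Round half away from zero
#'
#' Study tables report percentages with ties rounded up (so 41.65 prints as
#' 41.7), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(x, digits = 1) round_half_up(100 * x, digits)

#' Group-by-quartile interaction table
#'
#' Mean, SD and n of a per-video per-quartile fraction, by arm and quartile —
#' the numbers behind the study's interaction plots.
#'
#' @param summaries Per-video summary data.frame ([summarize_video()] rows).
#' @param endpoint `"abundant"` (bubbles) or `"adequate"` (cleanliness).
#' @return data.frame with columns `group`, `quartile`, `mean_fraction`,
#'   `sd`, `n`.
#' @export
interaction_table <- function(summaries, endpoint = c("abundant", "adequate")) {
  endpoint <- match.arg(endpoint)
  cols <- paste0(endpoint, "_q", 1:4)
  out <- do.call(rbind, lapply(split(summaries, summaries$arm), function(d) {
    data.frame(group = d$arm[1], quartile = 1:4,
               mean_fraction = vapply(cols, function(cn) mean(d[[cn]]), numeric(1)),
               sd = vapply(cols, function(cn) stats::sd(d[[cn]]), numeric(1)),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

anova_data <- function(summaries, endpoint) {
  cols <- paste0(endpoint, "_q", 1:4)
  do.call(rbind, lapply(1:4, function(k) {
    data.frame(subject = summaries$video_id, group = summaries$arm,
               quartile = k, value = summaries[[cols[k]]],
               stringsAsFactors = FALSE)
  }))
}

#' Run the mixed ANOVA on a cohort endpoint
#'
#' Reshapes per-video quartile fractions into long form (video = subject)
#' and fits [mixed_anova()].
#'
#' @param summaries Per-video summary data.frame.
#' @param endpoint `"abundant"` or `"adequate"`.
#' @param gg Request Greenhouse-Geisser adjusted p-values as well.
#' @return A `mixed_anova` object.
#' @export
cohort_anova <- function(summaries, endpoint = c("abundant", "adequate"),
                         gg = FALSE) {
  endpoint <- match.arg(endpoint)
  mixed_anova(anova_data(summaries, endpoint), gg = gg)
}

mean_sd_row <- function(x_by_arm, digits = 0) {
  vapply(x_by_arm, function(x)
    sprintf("%s ± %s", round_half_up(mean(x), digits),
            round_half_up(stats::sd(x), digits)), character(1))
}

#' Build the study report
#'
#' Assembles the group-level tables of the analysis: a demographics table, an
#' outcome table (diagnostic-yield rates, transit times, completion rate,
#' image counts, with chi-square or Welch-t p-values), the two
#' group-by-quartile interaction tables, and the mixed-ANOVA results for
#' both endpoints. Percentages are reported to one decimal, half-up.
#'
#' @param summaries Per-video summary data.frame covering both arms.
#' @param roster Cohort roster (one row per video, with `video_id`, `age`,
#'   `arm_label`).
#' @return A `study_report` list: `demographics`, `outcomes`,
#'   `bubbles_interaction`, `cleanliness_interaction`, `anova_bubbles`,
#'   `anova_cleanliness`, `arms`.
#' @export
build_report <- function(summaries, roster) {
  arms <- sort(unique(summaries$arm))
  if (length(arms) != 2) stop("report requires exactly two arms")
  by_arm <- split(summaries, factor(summaries$arm, levels = arms))
  if (any(vapply(by_arm, nrow, integer(1)) == 0))
    stop("arm with zero videos")
  n <- vapply(by_arm, nrow, integer(1))

  rate_row <- function(flag_col) {
    pos <- vapply(by_arm, function(d) sum(d[[flag_col]]), numeric(1))
    p <- tryCatch(
      chi_square_2x2(pos[1], n[1] - pos[1], pos[2], n[2] - pos[2])$p,
      error = function(e) NA_real_)  # degenerate margin: rates identical
    list(values = sprintf("%.1f", pct(pos / n)), p = p)
  }
  num_row <- function(col) {
    xs <- lapply(by_arm, function(d) d[[col]])
    list(values = mean_sd_row(xs), p = two_sample_t(xs[[1]], xs[[2]])$p)
  }
  p1 <- rate_row("p1_positive"); p2 <- rate_row("p2_positive")
  dy <- rate_row("dy_positive"); comp <- rate_row("complete")
  gt <- num_row("gastric_transit_min"); st <- num_row("sb_transit_min")
  ni <- num_row("n_images")
  outcomes <- data.frame(
    measure = c("P1 lesion rate (%)", "P2 lesion rate (%)",
                "P1 or P2 lesion rate (%)", "Gastric transit time (min)",
                "Small bowel transit time (min)", "Completion rate (%)",
                "Number of images per video"),
    stringsAsFactors = FALSE)
  outcomes[[arms[1]]] <- c(p1$values[1], p2$values[1], dy$values[1],
                           gt$values[1], st$values[1], comp$values[1],
                           ni$values[1])
  outcomes[[arms[2]]] <- c(p1$values[2], p2$values[2], dy$values[2],
                           gt$values[2], st$values[2], comp$values[2],
                           ni$values[2])
  outcomes$p <- round_half_up(c(p1$p, p2$p, dy$p, gt$p, st$p, comp$p, ni$p), 2)

  rost <- roster[match(summaries$video_id, roster$video_id), , drop = FALSE]
  ages <- split(rost$age, factor(summaries$arm, levels = arms))
  demographics <- data.frame(measure = c("n", "Age (years)"),
                             stringsAsFactors = FALSE)
  demographics[[arms[1]]] <- c(n[1], mean_sd_row(ages)[1])
  demographics[[arms[2]]] <- c(n[2], mean_sd_row(ages)[2])
  demographics$p <- c(NA, round_half_up(two_sample_t(ages[[1]], ages[[2]])$p, 2))

  structure(list(
    demographics = demographics,
    outcomes = outcomes,
    bubbles_interaction = interaction_table(summaries, "abundant"),
    cleanliness_interaction = interaction_table(summaries, "adequate"),
    anova_bubbles = cohort_anova(summaries, "abundant"),
    anova_cleanliness = cohort_anova(summaries, "adequate"),
    arms = arms), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Outcomes ==\n"); print(x$outcomes, row.names = FALSE)
  cat("\n== Bubble abundance ANOVA ==\n"); print(x$anova_bubbles)
  cat("\n== Cleanliness ANOVA ==\n"); print(x$anova_cleanliness)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the tables as CSV and the full report (including the ANOVA tables)
#' as JSON in `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    demographics = file.path(dir, "demographics.csv"),
    outcomes = file.path(dir, "outcomes.csv"),
    bubbles = file.path(dir, "interaction_bubbles.csv"),
    cleanliness = file.path(dir, "interaction_cleanliness.csv"),
    json = file.path(dir, "report.json"))
  utils::write.csv(report$demographics, paths["demographics"], row.names = FALSE)
  utils::write.csv(report$outcomes, paths["outcomes"], row.names = FALSE)
  utils::write.csv(report$bubbles_interaction, paths["bubbles"], row.names = FALSE)
  utils::write.csv(report$cleanliness_interaction, paths["cleanliness"],
                   row.names = FALSE)
  json <- list(demographics = report$demographics, outcomes = report$outcomes,
               bubbles_interaction = report$bubbles_interaction,
               cleanliness_interaction = report$cleanliness_interaction,
               anova_bubbles = report$anova_bubbles$table,
               anova_cleanliness = report$anova_cleanliness$table)
  jsonlite::write_json(json, paths["json"], dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
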