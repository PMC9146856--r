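#!/usr/bin/env Rscript
# Step 4 — group comparison and report. Takes the per-video summaries from
# step 3, runs the two-way mixed repeated-measures ANOVA (group x quartile,
# video as subject) for both endpoints, assembles the demographics/outcome
# tables and the interaction tables, and draws the interaction plots.
# Run analysis/03_score_cohort.R first.

suppressPackageStartupMessages(library(capsulevq))

summaries <- read.csv("results/video_summaries.csv", stringsAsFactors = FALSE)
roster <- read.csv("results/cohort_roster.csv", stringsAsFactors = FALSE)

report <- build_report(summaries, roster)
print(report)

cat("\nGreenhouse-Geisser-adjusted within-subject p-values (bubbles):\n")
gg <- cohort_anova(summaries, "abundant", gg = TRUE)
cat(sprintf("  epsilon %.3f, quartile p %.4f, interaction p %.4f\n",
            gg$gg_epsilon, gg$p_quartile_gg, gg$p_interaction_gg))

write_report(report, "results/report")
cat("wrote results/report/\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  for (ep in c("bubbles", "cleanliness")) {
    tab <- report[[paste0(ep, "_interaction")]]
    gp <- ggplot(tab, aes(quartile, 100 * mean_fraction,
                          colour = group, group = group)) +
      geom_line() + geom_point() +
      labs(x = "Small-bowel quartile",
           y = if (ep == "bubbles") "% frames abundant in bubbles"
               else "% frames adequately cleansed (R/G > 1.6)",
           colour = "Arm") +
      theme_minimal()
    ggsave(sprintf("results/report/interaction_%s.pdf", ep), gp,
           width = 5, height = 3.5)
  }
  cat("wrote interaction plots under results/report/\n")
}
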