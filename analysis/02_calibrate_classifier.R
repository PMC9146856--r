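#!/usr/bin/env Rscript
# Step 2 — classifier calibration. The GLCM-contrast cut-off separating
# scarce from abundant-in-bubbles frames is not published for the original
# detector, so it is calibrated here on 500 labelled synthetic frames
# (bubble coverage uniform on [0, 0.3], the ground-truth criterion being
# coverage >= 10% of the field of view), maximizing the Youden index.
# A further 1,000 held-out frames estimate the operating characteristics.

suppressPackageStartupMessages(library(capsulevq))
dir.create("results", showWarnings = FALSE)

seed <- 1
specs <- calibration_specs(500, seed = derive_seed(seed, "calib"))
cat("rendering and scoring 500 calibration frames...\n")
ctr <- contrasts_for_specs(specs)
cal <- calibrate_threshold(contrast = ctr, abundant = specs$abundant)
print(cal)

held <- calibration_specs(1000, seed = derive_seed(seed, "heldout"))
cat("scoring 1,000 held-out frames...\n")
pred <- contrasts_for_specs(held) >= cal$tau
sens <- mean(pred[held$abundant])
spec <- mean(!pred[!held$abundant])
cat(sprintf("held-out: sensitivity %.3f, specificity %.3f, balanced accuracy %.3f\n",
            sens, spec, (sens + spec) / 2))

out <- data.frame(tau = cal$tau,
                  calibration_sensitivity = cal$sensitivity,
                  calibration_specificity = cal$specificity,
                  heldout_sensitivity = sens,
                  heldout_specificity = spec,
                  heldout_balanced_accuracy = (sens + spec) / 2,
                  n_calibration = 500, n_heldout = 1000)
write.csv(out, "results/classifier_calibration.csv", row.names = FALSE)
cat("wrote results/classifier_calibration.csv\n")
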