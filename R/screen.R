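exclusion_flag_cols <- c("technical_defect_flag", "endoscopic_delivery_flag",
                         "recent_CE_flag", "gastric_retention_flag",
                         "active_bleeding_flag", "contraindication_flag")

roster_flag_cols <- c("washout_period_flag", exclusion_flag_cols)

#' Apply the screening inclusion/exclusion filters
#'
#' Applies the study's sequential screening filters in flow-chart order:
#' removal of washout-period examinations, restriction to the OGIB
#' indication, restriction to outpatients, split by preparation arm, then
#' removal of records with any exclusion-criterion flag (or age below 18).
#' Node counts at every stage are returned so the flow chart can be
#' reproduced; the final included set itself does not depend on the filter
#' order, only the intermediate counts do.
#'
#' @param roster data.frame of roster records (see
#'   [generate_screening_roster()] for the columns).
#' @return A `screening_flow` list: `counts` (named list: `screened`,
#'   `excluded_washout`, `ogib`, `inpatients_removed`, `eligible_per_arm`,
#'   `excluded_criteria_per_arm`, `included_per_arm`, `included_total`) and
#'   `included` (the surviving roster rows).
#' @export
apply_filters <- function(roster) {
  need <- c("patient_id", "setting", "indication", "age", "arm_label",
            roster_flag_cols)
  miss <- setdiff(need, names(roster))
  if (length(miss)) stop("roster is missing columns: ", paste(miss, collapse = ", "))
  for (f in roster_flag_cols) {
    bad <- which(is.na(roster[[f]]))
    if (length(bad))
      stop(sprintf("missing flag %s for record %s", f,
                   roster$patient_id[bad[1]]))
  }
  n0 <- nrow(roster)
  if (n0 == 0) {
    empty <- stats::setNames(numeric(0), character(0))
    return(structure(list(counts = list(screened = 0, excluded_washout = 0,
                                        ogib = 0, inpatients_removed = 0,
                                        eligible_per_arm = empty,
                                        excluded_criteria_per_arm = empty,
                                        included_per_arm = empty,
                                        included_total = 0),
                          included = roster),
                     class = "screening_flow"))
  }
  r1 <- roster[!roster$washout_period_flag, , drop = FALSE]
  r2 <- r1[r1$indication == "OGIB", , drop = FALSE]
  inpat <- sum(r2$setting != "outpatient")
  r3 <- r2[r2$setting == "outpatient", , drop = FALSE]
  eligible <- table(r3$arm_label)
  excl <- rowSums(as.matrix(r3[, exclusion_flag_cols])) > 0 | r3$age < 18
  r4 <- r3[!excl, , drop = FALSE]
  excluded_per_arm <- table(factor(r3$arm_label[excl], levels = names(eligible)))
  included <- table(factor(r4$arm_label, levels = names(eligible)))
  structure(list(counts = list(
    screened = n0,
    excluded_washout = n0 - nrow(r1),
    ogib = nrow(r2),
    inpatients_removed = inpat,
    eligible_per_arm = c(eligible),
    excluded_criteria_per_arm = c(excluded_per_arm),
    included_per_arm = c(included),
    included_total = nrow(r4)),
    included = r4), class = "screening_flow")
}

#' @export
print.screening_flow <- function(x, ...) {
  cts <- x$counts
  cat(sprintf(paste0("Screening flow: %d screened -> %d after washout -> ",
                     "%d OGIB -> %d outpatients -> %d included\n"),
              cts$screened, cts$screened - cts$excluded_washout, cts$ogib,
              cts$ogib - cts$inpatients_removed, cts$included_total))
  if (length(cts$included_per_arm))
    cat("Included per arm:",
        paste(names(cts$included_per_arm), cts$included_per_arm,
              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
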