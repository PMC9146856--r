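test_that("the screening roster reproduces the flow-chart strata", {
  roster <- generate_screening_roster(seed = 1)
  expect_equal(nrow(roster), 345)
  expect_equal(sum(roster$washout_period_flag), 18)
  post_washout <- roster[!roster$washout_period_flag, ]
  expect_equal(sum(post_washout$indication == "OGIB"), 266)
  ogib <- post_washout[post_washout$indication == "OGIB", ]
  expect_equal(sum(ogib$setting == "inpatient"), 122)
  expect_false(anyDuplicated(roster$patient_id) > 0)
})

test_that("sequential filters reproduce the inclusion counts", {
  flow <- apply_filters(generate_screening_roster(seed = 1))
  cts <- flow$counts
  expect_equal(cts$screened, 345)
  expect_equal(cts$excluded_washout, 18)
  expect_equal(cts$ogib, 266)
  expect_equal(cts$inpatients_removed, 122)
  expect_equal(unname(cts$eligible_per_arm[c("SMT-", "SMT+")]), c(66, 78))
  expect_equal(unname(cts$excluded_criteria_per_arm[c("SMT-", "SMT+")]),
               c(18, 21))
  expect_equal(unname(cts$included_per_arm[c("SMT-", "SMT+")]), c(48, 57))
  expect_equal(cts$included_total, 105)
  expect_equal(nrow(flow$included), 105)
})

test_that("flow counts do not depend on the roster seed", {
  a <- apply_filters(generate_screening_roster(seed = 1))$counts
  b <- apply_filters(generate_screening_roster(seed = 777))$counts
  expect_equal(a$included_per_arm, b$included_per_arm)
  expect_equal(a$ogib, b$ogib)
})

test_that("edge rosters filter cleanly", {
  empty <- generate_screening_roster(seed = 1)[0, ]
  flow <- apply_filters(empty)
  expect_equal(flow$counts$screened, 0)
  expect_equal(flow$counts$included_total, 0)

  five <- generate_screening_roster(seed = 1)
  five <- five[!five$washout_period_flag & five$indication == "OGIB" &
                 five$setting == "outpatient" & five$arm_label == "SMT-", ]
  five <- five[rowSums(five[, grep("_flag$", names(five))]) == 0, ][1:5, ]
  flow <- apply_filters(five)
  expect_equal(flow$counts$included_total, 5)
  expect_equal(unname(flow$counts$included_per_arm["SMT-"]), 5)
})

test_that("the included set equals the conjunction of all criteria", {
  # the sequential order only shapes the intermediate counts
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(20:60, 1)
    roster <- data.frame(
      patient_id = sprintf("R%02d", 1:n),
      setting = sample(c("outpatient", "inpatient"), n, replace = TRUE),
      indication = sample(c("OGIB", "other"), n, replace = TRUE),
      age = sample(15:90, n, replace = TRUE),
      washout_period_flag = runif(n) < 0.1,
      technical_defect_flag = runif(n) < 0.1,
      endoscopic_delivery_flag = runif(n) < 0.1,
      recent_CE_flag = runif(n) < 0.1,
      gastric_retention_flag = runif(n) < 0.1,
      active_bleeding_flag = runif(n) < 0.1,
      contraindication_flag = runif(n) < 0.1,
      arm_label = sample(c("SMT-", "SMT+"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    flow <- apply_filters(roster)
    keep <- !roster$washout_period_flag & roster$indication == "OGIB" &
      roster$setting == "outpatient" & roster$age >= 18 &
      !roster$technical_defect_flag & !roster$endoscopic_delivery_flag &
      !roster$recent_CE_flag & !roster$gastric_retention_flag &
      !roster$active_bleeding_flag & !roster$contraindication_flag
    expect_setequal(flow$included$patient_id, roster$patient_id[keep])
  }
})

test_that("missing flags are reported with the record id", {
  roster <- generate_screening_roster(seed = 1)
  roster$active_bleeding_flag[3] <- NA
  expect_error(apply_filters(roster),
               paste0("active_bleeding_flag.*", roster$patient_id[3]))
})
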