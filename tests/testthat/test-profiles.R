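test_that("the Type II boundary is exactly 30 percent, inclusive", {
  expect_identical(classify_profile(make_profile(random = 0.30))$label, "type_II")
  expect_identical(classify_profile(make_profile(random = 0.299))$label, "type_I")
  expect_identical(classify_profile(make_profile(random = 0))$label, "type_I")
  expect_identical(classify_profile(make_profile(random = 1))$label, "type_II")
  # exhaustive sweep in 1% steps: smallest Type II value is 30
  pct <- 0:100
  labels <- vapply(pct, function(x) {
    classify_profile(c(random = x / 100))$label
  }, character(1))
  expect_equal(min(pct[labels == "type_II"]), 30)
  expect_error(classify_profile(c(prototype = 0.9)), "random")
})

test_that("classification from counts equals classification from proportions", {
  # 9 of 30 random endorsements is exactly 30%
  trials <- make_task_trials("c1", 1, responses = c(rep(0, 30), rep(1, 9),
                                                    rep(0, 21)))
  prof <- profile_from_trials(trials)
  expect_equal(unname(unclass(prof)["random"]), 9 / 30)
  expect_identical(classify_profile(prof)$label, "type_II")
})

test_that("missing trials are dropped from the classification denominator", {
  miss <- c(rep(FALSE, 56), rep(TRUE, 4))  # last 4 random trials missing
  resp <- c(rep(1, 30), rep(1, 8), rep(0, 22))
  prof <- profile_from_trials(make_task_trials("c1", 1, resp, miss))
  expect_equal(unname(unclass(prof)["random"]), 8 / 26)
})

test_that("the missing-values exclusion fires above four missing trials", {
  five <- make_task_trials("drop", 1, c(rep(1, 30), rep(0, 30)),
                           missing = c(rep(TRUE, 5), rep(FALSE, 55)))
  four <- make_task_trials("keep", 1, c(rep(1, 30), rep(0, 30)),
                           missing = c(rep(TRUE, 4), rep(FALSE, 56)))
  out <- apply_exclusions(rbind(five, four))
  expect_false("drop" %in% out$retained$child_id)
  expect_true("keep" %in% out$retained$child_id)
  expect_equal(out$log$rule[out$log$child_id == "drop"], "missing_values")
})

test_that("strict left-right alternation across all tasks is excluded", {
  alt <- make_task_trials("alt", 1, rep(c(0, 1), 30))
  normal <- make_task_trials("ok", 1, c(rep(1, 35), rep(0, 25)))
  out <- apply_exclusions(rbind(alt, normal))
  expect_false("alt" %in% out$retained$child_id)
  expect_true("ok" %in% out$retained$child_id)
  expect_equal(out$log$rule[out$log$child_id == "alt"], "patterned_responding")

  # alternating in one task but not the other is retained
  mixed <- rbind(make_task_trials("m", 1, rep(c(0, 1), 30)),
                 make_task_trials("m", 2, c(rep(1, 30), rep(0, 30))))
  expect_true("m" %in% apply_exclusions(mixed)$retained$child_id)
})

test_that("exclusion then classification matches classifying retained records", {
  cohort <- generate_cohort(cohort_spec(n_children = 12, seed = 9,
                                        p_missing = 0.05))
  out <- apply_exclusions(cohort$trials)
  labs_after <- label_children(out$retained)
  labs_direct <- label_children(cohort$trials)
  kept <- unique(out$retained$child_id)
  expect_equal(labs_after,
               labs_direct[labs_direct$child_id %in% kept, ],
               ignore_attr = TRUE)
})

test_that("switch tables partition individuals by label stability", {
  labels <- list(a = c("type_I", "type_II"),
                 b = c("type_I", "type_I", "type_I", "type_I"),
                 c = c("type_II", "type_II"),
                 d = c("type_I", "type_II", "type_I", "type_II"))
  st <- switch_table(labels)
  expect_equal(unname(st$counts["switch"]), 2L)
  expect_equal(unname(st$counts["stay_I"]), 1L)
  expect_equal(unname(st$counts["stay_II"]), 1L)
  expect_equal(unname(st$counts["multiple_switches"]), 1L)
  # stay_I + stay_II + switch partitions the cohort
  expect_equal(sum(st$counts[c("switch", "stay_I", "stay_II")]),
               length(labels))
  expect_error(switch_table(list(a = "type_I")))
})

test_that("a cohort generated without switching never switches", {
  cohort <- generate_cohort(cohort_spec(n_children = 30, n_tasks = 3,
                                        p_switch = 0, p_missing = 0, seed = 2,
                                        profile_means = list(
                                          typical = stats::setNames(
                                            c(0.95, 0.9, 0.85, 0.8, 0.7, 0.6, 0.02),
                                            stimulus_classes()),
                                          atypical = stats::setNames(
                                            c(0.4, 0.4, 0.4, 0.4, 0.35, 0.35, 0.8),
                                            stimulus_classes()))))
  st <- switch_table(label_children(cohort$trials))
  expect_equal(unname(st$counts["switch"]), 0L)
  expect_equal(unname(st$counts["multiple_switches"]), 0L)
})
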