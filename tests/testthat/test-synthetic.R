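well_separated_means <- function() {
  list(typical = stats::setNames(c(0.90, 0.85, 0.80, 0.70, 0.60, 0.50, 0.10),
                                 stimulus_classes()),
       atypical = stats::setNames(c(0.35, 0.40, 0.35, 0.35, 0.30, 0.30, 0.50),
                                  stimulus_classes()))
}

test_that("cohort specs validate their probabilities and profile shapes", {
  expect_error(cohort_spec(p_typical = 1.2), "\\[0, 1\\]")
  bad_typ <- default_profile_means()
  bad_typ$typical["L3"] <- 0.95
  expect_error(cohort_spec(profile_means = bad_typ), "strictly decrease")
  bad_aty <- default_profile_means()
  bad_aty$atypical["random"] <- 0.2
  expect_error(cohort_spec(profile_means = bad_aty), ">= 0.30")
})

test_that("generated tasks have the canonical 60-trial structure", {
  cohort <- generate_cohort(cohort_spec(n_children = 4, n_tasks = 3, seed = 5))
  per_task <- split(cohort$trials, list(cohort$trials$child_id,
                                        cohort$trials$task_id))
  expect_length(per_task, 12L)
  for (tt in per_task) {
    expect_equal(nrow(tt), 60L)
    expect_equal(as.vector(table(factor(tt$class, stimulus_classes()))),
                 c(5, 5, 5, 5, 5, 5, 30))
  }
  # deterministic under the seed
  again <- generate_cohort(cohort_spec(n_children = 4, n_tasks = 3, seed = 5))
  expect_identical(cohort$trials, again$trials)
  expect_identical(cohort$latent, again$latent)
})

test_that("zero switching probability freezes the latent sequence", {
  cohort <- generate_cohort(cohort_spec(n_children = 25, n_tasks = 4,
                                        p_switch = 0, seed = 3))
  per_child <- split(cohort$latent$latent_profile, cohort$latent$child_id)
  expect_true(all(vapply(per_child,
                         function(l) length(unique(l)) == 1L, logical(1))))
})

test_that("classified Type II fraction recovers the mixture weight", {
  spec <- cohort_spec(n_children = 1000, n_tasks = 1, p_typical = 0.6,
                      p_missing = 0, seed = 8,
                      profile_means = well_separated_means())
  cohort <- generate_cohort(spec)
  labels <- label_children(cohort$trials)
  frac_II <- mean(labels$label == "type_II")
  se <- sqrt(0.4 * 0.6 / 1000)
  expect_lt(abs(frac_II - (1 - spec$p_typical)), 3 * se)
})

test_that("mixture and switching parameters are recovered within their CIs", {
  spec <- cohort_spec(n_children = 1000, n_tasks = 2, p_typical = 0.5,
                      p_switch = 0.36, p_missing = 0.02, seed = 13,
                      profile_means = well_separated_means())
  cohort <- generate_cohort(spec)
  est <- recover_parameters(cohort$trials)
  expect_true(est$p_typical$ci[1] <= 0.5 && 0.5 <= est$p_typical$ci[2])
  expect_true(est$p_switch$ci[1] <= 0.36 && 0.36 <= est$p_switch$ci[2])

  # estimates are invariant to the ordering of the trial rows
  shuffled <- cohort$trials[withr::with_seed(1, sample(nrow(cohort$trials))), ]
  est2 <- recover_parameters(shuffled)
  expect_equal(est2$p_typical$estimate, est$p_typical$estimate)
  expect_equal(est2$p_switch$estimate, est$p_switch$estimate)
})

test_that("a cohort without switching yields a zero switch estimate", {
  # profile means far from the 30% boundary, so labels carry no
  # classification noise and adjacent-task disagreement is exactly zero
  extreme <- list(
    typical = stats::setNames(c(0.95, 0.9, 0.85, 0.8, 0.7, 0.6, 0.02),
                              stimulus_classes()),
    atypical = stats::setNames(c(0.4, 0.4, 0.4, 0.4, 0.35, 0.35, 0.80),
                               stimulus_classes()))
  spec <- cohort_spec(n_children = 60, n_tasks = 2, p_switch = 0,
                      p_missing = 0, seed = 21, profile_means = extreme)
  est <- recover_parameters(generate_cohort(spec)$trials)
  expect_equal(est$p_switch$x, 0)
})

test_that("label recovery degrades as profiles approach the 30% boundary", {
  acc_at <- function(atypical_random) {
    means <- default_profile_means()
    means$atypical["random"] <- atypical_random
    spec <- cohort_spec(n_children = 300, n_tasks = 1, p_typical = 0.5,
                        p_missing = 0, seed = 31, profile_means = means)
    cohort <- generate_cohort(spec)
    labels <- label_children(cohort$trials)
    merged <- merge(labels, cohort$latent, by = c("child_id", "task_id"))
    mean((merged$label == "type_II") ==
           (merged$latent_profile == "atypical"))
  }
  accs <- vapply(c(0.60, 0.45, 0.34), acc_at, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_lt(accs[3], accs[1])
})

test_that("cohorts export to the tidy CSV format the classifier consumes", {
  cohort <- generate_cohort(cohort_spec(n_children = 3, seed = 2))
  tp <- withr::local_tempfile(fileext = ".csv")
  lp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, tp, lp)
  back <- read.csv(tp)
  expect_equal(nrow(back), nrow(cohort$trials))
  labels <- label_children(back)
  expect_true(all(labels$label %in% c("type_I", "type_II")))
  expect_equal(nrow(read.csv(lp)), nrow(cohort$latent))
})
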