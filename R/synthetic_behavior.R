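#' Default latent endorsement profiles for synthetic cohorts
#'
#' Synthetic stand-ins for the two characteristic performance profiles: the
#' typical profile has a steep generalization gradient (high prototype
#' endorsement declining to low foil endorsement) and the atypical profile
#' is flat and depressed with elevated foil endorsement. These digitize the
#' qualitative contrast between the two profile shapes; they are synthetic
#' defaults, not measured values.
#'
#' @return Named list with `typical` and `atypical` profiles (named numeric
#'   vectors over [stimulus_classes()]).
#' @export
default_profile_means <- function() {
  cls <- stimulus_classes()
  list(
    typical  = stats::setNames(c(0.90, 0.85, 0.80, 0.70, 0.60, 0.50, 0.10), cls),
    atypical = stats::setNames(c(0.35, 0.40, 0.35, 0.35, 0.30, 0.30, 0.45), cls)
  )
}

#' Specification of a synthetic behavioral cohort
#'
#' Defines the generative model for synthetic child-level test data: each
#' child draws a latent profile (typical with probability `p_typical`),
#' the latent profile may swap between consecutive tasks with probability
#' `p_switch`, and each of the 60 test trials of a task is endorsed by a
#' Bernoulli draw with the latent profile's class mean. Trials are missed
#' (timeout) i.i.d. with probability `p_missing`.
#'
#' @param n_children Number of children.
#' @param n_tasks Tasks per child (each with the canonical 60-trial test).
#' @param p_typical Mixture probability of the typical latent profile.
#' @param p_switch Per-task probability of swapping the latent profile.
#' @param profile_means List with `typical` and `atypical` class-mean
#'   vectors; the typical means must be strictly decreasing from prototype
#'   to random, and the atypical random-class mean must be at least 0.30.
#' @param p_missing Per-trial missing probability.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_children = 36L, n_tasks = 2L, p_typical = 0.5,
                        p_switch = 0.36,
                        profile_means = default_profile_means(),
                        p_missing = 0.02, seed = 1L) {
  probs <- c(p_typical, p_switch, p_missing,
             profile_means$typical, profile_means$atypical)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (any(diff(profile_means$typical[stimulus_classes()]) >= 0))
    stopf("typical profile means must strictly decrease from prototype to random")
  if (profile_means$atypical[["random"]] < 0.30)
    stopf("atypical profile's random-class mean must be >= 0.30")
  structure(list(n_children = as.integer(n_children),
                 n_tasks = as.integer(n_tasks),
                 p_typical = p_typical, p_switch = p_switch,
                 profile_means = profile_means, p_missing = p_missing,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Fully seed-deterministic. Each task's 60 trials follow the canonical test
#' composition (5 prototype, 5 each of L2/L3/L4/L5/L7, 30 random) in a
#' random presentation order.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: list with `trials` (tidy data frame:
#'   child_id, task_id, trial, class, response, missing) and `latent`
#'   (data frame: child_id, task_id, latent_profile -- the ground truth
#'   retained for recovery tests).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- test_class_counts()
  class_pool <- rep(names(counts), times = counts)
  withr::with_seed(spec$seed, {
    trials <- vector("list", spec$n_children * spec$n_tasks)
    latent <- vector("list", spec$n_children)
    k <- 0L
    for (ch in seq_len(spec$n_children)) {
      child_id <- sprintf("child_%03d", ch)
      prof <- if (runif(1) < spec$p_typical) "typical" else "atypical"
      lat <- character(spec$n_tasks)
      for (tk in seq_len(spec$n_tasks)) {
        if (tk > 1L && runif(1) < spec$p_switch)
          prof <- if (prof == "typical") "atypical" else "typical"
        lat[tk] <- prof
        cls <- sample(class_pool)
        means <- spec$profile_means[[prof]][cls]
        k <- k + 1L
        trials[[k]] <- data.frame(
          child_id = child_id, task_id = tk, trial = seq_len(60L),
          class = cls,
          response = rbinom(60L, 1L, means),
          missing = as.logical(rbinom(60L, 1L, spec$p_missing)),
          stringsAsFactors = FALSE)
      }
      latent[[ch]] <- data.frame(child_id = child_id,
                                 task_id = seq_len(spec$n_tasks),
                                 latent_profile = lat,
                                 stringsAsFactors = FALSE)
    }
    structure(list(trials = do.call(rbind, trials),
                   latent = do.call(rbind, latent),
                   spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d children x %d tasks (%d trials)\n",
              x$spec$n_children, x$spec$n_tasks, nrow(x$trials)))
  invisible(x)
}

#' Write a cohort to tidy CSV files
#'
#' Emits the trial table in the same format consumed by [apply_exclusions()]
#' and [label_children()], plus a sidecar CSV with the latent ground truth.
#'
#' @param cohort A `cohort`.
#' @param trials_path,latent_path Output CSV paths.
#' @return `trials_path`, invisibly.
#' @export
write_cohort <- function(cohort, trials_path, latent_path = NULL) {
  write.csv(cohort$trials, trials_path, row.names = FALSE)
  if (!is.null(latent_path))
    write.csv(cohort$latent, latent_path, row.names = FALSE)
  invisible(trials_path)
}

# Wilson-free simple binomial proportion CI (normal approximation would do,
# but the exact Clopper-Pearson interval from binom.test is available)
binom_ci <- function(x, n, level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(x, n, conf.level = level)$conf.int)
}

#' Recover cohort parameters from trial records
#'
#' Validation harness for the generative model: estimates `p_typical` from
#' the first-task Type I label frequency and `p_switch` from the frequency
#' of adjacent-task label disagreements, with exact binomial confidence
#' intervals. Labels are assigned by [classify_profile()], so estimates are
#' slightly attenuated by classification noise when the two profiles'
#' random-class means are close to the 30% boundary.
#'
#' @param trials Tidy trial table, e.g. `cohort$trials`.
#' @param level Confidence level.
#' @return List with `p_typical` and `p_switch`, each a list holding
#'   `estimate`, `ci` and the count/denominator used, plus `labels` (the
#'   per-child/task label table).
#' @export
recover_parameters <- function(trials, level = 0.95) {
  labels <- label_children(trials)
  if (max(table(labels$child_id)) < 2L)
    stopf("parameter recovery needs at least 2 tasks per child")
  first <- labels[!duplicated(labels$child_id), ]
  x_typ <- sum(first$label == "type_I")
  n_typ <- nrow(first)
  per_child <- split(labels, labels$child_id)
  changes <- vapply(per_child, function(d) {
    l <- d$label[order(d$task_id)]
    sum(l[-1] != l[-length(l)])
  }, numeric(1))
  pairs <- vapply(per_child, function(d) nrow(d) - 1L, integer(1))
  x_sw <- sum(changes)
  n_sw <- sum(pairs)
  list(
    p_typical = list(estimate = x_typ / n_typ, ci = binom_ci(x_typ, n_typ, level),
                     x = x_typ, n = n_typ),
    p_switch = list(estimate = x_sw / n_sw, ci = binom_ci(x_sw, n_sw, level),
                    x = x_sw, n = n_sw),
    labels = labels
  )
}
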