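#' Endorsement profile over the seven stimulus classes
#'
#' @param proportions Named numeric vector over the classes of
#'   [stimulus_classes()], each in \[0,1\].
#' @param n_trials Named integer vector of trials per class (defaults to the
#'   canonical 5/5/5/5/5/5/30 test composition).
#' @param source One of `"network"`, `"child"`, `"mixture"`.
#' @return An object of class `endorsement_profile` (a named numeric vector
#'   with attributes).
#' @export
endorsement_profile <- function(proportions, n_trials = test_class_counts(),
                                source = "network") {
  cls <- stimulus_classes()
  if (!setequal(names(proportions), cls))
    stopf("profile must be defined on exactly the 7 stimulus classes")
  proportions <- proportions[cls]
  if (any(!is.finite(proportions)) || any(proportions < 0 | proportions > 1))
    stopf("endorsement proportions must lie in [0, 1]")
  structure(proportions, class = "endorsement_profile",
            n_trials = n_trials[cls], source = source)
}

#' @export
print.endorsement_profile <- function(x, ...) {
  cat(sprintf("<endorsement_profile source=%s>\n", attr(x, "source")))
  print(round(unclass(x), 3))
  invisible(x)
}

# Encode every distinct stimulus of a regimen or test set at its blur level
# (test sets carry no blur column and are encoded unblurred). Returns a named
# list of 144-vectors keyed by stimulus id.
encode_manifest <- function(x) {
  blur <- if (!is.null(x$items$blur_level)) {
    stats::setNames(x$items$blur_level, x$items$stimulus_id)
  } else NULL
  out <- lapply(names(x$stimuli), function(id) {
    b <- if (is.null(blur)) "none" else blur[[id]]
    encode_vector(render(x$stimuli[[id]], blur_level = b))
  })
  stats::setNames(out, names(x$stimuli))
}

#' Build the shared stimulus battery for a set of simulations
#'
#' One prototype, one training manifest per regimen with its paired
#' 60-item test set, and their encodings, all derived deterministically from
#' the master seed. Every preset and replicate reuses this battery -- the
#' simulation analog of training all networks on one fixed stimulus set, so
#' that condition differences reflect learner parameters rather than
#' stimulus resampling.
#'
#' @param regimens Character vector of [regimen_names()].
#' @param master_seed Integer master seed.
#' @param schedule A [distortion_schedule()].
#' @param canvas A [canvas_spec()].
#' @return A list with `prototype` and per-regimen `cells` (regimen,
#'   test_set, and encoded inputs).
#' @export
build_sim_battery <- function(regimens, master_seed,
                              schedule = default_distortion_schedule(),
                              canvas = canvas_spec()) {
  seeds <- derive_seeds(master_seed, 1L + 2L * length(regimens))
  prototype <- generate_prototype(seeds[1], canvas)
  cells <- list()
  for (i in seq_along(regimens)) {
    rg <- build_regimen(regimens[i], prototype, schedule, seed = seeds[2 * i])
    ts <- build_test_set(prototype, schedule, rg, seed = seeds[2 * i + 1])
    cells[[regimens[i]]] <- list(
      regimen = rg, test_set = ts,
      train_enc = encode_manifest(rg), test_enc = encode_manifest(ts)
    )
  }
  list(prototype = prototype, cells = cells, master_seed = master_seed)
}

# seed streams for initial weights: one stream per simulated group, so the
# TD-group and ASD-group replicates use distinct random initial weight sets
group_weight_seeds <- function(master_seed, n_replicates) {
  s <- derive_seeds(master_seed + 1L, 2L)
  list(td = derive_seeds(s[1], n_replicates),
       asd = derive_seeds(s[2], n_replicates))
}

order_seeds_for <- function(master_seed, n_replicates) {
  derive_seeds(master_seed + 2L, n_replicates)
}

# Train, calibrate and test one replicate network on one regimen cell.
# Profiles are expected endorsement rates: the graded choice rule's
# endorsement probability averaged over the test items of each class.
run_replicate <- function(weight_seed, order_seed, cell, config) {
  net0 <- init_network(weight_seed, init_range = config$init_range)
  checksum <- sum(net0$W1) + sum(net0$W2)
  it <- cell$regimen$items
  expand <- rep(seq_len(nrow(it)), times = it$repeats)
  net <- train_network(net0, cell$train_enc[it$stimulus_id[expand]],
                       it$membership[expand], config,
                       order_seed = order_seed)
  member_ids <- it$stimulus_id[it$membership == "member"]
  foil_ids <- it$stimulus_id[it$membership == "nonmember"]
  rule <- calibrate_endorsement(net, cell$train_enc[member_ids],
                                cell$train_enc[foil_ids],
                                k = config$k, tau = config$tau,
                                baseline = net0)
  tt <- cell$test_set$items
  pr <- vapply(tt$stimulus_id, function(id) {
    endorse_probability(net, cell$test_enc[[id]], rule)
  }, numeric(1))
  props <- tapply(pr, factor(tt$class, levels = stimulus_classes()), mean)
  list(profile = endorsement_profile(stats::setNames(as.numeric(props),
                                                     stimulus_classes())),
       checksum = checksum)
}

#' Run one simulation condition
#'
#' Trains `n_replicates` networks under one preset and one training regimen
#' and returns their endorsement profiles over the 60-item test. All
#' replicates share one stimulus battery built from `master_seed`; replicate
#' i of a given group always starts from the same initial weights regardless
#' of the preset or regimen, enabling within-subject comparisons.
#'
#' @param preset Preset name (see [sim_config()]) or a `sim_config`.
#' @param regimen One of [regimen_names()].
#' @param n_replicates Number of replicate networks.
#' @param master_seed Integer master seed for stimuli, weights and
#'   presentation order.
#' @param schedule A [distortion_schedule()].
#' @param battery Optional precomputed [build_sim_battery()] result (must
#'   contain `regimen`); used to share stimuli across several calls.
#' @return A `condition_result`: list with `profiles` (replicate x class
#'   matrix), `mean_profile`, `se` (Monte-Carlo standard errors),
#'   `checksums`, `preset`, `regimen`.
#' @export
run_condition <- function(preset, regimen, n_replicates = 20L,
                          master_seed = 1L,
                          schedule = default_distortion_schedule(),
                          battery = NULL) {
  config <- if (inherits(preset, "sim_config")) preset else
    sim_config(preset, n_replicates = n_replicates)
  n_replicates <- as.integer(n_replicates)
  if (is.null(battery))
    battery <- build_sim_battery(regimen, master_seed, schedule)
  if (!regimen %in% names(battery$cells))
    stopf("battery does not contain regimen '%s'", regimen)
  wseeds <- group_weight_seeds(battery$master_seed, n_replicates)[[config$group]]
  oseeds <- order_seeds_for(battery$master_seed, n_replicates)
  cell <- battery$cells[[regimen]]
  reps <- lapply(seq_len(n_replicates), function(r) {
    tryCatch(run_replicate(wseeds[r], oseeds[r], cell, config),
             error = function(e) stopf("replicate %d: %s", r, conditionMessage(e)))
  })
  profiles <- do.call(rbind, lapply(reps, function(r) unclass(r$profile)))
  rownames(profiles) <- paste0("rep", seq_len(n_replicates))
  mean_p <- endorsement_profile(colMeans(profiles))
  se <- apply(profiles, 2, sd) / sqrt(n_replicates)
  structure(list(profiles = profiles, mean_profile = mean_p, se = se,
                 checksums = vapply(reps, `[[`, numeric(1), "checksum"),
                 preset = config$preset, regimen = regimen,
                 config = config),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result preset=%s regimen=%s n=%d>\n",
              x$preset, x$regimen, nrow(x$profiles)))
  print(round(unclass(x$mean_profile), 3))
  invisible(x)
}

#' Run the full preset-by-regimen simulation battery
#'
#' Every (preset, regimen) cell is run with the within-subject design:
#' replicate i of a group uses bit-identical initial weights in every cell,
#' and all cells share the stimulus battery built from `master_seed`.
#'
#' @param presets Character vector of preset names (see [sim_presets()]).
#' @param regimens Character vector of [regimen_names()].
#' @param n_replicates Replicates per cell.
#' @param master_seed Integer master seed.
#' @param schedule A [distortion_schedule()].
#' @return A `battery_result`: list with `results` (nested
#'   `[[preset]][[regimen]]` of `condition_result`), `table` (tidy data
#'   frame: preset, regimen, replicate, class, proportion) and `checksums`
#'   (data frame: preset, regimen, replicate, group, checksum).
#' @export
run_within_subject_battery <- function(presets, regimens, n_replicates = 20L,
                                       master_seed = 1L,
                                       schedule = default_distortion_schedule()) {
  battery <- build_sim_battery(regimens, master_seed, schedule)
  results <- list()
  rows <- list(); chk <- list()
  for (p in presets) {
    results[[p]] <- list()
    for (rg in regimens) {
      res <- run_condition(p, rg, n_replicates, master_seed,
                           schedule, battery = battery)
      results[[p]][[rg]] <- res
      rows[[paste(p, rg)]] <- data.frame(
        preset = p, regimen = rg,
        replicate = rep(seq_len(n_replicates), times = 7L),
        class = rep(stimulus_classes(), each = n_replicates),
        proportion = as.numeric(res$profiles),
        stringsAsFactors = FALSE
      )
      chk[[paste(p, rg)]] <- data.frame(
        preset = p, regimen = rg, replicate = seq_len(n_replicates),
        group = res$config$group, checksum = res$checksums,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(results = results,
                 table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 checksums = do.call(rbind, c(chk, make.row.names = FALSE)),
                 master_seed = master_seed),
            class = "battery_result")
}

#' Mixture of endorsement profiles
#'
#' Class-wise weighted average of component profiles with weights
#' proportional to component counts -- e.g. combining 7 typical-profile and
#' 6 atypical-profile networks into one group-level generalization pattern.
#'
#' @param components List of `endorsement_profile` objects.
#' @param counts Positive numeric vector, one count per component.
#' @return An `endorsement_profile` with `source = "mixture"`.
#' @export
mixture_profile <- function(components, counts) {
  stopifnot(length(components) == length(counts), all(counts > 0))
  mats <- do.call(rbind, lapply(components, function(p) {
    stopifnot(inherits(p, "endorsement_profile"))
    unclass(p)
  }))
  w <- counts / sum(counts)
  endorsement_profile(stats::setNames(as.numeric(crossprod(mats, w)),
                                      colnames(mats)),
                      source = "mixture")
}
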