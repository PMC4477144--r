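#' Group-by-class summary with bootstrap confidence intervals
#'
#' Computes per-group class means of endorsement proportions and seeded
#' bootstrap percentile intervals, plus the Type I vs Type II contrast on
#' pooled category-member endorsement (prototype through L7, i.e. excluding
#' the random class that defines the grouping).
#'
#' @param profiles Tidy data frame with columns `id` (child or replicate),
#'   `group`, `class`, `proportion`.
#' @param n_boot Bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return List with `means` (data frame: group, class, mean, lower, upper,
#'   n) and, when both `type_I` and `type_II` groups are present,
#'   `member_contrast` (list: estimate, lower, upper) for the Type I minus
#'   Type II difference in pooled member endorsement.
#' @export
summarize_groups <- function(profiles, n_boot = 1000L, level = 0.95,
                             seed = 1L) {
  need <- c("id", "group", "class", "proportion")
  stopifnot(all(need %in% names(profiles)))
  alpha <- (1 - level) / 2
  boot_seeds <- derive_seeds(seed, 2L)

  means <- withr::with_seed(boot_seeds[1], {
    out <- list()
    for (g in unique(profiles$group)) {
      for (cl in unique(profiles$class)) {
        v <- profiles$proportion[profiles$group == g & profiles$class == cl]
        if (length(v) == 0L) next
        bm <- vapply(seq_len(n_boot), function(i) {
          mean(v[sample.int(length(v), replace = TRUE)])
        }, numeric(1))
        out[[paste(g, cl)]] <- data.frame(
          group = g, class = cl, mean = mean(v),
          lower = as.numeric(quantile(bm, alpha)),
          upper = as.numeric(quantile(bm, 1 - alpha)),
          n = length(v), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })

  contrast <- NULL
  member_cls <- setdiff(stimulus_classes(), "random")
  if (all(c("type_I", "type_II") %in% profiles$group)) {
    pooled <- function(g) {
      d <- profiles[profiles$group == g & profiles$class %in% member_cls, ]
      tapply(d$proportion, d$id, mean)
    }
    a <- pooled("type_I"); b <- pooled("type_II")
    contrast <- withr::with_seed(boot_seeds[2], {
      bd <- vapply(seq_len(n_boot), function(i) {
        mean(a[sample.int(length(a), replace = TRUE)]) -
          mean(b[sample.int(length(b), replace = TRUE)])
      }, numeric(1))
      list(estimate = mean(a) - mean(b),
           lower = as.numeric(quantile(bd, alpha)),
           upper = as.numeric(quantile(bd, 1 - alpha)))
    })
  }
  list(means = means, member_contrast = contrast)
}

#' Plot generalization profiles
#'
#' Endorsement proportion by stimulus class, one line per group, one facet
#' per regimen when a `regimen` column is present -- the standard
#' generalization-gradient panel layout.
#'
#' @param means Data frame with columns `group`, `class`, `mean` and
#'   optionally `lower`/`upper` and `regimen`.
#' @return A ggplot object.
#' @export
plot_profiles <- function(means) {
  means$class <- factor(means$class, levels = stimulus_classes())
  p <- ggplot2::ggplot(means, ggplot2::aes(x = .data$class, y = .data$mean,
                                           group = .data$group,
                                           colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Stimulus class", y = "Endorsement proportion") +
    ggplot2::theme_minimal()
  if (!is.null(means$lower))
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                                 ymax = .data$upper),
                                    width = 0.15)
  if ("regimen" %in% names(means))
    p <- p + ggplot2::facet_wrap(~regimen)
  p
}

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (stimuli, regimens, network battery, profile
#'   classification) or `"cohort"` (synthetic behavioral cohort,
#'   exclusions, classification, switching).
#' @param seed Global seed; when `NULL` an auto-seed is drawn from the clock
#'   and logged in the manifest so the run can be replayed.
#' @param presets,regimens Battery cells for `mode = "simulate"`.
#' @param n_replicates Replicates per cell.
#' @param cohort A [cohort_spec()] for `mode = "cohort"` (its seed is
#'   overridden by the run seed).
#' @param n_boot Bootstrap resamples for group summaries.
#' @param plots Write PNG figures (requires a working png device).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "cohort"), seed = NULL,
                       presets = c("td", "asd_reduced_lr", "asd_nwd",
                                   "atypeII_single_epoch"),
                       regimens = c("repeated", "high_distortion", "blurry",
                                    "unique"),
                       n_replicates = 20L, cohort = cohort_spec(),
                       n_boot = 1000L, plots = FALSE) {
  structure(list(mode = match.arg(mode), seed = seed, presets = presets,
                 regimens = regimens, n_replicates = as.integer(n_replicates),
                 cohort = cohort, n_boot = as.integer(n_boot), plots = plots),
            class = "run_config")
}

config_digest <- function(config, dir) {
  cfg_path <- file.path(dir, "config.json")
  ser <- config
  ser$cohort <- unclass(ser$cohort)
  jsonlite::write_json(unclass(ser), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(cfg_path))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured pipeline and writes all artifacts into
#' `out_dir`: tidy profile/label/summary CSVs, optional PNG figures, and a
#' `manifest.json` recording the seed, the config hash and the package
#' version, so any output is traceable and the run can be reproduced
#' exactly.
#'
#' For `mode = "simulate"`: battery of presets x regimens
#' (`profiles.csv`, `mean_profiles.csv`, per-replicate labels in
#' `labels.csv`). For `mode = "cohort"`: synthetic cohort generation,
#' exclusions, per-task labels, switch table and group summary
#' (`trials.csv`, `labels.csv`, `switch_table.csv`, `summary.csv`,
#' `exclusions.csv`).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress progress messages.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(config$seed)) {
    config$seed <- as.integer(Sys.time()) %% 2147483647L
    say("no seed supplied; auto-seed %d (recorded in manifest)", config$seed)
  }
  seed <- config$seed

  if (config$mode == "simulate") {
    say("stage simulate: %d presets x %d regimens x %d replicates",
        length(config$presets), length(config$regimens), config$n_replicates)
    bat <- run_within_subject_battery(config$presets, config$regimens,
                                      config$n_replicates, master_seed = seed)
    write.csv(bat$table, file.path(out_dir, "profiles.csv"), row.names = FALSE)
    mean_tab <- stats::aggregate(proportion ~ preset + regimen + class,
                                 bat$table, mean)
    names(mean_tab)[names(mean_tab) == "proportion"] <- "mean"
    write.csv(mean_tab, file.path(out_dir, "mean_profiles.csv"),
              row.names = FALSE)
    say("stage classify: labeling replicate profiles")
    labs <- bat$table[bat$table$class == "random", ]
    labs$label <- vapply(labs$proportion, function(p) {
      classify_profile(c(random = p))$label
    }, character(1))
    write.csv(labs[, c("preset", "regimen", "replicate", "proportion",
                       "label")],
              file.path(out_dir, "labels.csv"), row.names = FALSE)
    if (config$plots) write_profile_plot(mean_tab, out_dir)
  } else {
    say("stage synth-cohort: %d children x %d tasks",
        config$cohort$n_children, config$cohort$n_tasks)
    spec <- config$cohort
    spec$seed <- seed
    cohort <- generate_cohort(spec)
    write_cohort(cohort, file.path(out_dir, "trials.csv"),
                 file.path(out_dir, "latent.csv"))
    say("stage classify: exclusions and per-task labels")
    excl <- apply_exclusions(cohort$trials)
    write.csv(excl$log, file.path(out_dir, "exclusions.csv"),
              row.names = FALSE)
    labels <- label_children(excl$retained)
    write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
    sw <- switch_table(labels)
    write.csv(data.frame(category = names(sw$counts),
                         n = as.integer(sw$counts)),
              file.path(out_dir, "switch_table.csv"), row.names = FALSE)
    say("stage report: group summary with bootstrap CIs")
    prof_rows <- list()
    for (i in seq_len(nrow(labels))) {
      tr <- excl$retained[excl$retained$child_id == labels$child_id[i] &
                            excl$retained$task_id == labels$task_id[i], ]
      pr <- profile_from_trials(tr)
      prof_rows[[i]] <- data.frame(
        id = paste(labels$child_id[i], labels$task_id[i], sep = "_"),
        group = labels$label[i], class = stimulus_classes(),
        proportion = as.numeric(pr), stringsAsFactors = FALSE)
    }
    prof_df <- do.call(rbind, prof_rows)
    summ <- summarize_groups(prof_df, n_boot = config$n_boot, seed = seed)
    write.csv(summ$means, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    if (config$plots) write_profile_plot(summ$means, out_dir)
  }

  manifest <- list(
    package = "protodist",
    version = as.character(packageVersion("protodist")),
    mode = config$mode,
    seed = seed,
    config_md5 = config_digest(config, out_dir),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  say("done: artifacts in %s", out_dir)
  invisible(out_dir)
}

write_profile_plot <- function(means, out_dir) {
  if (!capabilities("png")) return(invisible(NULL))
  if (!is.null(means$preset)) means$group <- means$preset
  p <- plot_profiles(means)
  try(ggplot2::ggsave(file.path(out_dir, "profiles.png"), p,
                      width = 8, height = 6, dpi = 120), silent = TRUE)
  invisible(NULL)
}

#' @importFrom rlang .data
NULL
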