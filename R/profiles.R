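#' Classify an endorsement profile as Type I or Type II
#'
#' A profile is labeled Type II iff the random-foil endorsement is 30% or
#' more (inclusive threshold); otherwise Type I. Type II profiles are the
#' atypical, flattened generalization patterns in which random shapes are
#' endorsed at rates approaching those of category members.
#'
#' @param profile An `endorsement_profile`, or any named numeric vector of
#'   proportions containing a `random` element.
#' @return An `atype_label`: list with `label` (`"type_I"`/`"type_II"`) and
#'   `random_endorsement_pct` (0-100).
#' @export
classify_profile <- function(profile) {
  p <- unclass(profile)
  if (!("random" %in% names(p)) || is.na(p[["random"]]))
    stopf("profile has no random-class endorsement proportion")
  pct <- 100 * p[["random"]]
  structure(list(label = if (pct >= 30) "type_II" else "type_I",
                 random_endorsement_pct = pct),
            class = "atype_label")
}

#' @export
print.atype_label <- function(x, ...) {
  cat(sprintf("<atype_label %s> random endorsement %.1f%%\n",
              x$label, x$random_endorsement_pct))
  invisible(x)
}

#' Endorsement profile from trial-level records
#'
#' Computes per-class endorsement proportions from one task's 60 test
#' trials. Missing trials are dropped, so the denominator for each class is
#' the number of answered trials of that class.
#'
#' @param trials Data frame with columns `class`, `response` (1 = endorsed,
#'   0 = rejected) and `missing` (logical or 0/1) for one child and task.
#' @return An `endorsement_profile` with `source = "child"`.
#' @export
profile_from_trials <- function(trials) {
  stopifnot(all(c("class", "response", "missing") %in% names(trials)))
  ans <- trials[!as.logical(trials$missing), , drop = FALSE]
  cls <- stimulus_classes()
  props <- vapply(cls, function(cl) {
    r <- ans$response[ans$class == cl]
    if (length(r) == 0L) NA_real_ else mean(r)
  }, numeric(1))
  n <- vapply(cls, function(cl) sum(ans$class == cl), integer(1))
  if (is.na(props[["random"]]))
    stopf("no answered random trials: profile cannot be classified")
  props[is.na(props)] <- 0
  endorsement_profile(props, n_trials = n, source = "child")
}

#' Apply the study's exclusion rules to trial-level records
#'
#' Two rules: (1) missing values -- a child is excluded if any of their tasks
#' has more than `max_missing` missing test trials (exactly `max_missing` is
#' retained); (2) patterned responding -- a child is excluded if, in every
#' task they completed, the answered test responses form a strict
#' member/non-member alternation (the keyboard's left-right alternation),
#' with at most `allowed_breaks` violations per task.
#'
#' @param trials Tidy trial table with columns `child_id`, `task_id`,
#'   `trial`, `class`, `response`, `missing`.
#' @param max_missing Maximum tolerated missing trials per task (default 4;
#'   "more than four" excludes).
#' @param allowed_breaks Alternation breaks tolerated while still counting a
#'   task as patterned (default 0, i.e. strict alternation).
#' @return List with `retained` (subset of `trials`) and `log` (data frame:
#'   child_id, rule, detail), one log row per exclusion.
#' @export
apply_exclusions <- function(trials, max_missing = 4L, allowed_breaks = 0L) {
  need <- c("child_id", "task_id", "trial", "class", "response", "missing")
  stopifnot(all(need %in% names(trials)))
  log <- list()
  drop <- character(0)
  for (ch in unique(trials$child_id)) {
    tr <- trials[trials$child_id == ch, , drop = FALSE]
    n_miss <- tapply(as.logical(tr$missing), tr$task_id, sum)
    if (any(n_miss > max_missing)) {
      drop <- c(drop, ch)
      log[[length(log) + 1L]] <- data.frame(
        child_id = ch, rule = "missing_values",
        detail = sprintf("%d missing trials in task %s",
                         max(n_miss), names(which.max(n_miss))),
        stringsAsFactors = FALSE)
      next
    }
    alternating <- vapply(split(tr, tr$task_id), function(tt) {
      tt <- tt[order(tt$trial), ]
      r <- tt$response[!as.logical(tt$missing)]
      length(r) >= 2L && sum(diff(r) == 0) <= allowed_breaks
    }, logical(1))
    if (length(alternating) > 0L && all(alternating)) {
      drop <- c(drop, ch)
      log[[length(log) + 1L]] <- data.frame(
        child_id = ch, rule = "patterned_responding",
        detail = "strict left-right alternation in every task",
        stringsAsFactors = FALSE)
    }
  }
  list(retained = trials[!trials$child_id %in% drop, , drop = FALSE],
       log = if (length(log)) do.call(rbind, log) else
         data.frame(child_id = character(0), rule = character(0),
                    detail = character(0), stringsAsFactors = FALSE))
}

#' Per-child, per-task profile labels from trial records
#'
#' @param trials Tidy trial table (see [apply_exclusions()]).
#' @return Data frame: child_id, task_id, random_endorsement_pct, label.
#' @export
label_children <- function(trials) {
  out <- list()
  for (ch in unique(trials$child_id)) {
    tr <- trials[trials$child_id == ch, , drop = FALSE]
    for (tk in unique(tr$task_id)) {
      cl <- classify_profile(profile_from_trials(tr[tr$task_id == tk, ]))
      out[[length(out) + 1L]] <- data.frame(
        child_id = ch, task_id = tk,
        random_endorsement_pct = cl$random_endorsement_pct,
        label = cl$label, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Tabulate within-individual profile switching
#'
#' Given each individual's ordered sequence of Type I/II labels across tasks,
#' counts who switched profile at least once, who stayed Type I, who stayed
#' Type II, and (among switchers with three or more tasks) who switched two
#' or more times. `stay_I + stay_II + switch` equals the number of
#' individuals; `multiple_switches` is the subset of switchers with two or
#' more label changes.
#'
#' @param labels Either a named list of per-individual label character
#'   vectors (ordered by task), or a data frame with columns `child_id`,
#'   `task_id`, `label` (ordered within child by `task_id`).
#' @return A `switch_table`: list with `counts` (named integer vector) and
#'   `per_child` (data frame: child_id, n_tasks, n_changes, category).
#' @export
switch_table <- function(labels) {
  if (is.data.frame(labels)) {
    labels <- lapply(split(labels, labels$child_id),
                     function(d) d$label[order(d$task_id)])
  }
  stopifnot(all(vapply(labels, length, integer(1)) >= 2L))
  per <- lapply(names(labels), function(ch) {
    l <- labels[[ch]]
    changes <- sum(l[-1] != l[-length(l)])
    cat_ <- if (changes == 0L) {
      if (l[1] == "type_I") "stay_I" else "stay_II"
    } else "switch"
    data.frame(child_id = ch, n_tasks = length(l), n_changes = changes,
               category = cat_, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  counts <- c(
    switch = sum(per$category == "switch"),
    stay_I = sum(per$category == "stay_I"),
    stay_II = sum(per$category == "stay_II"),
    multiple_switches = sum(per$n_changes >= 2L & per$n_tasks >= 3L)
  )
  structure(list(counts = counts, per_child = per), class = "switch_table")
}

#' @export
print.switch_table <- function(x, ...) {
  cat("<switch_table>\n")
  print(x$counts)
  invisible(x)
}
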