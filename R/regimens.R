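regimen_definitions <- function() {
  list(
    baseline        = list(members = c(L3 = 5L, L5 = 5L, L7 = 5L),
                           foils = 15L, repeats = 1L, blurred = FALSE),
    repeated        = list(members = c(L3 = 5L, L5 = 5L, L7 = 5L),
                           foils = 15L, repeats = 2L, blurred = FALSE),
    high_distortion = list(members = c(L3 = 4L, L5 = 5L, L7 = 6L),
                           foils = 15L, repeats = 2L, blurred = FALSE),
    blurry          = list(members = c(L3 = 5L, L5 = 5L, L7 = 5L),
                           foils = 15L, repeats = 2L, blurred = TRUE),
    unique          = list(members = c(L3 = 10L, L5 = 10L, L7 = 10L),
                           foils = 30L, repeats = 1L, blurred = FALSE)
  )
}

#' Regimen labels
#'
#' The five A/not-A training regimens: the standard baseline (every stimulus
#' shown once), and its four variants -- repeated (every stimulus twice),
#' high-distortion (member mix shifted toward high distortion levels),
#' blurry (stimuli at three reduced spatial-frequency strengths), and unique
#' (twice as many distinct stimuli, each shown once).
#'
#' @return Character vector of regimen names.
#' @export
regimen_names <- function() names(regimen_definitions())

#' Build a training regimen manifest
#'
#' Generates the training stimuli for the named regimen from a prototype:
#' member shapes are distortions of the prototype at the regimen's level mix,
#' non-members are independent random foils, and members and non-members each
#' make up half of the distinct training shapes.
#'
#' Compositions (distinct shapes): baseline and repeated, 5 each of L3/L5/L7
#' plus 15 foils; high-distortion, 4 L3 / 5 L5 / 6 L7 plus 15 foils; blurry,
#' 5/5/5 plus 15 foils with the 30 stimuli evenly divided across the three
#' blur strengths; unique, 10/10/10 plus 30 foils. Repeats are 2 for
#' repeated, high-distortion and blurry, otherwise 1.
#'
#' @param name One of [regimen_names()].
#' @param prototype A prototype `dot_pattern` defining the category.
#' @param schedule A [distortion_schedule()].
#' @param seed Integer seed controlling stimulus generation and blur
#'   assignment.
#' @return An object of class `regimen` with fields `name`, `items` (data
#'   frame: stimulus_id, class, membership, repeats, blur_level) and
#'   `stimuli` (named list of `dot_pattern`).
#' @export
build_regimen <- function(name, prototype,
                          schedule = default_distortion_schedule(), seed) {
  defs <- regimen_definitions()
  if (!name %in% names(defs)) stopf("unknown regimen '%s'", name)
  def <- defs[[name]]
  n_members <- sum(def$members)
  n_total <- n_members + def$foils
  seeds <- derive_seeds(seed, n_total + 1L)

  stimuli <- vector("list", n_total)
  class_lab <- character(n_total)
  k <- 0L
  for (lvl in names(def$members)) {
    for (i in seq_len(def$members[[lvl]])) {
      k <- k + 1L
      stimuli[[k]] <- distort(prototype, lvl, schedule, seed = seeds[k])
      class_lab[k] <- lvl
    }
  }
  for (i in seq_len(def$foils)) {
    k <- k + 1L
    stimuli[[k]] <- generate_random_foil(seeds[k], canvas = prototype$canvas)
    class_lab[k] <- "random"
  }
  ids <- vapply(stimuli, `[[`, character(1), "id")
  names(stimuli) <- ids

  blur <- rep("none", n_total)
  if (def$blurred) {
    # stimuli evenly divided across the three strengths, order seeded
    blur <- withr::with_seed(seeds[n_total + 1L],
                             sample(rep(c("low", "medium", "high"),
                                        length.out = n_total)))
  }
  items <- data.frame(
    stimulus_id = ids,
    class = class_lab,
    membership = ifelse(class_lab == "random", "nonmember", "member"),
    repeats = def$repeats,
    blur_level = blur,
    stringsAsFactors = FALSE
  )
  stopifnot(sum(items$membership == "member") ==
              sum(items$membership == "nonmember"))
  structure(list(name = name, items = items, stimuli = stimuli,
                 prototype_id = prototype$id, seed = as.integer(seed)),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen %s> %d distinct shapes (x%d), prototype %s\n",
              x$name, nrow(x$items), x$items$repeats[1], x$prototype_id))
  print(table(x$items$class))
  invisible(x)
}

#' Build the fixed 60-item generalization test set
#'
#' Five repetitions of the prototype, five new distortions at each of
#' L2/L3/L4/L5/L7, and 30 new random foils -- 60 test trials in total. No
#' test stimulus id appears in the paired training regimen; any collision is
#' resolved by regenerating the colliding stimulus from a fresh seed.
#'
#' @param prototype The prototype used to build `regimen`.
#' @param schedule A [distortion_schedule()].
#' @param regimen The paired training `regimen` (for the disjointness check).
#' @param seed Integer seed.
#' @return An object of class `test_set` with fields `items` (data frame of
#'   60 rows: stimulus_id, class) and `stimuli` (named list of distinct
#'   `dot_pattern`s, including the prototype once).
#' @export
build_test_set <- function(prototype, schedule = default_distortion_schedule(),
                           regimen, seed) {
  if (!identical(regimen$prototype_id, prototype$id))
    stopf("test set prototype does not match the regimen's category")
  train_ids <- regimen$items$stimulus_id
  counts <- test_class_counts()
  n_new <- sum(counts[distortion_levels()]) + counts[["random"]]
  seeds <- derive_seeds(seed, n_new)

  fresh <- function(make, s) {
    stim <- make(s)
    bump <- 0L
    while (stim$id %in% train_ids) {  # resample on id collision
      bump <- bump + 1L
      stim <- make(derive_seeds(s + bump, 1L))
    }
    stim
  }

  stimuli <- list()
  rows <- list(data.frame(stimulus_id = rep(prototype$id, counts[["prototype"]]),
                          class = "prototype", stringsAsFactors = FALSE))
  stimuli[[prototype$id]] <- prototype
  k <- 0L
  for (lvl in distortion_levels()) {
    for (i in seq_len(counts[[lvl]])) {
      k <- k + 1L
      stim <- fresh(function(s) distort(prototype, lvl, schedule, seed = s),
                    seeds[k])
      stimuli[[stim$id]] <- stim
      rows[[length(rows) + 1L]] <- data.frame(stimulus_id = stim$id,
                                              class = lvl,
                                              stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(counts[["random"]])) {
    k <- k + 1L
    stim <- fresh(function(s) generate_random_foil(s, canvas = prototype$canvas),
                  seeds[k])
    stimuli[[stim$id]] <- stim
    rows[[length(rows) + 1L]] <- data.frame(stimulus_id = stim$id,
                                            class = "random",
                                            stringsAsFactors = FALSE)
  }
  items <- do.call(rbind, rows)
  stopifnot(nrow(items) == 60L,
            !any(items$stimulus_id %in% train_ids))
  structure(list(items = items, stimuli = stimuli,
                 prototype_id = prototype$id, seed = as.integer(seed)),
            class = "test_set")
}

#' @export
print.test_set <- function(x, ...) {
  cat(sprintf("<test_set> 60 trials, prototype %s\n", x$prototype_id))
  print(table(x$items$class))
  invisible(x)
}

#' Write a regimen or test-set manifest to CSV
#'
#' @param x A `regimen` or `test_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  stopifnot(inherits(x, "regimen") || inherits(x, "test_set"))
  write.csv(x$items, path, row.names = FALSE)
  invisible(path)
}
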