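#' Canvas geometry for dot-pattern stimuli
#'
#' Stimuli live on a square canvas measured in grid units. Dots are placed on
#' integer grid positions inside a central placement region so that distorted
#' dots have room to move without leaving the canvas.
#'
#' @param size Side length of the canvas in grid units.
#' @param margin Width of the border excluded from initial dot placement, so
#'   dots are placed on the central `(size - 2*margin)^2` grid.
#' @return An object of class `canvas_spec`.
#' @export
canvas_spec <- function(size = 50, margin = 10) {
  if (size <= 2 * margin) stopf("canvas margin too large for size %s", size)
  structure(list(size = size, margin = margin), class = "canvas_spec")
}

new_dot_pattern <- function(points, origin_kind, level = NA_character_,
                            parent_id = NA_character_, id, seed, canvas) {
  stopifnot(is.matrix(points), nrow(points) == 9L, ncol(points) == 2L)
  colnames(points) <- c("x", "y")
  structure(
    list(points = points, origin_kind = origin_kind, level = level,
         parent_id = parent_id, id = id, seed = as.integer(seed),
         canvas = canvas),
    class = "dot_pattern"
  )
}

#' Validate a dot pattern
#'
#' Checks the structural invariants: exactly nine points, all coordinates on
#' the canvas, and consistency between origin kind and the level/parent
#' fields (distortions carry both, prototypes and random foils neither).
#'
#' @param pattern A `dot_pattern`.
#' @return The pattern, invisibly; errors if invalid.
#' @export
validate_dot_pattern <- function(pattern) {
  if (!inherits(pattern, "dot_pattern")) stopf("not a dot_pattern")
  p <- pattern$points
  if (nrow(p) != 9L) stopf("dot pattern must have exactly 9 points")
  sz <- pattern$canvas$size
  if (any(p < 0) || any(p > sz)) stopf("dot coordinates outside the canvas")
  if (pattern$origin_kind == "distortion") {
    if (is.na(pattern$level) || is.na(pattern$parent_id))
      stopf("distortion must carry a level and a parent_id")
  } else {
    if (!is.na(pattern$level) || !is.na(pattern$parent_id))
      stopf("%s pattern must not carry level/parent_id", pattern$origin_kind)
  }
  invisible(pattern)
}

# sample n distinct integer grid positions in the placement region
sample_grid_points <- function(n, canvas) {
  lo <- canvas$margin + 1L
  hi <- canvas$size - canvas$margin
  w <- hi - lo + 1L
  idx <- sample.int(w * w, n) - 1L
  cbind(x = lo + idx %% w, y = lo + idx %/% w)
}

#' Generate a category prototype
#'
#' Draws nine distinct dots uniformly at random from the integer grid of the
#' central placement region, in a sequential order that determines how the
#' dots are later connected into a closed polygon.
#'
#' @param seed Non-negative integer seed; the same seed always reproduces the
#'   same prototype.
#' @param canvas A [canvas_spec()].
#' @return A `dot_pattern` with `origin_kind = "prototype"`.
#' @export
generate_prototype <- function(seed, canvas = canvas_spec()) {
  stopifnot(is_count(seed + 1))
  pts <- withr::with_seed(as.integer(seed), sample_grid_points(9L, canvas))
  validate_dot_pattern(new_dot_pattern(
    pts, "prototype", id = sprintf("proto_s%d", as.integer(seed)),
    seed = seed, canvas = canvas
  ))
}

#' Generate a random foil
#'
#' A nine-dot pattern drawn independently of any prototype; a non-member of
#' every category.
#'
#' @inheritParams generate_prototype
#' @return A `dot_pattern` with `origin_kind = "random"`.
#' @export
generate_random_foil <- function(seed, canvas = canvas_spec()) {
  pts <- withr::with_seed(as.integer(seed), sample_grid_points(9L, canvas))
  validate_dot_pattern(new_dot_pattern(
    pts, "random", id = sprintf("rand_s%d", as.integer(seed)),
    seed = seed, canvas = canvas
  ))
}

#' Distortion schedule
#'
#' A distortion level is defined by a probability vector over concentric
#' displacement annuli. Annulus 1 is "no move"; annulus k displaces a dot by
#' a distance drawn uniformly from `[inner[k], outer[k])` in a uniformly
#' random direction. Higher levels put more mass on outer annuli, so the
#' expected displacement strictly increases over the level order.
#'
#' @param probs Numeric matrix, one row per level (rownames are the level
#'   labels in increasing-distortion order), one column per annulus; rows sum
#'   to 1.
#' @param inner,outer Inner and outer radii of the annuli in grid units;
#'   `inner[1]` and `outer[1]` must be 0 (the no-move annulus).
#' @return An object of class `distortion_schedule`.
#' @export
distortion_schedule <- function(probs, inner = c(0, 1, 2, 3, 4),
                                outer = c(0, 2, 3, 4, 6)) {
  stopifnot(is.matrix(probs), !is.null(rownames(probs)),
            ncol(probs) == length(inner), length(inner) == length(outer))
  if (inner[1] != 0 || outer[1] != 0) stopf("annulus 1 must be the no-move annulus")
  if (any(abs(rowSums(probs) - 1) > 1e-8)) stopf("annulus probabilities must sum to 1")
  if (any(probs < 0)) stopf("annulus probabilities must be non-negative")
  expected <- as.numeric(probs %*% ((inner + outer) / 2))
  if (any(diff(expected) <= 0))
    stopf("expected displacement must strictly increase over the level order")
  structure(list(probs = probs, inner = inner, outer = outer,
                 expected = stats::setNames(expected, rownames(probs))),
            class = "distortion_schedule")
}

#' Default distortion schedule
#'
#' Five annuli (no-move, then bands at 1-2, 2-3, 3-4 and 4-6 grid units) with
#' level-indexed probability vectors that increase the expected per-dot
#' displacement monotonically from L2 to L7.
#'
#' @return A [distortion_schedule()].
#' @export
default_distortion_schedule <- function() {
  probs <- rbind(
    L2 = c(0.65, 0.20, 0.10, 0.04, 0.01),
    L3 = c(0.45, 0.25, 0.15, 0.10, 0.05),
    L4 = c(0.30, 0.25, 0.20, 0.15, 0.10),
    L5 = c(0.15, 0.20, 0.25, 0.25, 0.15),
    L7 = c(0.05, 0.10, 0.20, 0.30, 0.35)
  )
  distortion_schedule(probs)
}

#' Read a distortion schedule from a YAML or JSON config file
#'
#' The file must define `probs` (a named map from level label to probability
#' vector) and optionally `inner`/`outer` annulus radii.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [distortion_schedule()].
#' @export
read_distortion_schedule <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  probs <- do.call(rbind, cfg$probs)
  args <- list(probs = probs)
  if (!is.null(cfg$inner)) args$inner <- as.numeric(cfg$inner)
  if (!is.null(cfg$outer)) args$outer <- as.numeric(cfg$outer)
  do.call(distortion_schedule, args)
}

# reflect coordinates into [0, size]
reflect_into <- function(v, size) {
  period <- 2 * size
  v <- v %% period
  ifelse(v > size, period - v, v)
}

#' Distort a prototype
#'
#' Each dot is independently displaced according to the level's annulus
#' distribution: an annulus is sampled from the level's probability vector,
#' then a displacement of uniform magnitude within the annulus is applied in
#' a uniformly random direction. Dot order (and hence polygon connectivity)
#' is preserved; dots pushed past the canvas edge are reflected back in.
#'
#' @param prototype A prototype `dot_pattern`.
#' @param level Level label present in the schedule (e.g. `"L3"`).
#' @param schedule A [distortion_schedule()].
#' @param seed Integer seed; deterministic per (prototype, level, seed).
#' @return A `dot_pattern` with `origin_kind = "distortion"`.
#' @export
distort <- function(prototype, level, schedule = default_distortion_schedule(),
                    seed) {
  validate_dot_pattern(prototype)
  if (prototype$origin_kind != "prototype")
    stopf("can only distort a prototype pattern")
  if (!level %in% rownames(schedule$probs))
    stopf("unknown distortion level '%s'", level)
  p <- schedule$probs[level, ]
  pts <- withr::with_seed(as.integer(seed), {
    ann <- sample.int(length(p), 9L, replace = TRUE, prob = p)
    mag <- runif(9L, schedule$inner[ann], schedule$outer[ann])
    mag[ann == 1L] <- 0
    theta <- runif(9L, 0, 2 * pi)
    prototype$points + cbind(mag * cos(theta), mag * sin(theta))
  })
  pts[, 1] <- reflect_into(pts[, 1], prototype$canvas$size)
  pts[, 2] <- reflect_into(pts[, 2], prototype$canvas$size)
  validate_dot_pattern(new_dot_pattern(
    pts, "distortion", level = level, parent_id = prototype$id,
    id = sprintf("%s_%s_s%d", prototype$id, level, as.integer(seed)),
    seed = seed, canvas = prototype$canvas
  ))
}

#' @export
print.dot_pattern <- function(x, ...) {
  cat(sprintf("<dot_pattern %s> kind=%s level=%s parent=%s\n",
              x$id, x$origin_kind, x$level, x$parent_id))
  invisible(x)
}

#' Tabulate dot patterns as a stimulus manifest
#'
#' One row per stimulus: id, origin kind, level, parent id, and the 18
#' coordinate columns `x1..x9`, `y1..y9`.
#'
#' @param patterns A list of `dot_pattern` objects.
#' @return A data frame.
#' @export
stimulus_manifest <- function(patterns) {
  rows <- lapply(patterns, function(p) {
    co <- as.numeric(rbind(p$points[, "x"], p$points[, "y"]))
    cf <- as.data.frame(t(co))
    names(cf) <- paste0(rep(c("x", "y"), 9), rep(1:9, each = 2))
    cbind(data.frame(id = p$id, origin_kind = p$origin_kind,
                     level = p$level, parent_id = p$parent_id,
                     stringsAsFactors = FALSE), cf)
  })
  do.call(rbind, rows)
}

#' Write / read a stimulus manifest CSV
#'
#' @param patterns List of `dot_pattern` objects.
#' @param path Output CSV path.
#' @return `write_stimulus_manifest` returns `path` invisibly;
#'   `read_stimulus_manifest` returns a list of `dot_pattern` objects.
#' @param canvas Canvas the coordinates refer to.
#' @export
write_stimulus_manifest <- function(patterns, path) {
  write.csv(stimulus_manifest(patterns), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_manifest
#' @export
read_stimulus_manifest <- function(path, canvas = canvas_spec()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    pts <- cbind(x = as.numeric(df[i, paste0("x", 1:9)]),
                 y = as.numeric(df[i, paste0("y", 1:9)]))
    new_dot_pattern(pts, df$origin_kind[i],
                    level = as.character(df$level[i]),
                    parent_id = as.character(df$parent_id[i]),
                    id = df$id[i], seed = NA_integer_, canvas = canvas)
  })
}
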