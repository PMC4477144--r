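blur_widths <- c(none = 0L, low = 3L, medium = 5L, high = 7L)

#' Render a dot pattern as a 12x12 feature matrix
#'
#' The nine dots, connected in their sequential order and closed back to the
#' first dot, define a (possibly self-intersecting) polygon filled by the
#' even-odd rule. The canvas is partitioned into a `grid` x `grid` array of
#' cells and each cell's activation is the fraction of the cell covered by
#' the filled shape, estimated on a regular `supersample` x `supersample`
#' sub-grid per cell. Row-major flattening of the matrix yields the
#' 144-element input vector of the network.
#'
#' Non-zero blur levels emulate reduced spatial frequency: the occupancy
#' matrix is smoothed with a normalized separable box kernel (widths 3, 5, 7
#' cells for low/medium/high) and rescaled to maximum 1.
#'
#' @param pattern A `dot_pattern`.
#' @param blur_level One of `"none"`, `"low"`, `"medium"`, `"high"`.
#' @param grid Cells per canvas side (12 gives the 144-node encoding).
#' @param supersample Sub-samples per cell side for occupancy estimation.
#' @return A `feature_matrix`: a `grid` x `grid` numeric matrix in \[0,1\]
#'   with attributes `blur_level` and `stimulus_id`.
#' @export
render <- function(pattern, blur_level = c("none", "low", "medium", "high"),
                   grid = 12L, supersample = 4L) {
  blur_level <- match.arg(blur_level)
  validate_dot_pattern(pattern)
  # collinear dots define a zero-area polygon that cannot be filled
  centered <- sweep(pattern$points, 2, colMeans(pattern$points))
  if (svd(centered)$d[2] < 1e-9)
    stopf("invalid stimulus: polygon '%s' has no interior area", pattern$id)
  size <- pattern$canvas$size
  n <- grid * supersample
  centers <- (seq_len(n) - 0.5) * size / n
  pts <- cbind(rep(centers, times = n), rep(centers, each = n))
  poly <- rbind(pattern$points, pattern$points[1L, , drop = FALSE])
  inside <- mgcv::in.out(poly, pts)
  fine <- matrix(inside, nrow = n, ncol = n)  # [x index, y index]
  occ <- matrix(0, grid, grid)
  for (i in seq_len(grid)) {
    xi <- ((i - 1L) * supersample + 1L):(i * supersample)
    for (j in seq_len(grid)) {
      yj <- ((j - 1L) * supersample + 1L):(j * supersample)
      occ[i, j] <- mean(fine[xi, yj])
    }
  }
  if (all(occ == 0))
    stopf("invalid stimulus: polygon '%s' has no interior area", pattern$id)
  if (blur_level != "none") {
    occ <- box_blur(occ, blur_widths[[blur_level]])
    if (max(occ) > 0) occ <- occ / max(occ)
  }
  structure(occ, class = "feature_matrix",
            blur_level = blur_level, stimulus_id = pattern$id)
}

# separable box filter with zero padding
box_blur <- function(m, width) {
  stopifnot(width %% 2 == 1)
  half <- (width - 1L) / 2L
  k <- rep(1 / width, width)
  smooth1 <- function(v) {
    padded <- c(rep(0, half), v, rep(0, half))
    as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, smooth1)
  t(apply(t(m), 2, smooth1))
}

#' Flatten a feature matrix to the network input vector
#'
#' Row-major flattening of the 12x12 matrix, giving the 144-element vector.
#'
#' @param fm A `feature_matrix`.
#' @return Numeric vector of length `nrow(fm) * ncol(fm)`.
#' @export
encode_vector <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  as.numeric(t(unclass(fm)))
}

#' Euclidean distance between two feature matrices
#'
#' @param a,b `feature_matrix` objects rendered at the same blur level.
#' @return Non-negative scalar; zero iff the matrices are identical.
#' @export
encoding_distance <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (!identical(attr(a, "blur_level"), attr(b, "blur_level")))
    stopf("cannot compare encodings at different blur levels")
  sqrt(sum((unclass(a) - unclass(b))^2))
}

#' Export feature matrices as a tidy CSV table
#'
#' One row per stimulus: id, blur level, then 144 value columns `v1..v144`
#' (row-major order).
#'
#' @param fms List of `feature_matrix` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrices <- function(fms, path) {
  rows <- lapply(fms, function(fm) {
    v <- as.data.frame(t(encode_vector(fm)))
    names(v) <- paste0("v", seq_along(v))
    cbind(data.frame(id = attr(fm, "stimulus_id"),
                     blur_level = attr(fm, "blur_level"),
                     stringsAsFactors = FALSE), v)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
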