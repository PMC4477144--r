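# shared fixtures built in code

# an endorsement profile with a given random-class proportion
make_profile <- function(random = 0.1, member = 0.8) {
  p <- stats::setNames(c(rep(member, 6), random), stimulus_classes())
  endorsement_profile(p)
}

# one child's trial table for a single task, canonical 60-trial structure
make_task_trials <- function(child_id, task_id, responses,
                             missing = rep(FALSE, 60)) {
  counts <- c(prototype = 5L, L2 = 5L, L3 = 5L, L4 = 5L, L5 = 5L, L7 = 5L,
              random = 30L)
  data.frame(child_id = child_id, task_id = task_id, trial = 1:60,
             class = rep(names(counts), times = counts),
             response = responses, missing = missing,
             stringsAsFactors = FALSE)
}

# a degenerate (collinear) nine-dot pattern, built through the internal
# constructor since the generators never produce one
collinear_pattern <- function() {
  pts <- cbind(x = seq(12, 36, length.out = 9), y = seq(12, 36, length.out = 9))
  protodist:::new_dot_pattern(pts, "prototype", id = "degenerate", seed = 0L,
                              canvas = canvas_spec())
}

# discrete Laplacian energy of a feature matrix (spatial roughness)
laplacian_energy <- function(m) {
  m <- unclass(m)
  n <- nrow(m)
  lap <- matrix(0, n, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    lap[i, j] <- m[i + 1, j] + m[i - 1, j] + m[i, j + 1] + m[i, j - 1] -
      4 * m[i, j]
  }
  sum(lap^2)
}

# fast small simulation config for orchestration tests
tiny_config <- function(...) {
  sim_config(learning_rate = 5e-05, epochs = 1L, n_replicates = 2L, ...)
}
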