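#' Initialize a feedforward auto-associator network
#'
#' A three-layer fully connected network (default 144-144-144) with logistic
#' sigmoid hidden and output units. Connection weights are drawn i.i.d.
#' uniform on `[-init_range, init_range]`; biases start at zero. The same
#' seed always reproduces the same initial state, which is what allows the
#' within-subject simulation design (one initial weight set reused across
#' every training condition for a given replicate).
#'
#' @param seed Integer seed for the weight draw.
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param init_range Half-width of the uniform initialization interval.
#' @return An object of class `category_net`.
#' @export
init_network <- function(seed, n_in = 144L, n_hidden = 144L, n_out = 144L,
                         init_range = 0.05) {
  w <- withr::with_seed(as.integer(seed), {
    list(W1 = matrix(runif(n_hidden * n_in, -init_range, init_range),
                     n_hidden, n_in),
         W2 = matrix(runif(n_out * n_hidden, -init_range, init_range),
                     n_out, n_hidden))
  })
  structure(list(W1 = w$W1, b1 = numeric(n_hidden),
                 W2 = w$W2, b2 = numeric(n_out),
                 dims = c(n_in = n_in, n_hidden = n_hidden, n_out = n_out),
                 init_seed = as.integer(seed)),
            class = "category_net")
}

#' @export
print.category_net <- function(x, ...) {
  cat(sprintf("<category_net %d-%d-%d> init_seed=%d\n",
              x$dims[1], x$dims[2], x$dims[3], x$init_seed))
  invisible(x)
}

# forward pass; returns hidden and output activations
net_forward <- function(net, x) {
  h <- plogis(as.numeric(net$W1 %*% x) + net$b1)
  y <- plogis(as.numeric(net$W2 %*% h) + net$b2)
  list(h = h, y = y)
}

#' Reconstruction error of a network on one pattern
#'
#' Squared reconstruction error `0.5 * sum((y - target)^2)` of the network
#' output against the training target (by default the input itself --
#' auto-association).
#'
#' @param net A `category_net`.
#' @param x Input vector (length `n_in`).
#' @param target Target vector (defaults to `x`).
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(net, x, target = x) {
  y <- net_forward(net, x)$y
  0.5 * sum((y - target)^2)
}

#' Analytic gradient of the reconstruction error
#'
#' Backpropagated gradient of `0.5 * sum((y - target)^2)` with respect to all
#' weights and biases.
#'
#' @inheritParams reconstruction_error
#' @return A list with components `W1`, `b1`, `W2`, `b2`.
#' @export
net_gradient <- function(net, x, target = x) {
  f <- net_forward(net, x)
  d2 <- (f$y - target) * f$y * (1 - f$y)
  d1 <- as.numeric(crossprod(net$W2, d2)) * f$h * (1 - f$h)
  list(W1 = d1 %*% t(x), b1 = d1, W2 = d2 %*% t(f$h), b2 = d2)
}

#' Simulation configuration
#'
#' Learner parameters for one simulated group. Named presets reproduce the
#' study conditions:
#' \describe{
#'   \item{td}{typical development: learning rate 5e-05, no weight decay,
#'     3 epochs}
#'   \item{asd_reduced_lr}{diminished synaptic plasticity: learning rate
#'     2.1e-05, no decay, 3 epochs}
#'   \item{asd_nwd}{diminished synaptic stability: learning rate 5e-05,
#'     negative weight decay -0.0007, 3 epochs}
#'   \item{atypeII_single_epoch}{atypical (Type II) profile: learning rate
#'     6e-04, single epoch}
#'   \item{atypeI_single_epoch}{typical (Type I) profile under single-epoch
#'     training: learning rate 0.1}
#'   \item{untrained}{learning rate 0 (no learning; calibration only)}
#' }
#' Presets starting with `asd` or `atypeII` draw initial weights from the
#' ASD-group seed stream; the others from the TD-group stream.
#'
#' @param preset Optional preset name; explicit arguments override preset
#'   values.
#' @param learning_rate Gradient step size (eta).
#' @param weight_decay Decay coefficient lambda in the update
#'   `w <- w - eta * dE/dw + lambda * w`; a negative value erodes weights on
#'   every update (see [train_network()]).
#' @param epochs Full passes over the repeat-expanded training manifest.
#' @param n_replicates Number of replicate networks.
#' @param k Calibration width for the member-only threshold (see
#'   [calibrate_endorsement()]).
#' @param tau Sensitivity of the graded endorsement rule, in familiarity
#'   units; shared by every preset.
#' @param init_range Initial weight interval half-width.
#' @param group Seed stream (`"td"` or `"asd"`) for initial weights.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(preset = NULL, learning_rate = NULL,
                       weight_decay = NULL, epochs = NULL,
                       n_replicates = 20L, k = 2, tau = 0.004,
                       init_range = 0.05, group = NULL) {
  presets <- list(
    td                   = list(learning_rate = 5e-05, weight_decay = 0,
                                epochs = 3L, group = "td"),
    asd_reduced_lr       = list(learning_rate = 2.1e-05, weight_decay = 0,
                                epochs = 3L, group = "asd"),
    asd_nwd              = list(learning_rate = 5e-05, weight_decay = -7e-04,
                                epochs = 3L, group = "asd"),
    atypeII_single_epoch = list(learning_rate = 6e-04, weight_decay = 0,
                                epochs = 1L, group = "asd"),
    atypeI_single_epoch  = list(learning_rate = 0.1, weight_decay = 0,
                                epochs = 1L, group = "td"),
    untrained            = list(learning_rate = 0, weight_decay = 0,
                                epochs = 1L, group = "td")
  )
  base <- list(learning_rate = 5e-05, weight_decay = 0, epochs = 3L,
               group = "td")
  if (!is.null(preset)) {
    if (!preset %in% names(presets)) stopf("unknown preset '%s'", preset)
    base <- presets[[preset]]
  }
  cfg <- list(
    preset = preset %||% "custom",
    learning_rate = learning_rate %||% base$learning_rate,
    weight_decay = weight_decay %||% base$weight_decay,
    epochs = as.integer(epochs %||% base$epochs),
    n_replicates = as.integer(n_replicates),
    k = k,
    tau = tau,
    init_range = init_range,
    group = group %||% base$group
  )
  if (cfg$epochs < 1L) stopf("epochs must be >= 1")
  if (cfg$n_replicates < 1L) stopf("n_replicates must be >= 1")
  if (cfg$learning_rate < 0) stopf("learning_rate must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Preset names for `sim_config`
#' @return Character vector.
#' @export
sim_presets <- function() {
  c("td", "asd_reduced_lr", "asd_nwd", "atypeII_single_epoch",
    "atypeI_single_epoch", "untrained")
}

#' Train a network on a regimen's encodings
#'
#' Online (per-pattern) gradient training. One epoch is one full pass over
#' the repeat-expanded training manifest in a seeded random order. Category
#' members are trained by auto-association (target = input encoding);
#' non-members contribute no associative target (they enter only through the
#' decision-rule calibration). Each member update applies
#' `w <- w - eta * dE/dw + lambda * w` to both weight matrices (biases take
#' the gradient step only). A negative decay coefficient therefore erodes
#' every weight toward zero on each update, continuously disrupting the
#' feedback-driven weight changes -- the model analog of diminished synaptic
#' stability.
#'
#' @param net A `category_net`.
#' @param inputs List of input vectors (repeat-expanded training patterns).
#' @param membership Character vector (`"member"`/`"nonmember"`), one per
#'   input.
#' @param config A [sim_config()].
#' @param order_seed Seed for the per-epoch presentation order.
#' @return The trained `category_net`.
#' @export
train_network <- function(net, inputs, membership, config, order_seed = 1L) {
  stopifnot(length(inputs) > 0L, length(inputs) == length(membership))
  eta <- config$learning_rate
  lambda <- config$weight_decay
  epoch_orders <- withr::with_seed(as.integer(order_seed), {
    lapply(seq_len(config$epochs), function(e) sample.int(length(inputs)))
  })
  for (e in seq_len(config$epochs)) {
    for (i in epoch_orders[[e]]) {
      if (membership[i] != "member") next
      x <- inputs[[i]]
      g <- net_gradient(net, x, target = x)
      net$W1 <- net$W1 - eta * g$W1 + lambda * net$W1
      net$b1 <- net$b1 - eta * g$b1
      net$W2 <- net$W2 - eta * g$W2 + lambda * net$W2
      net$b2 <- net$b2 - eta * g$b2
    }
    if (!all(is.finite(net$W1)) || !all(is.finite(net$W2)))
      stopf("training diverged: non-finite weights at epoch %d", e)
  }
  net
}

#' Familiarity of a stimulus under a trained network
#'
#' Without a baseline, familiarity is the negative reconstruction error.
#' With a baseline network (normally the same network's initial,
#' pre-training state), familiarity is the reduction in reconstruction
#' error achieved by training, `E_baseline - E_net`. The baseline-corrected
#' form isolates what the network has learned about a stimulus from how
#' well the stimulus happens to be reconstructed by chance: an untrained
#' network is exactly as familiar with every stimulus (familiarity 0).
#'
#' @param net A `category_net`.
#' @param x Input vector.
#' @param baseline Optional reference `category_net`.
#' @return Scalar familiarity.
#' @export
familiarity <- function(net, x, baseline = NULL) {
  e <- reconstruction_error(net, x)
  if (is.null(baseline)) -e else reconstruction_error(baseline, x) - e
}

#' Calibrate the endorsement rule
#'
#' The rule is fixed at the end of training, before the test phase. The
#' familiarity of every training member (and, when supplied, every training
#' non-member) is computed; the endorsement threshold is the midpoint
#' between the mean member and mean non-member familiarity when non-members
#' are given, or the mean member familiarity minus `k` standard deviations
#' otherwise. Non-members are part of the feedback-trained phase, so using
#' them in calibration mirrors the learner's exposure to both categories.
#'
#' `tau` is the sensitivity (softness) of the graded choice rule used by
#' [endorse_probability()]: familiarity margins are converted to endorsement
#' probabilities through a logistic function with scale `tau`. It is a fixed
#' property of the decision process, not re-fit per condition; the default
#' was calibrated once so that typically-developing networks under the
#' Repeated regimen endorse the prototype at a high rate and random foils at
#' a low rate, and is then held constant across all learner variants.
#'
#' @param net A trained `category_net`.
#' @param member_inputs List of the training members' input vectors.
#' @param foil_inputs Optional list of the training non-members' inputs.
#' @param k Threshold width in member-familiarity standard deviations (used
#'   only when `foil_inputs` is `NULL`).
#' @param tau Logistic sensitivity of the graded choice rule, in familiarity
#'   units.
#' @param baseline Optional pre-training network for baseline-corrected
#'   familiarity (see [familiarity()]).
#' @return An `endorsement_rule` with fields `threshold`, `tau`, `k`, `n`,
#'   `baseline`.
#' @export
calibrate_endorsement <- function(net, member_inputs, foil_inputs = NULL,
                                  k = 2, tau = 0.004, baseline = NULL) {
  stopifnot(length(member_inputs) > 0L)
  fam <- vapply(member_inputs,
                function(x) familiarity(net, x, baseline), numeric(1))
  threshold <- if (!is.null(foil_inputs)) {
    foil_fam <- vapply(foil_inputs,
                       function(x) familiarity(net, x, baseline), numeric(1))
    (mean(fam) + mean(foil_fam)) / 2
  } else {
    mean(fam) - k * (if (length(fam) > 1L) sd(fam) else 0)
  }
  structure(list(threshold = threshold, tau = tau, k = k,
                 n = length(fam), baseline = baseline),
            class = "endorsement_rule")
}

#' Endorse a test stimulus
#'
#' `endorse()` is the deterministic rule: the stimulus is endorsed as a
#' category member iff its familiarity reaches the calibrated threshold.
#' `endorse_probability()` is the graded choice rule used for simulated
#' endorsement rates: the familiarity margin is mapped through a logistic
#' function with the rule's sensitivity `tau` (`tau = 0` recovers the
#' deterministic step). Both are deterministic given weights and rule.
#'
#' @param net A `category_net`.
#' @param x Input vector of the test stimulus.
#' @param rule An `endorsement_rule` from [calibrate_endorsement()].
#' @return `endorse()`: list with `endorse` (logical) and `familiarity`
#'   (scalar). `endorse_probability()`: scalar endorsement probability.
#' @export
endorse <- function(net, x, rule) {
  if (!inherits(rule, "endorsement_rule") || is.na(rule$threshold))
    stopf("endorsement rule is not calibrated")
  fam <- familiarity(net, x, rule$baseline)
  list(endorse = fam >= rule$threshold, familiarity = fam)
}

#' @rdname endorse
#' @export
endorse_probability <- function(net, x, rule) {
  if (!inherits(rule, "endorsement_rule") || is.na(rule$threshold))
    stopf("endorsement rule is not calibrated")
  fam <- familiarity(net, x, rule$baseline)
  if (rule$tau <= 0) return(as.numeric(fam >= rule$threshold))
  plogis((fam - rule$threshold) / rule$tau)
}

#' Save / load network weights as CSV
#'
#' Plain-text weight dump: one long-format CSV with columns matrix, row,
#' col, value.
#'
#' @param net A `category_net`.
#' @param path CSV path.
#' @return `write_network` returns `path` invisibly; `read_network` a
#'   `category_net`.
#' @export
write_network <- function(net, path) {
  long <- function(m, name) {
    data.frame(matrix = name, row = c(row(m)), col = c(col(m)),
               value = c(m), stringsAsFactors = FALSE)
  }
  df <- rbind(long(net$W1, "W1"), long(as.matrix(net$b1), "b1"),
              long(net$W2, "W2"), long(as.matrix(net$b2), "b2"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  get_mat <- function(name) {
    d <- df[df$matrix == name, ]
    m <- matrix(0, max(d$row), max(d$col))
    m[cbind(d$row, d$col)] <- d$value
    m
  }
  W1 <- get_mat("W1"); W2 <- get_mat("W2")
  structure(list(W1 = W1, b1 = as.numeric(get_mat("b1")),
                 W2 = W2, b2 = as.numeric(get_mat("b2")),
                 dims = c(n_in = ncol(W1), n_hidden = nrow(W1),
                          n_out = nrow(W2)),
                 init_seed = NA_integer_),
            class = "category_net")
}
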