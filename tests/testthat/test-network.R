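test_that("initialization is seed-deterministic with near-zero mean weights", {
  n1 <- init_network(1)
  n2 <- init_network(1)
  n3 <- init_network(2)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$W2, n2$W2)
  expect_false(identical(n1$W1, n3$W1))
  expect_equal(dim(n1$W1), c(144L, 144L))
  # mean of 144^2 uniform(-0.05, 0.05) draws within 3 standard errors of 0
  se <- (0.05 / sqrt(3)) / sqrt(144^2)
  expect_lt(abs(mean(n1$W1)), 3 * se)
  expect_true(all(n1$b1 == 0) && all(n1$b2 == 0))
})

test_that("analytic gradient matches finite differences on a toy network", {
  net <- init_network(7, n_in = 3L, n_hidden = 3L, n_out = 3L)
  x <- c(0.2, 0.9, 0.4)
  target <- c(0.5, 0.1, 0.8)
  g <- net_gradient(net, x, target)
  eps <- 1e-6
  for (field in c("W1", "b1", "W2", "b2")) {
    analytic <- g[[field]]
    numeric_g <- array(0, dim = dim(as.matrix(net[[field]])))
    for (i in seq_along(net[[field]])) {
      up <- net; up[[field]][i] <- up[[field]][i] + eps
      dn <- net; dn[[field]][i] <- dn[[field]][i] - eps
      numeric_g[i] <- (reconstruction_error(up, x, target) -
                         reconstruction_error(dn, x, target)) / (2 * eps)
    }
    rel <- max(abs(analytic - numeric_g)) / max(abs(numeric_g))
    expect_lt(rel, 1e-5)
  }
})

test_that("a null update leaves the network unchanged", {
  net <- init_network(3)
  inputs <- lapply(1:5, function(i) runif(144))
  cfg <- sim_config(learning_rate = 0, weight_decay = 0, epochs = 2)
  out <- train_network(net, inputs, rep("member", 5), cfg)
  expect_identical(out$W1, net$W1)
  expect_identical(out$W2, net$W2)
})

test_that("negative weight decay erodes weights relative to no decay", {
  # paired across seeds: same data, same order, decay on vs off
  withr::with_seed(10, {
    inputs <- lapply(1:10, function(i) runif(144))
  })
  norms <- vapply(1:20, function(s) {
    net <- init_network(s)
    plain <- train_network(net, inputs, rep("member", 10),
                           sim_config(learning_rate = 5e-05, weight_decay = 0,
                                      epochs = 3), order_seed = s)
    nwd <- train_network(net, inputs, rep("member", 10),
                         sim_config(learning_rate = 5e-05,
                                    weight_decay = -7e-04, epochs = 3),
                         order_seed = s)
    norm(nwd$W1, "F") - norm(plain$W1, "F")
  }, numeric(1))
  expect_true(all(norms < 0))
})

test_that("training reduces reconstruction error on the training members", {
  proto <- generate_prototype(33)
  inputs <- lapply(1:6, function(s) encode_vector(render(distort(proto, "L3",
                                                                 seed = s))))
  net0 <- init_network(4)
  net <- train_network(net0, inputs, rep("member", 6), sim_config("td"))
  before <- mean(vapply(inputs, function(x) reconstruction_error(net0, x),
                        numeric(1)))
  after <- mean(vapply(inputs, function(x) reconstruction_error(net, x),
                       numeric(1)))
  expect_lt(after, before)
})

test_that("training signals divergence with the offending epoch", {
  inputs <- lapply(1:5, function(i) runif(144))
  cfg <- sim_config(learning_rate = 0, weight_decay = 1e3, epochs = 40)
  expect_error(
    train_network(init_network(1), inputs, rep("member", 5), cfg),
    "diverged.*epoch")
})

test_that("the endorsement rule is calibrated, deterministic and bounded", {
  net0 <- init_network(9)
  members <- lapply(1:6, function(i) runif(144))
  foils <- lapply(7:12, function(i) runif(144))
  net <- train_network(net0, members, rep("member", 6), sim_config("td"))
  rule <- calibrate_endorsement(net, members, foils, baseline = net0)
  x <- runif(144)
  d1 <- endorse(net, x, rule)
  d2 <- endorse(net, x, rule)
  expect_identical(d1, d2)
  expect_type(d1$endorse, "logical")
  p <- endorse_probability(net, x, rule)
  expect_true(p >= 0 && p <= 1)

  # familiarity of an untrained network relative to itself is exactly zero
  expect_equal(familiarity(net0, x, baseline = net0), 0)

  # degenerate thresholds
  inf_rule <- rule
  inf_rule$threshold <- Inf
  expect_false(endorse(net, x, inf_rule)$endorse)
  expect_equal(endorse_probability(net, x, inf_rule), 0)
  expect_error(endorse(net, x, list(threshold = 1)), "not calibrated")

  # member-only calibration uses the k-SD threshold
  r2 <- calibrate_endorsement(net, members, k = 2, baseline = net0)
  fam <- vapply(members, function(m) familiarity(net, m, net0), numeric(1))
  expect_equal(r2$threshold, mean(fam) - 2 * sd(fam))
})

test_that("after training, the prototype is more familiar than random foils", {
  proto <- generate_prototype(50)
  sch <- default_distortion_schedule()
  members <- lapply(1:15, function(s) {
    encode_vector(render(distort(proto, c("L3", "L5", "L7")[(s %% 3) + 1],
                                 sch, seed = s)))
  })
  proto_enc <- encode_vector(render(proto))
  foil_enc <- lapply(101:115, function(s)
    encode_vector(render(generate_random_foil(s))))
  diffs <- vapply(1:10, function(r) {
    net0 <- init_network(r)
    net <- train_network(net0, members, rep("member", 15), sim_config("td"),
                         order_seed = r)
    familiarity(net, proto_enc, net0) -
      mean(vapply(foil_enc, function(f) familiarity(net, f, net0), numeric(1)))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("network weights round-trip through the CSV dump", {
  net <- init_network(2, n_in = 5L, n_hidden = 4L, n_out = 5L)
  net$b1 <- runif(4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$W1, net$W1)
  expect_equal(back$W2, net$W2)
  expect_equal(back$b1, net$b1)
  x <- runif(5)
  expect_equal(reconstruction_error(back, x), reconstruction_error(net, x))
})
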