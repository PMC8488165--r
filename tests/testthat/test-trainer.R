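test_that("norm_label has the exact closed-form values and shape", {
  expect_identical(norm_label(0), 0)
  expect_equal(norm_label(0.2), 1 / 3, tolerance = 1e-15)
  expect_identical(norm_label(Inf), 1)
  d <- seq(0, 4, by = 0.01)
  v <- norm_label(d)
  expect_true(all(diff(v) > 0))          # strictly increasing
  # sup below 1 on finite input (checked within double-precision range;
  # beyond d ~ 10 the value is 1 to machine precision)
  expect_true(all(norm_label(seq(0, 8, by = 0.1)) < 1))
  # near-constant beyond 0.8 Angstrom: the analytic slope ratio there is
  # 4 * 2^-4 / (1 + 2^-4)^2 = 0.2215, and it keeps falling geometrically
  slope <- function(x) (norm_label(x + 1e-6) - norm_label(x)) / 1e-6
  expect_lt(slope(0.8), 0.25 * slope(0))
  expect_lt(slope(1.0), 0.15 * slope(0))
  expect_error(norm_label(-0.1), "must be >= 0")
})

test_that("instance_weight follows 1 + 1.5*amino + water", {
  expect_equal(instance_weight(0, 0), 1)
  expect_equal(instance_weight(2, 3), 7)
  expect_equal(instance_weight(1, 0), 2.5)
  expect_error(instance_weight(-1, 0), "non-negative")
})

test_that("static instances have the stated counts, labels and environments", {
  s <- generate_structure(fixture_spec(seed = 21))
  nw <- nrow(s$waters)
  cfg <- training_config(class_mix = c(1, 1, 1), seed = 4)
  set.seed(4)
  inst <- make_static_instances(s, cfg, sid = 1L)
  cls <- vapply(inst, `[[`, "", "class")
  expect_equal(sum(cls == "positive"), nw)
  expect_equal(sum(cls == "nearby_negative"), nw)
  expect_equal(sum(cls == "random_negative"), nw)
  W <- as.matrix(s$waters[, c("x", "y", "z")])
  for (b in inst) {
    if (b$class == "positive") {
      expect_identical(b$label, 0)
      expect_equal(nrow(b$waters), nw - 1)     # its own water removed
    } else if (b$class == "nearby_negative") {
      expect_lte(b$label, cfg$nearby_radius + 1e-12)
      # label equals the brute-force distance to the nearest crystal water
      dmin <- min(sqrt(rowSums((W - rep(b$probe, each = nw))^2)))
      expect_equal(b$label, dmin, tolerance = 1e-12)
    } else {
      expect_identical(b$label, Inf)
      expect_equal(nrow(b$waters), nw)          # full environment
      dmin <- min(sqrt(rowSums((W - rep(b$probe, each = nw))^2)))
      expect_gte(dmin, 2 * cfg$nearby_radius)
    }
    expect_gte(b$weight, 1)
  }
  expect_warning(make_static_instances(strip_waters(s), cfg), "no crystal waters")
})

test_that("leave-one-out negatives are labelled by brute-force nearest water", {
  s <- generate_structure(fixture_spec(seed = 22))
  p <- small_params()
  cfg <- training_config(seed = 1, class_mix = c(1, 1, 1))
  set.seed(1)
  batch <- make_static_instances(s, cfg, sid = 1L)
  loo <- make_leave_one_out_negatives(p, batch, list(s), cfg)
  n_pos <- sum(vapply(batch, `[[`, "", "class") == "positive")
  expect_lte(length(loo), n_pos)
  expect_gt(length(loo), 0)
  W <- as.matrix(s$waters[, c("x", "y", "z")])
  for (b in loo) {
    expect_identical(b$class, "leave_one_out")
    dmin <- min(sqrt(rowSums((W - rep(b$probe, each = nrow(W)))^2)))
    expect_equal(b$label, dmin, tolerance = 1e-12)
  }
})

test_that("end-to-end negatives carry nearest-crystal labels and staged environments", {
  s <- generate_structure(fixture_spec(seed = 23, n_scaffold_atoms = 6L))
  p <- small_params()
  pc <- placement_config(max_waters = 4)
  e2e <- make_end_to_end_negatives(p, s, pc, sid = 1L)
  W <- as.matrix(s$waters[, c("x", "y", "z")])
  expect_gt(length(e2e), 0)
  for (i in seq_along(e2e)) {
    b <- e2e[[i]]
    expect_identical(b$class, "end_to_end")
    dmin <- min(sqrt(rowSums((W - rep(b$probe, each = nrow(W)))^2)))
    expect_equal(b$label, dmin, tolerance = 1e-12)
    expect_gte(b$label, 0)
    expect_equal(nrow(b$waters), i - 1L)   # earlier predictions only
  }
})

test_that("the loss is the weighted squared error plus L2", {
  s <- generate_structure(fixture_spec(seed = 24))
  p <- small_params()
  cfg <- training_config(lambda_l2 = 0, seed = 2, class_mix = c(1, 1, 1))
  set.seed(2)
  inst <- make_static_instances(s, cfg, 1L)
  got <- training_loss(p, inst, list(s), cfg)
  manual <- 0
  for (b in inst) {
    env <- add_waters(strip_waters(s), b$waters)
    pred <- score_position(p, env, b$probe)$value
    manual <- manual + b$weight * (pred - norm_label(b$label))^2
  }
  expect_equal(got, manual, tolerance = 1e-10)
  # single-instance arithmetic: weight 7, predict against label Inf
  one <- inst[[1]]
  one$label <- Inf
  one$weight <- 7
  pred <- score_position(p, add_waters(strip_waters(s), one$waters),
                         one$probe)$value
  expect_equal(training_loss(p, list(one), list(s), cfg),
               7 * (pred - 1)^2, tolerance = 1e-10)
  # a zero-output head with zero labels gives exactly zero loss at lambda 0
  p0 <- p
  p0$output_head$W2[] <- 0
  zero_batch <- Filter(function(b) b$class == "positive", inst)
  expect_equal(training_loss(p0, zero_batch, list(s), cfg), 0)
  # lambda > 0 adds the parameter sum computed independently
  cfg2 <- training_config(lambda_l2 = 0.5, seed = 2)
  expect_equal(training_loss(p0, zero_batch, list(s), cfg2),
               0.5 * sum(unlist(p0[c("atom_embeddings", "bond_embeddings",
                                     "distance_term_net", "angle_term_net",
                                     "atom_reduce_net", "final_reduce_net",
                                     "output_head")])^2),
               tolerance = 1e-10)
})

test_that("training is deterministic, reduces the loss, and L2 shrinks parameters", {
  structures <- lapply(31:35, function(k)
    generate_structure(fixture_spec(seed = k, n_scaffold_atoms = 9L)))
  cfg <- training_config(epochs = 10L, seed = 7, end_to_end_period = 0L,
                         loo_steps = 4L)
  fit1 <- train_scorer(structures, cfg)
  fit2 <- train_scorer(structures, cfg)
  expect_identical(hydrosite:::flatten_params(fit1$params),
                   hydrosite:::flatten_params(fit2$params))
  expect_lt(fit1$log$loss[10], fit1$log$loss[1])
  # dominant regularization drags parameters toward zero
  cfg_l2 <- training_config(epochs = 30L, seed = 7, lambda_l2 = 1e6,
                            end_to_end_period = 0L, loo_steps = 0L)
  fit3 <- train_scorer(structures, cfg_l2)
  init <- scorer_params(widths = cfg_l2$widths, seed = cfg_l2$seed)
  expect_lt(mean(abs(hydrosite:::flatten_params(fit3$params))),
            0.3 * mean(abs(hydrosite:::flatten_params(init))))
})
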