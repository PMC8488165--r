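test_that("the fixture generator follows its deterministic water rule", {
  # no polar fragments, no waters
  s0 <- generate_structure(fixture_spec(polar_fraction = 0, seed = 3))
  expect_equal(nrow(s0$waters), 0)
  # zero jitter and zero angular tolerance: every water sits exactly at the
  # donor distance from its anchor oxygen (or from its partner water)
  sp <- fixture_spec(jitter_sigma = 0,
                     water_rule = list(distance = 2.8,
                                       angular_tolerance_deg = 0,
                                       second_shell_prob = 1.0),
                     seed = 6)
  s <- generate_structure(sp)
  O <- as.matrix(s$atoms[s$atoms$element == "O", c("x", "y", "z")])
  W <- as.matrix(s$waters[, c("x", "y", "z")])
  dO <- hydrosite:::.min_cross_dist(W, O)
  expect_true(all(abs(dO - 2.8) < 1e-6))
  # determinism
  expect_identical(generate_structure(sp), generate_structure(sp))
  # structures are valid: typed, bonded, symmetric adjacency
  expect_true(all(s$atoms$type_id >= 1))
  expect_true(all(s$bonds$i < s$bonds$j))
  expect_gte(min(hydrosite:::.min_cross_dist(
    W, as.matrix(s$atoms[, c("x", "y", "z")]))), 2.0)
})

test_that("fragment counts follow the spec fields", {
  sp <- fixture_spec(n_scaffold_atoms = 12L, polar_fraction = 0.5, seed = 9)
  s <- generate_structure(sp)
  expect_equal(nrow(s$atoms), 12)                      # 4 fragments x 3
  expect_equal(length(unique(s$atoms$resseq)), 4)
})

test_that("the analytic scorer is a Norm-squashed soft-min with exact minima", {
  s <- toy_structure()
  tg <- rbind(c(1, 2, 0), c(-3, 1, 2))
  an <- analytic_scorer(tg, temperature = 0.2)
  expect_lt(abs(analytic_score(an, s, tg[1, ])$value), 1e-6)
  expect_gt(analytic_score(an, s, c(50, 50, 50))$value, 0.999)
  # gradient vs finite differences
  set.seed(2)
  for (k in 1:5) {
    p <- rnorm(3, sd = 3)
    g <- analytic_score(an, s, p)$gradient
    fd <- fd_gradient(function(q) analytic_score(an, s, q)$value, p)
    expect_lt(max(abs(g - fd)), 1e-5)
  }
  # conditional targets activate only with a trigger water present
  cond <- analytic_scorer(tg[1, , drop = FALSE], temperature = 0.2,
                          conditional = list(list(target = c(4, 2, 0),
                                                  trigger = tg[1, ],
                                                  radius = 3)))
  expect_gt(score_at(cond, s, c(4, 2, 0))$value, 0.5)
  s_w <- add_waters(s, rbind(tg[1, ]))
  expect_lt(abs(score_at(cond, s_w, c(4, 2, 0))$value), 1e-6)
})
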