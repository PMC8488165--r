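test_that("polynn_forward evaluates the published layer formulas", {
  pp <- polynn_params(2, 3, 2)
  pp$W0[] <- 0
  expect_equal(polynn_forward(pp, c(1, 2)), c(0, 0))   # zeros propagate

  ident <- list(W0 = diag(1), b0 = 0, W1 = diag(1), W2 = diag(1))
  got <- polynn_forward(ident, 1)
  sw <- 1 / (1 + exp(-1))
  expect_equal(got, exp(log(1 + sw)) - 1)              # == Swish(1)
  expect_equal(got, sw, tolerance = 1e-12)

  # matches the straight-line oracle on random parameters
  set.seed(7)
  pp <- polynn_params(5, 6, 4)
  x <- rnorm(5)
  expect_equal(polynn_forward(pp, x), oracle_polynn(pp, x), tolerance = 1e-12)
})

test_that("Swish domain safety keeps the log-layer defined", {
  z <- seq(-50, 50, length.out = 10001)
  sw <- z / (1 + exp(-z))
  expect_true(min(sw) > -0.2785)
  expect_true(all(1 + sw > 0.72))
})

test_that("statistical_reduce pools sum/avg/max/std and is permutation invariant", {
  set.seed(1)
  net <- polynn_params(8, 6, 3)
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(statistical_reduce(net, X),
               polynn_forward(net, c(4, 6, 2, 3, 3, 4, 1, 1)))
  # single input: sum = avg = max, std = 0
  x <- c(0.3, -1.2)
  expect_equal(statistical_reduce(net, rbind(x)),
               polynn_forward(net, c(x, x, x, 0, 0)))
  # shuffling the input set leaves the output unchanged
  Y <- matrix(rnorm(14), 7, 2)
  expect_identical(statistical_reduce(net, Y),
                   statistical_reduce(net, Y[sample(7), ]))
})

test_that("distance and angle terms expose only invariant geometry", {
  p <- small_params()
  s <- toy_structure()
  a1 <- s$atoms[1, ]
  # equidistant probes give identical distance terms
  expect_identical(distance_term(p, a1, c(2, 0, 0)),
                   distance_term(p, a1, c(0, 2, 0)))
  # collinear and orthogonal probes hit cosine 1 / 0
  a2 <- s$atoms[2, ]
  t_collin <- angle_term(p, a1, a2, 1L, c(5, 0, 0))
  ref1 <- polynn_forward(p$angle_term_net,
                         c(p$atom_embeddings[a1$type_id, ],
                           p$atom_embeddings[a2$type_id, ],
                           p$bond_embeddings[1L, ], 1))
  expect_equal(t_collin, ref1, tolerance = 1e-12)
  t_orth <- angle_term(p, a1, a2, 1L, c(0, 2, 0))
  ref0 <- polynn_forward(p$angle_term_net,
                         c(p$atom_embeddings[a1$type_id, ],
                           p$atom_embeddings[a2$type_id, ],
                           p$bond_embeddings[1L, ], 0))
  expect_equal(t_orth, ref0, tolerance = 1e-12)
  # random geometry: cosine equals the dot-product computation
  set.seed(3)
  probe <- rnorm(3)
  u <- probe - c(a1$x, a1$y, a1$z)
  v <- c(a2$x, a2$y, a2$z) - c(a1$x, a1$y, a1$z)
  cth <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  refc <- polynn_forward(p$angle_term_net,
                         c(p$atom_embeddings[a1$type_id, ],
                           p$atom_embeddings[a2$type_id, ],
                           p$bond_embeddings[1L, ], cth))
  expect_equal(angle_term(p, a1, a2, 1L, probe), refc, tolerance = 1e-12)
  expect_error(angle_term(p, a1, a2, 1L, c(a1$x, a1$y, a1$z)), "degenerate")
})

test_that("interaction_embedding pools one distance term plus one angle term per bond", {
  p <- small_params()
  s <- toy_structure()
  probe <- c(1, 1.5, 0)
  got <- interaction_embedding(p, s, 1L, probe)
  manual <- statistical_reduce(
    p$atom_reduce_net,
    rbind(distance_term(p, s$atoms[1, ], probe),
          angle_term(p, s$atoms[1, ], s$atoms[2, ], s$bonds$bond_id[1], probe)))
  expect_equal(got, manual, tolerance = 1e-12)
  # a lone water contributes its distance term only
  sw <- add_waters(s, rbind(c(0, 3, 0)))
  gw <- interaction_embedding(p, sw, -1L, probe)
  w <- sw$waters[1, ]
  manual_w <- statistical_reduce(
    p$atom_reduce_net,
    rbind(distance_term(p, list(type_id = w$type_id,
                                position = c(w$x, w$y, w$z)), probe)))
  expect_equal(gw, manual_w, tolerance = 1e-12)
})

test_that("score has the empty-field contract and matches the R composition", {
  p <- small_params()
  s <- toy_structure()
  far <- score_position(p, s, c(100, 100, 100), gradient = TRUE)
  expect_equal(far$value, 1.0)
  expect_equal(far$gradient, c(0, 0, 0))
  # compiled path equals the oracle composition at random probes
  set.seed(11)
  g <- generate_structure(fixture_spec(seed = 8))
  for (k in 1:5) {
    probe <- as.numeric(g$waters[1, c("x", "y", "z")]) + rnorm(3, sd = 1)
    expect_equal(score_position(p, g, probe)$value, oracle_score(p, g, probe),
                 tolerance = 1e-10)
  }
})

test_that("score gradient matches finite differences and rotates covariantly", {
  p <- small_params()
  g <- generate_structure(fixture_spec(seed = 8))
  set.seed(5)
  probe <- as.numeric(g$waters[2, c("x", "y", "z")]) + rnorm(3, sd = 0.5)
  an <- score_gradient(p, g, probe)
  fd <- fd_gradient(function(q) score_position(p, g, q)$value, probe)
  expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-4)
  # covariance under rotation: grad(R system) = R grad(system)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  gr <- g
  gr$atoms[, c("x", "y", "z")] <-
    as.matrix(g$atoms[, c("x", "y", "z")]) %*% t(R)
  gr$waters[, c("x", "y", "z")] <-
    as.matrix(g$waters[, c("x", "y", "z")]) %*% t(R)
  gr$env <- hydrosite:::.build_env(gr)
  an_rot <- score_gradient(p, gr, as.numeric(R %*% probe))
  expect_equal(an_rot, as.numeric(R %*% an), tolerance = 1e-6)
})

test_that("checkpoints round-trip parameters exactly", {
  p <- small_params(seed = 9)
  f <- tempfile(fileext = ".json")
  save_checkpoint(p, f)
  q <- load_checkpoint(f)
  expect_equal(hydrosite:::flatten_params(q), hydrosite:::flatten_params(p),
               tolerance = 1e-14)
  s <- toy_structure()
  # JSON text round-trips to the last printed digit (~1 ulp)
  expect_equal(score_position(q, s, c(1, 1, 1))$value,
               score_position(p, s, c(1, 1, 1))$value, tolerance = 1e-10)
  expect_error(load_checkpoint(tempfile()), ".")
})
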