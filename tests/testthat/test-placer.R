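test_that("build_grid spans the padded box and deactivates clash/vacuum boxes", {
  at <- data.frame(serial = 1L, name = "C1", element = "C", x = 0, y = 0,
                   z = 0, resname = "NON", chain = "A", resseq = 1L,
                   is_ligand = FALSE, hyb = "sp3", aromatic = FALSE)
  s <- protein_structure(at, id = "one")
  s$bonds <- data.frame(i = integer(), j = integer(), order = character())
  s <- assign_types(s)
  cfg <- placement_config()
  g <- build_grid(s, cfg, receptive_radius = 4.0)
  expect_equal(length(unique(g$cx)), ceiling(8 / 0.8) + 1)   # 11 per axis
  expect_equal(nrow(g), 11^3)
  d <- sqrt(g$cx^2 + g$cy^2 + g$cz^2)
  expect_false(any(g$active[d < cfg$clash_distance]))   # clash rule
  expect_false(any(g$active[d > 4.0]))                  # vacuum rule
  expect_true(all(g$active[d >= cfg$clash_distance & d <= 4.0]))
})

test_that("optimize_box descends into an analytic minimum", {
  s <- toy_structure()
  target <- c(1.5, 2.0, 0.3)
  an <- analytic_scorer(rbind(target), temperature = 0.2)
  cfg <- placement_config()
  box <- list(cx = 1.2, cy = 2.2, cz = 0.1, ox = NA, oy = NA, oz = NA,
              score = NA)
  out <- optimize_box(an, s, box, cfg)
  expect_lt(sqrt(sum((c(out$ox, out$oy, out$oz) - target)^2)), 0.05)
  center_score <- score_at(an, s, c(box$cx, box$cy, box$cz))$value
  expect_lte(out$score, center_score)   # descent contract
  # a flat scorer leaves the start untouched
  flat <- analytic_scorer(matrix(numeric(0), 0, 3))
  out2 <- optimize_box(flat, s, box, cfg)
  expect_equal(c(out2$ox, out2$oy, out2$oz), c(box$cx, box$cy, box$cz))
})

test_that("iterative placement is best-first, deduplicated and threshold-bounded", {
  s <- toy_structure()
  # an above-threshold field everywhere places nothing
  none <- analytic_scorer(matrix(numeric(0), 0, 3))
  res0 <- place_waters(none, s, placement_config())
  expect_equal(nrow(res0$waters), 0)
  expect_equal(res0$rounds, 1)
  # one minimum between adjacent boxes is accepted exactly once
  one <- analytic_scorer(rbind(c(1.4, 1.9, 0)), temperature = 0.2)
  res1 <- iterative_place(one, s, placement_config())
  expect_equal(nrow(res1$waters), 1)
  expect_lt(sqrt(sum((as.numeric(res1$waters[1, 1:3]) - c(1.4, 1.9, 0))^2)),
            0.1)
  # accepted scores are non-decreasing under a static field
  three <- analytic_scorer(rbind(c(1.5, 2.5, 0), c(1.5, -2.5, 0.5),
                                 c(-2, 0, 1)), temperature = 0.2)
  res3 <- iterative_place(three, s, placement_config())
  expect_equal(nrow(res3$waters), 3)
  # non-decreasing up to the optimizer's convergence tolerance (warm-started
  # re-optimization can polish a later box below an earlier accepted score)
  expect_true(all(diff(res3$waters$score) >= -1e-4))
})

test_that("refinement is a fixed point at minima and prunes planted spurious waters", {
  s <- toy_structure()
  cfg <- placement_config()
  tg <- rbind(c(1.5, 2.5, 0), c(-2, 0, 1))
  an <- analytic_scorer(tg, temperature = 0.2)
  expect_equal(nrow(refine_waters(an, s, matrix(numeric(0), 0, 3), cfg)$waters), 0)
  ref <- refine_waters(an, s, tg, cfg)
  expect_equal(nrow(ref$waters), 2)
  expect_lt(max(hydrosite:::.min_cross_dist(ref$waters, tg)), 1e-3)
  # a planted third water with no minimum under it is resampled away
  planted <- rbind(tg, c(1.5, 5.3, 0))
  ref2 <- refine_waters(an, s, planted, cfg)
  expect_equal(nrow(ref2$waters), 2)
  expect_lt(max(hydrosite:::.min_cross_dist(ref2$waters, tg)), 0.05)
})

test_that("place_waters recovers hidden minima, respects invariants and is deterministic", {
  s <- toy_structure()
  cfg <- placement_config()
  targets <- rbind(c(1.5, 2.5, 0), c(1.5, -2.5, 0.5), c(-2, 0, 1),
                   c(4.5, 1.5, -1.5), c(-1, -2.5, -1.5))
  an <- analytic_scorer(targets, temperature = 0.2)
  res <- place_waters(an, s, cfg)
  P <- as.matrix(res$waters[, 1:3])
  expect_equal(nrow(P), 5)
  for (k in seq_len(5)) {
    expect_lt(min(hydrosite:::.min_cross_dist(matrix(targets[k, ], 1, 3), P)),
              0.1)
  }
  # pairwise exclusion and clash invariants
  expect_gte(min(dist(P)), cfg$min_water_distance)
  A <- as.matrix(s$atoms[, c("x", "y", "z")])
  expect_gte(min(hydrosite:::.min_cross_dist(P, A)), cfg$clash_distance)
  expect_true(all(res$waters$score <= cfg$score_threshold))
  # bit-identical across runs
  res2 <- place_waters(an, s, cfg)
  expect_identical(res$waters, res2$waters)
})

test_that("water-network minima are revealed iteratively by conditional targets", {
  s <- toy_structure()
  t1 <- c(1.5, 2.5, 0)
  t2 <- t1 + c(2.8, 0, 0)
  an <- analytic_scorer(rbind(t1), temperature = 0.2,
                        conditional = list(list(target = t2, trigger = t1,
                                                radius = 3.0)))
  # without the first water the second site scores poorly
  expect_gt(score_at(an, s, t2)$value, 0.5)
  res <- place_waters(an, s, placement_config())
  P <- as.matrix(res$waters[, 1:3])
  expect_equal(nrow(P), 2)
  expect_lt(min(hydrosite:::.min_cross_dist(matrix(t1, 1, 3), P)), 0.1)
  expect_lt(min(hydrosite:::.min_cross_dist(matrix(t2, 1, 3), P)), 0.1)
})
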