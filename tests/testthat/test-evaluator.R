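test_that("match_waters enforces one-to-one matching within the cutoff", {
  crystal <- rbind(c(0, 0, 0))
  predicted <- rbind(c(0.4, 0, 0), c(0, 0.2, 0))
  m <- match_waters(crystal, predicted, 0.5)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$predicted, 2)   # the nearer one
  # disjoint sets beyond the cutoff match nothing
  m0 <- match_waters(rbind(c(0, 0, 0)), rbind(c(5, 5, 5)), 1.5)
  expect_equal(nrow(m0$pairs), 0)
  expect_equal(m0$unmatched_crystal, 1L)
  expect_equal(m0$unmatched_predicted, 1L)
})

test_that("optimal matching equals the exhaustive oracle on random instances", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(2:7, 1)
    m <- sample(2:8, 1)
    crystal <- matrix(runif(n * 3, 0, 4), n, 3)
    predicted <- matrix(runif(m * 3, 0, 4), m, 3)
    for (cutoff in c(0.5, 1.0, 1.5)) {
      got <- match_waters(crystal, predicted, cutoff)
      ora <- oracle_match(crystal, predicted, cutoff)
      expect_equal(nrow(got$pairs), ora$count)
      if (ora$count > 0)
        expect_equal(sum(got$pairs$distance), ora$dist, tolerance = 1e-9)
      # every pair honours the cutoff and indices are one-to-one
      expect_true(all(got$pairs$distance <= cutoff))
      expect_false(any(duplicated(got$pairs$crystal)))
      expect_false(any(duplicated(got$pairs$predicted)))
    }
    # TP monotone in the cutoff
    tps <- vapply(c(0.5, 1.0, 1.5),
                  function(ct) nrow(match_waters(crystal, predicted, ct)$pairs),
                  0L)
    expect_true(all(diff(tps) >= 0))
  }
})

test_that("metrics follow the precision/recall/F1 definitions exactly", {
  fake <- function(tp, np, nc) {
    structure(list(cutoff = 1, pairs = data.frame(crystal = seq_len(tp),
                                                  predicted = seq_len(tp),
                                                  distance = numeric(tp)),
                   n_crystal = nc, n_predicted = np),
              class = "match_result")
  }
  m <- water_metrics(fake(5, 10, 10))
  expect_equal(c(m$precision, m$recall, m$f1), c(0.5, 0.5, 0.5))
  m2 <- water_metrics(fake(0, 10, 10))
  expect_equal(c(m2$precision, m2$recall, m2$f1), c(0, 0, 0))
  m3 <- water_metrics(fake(3, 4, 6))
  expect_equal(c(m3$precision, m3$recall, m3$f1), c(0.75, 0.5, 0.6))
  # pooled identities: precision * n_predicted == recall * n_crystal == TP
  set.seed(5)
  crystal <- matrix(runif(18), 6, 3) * 4
  predicted <- matrix(runif(15), 5, 3) * 4
  mm <- water_metrics(match_waters(crystal, predicted, 1.0))
  expect_identical(mm$precision * mm$n_predicted, as.numeric(mm$tp))
  expect_identical(mm$recall * mm$n_crystal, as.numeric(mm$tp))
  # swapping the sets swaps precision and recall
  sw <- water_metrics(match_waters(predicted, crystal, 1.0))
  expect_equal(sw$precision, mm$recall)
  expect_equal(sw$recall, mm$precision)
})

test_that("binding-site filter keeps waters near both protein and ligand", {
  s <- assign_types(perceive_bonds(parse_pdb(sample_pdb_text())))
  lig <- as.matrix(s$atoms[s$atoms$is_ligand, c("x", "y", "z")])
  prot <- as.matrix(s$atoms[!s$atoms$is_ligand, c("x", "y", "z")])
  near_both <- (lig[1, ] + prot[1, ]) / 2   # LIG C1 and GLY N are ~12 A apart
  pos <- rbind(prot[1, ] + c(1, 0, 0),      # near protein only
               lig[1, ] + c(1, 0, 0),       # near ligand only
               near_both)
  kept <- binding_site_filter(s, pos)
  d_p <- hydrosite:::.min_cross_dist(pos, prot)
  d_l <- hydrosite:::.min_cross_dist(pos, lig)
  expect_equal(unname(kept), unname(pos[d_p <= 4 & d_l <= 4, , drop = FALSE]))
  # random fixtures against the brute-force double scan
  set.seed(8)
  rnd <- matrix(runif(60, 0, 16), 20, 3)
  kept2 <- binding_site_filter(s, rnd)
  man <- rnd[hydrosite:::.min_cross_dist(rnd, prot) <= 4 &
               hydrosite:::.min_cross_dist(rnd, lig) <= 4, , drop = FALSE]
  expect_equal(kept2, man)
  # structures without a ligand direct the caller to whole-structure mode
  g <- generate_structure(fixture_spec(seed = 2))
  expect_error(binding_site_filter(g, rnd), "whole-structure")
})

test_that("water categorization counts polar and water contacts", {
  s <- parse_pdb(sample_pdb_text())
  iso <- categorize_waters(s)          # single water far from everything
  expect_equal(iso$polar_contacts, 0L)
  expect_equal(iso$water_contacts, 0L)
  s2 <- add_waters(s, rbind(c(13.2, 4.2, -5.5), c(13.5, 4.4, -5.0)))
  cats <- categorize_waters(s2, radius = 3.5)
  at <- s2$atoms
  polar <- as.matrix(at[!at$is_ligand & at$element %in% c("N", "O"),
                        c("x", "y", "z")])
  W <- as.matrix(s2$waters[, c("x", "y", "z")])
  for (i in seq_len(nrow(W))) {
    dp <- sqrt(rowSums((polar - rep(W[i, ], each = nrow(polar)))^2))
    dw <- sqrt(rowSums((W - rep(W[i, ], each = nrow(W)))^2))
    expect_equal(cats$polar_contacts[i], sum(dp <= 3.5))
    expect_equal(cats$water_contacts[i], sum(dw <= 3.5) - 1L)
  }
})
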