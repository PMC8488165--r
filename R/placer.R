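#' Placement configuration
#'
#' @param grid_spacing edge length (Angstrom) of the grid boxes; 0.8 is small
#'   enough that each box holds at most one water.
#' @param score_threshold stopping threshold on the (Norm-scaled) score; a
#'   water is only accepted while the best score is at or below it.  The
#'   default 0.5 corresponds to roughly 0.32 Angstrom of predicted distance.
#' @param max_step per-iteration displacement cap (Angstrom) of the gradient
#'   descent.
#' @param max_gd_iters gradient-descent iteration cap per box.
#' @param min_water_distance minimal allowed O-O distance between placed
#'   waters (deduplication radius).
#' @param clash_distance minimal allowed distance between a placed water and
#'   a protein heavy atom.
#' @param rescore_radius after accepting a water, only boxes within this
#'   radius are re-optimized (the receptive field bounds the region a new
#'   water can influence); set `full_rescore = TRUE` to re-optimize all.
#' @param escape_radius how far an optimized position may travel from its box
#'   center.
#' @param refine_iters joint-refinement gradient-descent iteration cap.
#' @param max_rounds cap on placement/refinement alternation rounds.
#' @param max_waters optional cap on the number of accepted waters.
#' @param full_rescore re-optimize every box after each acceptance.
#' @param cluster_cutoff single-linkage cutoff (Angstrom) for local
#'   resampling clusters.
#' @param max_exhaustive clusters up to this size are resampled by exhaustive
#'   subset enumeration; larger ones greedily.
#' @param seed integer seed recorded with the run.
#' @return list of class `placement_config`.
#' @export
placement_config <- function(grid_spacing = 0.8,
                             score_threshold = 0.5,
                             max_step = 0.3,
                             max_gd_iters = 60L,
                             min_water_distance = 2.2,
                             clash_distance = 1.8,
                             rescore_radius = 6.0,
                             escape_radius = 1.2,
                             refine_iters = 40L,
                             max_rounds = 20L,
                             max_waters = Inf,
                             full_rescore = FALSE,
                             cluster_cutoff = 3.5,
                             max_exhaustive = 6L,
                             seed = 1L) {
  stopifnot(grid_spacing > 0, score_threshold > 0, score_threshold < 1,
            min_water_distance > grid_spacing)
  structure(as.list(environment()), class = "placement_config")
}

#' Build the placement grid
#'
#' An axis-aligned grid of box centers covering the protein bounding box
#' padded by the receptive radius.  Boxes are deactivated when their center
#' is closer than `clash_distance` to a protein heavy atom or farther than
#' the receptive radius from every atom (protein or water): no water can
#' score there.
#'
#' @param structure a [protein_structure()].
#' @param config a [placement_config()].
#' @param receptive_radius the scorer's receptive radius (Angstrom).
#' @return data frame of boxes: centers (`cx`, `cy`, `cz`), `active`, and
#'   placeholders for the optimized position and score.
#' @export
build_grid <- function(structure, config = placement_config(),
                       receptive_radius = 4.0) {
  bb <- bounding_box(structure, pad = receptive_radius)
  ax <- lapply(1:3, function(k) {
    n <- ceiling((bb["hi", k] - bb["lo", k]) / config$grid_spacing) + 1L
    bb["lo", k] + (seq_len(n) - 1L) * config$grid_spacing
  })
  g <- expand.grid(cx = ax[[1]], cy = ax[[2]], cz = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  P <- as.matrix(structure$atoms[, c("x", "y", "z")])
  W <- .water_matrix(structure)
  A <- rbind(P, W)
  C <- as.matrix(g)
  # nearest-atom distances via a block scan (desk-scale sizes)
  dmin_prot <- .min_cross_dist(C, P)
  dmin_any <- if (nrow(W)) pmin(dmin_prot, .min_cross_dist(C, W)) else dmin_prot
  g$active <- dmin_prot >= config$clash_distance & dmin_any <= receptive_radius
  g$ox <- g$cx; g$oy <- g$cy; g$oz <- g$cz
  g$score <- NA_real_
  g
}

# row-wise minimum Euclidean distance from each row of A to the rows of B
.min_cross_dist <- function(A, B) {
  if (nrow(B) == 0) return(rep(Inf, nrow(A)))
  out <- rep(Inf, nrow(A))
  for (j in seq_len(nrow(B))) {
    d2 <- (A[, 1] - B[j, 1])^2 + (A[, 2] - B[j, 2])^2 + (A[, 3] - B[j, 3])^2
    out <- pmin(out, d2)
  }
  sqrt(out)
}

#' Optimize a single grid box
#'
#' Gradient descent from the box center under the scorer, with per-step
#' displacement capped at `max_step`, halted after `max_gd_iters` or when the
#' step norm drops below 1e-3 Angstrom.  The environment (including any
#' waters already in the structure) is fixed.
#'
#' @param scorer a [scorer_params()] or [analytic_scorer()].
#' @param structure a [protein_structure()].
#' @param box list or one-row data frame with the box center (`cx`,`cy`,`cz`).
#' @param config a [placement_config()].
#' @return the box with `ox`, `oy`, `oz` (optimized position) and `score`.
#' @export
optimize_box <- function(scorer, structure, box, config = placement_config()) {
  res <- optimize_positions(scorer, structure,
                            matrix(c(box$cx, box$cy, box$cz), 1, 3), config)
  box$ox <- res$positions[1, 1]
  box$oy <- res$positions[1, 2]
  box$oz <- res$positions[1, 3]
  box$score <- res$scores[1]
  box
}

# optimize the boxes in `idx` (warm-started from their cached optimized
# position when available) and store positions/scores back on the grid
.optimize_grid_boxes <- function(scorer, structure, grid, idx, config) {
  if (!length(idx)) return(grid)
  centers <- as.matrix(grid[idx, c("cx", "cy", "cz")])
  starts <- as.matrix(grid[idx, c("ox", "oy", "oz")])
  cold <- !is.finite(grid$score[idx])
  starts[cold, ] <- centers[cold, , drop = FALSE]
  res <- optimize_positions(scorer, structure, starts, config, centers)
  grid[idx, c("ox", "oy", "oz")] <- res$positions
  grid$score[idx] <- res$scores
  grid
}

#' Iterative best-first water placement
#'
#' Optimizes every active box, then repeatedly accepts the globally
#' best-scoring optimized water, adds it to the environment, blocks boxes
#' whose optimized position falls within `min_water_distance` of it, and
#' re-optimizes the boxes whose environment changed (within
#' `rescore_radius` of the new water).  Stops when the best score is worse
#' than `score_threshold`.
#'
#' @inheritParams optimize_box
#' @param grid optional pre-built grid (from [build_grid()]); a grid
#'   returned by a previous pass is reused incrementally (only boxes marked
#'   dirty are re-optimized).
#' @return list with `waters` (data frame: x, y, z, score, iteration),
#'   `structure` (input plus accepted waters), `grid` (updated state),
#'   `iterations`, and `log`.
#' @export
iterative_place <- function(scorer, structure, config = placement_config(),
                            grid = NULL) {
  radius <- if (inherits(scorer, "scorer_params")) scorer$receptive_radius else 4.0
  if (is.null(grid)) grid <- build_grid(structure, config, radius)
  if (is.null(grid$dirty)) grid$dirty <- grid$active
  accepted <- NULL
  log <- character(0)
  cur <- structure
  grid <- .optimize_grid_boxes(scorer, cur, grid,
                               which(grid$active & grid$dirty), config)
  grid$dirty[grid$active] <- FALSE
  P <- as.matrix(structure$atoms[, c("x", "y", "z")])
  # blocked: optimized position sits on an existing water (recomputed per
  # pass so waters removed by refinement free their boxes again)
  Wcur <- .water_matrix(cur)
  opt <- as.matrix(grid[, c("ox", "oy", "oz")])
  blocked <- if (nrow(Wcur))
    .min_cross_dist(opt, Wcur) < config$min_water_distance
  else rep(FALSE, nrow(grid))
  n_iter <- 0L
  max_iter <- sum(grid$active)
  while (n_iter < max_iter) {
    act <- which(grid$active & !blocked)
    if (!length(act)) break
    best <- act[which.min(grid$score[act])]
    if (!is.finite(grid$score[best]) ||
        grid$score[best] > config$score_threshold)
      break
    pos <- as.numeric(grid[best, c("ox", "oy", "oz")])
    # reject clashes and duplicates rather than accepting them
    if (min(.min_cross_dist(matrix(pos, 1, 3), P)) < config$clash_distance) {
      blocked[best] <- TRUE
      next
    }
    Wcur <- .water_matrix(cur)
    if (nrow(Wcur) &&
        min(.min_cross_dist(matrix(pos, 1, 3), Wcur)) <
          config$min_water_distance) {
      blocked[best] <- TRUE
      next
    }
    n_iter <- n_iter + 1L
    accepted <- rbind(accepted,
                      data.frame(x = pos[1], y = pos[2], z = pos[3],
                                 score = grid$score[best],
                                 iteration = n_iter))
    log <- c(log, sprintf("iter %d: accepted (%.2f, %.2f, %.2f) score %.4f",
                          n_iter, pos[1], pos[2], pos[3], grid$score[best]))
    cur <- add_waters(cur, matrix(pos, 1, 3))
    if (nrow(accepted) >= config$max_waters) break
    # block boxes that converged onto the accepted water
    od <- sqrt((grid$ox - pos[1])^2 + (grid$oy - pos[2])^2 +
               (grid$oz - pos[3])^2)
    blocked <- blocked | od < config$min_water_distance
    # re-optimize boxes whose environment changed
    act <- which(grid$active & !blocked)
    if (!length(act)) break
    cd <- sqrt((grid$cx[act] - pos[1])^2 + (grid$cy[act] - pos[2])^2 +
               (grid$cz[act] - pos[3])^2)
    redo <- if (config$full_rescore) act else act[cd <= config$rescore_radius]
    grid <- .optimize_grid_boxes(scorer, cur, grid, redo, config)
    if (length(redo)) {
      # re-optimized boxes may have slid onto an existing water: re-block
      Wnow <- .water_matrix(cur)
      db <- .min_cross_dist(as.matrix(grid[redo, c("ox", "oy", "oz")]), Wnow)
      blocked[redo] <- blocked[redo] | db < config$min_water_distance
    }
  }
  if (is.null(accepted))
    accepted <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                           score = numeric(), iteration = integer())
  list(waters = accepted, structure = cur, grid = grid,
       iterations = n_iter, log = log)
}

#' Joint refinement with local resampling
#'
#' First optimizes all given waters simultaneously by gradient descent on the
#' summed score (cross interactions included), then resamples locally:
#' waters are clustered by single linkage at `cluster_cutoff`; per cluster,
#' add-back subsets are enumerated (exhaustively up to `max_exhaustive`
#' members, greedily beyond), each candidate subset is re-optimized, and the
#' subset with the best total of (score - threshold) over kept waters is
#' retained.  Iterates until no cluster improves.
#'
#' @inheritParams optimize_box
#' @param waters numeric matrix (k x 3) of water positions to refine (the
#'   structure's own waters stay fixed).
#' @return list with `waters` (refined positions, possibly fewer rows) and
#'   `scores`.
#' @export
refine_waters <- function(scorer, structure, waters,
                          config = placement_config()) {
  waters <- matrix(waters, ncol = 3)
  if (nrow(waters) == 0) return(list(waters = waters, scores = numeric(0)))
  jr <- optimize_waters_jointly(scorer, structure, waters, config)
  waters <- jr$waters
  scores <- jr$scores
  objective <- function(keep_scores) sum(keep_scores - config$score_threshold)
  for (round in seq_len(5L)) {
    improved <- FALSE
    k <- nrow(waters)
    if (k == 0) break
    cl <- if (k == 1) 1L else
      cutree(hclust(dist(waters), method = "single"), h = config$cluster_cutoff)
    for (ci in sort(unique(cl))) {
      members <- which(cl == ci)
      others <- waters[-members, , drop = FALSE]
      base_env <- add_waters(structure, others)
      best <- NULL
      cand_sets <- if (length(members) <= config$max_exhaustive) {
        .all_subsets(length(members))
      } else {
        .greedy_subsets(scores[members] - config$score_threshold)
      }
      sub_cfg <- config
      sub_cfg$refine_iters <- min(10L, config$refine_iters)
      for (sub in cand_sets) {
        if (length(sub) == 0) {
          cand <- list(waters = matrix(numeric(0), 0, 3), scores = numeric(0))
        } else {
          cand <- optimize_waters_jointly(
            scorer, base_env, waters[members[sub], , drop = FALSE], sub_cfg)
          cand <- .dedup_waters(cand$waters, cand$scores,
                                config$min_water_distance)
        }
        val <- objective(cand$scores)
        if (is.null(best) || val < best$val - 1e-9) {
          best <- list(val = val, waters = cand$waters, scores = cand$scores)
        }
      }
      cur_val <- objective(scores[members])
      if (best$val < cur_val - 1e-6) {
        waters <- rbind(others, best$waters)
        scores <- c(scores[-members], best$scores)
        improved <- TRUE
        break   # cluster labels are stale; recluster
      }
    }
    if (!improved) break
  }
  .dedup_waters(waters, scores, config$min_water_distance)
}

# joint descent can draw two waters into one basin; enforce the O-O
# exclusion by dropping the worse-scored of any pair below min_dist
.dedup_waters <- function(waters, scores, min_dist) {
  repeat {
    if (nrow(waters) < 2) break
    dd <- as.matrix(dist(waters))
    diag(dd) <- Inf
    hit <- which(dd < min_dist, arr.ind = TRUE)
    if (!nrow(hit)) break
    i <- hit[1, 1]; j <- hit[1, 2]
    drop <- if (scores[i] > scores[j]) i else j
    waters <- waters[-drop, , drop = FALSE]
    scores <- scores[-drop]
  }
  list(waters = waters, scores = scores)
}

.all_subsets <- function(n) {
  out <- list(integer(0))
  for (k in seq_len(n)) {
    cmb <- utils::combn(n, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

# candidate subsets for large clusters: full set and drop-worst prefixes
.greedy_subsets <- function(rel_scores) {
  n <- length(rel_scores)
  ord <- order(rel_scores, decreasing = TRUE)   # worst first
  out <- list(seq_len(n))
  keep <- seq_len(n)
  for (i in ord) {
    keep <- setdiff(keep, i)
    out[[length(out) + 1L]] <- keep
  }
  out
}

#' Place waters: full prediction pipeline
#'
#' Alternates [iterative_place()] and [refine_waters()] until a placement
#' pass accepts no new water (capped at `max_rounds` alternations).  The
#' result satisfies the pairwise distance and clash invariants and every
#' reported score is at or below the threshold.
#'
#' @inheritParams optimize_box
#' @return list of class `placement_result` with `waters` (data frame: x, y,
#'   z, score, iteration), `rounds`, and `log`.
#' @export
place_waters <- function(scorer, structure, config = placement_config()) {
  predicted <- matrix(numeric(0), 0, 3)
  pred_scores <- numeric(0)
  log <- character(0)
  rounds <- 0L
  grid <- NULL
  repeat {
    rounds <- rounds + 1L
    cur <- add_waters(structure, predicted)
    cfg <- config
    if (is.finite(config$max_waters))
      cfg$max_waters <- config$max_waters - nrow(predicted)
    res <- iterative_place(scorer, cur, cfg, grid = grid)
    grid <- res$grid
    log <- c(log, sprintf("round %d: placed %d", rounds, nrow(res$waters)),
             res$log)
    if (nrow(res$waters) == 0) break
    before <- predicted
    predicted <- rbind(predicted, as.matrix(res$waters[, c("x", "y", "z")]))
    ref <- refine_waters(scorer, structure, predicted, config)
    after <- ref$waters
    # waters moved or removed by refinement: their neighbourhoods must rescore
    changed <- rbind(
      predicted[.min_cross_dist(predicted, after) > 1e-6, , drop = FALSE],
      if (nrow(after)) after[.min_cross_dist(after, predicted) > 1e-6, ,
                             drop = FALSE])
    predicted <- after
    pred_scores <- ref$scores
    if (!is.null(changed) && nrow(changed)) {
      cd <- .min_cross_dist(as.matrix(grid[, c("cx", "cy", "cz")]), changed)
      grid$dirty <- grid$dirty | (grid$active & cd <= config$rescore_radius)
    }
    if (rounds >= config$max_rounds) {
      log <- c(log, sprintf("alternation cap (%d rounds) reached", rounds))
      break
    }
    if (nrow(predicted) >= config$max_waters) break
    # converged: refinement returned the previous round's water set
    # (placement's additions were all rejected again)
    if (nrow(before) == nrow(predicted) && nrow(before) > 0 &&
        max(.min_cross_dist(before, predicted)) < 0.02 &&
        max(.min_cross_dist(predicted, before)) < 0.02) break
  }
  waters <- data.frame(x = predicted[, 1], y = predicted[, 2],
                       z = predicted[, 3],
                       score = if (length(pred_scores)) pred_scores else numeric(0),
                       iteration = seq_len(nrow(predicted)))
  structure(list(waters = waters, rounds = rounds, log = log),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("<placement_result: %d waters in %d round(s)>\n",
              nrow(x$waters), x$rounds))
  invisible(x)
}
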