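#' One-to-one cutoff matching of crystal and predicted waters
#'
#' Finds the maximum-cardinality one-to-one matching between crystal and
#' predicted positions among pairs within `cutoff`; among maximum matchings
#' the one with minimal total distance is chosen (optimal assignment).  A
#' greedy nearest-pair variant is available for sensitivity checks.
#'
#' @param crystal numeric matrix (n x 3) of crystal water positions.
#' @param predicted numeric matrix (m x 3) of predicted positions.
#' @param cutoff matching cutoff (Angstrom), `> 0`.
#' @param method `"optimal"` (default) or `"greedy"` (repeatedly match the
#'   closest remaining pair).
#' @return list of class `match_result`: `cutoff`, `pairs` (data frame:
#'   crystal, predicted, distance), `unmatched_crystal`,
#'   `unmatched_predicted`, `n_crystal`, `n_predicted`.
#' @export
match_waters <- function(crystal, predicted, cutoff,
                         method = c("optimal", "greedy")) {
  stopifnot(cutoff > 0)
  method <- match.arg(method)
  crystal <- matrix(crystal, ncol = 3)
  predicted <- matrix(predicted, ncol = 3)
  n <- nrow(crystal); m <- nrow(predicted)
  empty <- data.frame(crystal = integer(), predicted = integer(),
                      distance = numeric())
  if (n == 0 || m == 0) {
    return(structure(list(cutoff = cutoff, pairs = empty,
                          unmatched_crystal = seq_len(n),
                          unmatched_predicted = seq_len(m),
                          n_crystal = n, n_predicted = m),
                     class = "match_result"))
  }
  D <- sqrt(pmax(outer(rowSums(crystal^2), rep(1, m)) +
                 outer(rep(1, n), rowSums(predicted^2)) -
                 2 * crystal %*% t(predicted), 0))
  if (method == "greedy") {
    pairs <- empty
    Dm <- D
    Dm[Dm > cutoff] <- Inf
    while (any(is.finite(Dm))) {
      k <- arrayInd(which.min(Dm), dim(Dm))
      pairs <- rbind(pairs, data.frame(crystal = k[1], predicted = k[2],
                                       distance = D[k[1], k[2]]))
      Dm[k[1], ] <- Inf
      Dm[, k[2]] <- Inf
    }
  } else {
    BIG <- 1e6   # dominates any feasible total distance
    C <- ifelse(D <= cutoff, D, BIG)
    if (n <= m) {
      asg <- as.integer(cpp_assignment(C))
      pairs <- data.frame(crystal = seq_len(n), predicted = asg,
                          distance = D[cbind(seq_len(n), asg)])
    } else {
      asg <- as.integer(cpp_assignment(t(C)))
      pairs <- data.frame(crystal = asg, predicted = seq_len(m),
                          distance = D[cbind(asg, seq_len(m))])
    }
    pairs <- pairs[pairs$distance <= cutoff, , drop = FALSE]
  }
  pairs <- pairs[order(pairs$crystal), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(cutoff = cutoff, pairs = pairs,
                 unmatched_crystal = setdiff(seq_len(n), pairs$crystal),
                 unmatched_predicted = setdiff(seq_len(m), pairs$predicted),
                 n_crystal = n, n_predicted = m),
            class = "match_result")
}

#' Precision / recall / F1 of a match
#'
#' `precision = TP / #predicted`, `recall = TP / #crystal`,
#' `F1 = 2 p r / (p + r)`; degenerate zero denominators yield 0 with a flag.
#'
#' @param match a [match_waters()] result.
#' @return list of class `metrics_report`: `cutoff`, `tp`, `n_predicted`,
#'   `n_crystal`, `precision`, `recall`, `f1`, `degenerate`.
#' @export
water_metrics <- function(match) {
  tp <- nrow(match$pairs)
  degenerate <- FALSE
  precision <- if (match$n_predicted > 0) tp / match$n_predicted else {
    degenerate <- TRUE; 0
  }
  recall <- if (match$n_crystal > 0) tp / match$n_crystal else {
    degenerate <- TRUE; 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    degenerate <- degenerate || tp == 0
    0
  }
  structure(list(cutoff = match$cutoff, tp = tp,
                 n_predicted = match$n_predicted,
                 n_crystal = match$n_crystal,
                 precision = precision, recall = recall, f1 = f1,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' Evaluate predictions over structures and cutoffs
#'
#' Matches predicted against crystal waters per structure and cutoff and
#' reports both pooled metrics (corpus-level TP / predicted / crystal counts)
#' and per-structure macro averages.
#'
#' @param crystal list of numeric matrices (or a single matrix) of crystal
#'   positions.
#' @param predicted list of numeric matrices (or a single matrix) of
#'   predicted positions, parallel to `crystal`.
#' @param cutoffs numeric vector of matching cutoffs (Angstrom).
#' @param method matching method, see [match_waters()].
#' @return data frame with one row per cutoff and aggregation mode
#'   (`pooled` / `macro`): tp, n_predicted, n_crystal, precision, recall, f1.
#' @export
evaluate_predictions <- function(crystal, predicted,
                                 cutoffs = c(0.5, 1.0, 1.5),
                                 method = "optimal") {
  if (!is.list(crystal)) crystal <- list(crystal)
  if (!is.list(predicted)) predicted <- list(predicted)
  stopifnot(length(crystal) == length(predicted))
  out <- NULL
  for (cutoff in cutoffs) {
    ms <- lapply(seq_along(crystal), function(i) {
      water_metrics(match_waters(crystal[[i]], predicted[[i]], cutoff,
                                 method = method))
    })
    tp <- sum(vapply(ms, `[[`, 0, "tp"))
    np <- sum(vapply(ms, `[[`, 0, "n_predicted"))
    nc <- sum(vapply(ms, `[[`, 0, "n_crystal"))
    prec <- if (np > 0) tp / np else 0
    rec <- if (nc > 0) tp / nc else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out <- rbind(out,
                 data.frame(cutoff = cutoff, aggregation = "pooled", tp = tp,
                            n_predicted = np, n_crystal = nc,
                            precision = prec, recall = rec, f1 = f1),
                 data.frame(cutoff = cutoff, aggregation = "macro", tp = tp,
                            n_predicted = np, n_crystal = nc,
                            precision = mean(vapply(ms, `[[`, 0, "precision")),
                            recall = mean(vapply(ms, `[[`, 0, "recall")),
                            f1 = mean(vapply(ms, `[[`, 0, "f1"))))
  }
  out
}

#' Binding-site filter
#'
#' Keeps positions within 4.0 Angstrom of at least one protein atom and
#' within 4.0 Angstrom of at least one ligand atom; applied symmetrically to
#' crystal and predicted waters before binding-site matching.
#'
#' @param structure a [protein_structure()] with at least one ligand atom.
#' @param positions numeric matrix (k x 3).
#' @param radius contact radius (Angstrom).
#' @return the retained rows of `positions`.
#' @export
binding_site_filter <- function(structure, positions, radius = 4.0) {
  at <- structure$atoms
  if (!any(at$is_ligand))
    stop("structure has no ligand atoms; evaluate in whole-structure mode instead")
  positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 0) return(positions)
  P <- as.matrix(at[!at$is_ligand, c("x", "y", "z")])
  L <- as.matrix(at[at$is_ligand, c("x", "y", "z")])
  keep <- .min_cross_dist(positions, P) <= radius &
    .min_cross_dist(positions, L) <= radius
  positions[keep, , drop = FALSE]
}

#' Categorize crystal waters by local contacts
#'
#' For each crystal water, counts protein N/O (polar) atoms and other
#' crystal waters within `radius`; recall can then be reported per category
#' bucket.
#'
#' @param structure a [protein_structure()] with waters.
#' @param radius contact radius (Angstrom).
#' @return data frame with one row per crystal water: `polar_contacts`,
#'   `water_contacts`.
#' @export
categorize_waters <- function(structure, radius = 3.5) {
  W <- .water_matrix(structure)
  at <- structure$atoms
  polar <- as.matrix(at[!at$is_ligand & at$element %in% c("N", "O"),
                        c("x", "y", "z"), drop = FALSE])
  n <- nrow(W)
  out <- data.frame(polar_contacts = integer(n), water_contacts = integer(n))
  for (i in seq_len(n)) {
    if (nrow(polar)) {
      dp <- sqrt((polar[, 1] - W[i, 1])^2 + (polar[, 2] - W[i, 2])^2 +
                 (polar[, 3] - W[i, 3])^2)
      out$polar_contacts[i] <- sum(dp <= radius)
    }
    dw <- sqrt((W[, 1] - W[i, 1])^2 + (W[, 2] - W[i, 2])^2 +
               (W[, 3] - W[i, 3])^2)
    out$water_contacts[i] <- sum(dw <= radius) - 1L   # exclude itself
  }
  out
}
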