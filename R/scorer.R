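#' PolyNN parameter set
#'
#' The three-layer perceptron variant used throughout the scorer:
#' `x1 = Swish(W0 x0 + b0)`, `x2 = exp(W1 log(1 + x1)) - 1`, `x3 = W2 x2`.
#' Swish is bounded below by about -0.2785, so `1 + x1 > 0.72` and the log is
#' always defined.
#'
#' @param n_in,n_hidden,n_out layer widths.
#' @param init_scale standard deviation of the random weight initialization
#'   (biases start at zero).
#' @return list with entries `W0`, `b0`, `W1`, `W2`, class `polynn_params`.
#' @export
polynn_params <- function(n_in, n_hidden, n_out, init_scale = 0.1) {
  structure(list(
    W0 = matrix(rnorm(n_hidden * n_in, sd = init_scale), n_hidden, n_in),
    b0 = numeric(n_hidden),
    W1 = matrix(rnorm(n_hidden * n_hidden, sd = init_scale), n_hidden, n_hidden),
    W2 = matrix(rnorm(n_out * n_hidden, sd = init_scale), n_out, n_hidden)
  ), class = "polynn_params")
}

#' Evaluate a PolyNN
#'
#' @param params a [polynn_params()].
#' @param x0 numeric input vector whose length matches `ncol(params$W0)`.
#' @return numeric output vector.
#' @export
polynn_forward <- function(params, x0) {
  stopifnot(length(x0) == ncol(params$W0), all(is.finite(x0)))
  z <- drop(params$W0 %*% x0) + params$b0
  x1 <- z / (1 + exp(-z))          # Swish
  if (any(1 + x1 <= 0)) stop("PolyNN domain error: 1 + x1 <= 0")
  x2 <- exp(drop(params$W1 %*% log1p(x1))) - 1
  drop(params$W2 %*% x2)
}

#' Permutation-invariant statistical reduction
#'
#' Pools a set of M vectors into component-wise sum, average, maximum and
#' population standard deviation (divide by M), concatenates them in that
#' order and applies a PolyNN.  An empty set reduces to the zero statistics
#' vector rather than raising an error.
#'
#' @param params a [polynn_params()] whose input width is 4 times the vector
#'   width.
#' @param inputs numeric matrix with one input vector per row (M x n), or a
#'   list of vectors.
#' @return numeric output vector of the PolyNN.
#' @export
statistical_reduce <- function(params, inputs) {
  if (is.list(inputs)) inputs <- do.call(rbind, inputs)
  n <- ncol(params$W0) / 4
  if (is.null(inputs) || nrow(inputs) == 0) {
    return(polynn_forward(params, numeric(4 * n)))
  }
  stopifnot(ncol(inputs) == n)
  M <- nrow(inputs)
  s <- colSums(inputs)
  avg <- s / M
  mx <- apply(inputs, 2, max)
  sd_ <- sqrt(colSums((inputs - rep(avg, each = M))^2) / M)
  polynn_forward(params, c(s, avg, mx, sd_))
}

#' Full learnable state of the scorer
#'
#' Embedding tables plus the five PolyNN blocks: distance-term net,
#' angle-term net, per-atom reduction, final reduction and the scalar output
#' head.  Widths default to atom embedding 32, bond embedding 8, hidden 64
#' and interaction embedding 64; smaller widths are useful for desk-scale
#' training.
#'
#' @param n_atom_types,n_bond_types vocabulary sizes (defaults from
#'   [atom_type_vocabulary()] / [bond_type_vocabulary()]).
#' @param widths named list: `atom`, `bond`, `hidden`, `interaction`.
#' @param receptive_radius radius (Angstrom) of the receptive field.
#' @param init_scale weight initialization scale.
#' @param seed integer seed for the initialization.
#' @return list of class `scorer_params`.
#' @export
scorer_params <- function(n_atom_types = nrow(atom_type_vocabulary()),
                          n_bond_types = nrow(bond_type_vocabulary()),
                          widths = list(atom = 32L, bond = 8L, hidden = 64L,
                                        interaction = 64L),
                          receptive_radius = 4.0,
                          init_scale = 0.1,
                          seed = 1L) {
  stopifnot(receptive_radius > 0)
  set.seed(seed)
  da <- widths$atom; db <- widths$bond
  dh <- widths$hidden; de <- widths$interaction
  p <- list(
    atom_embeddings = matrix(rnorm(n_atom_types * da, sd = init_scale),
                             n_atom_types, da),
    bond_embeddings = matrix(rnorm(n_bond_types * db, sd = init_scale),
                             n_bond_types, db),
    distance_term_net = polynn_params(da + 1, dh, de, init_scale),
    angle_term_net = polynn_params(2 * da + db + 1, dh, de, init_scale),
    atom_reduce_net = polynn_params(4 * de, dh, de, init_scale),
    final_reduce_net = polynn_params(4 * de, dh, de, init_scale),
    output_head = polynn_params(de, dh, 1, init_scale),
    receptive_radius = receptive_radius,
    widths = widths
  )
  class(p) <- "scorer_params"
  p
}

#' @export
print.scorer_params <- function(x, ...) {
  cat(sprintf("<scorer_params: %d atom types x %d, %d bond types x %d, hidden %d, interaction %d, R = %.1f A, %d parameters>\n",
              nrow(x$atom_embeddings), ncol(x$atom_embeddings),
              nrow(x$bond_embeddings), ncol(x$bond_embeddings),
              x$widths$hidden, x$widths$interaction, x$receptive_radius,
              length(flatten_params(x))))
  invisible(x)
}

# the learnable entries, in a fixed order, as one numeric vector
flatten_params <- function(params) {
  unlist(params[c("atom_embeddings", "bond_embeddings", "distance_term_net",
                  "angle_term_net", "atom_reduce_net", "final_reduce_net",
                  "output_head")], use.names = FALSE)
}

unflatten_params <- function(params, flat) {
  skel <- params[c("atom_embeddings", "bond_embeddings", "distance_term_net",
                   "angle_term_net", "atom_reduce_net", "final_reduce_net",
                   "output_head")]
  filled <- utils::relist(flat, lapply(skel, unclass))
  for (nm in names(skel)) {
    if (is.matrix(params[[nm]])) {
      params[[nm]] <- matrix(unlist(filled[[nm]], use.names = FALSE),
                             nrow(params[[nm]]), ncol(params[[nm]]))
    } else {
      for (w in c("W0", "b0", "W1", "W2")) {
        v <- filled[[nm]][[w]]
        params[[nm]][[w]] <- if (is.matrix(params[[nm]][[w]]))
          matrix(v, nrow(params[[nm]][[w]]), ncol(params[[nm]][[w]])) else v
      }
    }
  }
  params
}

# relist() needs plain lists; flatten gradient list returned by the core
flatten_grads <- function(grads) unlist(grads, use.names = FALSE)

.check_env <- function(structure) {
  if (is.null(structure$env))
    stop("structure has no typed environment; run perceive_bonds() and assign_types() first")
  structure$env
}

#' Distance interaction term
#'
#' Concatenates the atom-type embedding of `q` with the Euclidean distance
#' from `q` to the probe `p` and applies the distance-term PolyNN.
#'
#' @param params a [scorer_params()].
#' @param q a single-row atom data frame (as returned by
#'   [neighbors_within()]) or a list with `type_id` and `position`.
#' @param p numeric length-3 probe position.
#' @return numeric interaction-term vector.
#' @export
distance_term <- function(params, q, p) {
  qa <- .atom_ref(q)
  d <- sqrt(sum((qa$position - p)^2))
  polynn_forward(params$distance_term_net,
                 c(params$atom_embeddings[qa$type_id, ], d))
}

#' Angle interaction term
#'
#' For a neighbour `r` bonded to `q`: concatenates the embeddings of `q`,
#' `r` and the bond, plus `cos` of the angle between `q->p` and `q->r`.
#'
#' @inheritParams distance_term
#' @param r the bonded neighbour atom.
#' @param bond_id bond-type id of the q-r bond.
#' @return numeric interaction-term vector.
#' @export
angle_term <- function(params, q, r, bond_id, p) {
  qa <- .atom_ref(q); ra <- .atom_ref(r)
  u <- p - qa$position
  v <- ra$position - qa$position
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9) stop("degenerate geometry: probe coincides with atom q")
  if (nv < 1e-9) stop("degenerate geometry: r coincides with q")
  cth <- sum(u * v) / (nu * nv)
  polynn_forward(params$angle_term_net,
                 c(params$atom_embeddings[qa$type_id, ],
                   params$atom_embeddings[ra$type_id, ],
                   params$bond_embeddings[bond_id, ],
                   cth))
}

.atom_ref <- function(q) {
  if (is.data.frame(q)) {
    list(type_id = q$type_id[1], position = c(q$x[1], q$y[1], q$z[1]))
  } else {
    q
  }
}

#' Interaction embedding of one atom
#'
#' Pools the distance term and one angle term per bonded neighbour of atom
#' `q` through the per-atom statistical reduction.  Bond-less atoms (e.g. a
#' water oxygen) contribute their distance term alone.
#'
#' @param params a [scorer_params()].
#' @param structure a typed [protein_structure()].
#' @param q_index row index of the atom in `structure$atoms`, or a negative
#'   index `-k` for the k-th water.
#' @param p numeric length-3 probe position.
#' @return numeric interaction-embedding vector.
#' @export
interaction_embedding <- function(params, structure, q_index, p) {
  if (q_index < 0) {
    w <- structure$waters[-q_index, ]
    q <- list(type_id = w$type_id, position = c(w$x, w$y, w$z))
    terms <- list(distance_term(params, q, p))
  } else {
    at <- structure$atoms[q_index, ]
    terms <- list(distance_term(params, at, p))
    b <- structure$bonds
    hit <- which(b$i == q_index | b$j == q_index)
    if (length(hit)) {
      other <- ifelse(b$i[hit] == q_index, b$j[hit], b$i[hit])
      ord <- order(other)
      for (k in ord) {
        terms[[length(terms) + 1L]] <-
          angle_term(params, at, structure$atoms[other[k], ], b$bond_id[hit[k]], p)
      }
    }
  }
  statistical_reduce(params$atom_reduce_net, do.call(rbind, terms))
}

#' Score a position
#'
#' Evaluates the learned score at probe position `p`: interaction embeddings
#' of all atoms within the receptive radius are statistically reduced and
#' passed through the output head.  After training the value approximates the
#' Norm-squashed distance from `p` to the nearest missing water.  An empty
#' receptive field returns the worst score 1.0 with zero gradient, so the
#' placer never builds waters in vacuum.
#'
#' @param params a [scorer_params()].
#' @param structure a typed [protein_structure()].
#' @param p numeric length-3 position (Angstrom).
#' @param gradient if `TRUE`, also return the exact derivative of the value
#'   with respect to `p` (analytic backpropagation).
#' @return list with `value` and, when requested, `gradient` (length-3).
#' @export
score_position <- function(params, structure, p, gradient = FALSE) {
  env <- .check_env(structure)
  res <- cpp_score(unclass(params), env, .water_matrix(structure),
                   as.numeric(p), gradient)
  if (gradient) {
    list(value = res$value, gradient = as.numeric(res$grad_p))
  } else {
    list(value = res$value, gradient = NULL)
  }
}

#' Gradient of the score with respect to the probe position
#'
#' @inheritParams score_position
#' @return numeric length-3 gradient.
#' @export
score_gradient <- function(params, structure, p) {
  score_position(params, structure, p, gradient = TRUE)$gradient
}

# ---------------------------------------------------------------------------
# Generic scorer interface used by the placer: the trained neural scorer and
# the analytic fixture scorer plug into the same slots.

#' Evaluate a scorer at a position
#'
#' S3 generic dispatched on the scorer: [scorer_params()] objects use the
#' compiled network, [analytic_scorer()] objects the closed-form field.
#'
#' @param scorer the scorer object.
#' @param structure a [protein_structure()].
#' @param p numeric length-3 position.
#' @return list with `value` and `gradient`.
#' @export
score_at <- function(scorer, structure, p) UseMethod("score_at")

#' @export
score_at.scorer_params <- function(scorer, structure, p) {
  score_position(scorer, structure, p, gradient = TRUE)
}

#' Batch-score positions under a scorer
#' @inheritParams score_at
#' @param probes numeric matrix (k x 3).
#' @return numeric vector of score values.
#' @export
score_many <- function(scorer, structure, probes) UseMethod("score_many")

#' @export
score_many.scorer_params <- function(scorer, structure, probes) {
  env <- .check_env(structure)
  as.numeric(cpp_score_many(unclass(scorer), env, .water_matrix(structure),
                            matrix(probes, ncol = 3)))
}

#' @export
score_many.default <- function(scorer, structure, probes) {
  probes <- matrix(probes, ncol = 3)
  vapply(seq_len(nrow(probes)),
         function(i) score_at(scorer, structure, probes[i, ])$value, 0)
}

# gradient-descent position optimization (batched); dispatched so the
# compiled path serves the neural scorer and an R path serves analytic ones.
# `centers` anchor the escape ball (grid box centers); defaults to `starts`.
optimize_positions <- function(scorer, structure, starts, config,
                               centers = starts) {
  UseMethod("optimize_positions")
}

#' @export
optimize_positions.scorer_params <- function(scorer, structure, starts, config,
                                             centers = starts) {
  env <- .check_env(structure)
  res <- cpp_optimize(unclass(scorer), env, .water_matrix(structure),
                      matrix(starts, ncol = 3), matrix(centers, ncol = 3),
                      config$max_step, config$max_gd_iters, 1e-3,
                      config$escape_radius)
  list(positions = res$positions, scores = as.numeric(res$scores))
}

#' @export
optimize_positions.default <- function(scorer, structure, starts, config,
                                       centers = starts) {
  starts <- matrix(starts, ncol = 3)
  centers <- matrix(centers, ncol = 3)
  k <- nrow(starts)
  pos <- starts
  val <- numeric(k)
  for (i in seq_len(k)) {
    cur <- starts[i, ]
    sv <- score_at(scorer, structure, cur)
    f <- sv$value; g <- sv$gradient
    lr <- 0.1
    for (it in seq_len(config$max_gd_iters)) {
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) break
      step <- -lr * g
      sn <- sqrt(sum(step^2))
      if (sn > config$max_step) step <- step * config$max_step / sn
      cand <- cur + step
      off <- cand - centers[i, ]
      on <- sqrt(sum(off^2))
      if (on > config$escape_radius)
        cand <- centers[i, ] + off * config$escape_radius / on
      sc <- score_at(scorer, structure, cand)
      if (sc$value < f - 1e-12) {
        moved <- sqrt(sum((cand - cur)^2))
        cur <- cand; f <- sc$value; g <- sc$gradient
        lr <- min(lr * 1.3, 1)
        if (moved < 1e-3) break
      } else {
        lr <- lr / 2
        if (lr < 1e-4) break
      }
    }
    pos[i, ] <- cur
    val[i] <- f
  }
  list(positions = pos, scores = val)
}

# joint descent on a set of water positions under the summed score;
# cross-terms through the other waters' receptive fields are included for
# the neural scorer
optimize_waters_jointly <- function(scorer, structure, waters, config) {
  UseMethod("optimize_waters_jointly")
}

#' @export
optimize_waters_jointly.scorer_params <- function(scorer, structure, waters,
                                                  config) {
  env <- .check_env(structure)
  base <- .water_matrix(structure)
  k <- nrow(waters)
  if (k == 0) return(list(waters = waters, scores = numeric(0)))
  # the structure's own (crystal) waters stay fixed: append them to the
  # protein-side environment by treating them as extra fixed waters
  res <- cpp_joint_refine_fixed(unclass(scorer), env, base,
                                matrix(waters, ncol = 3),
                                config$refine_iters, config$max_step, 1e-4)
  list(waters = res$waters, scores = as.numeric(res$scores))
}

#' @export
optimize_waters_jointly.default <- function(scorer, structure, waters, config) {
  waters <- matrix(waters, ncol = 3)
  k <- nrow(waters)
  if (k == 0) return(list(waters = waters, scores = numeric(0)))
  eval_all <- function(W) {
    vals <- numeric(k); G <- matrix(0, k, 3)
    for (j in seq_len(k)) {
      envs <- add_waters(structure, W[-j, , drop = FALSE])
      sv <- score_at(scorer, envs, W[j, ])
      vals[j] <- sv$value; G[j, ] <- sv$gradient
    }
    list(F = sum(vals), vals = vals, G = G)
  }
  cur <- eval_all(waters)
  lr <- 0.05
  for (it in seq_len(config$refine_iters)) {
    step <- -lr * cur$G
    nn <- sqrt(rowSums(step^2))
    over <- nn > config$max_step
    step[over, ] <- step[over, , drop = FALSE] * (config$max_step / nn[over])
    cand <- waters + step
    cc <- eval_all(cand)
    if (cc$F < cur$F - 1e-12) {
      moved <- sqrt(sum((cand - waters)^2))
      waters <- cand; cur <- cc
      lr <- min(lr * 1.3, 0.5)
      if (moved < 1e-4) break
    } else {
      lr <- lr / 2
      if (lr < 1e-4) break
    }
  }
  list(waters = waters, scores = cur$vals)
}

# ---------------------------------------------------------------------------
# Checkpoints: versioned JSON with an md5 checksum of the parameter payload.

#' Save scorer parameters to a JSON checkpoint
#'
#' @param params a [scorer_params()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  payload <- jsonlite::toJSON(list(
    widths = params$widths,
    receptive_radius = params$receptive_radius,
    n_atom_types = nrow(params$atom_embeddings),
    n_bond_types = nrow(params$bond_embeddings),
    values = flatten_params(params)
  ), digits = NA, auto_unbox = TRUE)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(payload, tf)
  sum <- unname(tools::md5sum(tf))
  jsonlite::write_json(list(format = "hydrosite-checkpoint", version = 1L,
                            checksum = sum,
                            payload = jsonlite::fromJSON(payload)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load scorer parameters from a JSON checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a [scorer_params()].
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::fromJSON(path)
  if (!identical(ck$format, "hydrosite-checkpoint"))
    stop("not a hydrosite checkpoint: ", path)
  pl <- ck$payload
  params <- scorer_params(n_atom_types = pl$n_atom_types,
                          n_bond_types = pl$n_bond_types,
                          widths = as.list(pl$widths),
                          receptive_radius = pl$receptive_radius)
  flat <- as.numeric(pl$values)
  if (length(flat) != length(flatten_params(params)))
    stop("checkpoint parameter count does not match its declared widths")
  unflatten_params(params, flat)
}
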