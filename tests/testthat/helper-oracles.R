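# Independent straight-line oracles used to cross-check the implementation.
# These are deliberately written as plain loops over the published formulas
# and share no code with the package internals.

oracle_polynn <- function(pp, x0) {
  z <- as.vector(pp$W0 %*% x0) + pp$b0
  x1 <- z / (1 + exp(-z))                       # Swish
  x2 <- exp(as.vector(pp$W1 %*% log(1 + x1))) - 1
  as.vector(pp$W2 %*% x2)
}

oracle_stats <- function(X) {                   # rows = input vectors
  M <- nrow(X)
  s <- colSums(X)
  avg <- s / M
  mx <- apply(X, 2, max)
  sd_ <- sqrt(colSums((X - matrix(avg, M, ncol(X), byrow = TRUE))^2) / M)
  c(s, avg, mx, sd_)
}

# full forward pass of the score: interaction terms -> per-atom reduction ->
# across-atom reduction -> output head; canonical order is protein atoms by
# serial, then waters
oracle_score <- function(params, structure, p) {
  at <- structure$atoms
  W <- structure$waters
  R <- params$receptive_radius
  A <- params$atom_embeddings
  B <- params$bond_embeddings
  b <- structure$bonds
  emb <- list()
  for (i in seq_len(nrow(at))) {
    qpos <- c(at$x[i], at$y[i], at$z[i])
    d <- sqrt(sum((qpos - p)^2))
    if (d > R) next
    terms <- list(oracle_polynn(params$distance_term_net,
                                c(A[at$type_id[i], ], d)))
    hit <- which(b$i == i | b$j == i)
    other <- ifelse(b$i[hit] == i, b$j[hit], b$i[hit])
    for (k in order(other)) {
      j <- other[k]
      u <- p - qpos
      v <- c(at$x[j], at$y[j], at$z[j]) - qpos
      cth <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      terms[[length(terms) + 1L]] <-
        oracle_polynn(params$angle_term_net,
                      c(A[at$type_id[i], ], A[at$type_id[j], ],
                        B[b$bond_id[hit[k]], ], cth))
    }
    emb[[length(emb) + 1L]] <-
      oracle_polynn(params$atom_reduce_net, oracle_stats(do.call(rbind, terms)))
  }
  for (i in seq_len(nrow(W))) {
    d <- sqrt(sum((c(W$x[i], W$y[i], W$z[i]) - p)^2))
    if (d > R) next
    X <- rbind(oracle_polynn(params$distance_term_net,
                             c(A[W$type_id[i], ], d)))
    emb[[length(emb) + 1L]] <-
      oracle_polynn(params$atom_reduce_net, oracle_stats(X))
  }
  if (!length(emb)) return(1.0)
  h <- oracle_polynn(params$final_reduce_net,
                     oracle_stats(do.call(rbind, emb)))
  oracle_polynn(params$output_head, h)[1]
}

# exhaustive one-to-one matching: maximize pair count, then minimize total
# distance (branch over match/skip decisions; fine for <= 8 points per side)
oracle_match <- function(crystal, predicted, cutoff) {
  crystal <- matrix(crystal, ncol = 3)
  predicted <- matrix(predicted, ncol = 3)
  n <- nrow(crystal)
  m <- nrow(predicted)
  D <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) D[i, j] <- sqrt(sum((crystal[i, ] - predicted[j, ])^2))
  }
  best <- list(count = -1L, dist = Inf)
  rec <- function(i, used, count, dtot) {
    if (i > n) {
      if (count > best$count ||
          (count == best$count && dtot < best$dist - 1e-12)) {
        best <<- list(count = count, dist = dtot)
      }
      return(invisible())
    }
    rec(i + 1L, used, count, dtot)
    for (j in seq_len(m)) {
      if (!used[j] && D[i, j] <= cutoff) {
        used[j] <- TRUE
        rec(i + 1L, used, count + 1L, dtot + D[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(m), 0L, 0)
  best
}

# small typed structure built in code (two bonded carbons), handy wherever a
# minimal environment is needed
toy_structure <- function(x2 = 3) {
  at <- data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
                   x = c(0, x2), y = 0, z = 0, resname = "NON", chain = "A",
                   resseq = 1L, is_ligand = FALSE, hyb = "sp3",
                   aromatic = FALSE)
  s <- protein_structure(at, id = "toy")
  s$bonds <- data.frame(i = 1L, j = 2L, order = "single")
  assign_types(s)
}

small_params <- function(seed = 2) {
  scorer_params(widths = list(atom = 8L, bond = 4L, hidden = 16L,
                              interaction = 16L), seed = seed)
}

fd_gradient <- function(f, p, h = 1e-4) {
  vapply(1:3, function(k) {
    e <- numeric(3)
    e[k] <- h
    (f(p + e) - f(p - e)) / (2 * h)
  }, 0)
}

# a small PDB text fixture: two-residue peptide with a water, a ligand with
# CONECT records, and an altloc pair on one atom
sample_pdb_text <- function() {
  c(
    "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   GLY A   1      12.800   5.100  -4.900  1.00  0.00           C",
    "ATOM      4  O   GLY A   1      13.000   4.000  -5.700  1.00  0.00           O",
    "ATOM      5  N   ALA A   2      13.350   5.300  -3.700  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2      14.500   4.500  -3.300  1.00  0.00           C",
    "ATOM      7  C   ALA A   2      15.700   5.400  -3.100  1.00  0.00           C",
    "ATOM      8  O   ALA A   2      15.600   6.600  -3.400  1.00  0.00           O",
    "ATOM      9  CB AALA A   2      14.200   3.800  -2.000  0.60  0.00           C",
    "ATOM     10  CB BALA A   2      14.300   3.700  -1.900  0.40  0.00           C",
    "HETATM   11  C1  LIG B   1       2.000   2.000   2.000  1.00  0.00           C",
    "HETATM   12  O1  LIG B   1       3.230   2.000   2.000  1.00  0.00           O",
    "HETATM   13  O   HOH C   1       8.000   8.000   8.000  1.00  0.00           O",
    "CONECT   11   12",
    "CONECT   12   11",
    "END"
  )
}
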