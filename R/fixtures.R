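#' Synthetic fixture specification
#'
#' Describes a toy structure made of bonded three-atom mini-scaffolds with a
#' deterministic water-placement rule, used to train and test every stage at
#' desk scale.  Polar fragments (carbonyl C1-C2=O3 or hydroxyl C1-C2-O3
#' heads) anchor waters at hydrogen-bond-like geometry: the first-shell water
#' sits `distance` Angstrom from the oxygen, in the fragment plane, at the
#' template angle to the C-O bond; hydroxyl heads extend a second-shell water
#' from the first at a geometry that keeps the anchor oxygen inside the
#' receptive field, so each site remains locally identifiable.  Nonpolar
#' fragments (propane-like C-C-C) anchor nothing.
#'
#' @param n_scaffold_atoms total scaffold atoms (3 per fragment).
#' @param polar_fraction fraction of fragments that are polar.
#' @param water_rule list with `distance` (Angstrom), `angular_tolerance_deg`
#'   (placement direction jitter within this cone), and
#'   `second_shell_prob` (probability a hydroxyl head carries its
#'   second-shell water; 1 keeps the rule fully deterministic).
#' @param jitter_sigma Gaussian positional noise (Angstrom) on water
#'   positions.
#' @param min_separation minimal distance between fragment centers.
#' @param seed integer seed; generation is deterministic given it.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_scaffold_atoms = 18L,
                         polar_fraction = 0.5,
                         water_rule = list(distance = 2.8,
                                           angular_tolerance_deg = 5,
                                           second_shell_prob = 1.0),
                         jitter_sigma = 0.05,
                         min_separation = 9.0,
                         seed = 1L) {
  stopifnot(water_rule$distance > 0, polar_fraction >= 0, polar_fraction <= 1,
            water_rule$second_shell_prob >= 0,
            water_rule$second_shell_prob <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

# fragment templates in local coordinates (fragment plane = xy);
# waters lists ground-truth oxygen positions implied by the rule at
# distance 2.8 (rescaled by the spec's distance)
.fragment_library <- function() {
  deg <- pi / 180
  # carbonyl: C1-C2=O3, water at 120 deg to the C2->O3 bond, anti to C1
  carbonyl <- list(
    atoms = data.frame(
      name = c("C1", "C2", "O3"), element = c("C", "C", "O"),
      hyb = c("sp3", "sp2", "sp2"), aromatic = FALSE,
      x = c(1.5 * cos(120 * deg), 0, 1.23),
      y = c(1.5 * sin(120 * deg), 0, 0), z = 0),
    bonds = data.frame(i = c(1, 2), j = c(2, 3),
                       order = c("single", "double")),
    anchor = 3L,
    water_dirs = list(c(cos(-60 * deg), sin(-60 * deg), 0)),
    chain = FALSE
  )
  # hydroxyl: C1-C2-O3, water at 109.47 deg to the C2->O3 bond, anti to C1;
  # a second-shell water continues at 80 deg at the first-shell water
  th <- 109.47 * deg
  hydroxyl <- list(
    atoms = data.frame(
      name = c("C1", "C2", "O3"), element = c("C", "C", "O"),
      hyb = "sp3", aromatic = FALSE,
      x = c(1.52 * cos(th), 0, 1.43),
      y = c(1.52 * sin(th), 0, 0), z = 0),
    bonds = data.frame(i = c(1, 2), j = c(2, 3),
                       order = c("single", "single")),
    anchor = 3L,
    # direction making th with O3->C2 (= -x), on the -y side (anti to C1)
    water_dirs = list(c(-cos(th), -sin(th), 0)),
    chain = TRUE
  )
  # nonpolar: propane-like chain
  nonpolar <- list(
    atoms = data.frame(
      name = c("C1", "C2", "C3"), element = "C",
      hyb = "sp3", aromatic = FALSE,
      x = c(1.52 * cos(th), 0, 1.52),
      y = c(1.52 * sin(th), 0, 0), z = 0),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), order = "single"),
    anchor = NA_integer_,
    water_dirs = list(),
    chain = FALSE
  )
  list(carbonyl = carbonyl, hydroxyl = hydroxyl, nonpolar = nonpolar)
}

# random rotation matrix, uniform over SO(3)
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# jitter a unit direction within a cone of half-angle tol (radians)
.jitter_dir <- function(dir, tol) {
  if (tol <= 0) return(dir)
  a <- runif(1, 0, tol)
  phi <- runif(1, 0, 2 * pi)
  # orthonormal frame around dir
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  cos(a) * dir + sin(a) * (cos(phi) * e1 + sin(phi) * e2)
}

#' Generate a synthetic structure with ground-truth waters
#'
#' Builds typed, bonded mini-scaffolds (so angle terms are exercised), places
#' ground-truth waters by the spec's deterministic geometric rule, adds
#' Gaussian jitter, and returns a fully typed [protein_structure()].
#'
#' @param spec a [fixture_spec()].
#' @param id label for the structure.
#' @return a typed `protein_structure` whose `$waters` are the ground truth.
#' @export
generate_structure <- function(spec = fixture_spec(), id = NULL) {
  set.seed(spec$seed)
  if (is.null(id)) id <- sprintf("fixture-%d", spec$seed)
  lib <- .fragment_library()
  n_frag <- max(1L, round(spec$n_scaffold_atoms / 3))
  n_polar <- round(spec$polar_fraction * n_frag)
  kinds <- c(rep(c("carbonyl", "hydroxyl"), length.out = n_polar),
             rep("nonpolar", n_frag - n_polar))
  deg <- pi / 180
  # fragment centers by rejection sampling, cube grown on failure
  side <- max(10, 9 * n_frag^(1 / 3))
  repeat {
    centers <- matrix(NA_real_, n_frag, 3)
    ok <- TRUE
    for (i in seq_len(n_frag)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        cand <- runif(3, 0, side)
        if (i == 1 ||
            min(.min_cross_dist(matrix(cand, 1, 3),
                                centers[seq_len(i - 1), , drop = FALSE])) >=
              spec$min_separation) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
    side <- side + 2
  }
  atoms <- NULL; bonds <- NULL; waters <- NULL
  tol <- spec$water_rule$angular_tolerance_deg * deg
  dist0 <- spec$water_rule$distance
  serial <- 0L
  for (i in seq_len(n_frag)) {
    fr <- lib[[kinds[i]]]
    Rt <- .random_rotation()
    loc <- as.matrix(fr$atoms[, c("x", "y", "z")])
    pos <- loc %*% t(Rt) + rep(centers[i, ], each = nrow(loc))
    atoms <- rbind(atoms, data.frame(
      serial = serial + seq_len(nrow(loc)),
      name = fr$atoms$name, element = fr$atoms$element,
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      resname = toupper(substr(kinds[i], 1, 3)), chain = "A", resseq = i,
      is_ligand = FALSE, hyb = fr$atoms$hyb, aromatic = fr$atoms$aromatic,
      stringsAsFactors = FALSE))
    bonds <- rbind(bonds, data.frame(i = serial + fr$bonds$i,
                                     j = serial + fr$bonds$j,
                                     order = fr$bonds$order,
                                     stringsAsFactors = FALSE))
    if (!is.na(fr$anchor)) {
      anchor <- pos[fr$anchor, ]
      for (dirs in fr$water_dirs) {
        dir <- as.numeric(Rt %*% .jitter_dir(dirs / sqrt(sum(dirs^2)), tol))
        w1 <- anchor + dist0 * dir
        wset <- matrix(w1, 1, 3)
        if (fr$chain && runif(1) <= spec$water_rule$second_shell_prob) {
          # water pair: the partner water sits at the donor distance from
          # both the anchor oxygen and the first water (equilateral
          # O-w1-w2), in the fragment plane on the side away from C2.  Its
          # position is then pinned by local features (distances to O and
          # w1 plus the angle at O), which keeps the rule recoverable.
          u <- (w1 - anchor) / dist0
          c2 <- pos[2, ]
          ref <- (c2 - anchor)
          ref <- ref - sum(ref * u) * u
          rn <- sqrt(sum(ref^2))
          perp <- if (rn > 1e-8) -ref / rn else {
            pp <- .jitter_dir(u, pi / 2) - u
            pp / sqrt(sum(pp^2))
          }
          ang <- 60 * deg   # rotation of u within the plane, away from C2
          dir2 <- cos(ang) * u + sin(ang) * perp
          w2 <- anchor + dist0 * .jitter_dir(dir2, tol)
          wset <- rbind(wset, w2)
        }
        waters <- rbind(waters, wset)
      }
    }
    serial <- serial + nrow(loc)
  }
  if (!is.null(waters) && nrow(waters)) {
    waters <- waters + matrix(rnorm(length(waters), sd = spec$jitter_sigma),
                              nrow(waters), 3)
    wdf <- data.frame(serial = serial + seq_len(nrow(waters)),
                      x = waters[, 1], y = waters[, 2], z = waters[, 3])
  } else {
    wdf <- NULL
  }
  s <- protein_structure(atoms, wdf, id = id)
  s$bonds <- data.frame(i = pmin(bonds$i, bonds$j),
                        j = pmax(bonds$i, bonds$j), order = bonds$order,
                        stringsAsFactors = FALSE)
  assign_types(s)
}

#' Analytic scorer (closed-form test oracle)
#'
#' A differentiable score field with known minima: the Norm-squashed soft
#' minimum of distances to a set of hidden targets.  Conditional targets
#' activate only when the structure contains a water within `radius` of
#' their trigger point, reconstructing the water-network scenario where a
#' second-shell site only appears once its first-shell partner exists.
#'
#' @param targets numeric matrix (k x 3) of always-active target positions.
#' @param temperature soft-min temperature (Angstrom); smaller is sharper.
#' @param conditional optional list of `list(target =, trigger =, radius =)`
#'   entries.
#' @return object of class `analytic_scorer`.
#' @export
analytic_scorer <- function(targets, temperature = 0.3, conditional = list()) {
  targets <- matrix(targets, ncol = 3)
  structure(list(targets = targets, temperature = temperature,
                 conditional = conditional),
            class = "analytic_scorer")
}

#' @export
score_at.analytic_scorer <- function(scorer, structure, p) {
  tg <- scorer$targets
  W <- .water_matrix(structure)
  for (cc in scorer$conditional) {
    r <- if (is.null(cc$radius)) 3.0 else cc$radius
    if (nrow(W) &&
        min(.min_cross_dist(matrix(cc$trigger, 1, 3), W)) <= r) {
      tg <- rbind(tg, cc$target)
    }
  }
  if (nrow(tg) == 0) return(list(value = 1.0, gradient = c(0, 0, 0)))
  d <- sqrt(rowSums((tg - rep(p, each = nrow(tg)))^2))
  tau <- scorer$temperature
  e <- exp(-(d - min(d)) / tau)
  sm <- min(d) - tau * log(sum(e))
  wgt <- e / sum(e)
  # gradient of the soft min
  gsm <- colSums(wgt * (rep(p, each = nrow(tg)) - tg) / pmax(d, 1e-9))
  s <- exp(-5 * sm * log(2))
  value <- 2 / (1 + s) - 1
  dval <- 2 * s * 5 * log(2) / (1 + s)^2
  list(value = value, gradient = as.numeric(dval * gsm))
}

#' Evaluate an analytic scorer
#'
#' Convenience wrapper over [score_at()] for the analytic oracle.
#'
#' @param scorer an [analytic_scorer()].
#' @param structure a [protein_structure()] (supplies the waters that
#'   activate conditional targets).
#' @param p numeric length-3 position.
#' @return list with `value` and `gradient`.
#' @export
analytic_score <- function(scorer, structure, p) score_at(scorer, structure, p)
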