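#' Protein structure container
#'
#' A light container for heavy-atom protein structures: a data frame of
#' protein atoms, a data frame of water oxygens, and a bond table filled in by
#' [perceive_bonds()].  Atoms are stored sorted by serial so that downstream
#' reductions are independent of input order.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`, `x`,
#'   `y`, `z`, `resname`, `chain`, `resseq`, `is_ligand`; optional `hyb`,
#'   `aromatic`.
#' @param waters data frame with columns `serial`, `x`, `y`, `z` (water
#'   oxygens; waters are represented by their oxygen atom only and carry no
#'   bonds).
#' @param id character label.
#' @param source_lines original PDB records, kept so [write_structure()] can
#'   preserve them.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, waters = NULL, id = "structure",
                              source_lines = NULL) {
  req <- c("serial", "name", "element", "x", "y", "z", "resname", "chain",
           "resseq", "is_ligand")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: no heavy atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (is.null(atoms$hyb)) atoms$hyb <- NA_character_
  if (is.null(atoms$aromatic)) atoms$aromatic <- NA
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  if (is.null(waters) || nrow(waters) == 0) {
    waters <- data.frame(serial = integer(), x = numeric(), y = numeric(),
                         z = numeric())
  } else {
    if (!all(is.finite(as.matrix(waters[, c("x", "y", "z")]))))
      stop("non-finite water coordinates")
    waters <- waters[order(waters$serial), , drop = FALSE]
    rownames(waters) <- NULL
  }
  structure(list(id = id, atoms = atoms, waters = waters,
                 bonds = NULL, env = NULL, source_lines = source_lines),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure '%s': %d atoms (%d ligand), %d waters, %s bonds>\n",
              x$id, nrow(x$atoms), sum(x$atoms$is_ligand), nrow(x$waters),
              if (is.null(x$bonds)) "no" else nrow(x$bonds)))
  invisible(x)
}

.water_resnames <- c("HOH", "WAT", "H2O")

#' Parse a PDB file or character stream
#'
#' Reads ATOM/HETATM records through bio3d, discards hydrogens, resolves
#' alternate locations to the highest-occupancy copy (ties broken by altloc
#' letter), routes HOH/WAT/H2O oxygens to the water list and flags non-water
#' HETATM residues as ligand atoms.  CONECT records are retained for bond
#' perception of hetero groups.
#'
#' @param x path to a PDB file, or a character vector/string of PDB records.
#' @param id label for the structure; defaults to the file name.
#' @return a [protein_structure()].
#' @export
parse_pdb <- function(x, id = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (is.null(id)) id <- sub("\\.pdb$", "", basename(x))
  } else {
    lines <- unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(id)) id <- "structure"
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM or HETATM records found")
  # validate coordinate fields before handing off, so errors name the line
  for (ln in which(is_atom)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[ln], fld[1], fld[2])))
      if (is.na(v))
        stop(sprintf("malformed coordinate field at line %d: '%s'", ln, lines[ln]))
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  at$elesy <- trimws(at$elesy)
  blank <- is.na(at$elesy) | at$elesy == ""
  # derive the element from the atom name when the element column is blank
  at$elesy[blank] <- sub("^[0-9]*([A-Za-z]).*", "\\1", trimws(at$elety[blank]))
  at$elesy <- toupper(at$elesy)
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no heavy atoms")
  # alternate locations: keep the highest occupancy, ties by altloc letter
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  akey <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(at)), akey), function(ix) {
    if (length(ix) == 1) return(ix)
    ix[order(-at$o[ix], at$alt[ix])][1]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  is_water <- at$resid %in% .water_resnames
  wat <- at[is_water & at$elesy == "O", , drop = FALSE]
  prot <- at[!is_water, , drop = FALSE]
  if (nrow(prot) == 0) stop("empty structure: no non-water heavy atoms")
  atoms <- data.frame(
    serial = prot$eleno, name = trimws(prot$elety), element = prot$elesy,
    x = prot$x, y = prot$y, z = prot$z,
    resname = prot$resid, chain = ifelse(is.na(prot$chain), "", prot$chain),
    resseq = prot$resno,
    is_ligand = prot$type == "HETATM",
    stringsAsFactors = FALSE
  )
  waters <- data.frame(serial = wat$eleno, x = wat$x, y = wat$y, z = wat$z)
  keep_lines <- is_atom | substr(lines, 1, 6) == "CONECT"
  s <- protein_structure(atoms, waters, id = id,
                         source_lines = lines[keep_lines])
  s$conect <- .parse_conect(lines)
  s
}

# CONECT serial pairs; repeated pairs indicate higher bond order by PDB
# convention.  bio3d drops CONECT, so these are read from the raw lines.
.parse_conect <- function(lines) {
  cl <- lines[substr(lines, 1, 6) == "CONECT"]
  if (!length(cl)) {
    return(data.frame(a = integer(), b = integer(), count = integer()))
  }
  pairs <- do.call(rbind, lapply(cl, function(l) {
    f <- suppressWarnings(as.integer(c(substr(l, 7, 11), substr(l, 12, 16),
                                       substr(l, 17, 21), substr(l, 22, 26),
                                       substr(l, 27, 31))))
    f <- f[!is.na(f)]
    if (length(f) < 2) return(NULL)
    cbind(pmin(f[1], f[-1]), pmax(f[1], f[-1]))
  }))
  if (is.null(pairs)) {
    return(data.frame(a = integer(), b = integer(), count = integer()))
  }
  key <- paste(pairs[, 1], pairs[, 2])
  tab <- table(key)
  ab <- do.call(rbind, strsplit(names(tab), " "))
  # each bond is listed from both endpoints; a doubly listed bond from both
  # sides appears 4 times
  data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
             count = pmax(1L, as.integer(ceiling(as.vector(tab) / 2))))
}

#' Perceive covalent bonds
#'
#' Assigns bonds from amino-acid residue templates, inter-residue peptide
#' bonds (C-N of consecutive residues in the same chain within 1.9 Angstrom),
#' and CONECT records for hetero groups.  Also stamps template hybridization
#' and aromaticity onto each atom.  Waters stay bond-less.  Atoms of unknown
#' residues without CONECT records are left bond-less with a warning.
#'
#' @param structure a [protein_structure()].
#' @return the structure with a symmetric bond table (`$bonds`: atom row
#'   indices `i`, `j` with `i < j`, plus `order`).
#' @export
perceive_bonds <- function(structure) {
  at <- structure$atoms
  n <- nrow(at)
  tmpl <- residue_templates()
  at$hyb <- NA_character_
  at$aromatic <- FALSE
  bi <- integer(0); bj <- integer(0); bo <- character(0)
  rkey <- paste(at$chain, at$resseq, at$resname, sep = "\r")
  unknown <- character(0)
  for (ix in split(seq_len(n), rkey)) {
    rn <- at$resname[ix[1]]
    tp <- tmpl[[rn]]
    if (is.null(tp)) {
      unknown <- c(unknown, rn)
      next
    }
    pos <- match(at$name[ix], tp$atoms$name)
    ok <- !is.na(pos)
    at$hyb[ix[ok]] <- tp$atoms$hyb[pos[ok]]
    at$aromatic[ix[ok]] <- tp$atoms$aromatic[pos[ok]]
    # terminal carboxylate oxygen
    oxt <- ix[at$name[ix] == "OXT"]
    if (length(oxt)) { at$hyb[oxt] <- "sp2"; at$aromatic[oxt] <- FALSE }
    loc <- function(nm) ix[match(nm, at$name[ix])]
    for (b in seq_len(nrow(tp$bonds))) {
      ia <- loc(tp$bonds$a[b]); ja <- loc(tp$bonds$b[b])
      if (!is.na(ia) && !is.na(ja)) {
        bi <- c(bi, ia); bj <- c(bj, ja); bo <- c(bo, tp$bonds$order[b])
      }
    }
    if (length(oxt)) {
      ic <- loc("C")
      if (!is.na(ic)) { bi <- c(bi, ic); bj <- c(bj, oxt[1]); bo <- c(bo, "single") }
    }
  }
  if (length(unknown)) {
    has_conect <- !is.null(structure$conect) && nrow(structure$conect) > 0
    if (!has_conect)
      warning("unknown residue(s) left bond-less: ",
              paste(unique(unknown), collapse = ", "))
  }
  # peptide bonds: C(i) - N(i+1), same chain, consecutive resseq, d <= 1.9 A
  for (ch in unique(at$chain)) {
    cc <- which(at$chain == ch & at$name == "C" & !at$is_ligand)
    nn <- which(at$chain == ch & at$name == "N" & !at$is_ligand)
    if (!length(cc) || !length(nn)) next
    nxt <- match(at$resseq[cc] + 1L, at$resseq[nn])
    for (k in seq_along(cc)) {
      if (is.na(nxt[k])) next
      i <- cc[k]; j <- nn[nxt[k]]
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
      if (d <= 1.9) { bi <- c(bi, i); bj <- c(bj, j); bo <- c(bo, "single") }
    }
  }
  # CONECT bonds for hetero groups (serial-based); duplicates raise the order
  if (!is.null(structure$conect) && nrow(structure$conect) > 0) {
    ia <- match(structure$conect$a, at$serial)
    ja <- match(structure$conect$b, at$serial)
    ok <- !is.na(ia) & !is.na(ja)
    ord <- c("single", "double", "triple")[pmin(structure$conect$count[ok], 3L)]
    bi <- c(bi, ia[ok]); bj <- c(bj, ja[ok]); bo <- c(bo, ord)
  }
  bonds <- data.frame(i = pmin(bi, bj), j = pmax(bi, bj), order = bo,
                      stringsAsFactors = FALSE)
  bonds <- bonds[!duplicated(paste(bonds$i, bonds$j)), , drop = FALSE]
  rownames(bonds) <- NULL
  # hetero atoms: hybridization from bond orders
  het <- which(is.na(at$hyb))
  if (length(het)) {
    for (i in het) {
      ords <- bonds$order[bonds$i == i | bonds$j == i]
      at$hyb[i] <- if (any(ords == "triple")) "sp"
                   else if (any(ords %in% c("double", "aromatic"))) "sp2"
                   else "sp3"
      at$aromatic[i] <- any(ords == "aromatic")
    }
  }
  structure$atoms <- at
  structure$bonds <- bonds
  structure$env <- NULL
  structure
}

#' Assign atom and bond type ids
#'
#' Maps each atom's (element, heavy-atom degree, hybridization, aromatic)
#' tuple and each bond's order to vocabulary indices.  Lookups never fail:
#' unseen keys get the unknown id.
#'
#' @param structure a [protein_structure()] with perceived bonds.
#' @param atom_vocab an [atom_type_vocabulary()].
#' @param bond_vocab a [bond_type_vocabulary()].
#' @return the structure with `type_id` on atoms and waters and `bond_id` on
#'   bonds, plus a cached numeric environment used by the compiled scorer.
#' @export
assign_types <- function(structure,
                         atom_vocab = atom_type_vocabulary(),
                         bond_vocab = bond_type_vocabulary()) {
  if (is.null(structure$bonds)) stop("perceive_bonds() must be called first")
  at <- structure$atoms
  degree <- tabulate(c(structure$bonds$i, structure$bonds$j), nbins = nrow(at))
  hyb <- at$hyb
  hyb[is.na(hyb)] <- "none"
  at$degree <- degree
  at$type_id <- atom_type_id(atom_vocab, at$element, degree, hyb,
                             at$aromatic %in% TRUE)
  structure$atoms <- at
  structure$bonds$bond_id <- bond_type_id(bond_vocab, structure$bonds$order)
  structure$waters$type_id <- rep(attr(atom_vocab, "water_id"),
                                  nrow(structure$waters))
  structure$vocab_sizes <- c(atom = nrow(atom_vocab), bond = nrow(bond_vocab))
  structure$water_type <- attr(atom_vocab, "water_id")
  structure$env <- .build_env(structure)
  structure
}

# numeric arrays consumed by the compiled scorer (0-based CSR adjacency)
.build_env <- function(structure) {
  at <- structure$atoms
  n <- nrow(at)
  b <- structure$bonds
  nbr <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nbr[[b$i[k]]] <- rbind(nbr[[b$i[k]]], c(b$j[k], b$bond_id[k]))
    nbr[[b$j[k]]] <- rbind(nbr[[b$j[k]]], c(b$i[k], b$bond_id[k]))
  }
  cnt <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  nptr <- c(0L, cumsum(cnt))
  nidx <- integer(sum(cnt)); nbond <- integer(sum(cnt))
  off <- 0L
  for (i in seq_len(n)) {
    if (cnt[i] == 0L) next
    m <- nbr[[i]][order(nbr[[i]][, 1]), , drop = FALSE]   # canonical order
    nidx[off + seq_len(cnt[i])] <- m[, 1] - 1L
    nbond[off + seq_len(cnt[i])] <- m[, 2] - 1L
    off <- off + cnt[i]
  }
  list(P = as.matrix(at[, c("x", "y", "z")]),
       ptype = as.integer(at$type_id - 1L),
       nptr = nptr, nidx = nidx, nbond = nbond,
       wtype = as.integer(structure$water_type - 1L))
}

.water_matrix <- function(structure) {
  if (nrow(structure$waters) == 0) {
    return(matrix(numeric(0), 0, 3))
  }
  as.matrix(structure$waters[, c("x", "y", "z")])
}

#' Atoms within a radius of a point
#'
#' Returns exactly the atoms (protein and water) whose Euclidean distance to
#' `center` is at most `radius` (closed ball).  Rows are canonically ordered
#' (protein atoms by serial, then waters by serial) so downstream reductions
#' are reproducible bit-for-bit regardless of storage order.
#'
#' @param structure a [protein_structure()].
#' @param center numeric length-3 position (Angstrom).
#' @param radius positive radius (Angstrom).
#' @return data frame of atoms with columns of `structure$atoms` plus
#'   `is_water` and `dist`.
#' @export
neighbors_within <- function(structure, center, radius) {
  stopifnot(radius > 0, length(center) == 3)
  at <- structure$atoms
  d <- sqrt((at$x - center[1])^2 + (at$y - center[2])^2 + (at$z - center[3])^2)
  sel <- at[d <= radius, , drop = FALSE]
  sel$is_water <- rep(FALSE, nrow(sel))
  sel$dist <- d[d <= radius]
  w <- structure$waters
  if (nrow(w)) {
    dw <- sqrt((w$x - center[1])^2 + (w$y - center[2])^2 + (w$z - center[3])^2)
    wsel <- w[dw <= radius, , drop = FALSE]
    if (nrow(wsel)) {
      pad <- sel[0, , drop = FALSE]
      wdf <- data.frame(serial = wsel$serial, name = "O", element = "O",
                        x = wsel$x, y = wsel$y, z = wsel$z, resname = "HOH",
                        chain = "", resseq = NA_integer_, is_ligand = FALSE,
                        hyb = "sp3", aromatic = FALSE,
                        stringsAsFactors = FALSE)
      for (cn in setdiff(names(sel), c(names(wdf), "is_water", "dist")))
        wdf[[cn]] <- if (cn == "type_id" && !is.null(wsel$type_id)) wsel$type_id else NA
      if (!is.null(wsel$type_id)) wdf$type_id <- wsel$type_id
      wdf$is_water <- TRUE
      wdf$dist <- dw[dw <= radius]
      sel <- rbind(sel, wdf[, names(sel), drop = FALSE])
    }
  }
  rownames(sel) <- NULL
  sel
}

#' Append waters to a structure
#'
#' @param structure a [protein_structure()].
#' @param positions numeric matrix (k x 3) of water oxygen positions.
#' @return the structure with the new waters appended (serials continue after
#'   the current maximum).
#' @export
add_waters <- function(structure, positions) {
  positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 0) return(structure)
  base <- max(c(structure$atoms$serial, structure$waters$serial, 0L))
  nw <- data.frame(serial = base + seq_len(nrow(positions)),
                   x = positions[, 1], y = positions[, 2], z = positions[, 3])
  if (!is.null(structure$water_type))
    nw$type_id <- rep(structure$water_type, nrow(nw))
  structure$waters <- rbind(structure$waters, nw)
  structure
}

#' Remove all waters from a structure
#' @param structure a [protein_structure()].
#' @export
strip_waters <- function(structure) {
  structure$waters <- structure$waters[0, , drop = FALSE]
  if (!is.null(structure$source_lines)) {
    res <- substr(structure$source_lines, 18, 20)
    structure$source_lines <-
      structure$source_lines[!trimws(res) %in% .water_resnames]
  }
  structure
}

#' Write a structure (plus predicted waters) as PDB records
#'
#' Original records are preserved when the structure came from [parse_pdb()];
#' structures built in code are formatted from their tables.  Predicted
#' waters are appended as HETATM HOH oxygen records on a distinct chain.
#'
#' @param structure a [protein_structure()].
#' @param predicted numeric matrix (k x 3) of predicted water positions.
#' @param file optional path; when given the records are written there.
#' @return character vector of PDB records, invisibly when `file` is given.
#' @export
write_structure <- function(structure, predicted = NULL, file = NULL) {
  if (!is.null(predicted) && length(predicted)) {
    predicted <- matrix(predicted, ncol = 3)
    if (any(abs(predicted) >= 10000))
      stop("predicted coordinate exceeds PDB fixed-width field (|x| >= 10000)")
  } else {
    predicted <- matrix(numeric(0), 0, 3)
  }
  fmt <- function(type, serial, name, resname, chain, resseq, x, y, z, element) {
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial %% 100000, name, resname, chain, resseq %% 10000,
            x, y, z, 1, 0, element)
  }
  if (!is.null(structure$source_lines)) {
    body <- structure$source_lines
  } else {
    at <- structure$atoms
    body <- fmt(ifelse(at$is_ligand, "HETATM", "ATOM"), at$serial,
                .pdb_atom_name(at$name, at$element), at$resname, at$chain,
                at$resseq, at$x, at$y, at$z, at$element)
    w <- structure$waters
    if (nrow(w))
      body <- c(body, fmt("HETATM", w$serial, " O", "HOH", "w",
                          seq_len(nrow(w)), w$x, w$y, w$z, "O"))
    # bonds as CONECT records (repeated per bond order) so connectivity of
    # non-template residues survives a round trip through the format
    b <- structure$bonds
    if (!is.null(b) && nrow(b)) {
      reps <- c(single = 1L, double = 2L, triple = 3L, aromatic = 1L,
                unknown = 1L)[b$order]
      reps[is.na(reps)] <- 1L
      a1 <- rep(c(at$serial[b$i], at$serial[b$j]), rep(reps, 2))
      a2 <- rep(c(at$serial[b$j], at$serial[b$i]), rep(reps, 2))
      body <- c(body, sprintf("CONECT%5d%5d", a1, a2))
    }
  }
  used_chains <- unique(c(structure$atoms$chain, "w"))
  pred_chain <- setdiff(c("Z", "Y", "X", "V", "U", "0"), used_chains)[1]
  base <- max(c(structure$atoms$serial, structure$waters$serial, 0L))
  if (nrow(predicted)) {
    body <- c(body, fmt("HETATM", base + seq_len(nrow(predicted)), " O",
                        "HOH", pred_chain, seq_len(nrow(predicted)),
                        predicted[, 1], predicted[, 2], predicted[, 3], "O"))
  }
  out <- c(body, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# PDB alignment: element right-justified in columns 13-14
.pdb_atom_name <- function(name, element) {
  ifelse(nchar(element) == 1 & nchar(name) < 4, paste0(" ", name), name)
}

# axis-aligned bounding box of the protein atoms, padded
bounding_box <- function(structure, pad = 0) {
  at <- structure$atoms
  rbind(lo = c(min(at$x), min(at$y), min(at$z)) - pad,
        hi = c(max(at$x), max(at$y), max(at$z)) + pad)
}
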