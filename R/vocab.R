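#' Atom-type vocabulary
#'
#' Discrete atom types index the learnable embedding table.  Types are keyed
#' by (element, heavy-atom degree, hybridization, aromatic flag), the
#' properties that determine an atom's interaction behaviour.  The table
#' enumerates the full cross product over the elements commonly seen in
#' protein heavy atoms, so any atom of those elements maps to a stable id;
#' anything else falls back to the final "unknown" entry.
#'
#' @param elements character vector of element symbols to enumerate.
#' @return A data frame of class `atom_type_vocabulary` with columns
#'   `element`, `degree`, `hyb`, `aromatic`, `key`, plus attributes
#'   `unknown_id` and `water_id` (the id of a lone water oxygen).
#' @export
atom_type_vocabulary <- function(elements = c("C", "N", "O", "S")) {
  grid <- expand.grid(
    aromatic = c(FALSE, TRUE),
    hyb = c("sp", "sp2", "sp3"),
    degree = 0:4,
    element = elements,
    stringsAsFactors = FALSE
  )[, c("element", "degree", "hyb", "aromatic")]
  grid <- rbind(grid, data.frame(element = "X", degree = NA_integer_,
                                 hyb = "none", aromatic = FALSE))
  grid$key <- atom_type_key(grid$element, grid$degree, grid$hyb, grid$aromatic)
  grid$key[nrow(grid)] <- "unknown"
  structure(grid,
            class = c("atom_type_vocabulary", "data.frame"),
            unknown_id = nrow(grid),
            water_id = match(atom_type_key("O", 0L, "sp3", FALSE), grid$key))
}

atom_type_key <- function(element, degree, hyb, aromatic) {
  paste(element, degree, hyb, ifelse(aromatic, "ar", "al"), sep = "|")
}

#' Look up atom type ids
#'
#' Never fails: atoms whose key is not in the vocabulary get the unknown id.
#'
#' @param vocab an [atom_type_vocabulary()].
#' @param element,degree,hyb,aromatic vectors describing each atom.
#' @return integer vector of type ids.
#' @export
atom_type_id <- function(vocab, element, degree, hyb, aromatic) {
  id <- match(atom_type_key(element, degree, hyb, aromatic), vocab$key)
  id[is.na(id)] <- attr(vocab, "unknown_id")
  id
}

#' Bond-type vocabulary
#'
#' Bond types are keyed by bond order / aromaticity; lookups never fail
#' (unknown orders map to the unknown id).
#'
#' @return data frame of class `bond_type_vocabulary` with column `key` and
#'   attribute `unknown_id`.
#' @export
bond_type_vocabulary <- function() {
  v <- data.frame(key = c("single", "double", "triple", "aromatic", "unknown"),
                  stringsAsFactors = FALSE)
  structure(v, class = c("bond_type_vocabulary", "data.frame"),
            unknown_id = nrow(v))
}

#' @rdname bond_type_vocabulary
#' @param vocab a `bond_type_vocabulary`.
#' @param order character vector of bond orders (`"single"`, `"double"`,
#'   `"triple"`, `"aromatic"`).
#' @export
bond_type_id <- function(vocab, order) {
  id <- match(order, vocab$key)
  id[is.na(id)] <- attr(vocab, "unknown_id")
  id
}
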