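# Heavy-atom connectivity templates for the standard amino acids.
# Atoms: NAME:ELEMENT:HYB[:ar]; bonds: A-B:ORDER with ORDER in {1,2,3,a}.
# Hybridization is template-assigned (not geometric) so typing is
# deterministic.  The shared backbone (N, CA, C, O and the C=O double bond)
# is prepended to every residue; OXT is handled at perception time.

.backbone_atoms <- "N:N:sp2 CA:C:sp3 C:C:sp2 O:O:sp2"
.backbone_bonds <- "N-CA:1 CA-C:1 C-O:2"

.sidechains <- list(
  ALA = c("CB:C:sp3", "CA-CB:1"),
  ARG = c("CB:C:sp3 CG:C:sp3 CD:C:sp3 NE:N:sp2 CZ:C:sp2 NH1:N:sp2 NH2:N:sp2",
          "CA-CB:1 CB-CG:1 CG-CD:1 CD-NE:1 NE-CZ:1 CZ-NH1:2 CZ-NH2:1"),
  ASN = c("CB:C:sp3 CG:C:sp2 OD1:O:sp2 ND2:N:sp2",
          "CA-CB:1 CB-CG:1 CG-OD1:2 CG-ND2:1"),
  ASP = c("CB:C:sp3 CG:C:sp2 OD1:O:sp2 OD2:O:sp2",
          "CA-CB:1 CB-CG:1 CG-OD1:2 CG-OD2:1"),
  CYS = c("CB:C:sp3 SG:S:sp3", "CA-CB:1 CB-SG:1"),
  GLN = c("CB:C:sp3 CG:C:sp3 CD:C:sp2 OE1:O:sp2 NE2:N:sp2",
          "CA-CB:1 CB-CG:1 CG-CD:1 CD-OE1:2 CD-NE2:1"),
  GLU = c("CB:C:sp3 CG:C:sp3 CD:C:sp2 OE1:O:sp2 OE2:O:sp2",
          "CA-CB:1 CB-CG:1 CG-CD:1 CD-OE1:2 CD-OE2:1"),
  GLY = c("", ""),
  HIS = c("CB:C:sp3 CG:C:sp2:ar ND1:N:sp2:ar CD2:C:sp2:ar CE1:C:sp2:ar NE2:N:sp2:ar",
          "CA-CB:1 CB-CG:1 CG-ND1:a ND1-CE1:a CE1-NE2:a NE2-CD2:a CD2-CG:a"),
  ILE = c("CB:C:sp3 CG1:C:sp3 CG2:C:sp3 CD1:C:sp3",
          "CA-CB:1 CB-CG1:1 CB-CG2:1 CG1-CD1:1"),
  LEU = c("CB:C:sp3 CG:C:sp3 CD1:C:sp3 CD2:C:sp3",
          "CA-CB:1 CB-CG:1 CG-CD1:1 CG-CD2:1"),
  LYS = c("CB:C:sp3 CG:C:sp3 CD:C:sp3 CE:C:sp3 NZ:N:sp3",
          "CA-CB:1 CB-CG:1 CG-CD:1 CD-CE:1 CE-NZ:1"),
  MET = c("CB:C:sp3 CG:C:sp3 SD:S:sp3 CE:C:sp3",
          "CA-CB:1 CB-CG:1 CG-SD:1 SD-CE:1"),
  PHE = c("CB:C:sp3 CG:C:sp2:ar CD1:C:sp2:ar CD2:C:sp2:ar CE1:C:sp2:ar CE2:C:sp2:ar CZ:C:sp2:ar",
          "CA-CB:1 CB-CG:1 CG-CD1:a CD1-CE1:a CE1-CZ:a CZ-CE2:a CE2-CD2:a CD2-CG:a"),
  PRO = c("CB:C:sp3 CG:C:sp3 CD:C:sp3",
          "CA-CB:1 CB-CG:1 CG-CD:1 CD-N:1"),
  SER = c("CB:C:sp3 OG:O:sp3", "CA-CB:1 CB-OG:1"),
  THR = c("CB:C:sp3 OG1:O:sp3 CG2:C:sp3", "CA-CB:1 CB-OG1:1 CB-CG2:1"),
  TRP = c(paste("CB:C:sp3 CG:C:sp2:ar CD1:C:sp2:ar NE1:N:sp2:ar CE2:C:sp2:ar",
                "CD2:C:sp2:ar CE3:C:sp2:ar CZ2:C:sp2:ar CZ3:C:sp2:ar CH2:C:sp2:ar"),
          paste("CA-CB:1 CB-CG:1 CG-CD1:a CD1-NE1:a NE1-CE2:a CE2-CD2:a CD2-CG:a",
                "CD2-CE3:a CE3-CZ3:a CZ3-CH2:a CH2-CZ2:a CZ2-CE2:a")),
  TYR = c("CB:C:sp3 CG:C:sp2:ar CD1:C:sp2:ar CD2:C:sp2:ar CE1:C:sp2:ar CE2:C:sp2:ar CZ:C:sp2:ar OH:O:sp3",
          "CA-CB:1 CB-CG:1 CG-CD1:a CD1-CE1:a CE1-CZ:a CZ-CE2:a CE2-CD2:a CD2-CG:a CZ-OH:1"),
  VAL = c("CB:C:sp3 CG1:C:sp3 CG2:C:sp3", "CA-CB:1 CB-CG1:1 CB-CG2:1")
)

.parse_atom_spec <- function(txt) {
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) {
    return(data.frame(name = character(), element = character(),
                      hyb = character(), aromatic = logical()))
  }
  parts <- strsplit(toks, ":", fixed = TRUE)
  data.frame(
    name = vapply(parts, `[`, "", 1L),
    element = vapply(parts, `[`, "", 2L),
    hyb = vapply(parts, `[`, "", 3L),
    aromatic = vapply(parts, function(x) length(x) > 3 && x[4] == "ar", TRUE),
    stringsAsFactors = FALSE
  )
}

.parse_bond_spec <- function(txt) {
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) {
    return(data.frame(a = character(), b = character(), order = character()))
  }
  parts <- strsplit(toks, "[-:]")
  ord <- vapply(parts, `[`, "", 3L)
  data.frame(
    a = vapply(parts, `[`, "", 1L),
    b = vapply(parts, `[`, "", 2L),
    order = c("1" = "single", "2" = "double", "3" = "triple",
              "a" = "aromatic")[ord],
    stringsAsFactors = FALSE
  )
}

# Returns list(resname -> list(atoms = df, bonds = df)); memoised.
residue_templates <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    out <- lapply(.sidechains, function(sc) {
      atoms <- rbind(.parse_atom_spec(.backbone_atoms), .parse_atom_spec(sc[1]))
      bonds <- rbind(.parse_bond_spec(.backbone_bonds), .parse_bond_spec(sc[2]))
      list(atoms = atoms, bonds = bonds)
    })
    cache <<- out
    out
  }
})
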