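# Molecular topology templates for HA oligosaccharides.
#
# A topology is an ordered internal-coordinate build tree: every atom is
# placed once from three previously placed reference atoms with a bond
# length (A), bond angle (deg) and a dihedral slot that is either fixed or
# bound to a named torsion (plus a fixed offset for substituents that ride
# on the same rotatable bond). Closed pyranose rings are treated as rigid
# bodies: their dihedrals are fixed at idealised 4C1-chair values and only
# the listed rotatable bonds of the opened reducing terminus (and its
# label) are free. Bond lengths and angles are standard carbohydrate/
# aromatic values (C-C 1.52, C-O 1.43, C-N 1.47, Car-Car 1.39, C=O 1.25,
# sp3 109.5 deg, sp2 120 deg).

BOND <- c(CC = 1.52, CO = 1.43, CN = 1.47, NH = 1.01, CH = 1.09,
          CAR = 1.39, CARN = 1.40, CARC = 1.49, CDO = 1.25)
ANG <- c(SP3 = 109.5, SP2 = 120, RING_O = 111.5, CARBOX = 123)

new_tree_builder <- function() {
  rows <- list()
  add <- function(atom, ref1 = NA, ref2 = NA, ref3 = NA, length = NA,
                  angle = NA, torsion = NA_character_, offset = 0) {
    rows[[base::length(rows) + 1L]] <<- data.frame(
      atom = atom, ref1 = ref1, ref2 = ref2, ref3 = ref3,
      length = length, angle = angle, torsion = torsion, offset = offset,
      stringsAsFactors = FALSE)
    invisible(atom)
  }
  list(add = add, tree = function() do.call(rbind, rows))
}

element_of <- function(atom_id) {
  # atom ids look like "T4 C2", "X5 HN11", "S2 OG"
  a <- sub("^\\S+ ", "", atom_id)
  substr(a, 1, 1)
}

# Append one closed pyranose ring (rigid) entered from the previous
# residue's anomeric carbon through a glycosidic oxygen. `res` is the
# residue label; `prev` the anomeric carbon (and two ring atoms) of the
# previous residue. Returns atom ids of this ring.
add_closed_ring <- function(b, res, prev_c1, prev_r2, prev_r3,
                            glca = FALSE, carbox_torsion = NA) {
  og <- paste(res, "OG")
  c4 <- paste(res, "C4"); c3 <- paste(res, "C3"); c5 <- paste(res, "C5")
  c2 <- paste(res, "C2"); c1 <- paste(res, "C1"); o5 <- paste(res, "O5")
  b$add(og, prev_c1, prev_r2, prev_r3, BOND["CO"], ANG["SP3"], offset = -60)
  b$add(c4, og, prev_c1, prev_r2, BOND["CO"], 117, offset = -120)
  b$add(c3, c4, og, prev_c1, BOND["CC"], ANG["SP3"], offset = 170)
  b$add(c5, c4, og, prev_c1, BOND["CC"], ANG["SP3"], offset = 50)
  b$add(c2, c3, c4, c5, BOND["CC"], ANG["SP3"], offset = 55)
  b$add(c1, c2, c3, c4, BOND["CC"], ANG["SP3"], offset = -55)
  b$add(o5, c5, c4, c3, BOND["CO"], ANG["RING_O"], offset = -55)
  if (glca) {
    c6 <- paste(res, "C6")
    b$add(c6, c5, c4, c3, BOND["CC"], ANG["SP3"], offset = 65)
    b$add(paste(res, "O6A"), c6, c5, c4, BOND["CDO"], ANG["SP2"],
          torsion = carbox_torsion,
          offset = if (is.na(carbox_torsion)) 0 else 0)
    b$add(paste(res, "O6B"), c6, paste(res, "O6A"), c5, BOND["CDO"],
          ANG["CARBOX"], offset = 180)
  }
  add_ring_protons(b, res)
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, o5 = o5)
}

# fixed ring CH protons (NOE partners); staggered placements
add_ring_protons <- function(b, res) {
  p <- function(h, a, r2, r3, off)
    b$add(paste(res, h), paste(res, a), paste(res, r2), paste(res, r3),
          BOND["CH"], ANG["SP3"], offset = off)
  p("H1", "C1", "C2", "C3", 65)
  p("H2", "C2", "C3", "C4", 175)
  p("H3", "C3", "C4", "C5", -65)
  p("H4", "C4", "C3", "C2", 170)
  p("H5", "C5", "C4", "C3", -175)
  invisible(NULL)
}

#' Molecular topology of a (modified) HA oligosaccharide
#'
#' Builds the internal-coordinate template for an HA oligomer of
#' `n_residues` monosaccharides (GlcA/GlcNAc alternating, nonreducing
#' terminal GlcA, reducing terminal GlcNAc). With
#' `modification = "2AA"` the reducing GlcNAc ring is opened (reductive
#' amination) and carries a 2-aminobenzoate label; the opened chain and
#' label contribute the 11 rotatable bonds of the dynamic region, named
#' with the role labels of the tetrasaccharide nomenclature
#' (`G3` penultimate GlcA, `T4` opened GlcNAc, `X5` aminobenzoate) so that
#' one dynamic model drives any oligomer length. Explicit hydrogens are
#' included on the opened chain and the aniline nitrogen (the atoms used in
#' restraints and hydrogen-bond checks); elsewhere hydrogens are implicit.
#'
#' @param n_residues even number of monosaccharides (4 or 6 in the shipped
#'   fixtures).
#' @param modification `"2AA"` (opened reducing ring with 2-aminobenzoate)
#'   or `"none"` (unmodified closed ring; rigid template with no free
#'   torsions).
#' @return an object of class `glyco_topology`: list with `atoms`
#'   (data.frame id/element/residue), `tree` (build records), `bonds`,
#'   `anchor` (ids of atoms not downstream of any free torsion),
#'   `torsion_atoms` (named list of defining quadruples),
#'   `carboxylate_oxygens`, `aromatic_carbons`, `hbond_donors` /
#'   `hbond_acceptors`, and `stereocenters`.
#' @export
ha_topology <- function(n_residues = 4, modification = c("2AA", "none")) {
  modification <- match.arg(modification)
  stopifnot(n_residues >= 2, n_residues %% 2 == 0)
  b <- new_tree_builder()

  n_closed <- if (modification == "2AA") n_residues - 1L else n_residues
  res_labels <- character(n_closed)
  for (i in seq_len(n_closed)) {
    glca <- (i %% 2 == 1L)              # odd positions are GlcA
    res_labels[i] <-
      if (i == n_closed && modification == "2AA") "G3"
      else paste0(if (glca) "A" else "S", i)
  }

  # first ring seeded explicitly (origin / +x / xy-plane convention)
  r1 <- res_labels[1]
  c1 <- paste(r1, "C1"); c2 <- paste(r1, "C2"); c3 <- paste(r1, "C3")
  c4 <- paste(r1, "C4"); c5 <- paste(r1, "C5"); o5 <- paste(r1, "O5")
  b$add(c4, length = 0)
  b$add(c3, c4, length = BOND["CC"])
  b$add(c5, c4, c3, length = BOND["CC"], angle = ANG["SP3"])
  b$add(c2, c3, c4, c5, BOND["CC"], ANG["SP3"], offset = 55)
  b$add(c1, c2, c3, c4, BOND["CC"], ANG["SP3"], offset = -55)
  b$add(o5, c5, c4, c3, BOND["CO"], ANG["RING_O"], offset = -55)
  add_ring_protons(b, r1)
  ring <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, o5 = o5)

  for (i in seq_len(n_closed)[-1]) {
    lab <- res_labels[i]
    ring <- add_closed_ring(
      b, lab, ring["c1"], ring["c2"], ring["c3"],
      glca = (i %% 2 == 1L),
      carbox_torsion = if (lab == "G3") "G3 C5-C6" else NA)
  }

  torsion_atoms <- list()
  stereocenters <- list()
  if (modification == "2AA") {
    g1 <- ring["c1"]; g5o <- ring["o5"]; g2 <- ring["c2"]
    # opened GlcNAc chain (T4) entered at C3 via the 1->3 glycosidic link
    b$add("T4 O3", g1, g5o, ring["c5"], BOND["CO"], 108, offset = -60)
    b$add("T4 C3", "T4 O3", g1, g5o, BOND["CO"], 116,
          torsion = "G3-T4 phi")
    b$add("T4 C2", "T4 C3", "T4 O3", g1, BOND["CC"], ANG["SP3"],
          torsion = "G3-T4 psi")
    b$add("T4 C4", "T4 C3", "T4 O3", g1, BOND["CC"], ANG["SP3"],
          torsion = "G3-T4 psi", offset = -120)
    b$add("T4 H3", "T4 C3", "T4 O3", g1, BOND["CH"], ANG["SP3"],
          torsion = "G3-T4 psi", offset = 120)
    b$add("T4 C1", "T4 C2", "T4 C3", "T4 C4", BOND["CC"], ANG["SP3"],
          torsion = "T4 C2-C3")
    b$add("T4 H2", "T4 C2", "T4 C3", "T4 C4", BOND["CH"], ANG["SP3"],
          torsion = "T4 C2-C3", offset = 120)
    b$add("T4 N2", "T4 C2", "T4 C3", "T4 C4", BOND["CN"], ANG["SP3"],
          torsion = "T4 C2-C3", offset = -120)
    b$add("T4 C5", "T4 C4", "T4 C3", "T4 C2", BOND["CC"], ANG["SP3"],
          torsion = "T4 C3-C4")
    b$add("T4 O4", "T4 C4", "T4 C3", "T4 C2", BOND["CO"], ANG["SP3"],
          torsion = "T4 C3-C4", offset = 120)
    b$add("T4 H4", "T4 C4", "T4 C3", "T4 C2", BOND["CH"], ANG["SP3"],
          torsion = "T4 C3-C4", offset = -120)
    b$add("T4 C6", "T4 C5", "T4 C4", "T4 C3", BOND["CC"], ANG["SP3"],
          torsion = "T4 C4-C5")
    b$add("T4 O5", "T4 C5", "T4 C4", "T4 C3", BOND["CO"], ANG["SP3"],
          torsion = "T4 C4-C5", offset = 120)
    b$add("T4 H5", "T4 C5", "T4 C4", "T4 C3", BOND["CH"], ANG["SP3"],
          torsion = "T4 C4-C5", offset = -120)
    b$add("T4 O6", "T4 C6", "T4 C5", "T4 C4", BOND["CO"], ANG["SP3"],
          torsion = "T4 C5-C6")
    b$add("T4 H6A", "T4 C6", "T4 C5", "T4 C4", BOND["CH"], ANG["SP3"],
          torsion = "T4 C5-C6", offset = 120)
    b$add("T4 H6B", "T4 C6", "T4 C5", "T4 C4", BOND["CH"], ANG["SP3"],
          torsion = "T4 C5-C6", offset = -120)
    b$add("X5 N11", "T4 C1", "T4 C2", "T4 C3", BOND["CN"], ANG["SP3"],
          torsion = "T4 C1-C2")
    b$add("T4 H1A", "T4 C1", "T4 C2", "T4 C3", BOND["CH"], ANG["SP3"],
          torsion = "T4 C1-C2", offset = 120)
    b$add("T4 H1B", "T4 C1", "T4 C2", "T4 C3", BOND["CH"], ANG["SP3"],
          torsion = "T4 C1-C2", offset = -120)
    b$add("X5 C7", "X5 N11", "T4 C1", "T4 C2", BOND["CARN"], ANG["SP2"],
          torsion = "T4 C1-X5 NH11")
    b$add("X5 HN11", "X5 N11", "X5 C7", "T4 C1", BOND["NH"], 118,
          offset = 180)   # sp2 N: H in the C1-N-C7 plane, anti to C1
    b$add("X5 C8", "X5 C7", "X5 N11", "T4 C1", BOND["CAR"], ANG["SP2"],
          torsion = "X5 N11-C7")
    b$add("X5 C9", "X5 C8", "X5 C7", "X5 N11", BOND["CAR"], ANG["SP2"],
          offset = 180)
    b$add("X5 C10", "X5 C9", "X5 C8", "X5 C7", BOND["CAR"], ANG["SP2"],
          offset = 0)
    b$add("X5 C11", "X5 C10", "X5 C9", "X5 C8", BOND["CAR"], ANG["SP2"],
          offset = 0)
    b$add("X5 C12", "X5 C11", "X5 C10", "X5 C9", BOND["CAR"], ANG["SP2"],
          offset = 0)
    b$add("X5 C13", "X5 C8", "X5 C7", "X5 N11", BOND["CARC"], ANG["SP2"],
          offset = 0)   # ortho substituent, same side as the aniline H
    b$add("X5 O7A", "X5 C13", "X5 C8", "X5 C7", BOND["CDO"], ANG["SP2"],
          torsion = "X5 C8-C13")
    b$add("X5 O7B", "X5 C13", "X5 O7A", "X5 C8", BOND["CDO"],
          ANG["CARBOX"], offset = 180)

    g1 <- unname(g1); g5o <- unname(g5o)
    torsion_atoms <- list(
      "G3-T4 phi"      = c("T4 C3", "T4 O3", g1, g5o),
      "G3-T4 psi"      = c("T4 C2", "T4 C3", "T4 O3", g1),
      "T4 C2-C3"       = c("T4 C1", "T4 C2", "T4 C3", "T4 C4"),
      "T4 C3-C4"       = c("T4 C5", "T4 C4", "T4 C3", "T4 C2"),
      "T4 C4-C5"       = c("T4 C6", "T4 C5", "T4 C4", "T4 C3"),
      "T4 C5-C6"       = c("T4 O6", "T4 C6", "T4 C5", "T4 C4"),
      "T4 C1-C2"       = c("X5 N11", "T4 C1", "T4 C2", "T4 C3"),
      "T4 C1-X5 NH11"  = c("X5 C7", "X5 N11", "T4 C1", "T4 C2"),
      "X5 N11-C7"      = c("X5 C8", "X5 C7", "X5 N11", "T4 C1"),
      "X5 C8-C13"      = c("X5 O7A", "X5 C13", "X5 C8", "X5 C7"),
      "G3 C5-C6"       = c("G3 O6A", "G3 C6", "G3 C5", "G3 C4"))
    stereocenters <- list(
      c("T4 C2", "T4 C1", "T4 C3", "T4 H2"),
      c("T4 C4", "T4 C3", "T4 C5", "T4 O4"),
      c("T4 C5", "T4 C4", "T4 C6", "T4 O5"))
  }

  tree <- b$tree()
  ids <- tree$atom
  atoms <- data.frame(
    id = ids,
    element = vapply(ids, element_of, ""),
    residue = sub(" .*$", "", ids),
    stringsAsFactors = FALSE)

  bonds <- data.frame(a1 = tree$atom[-(1:2)][!is.na(tree$ref1[-(1:2)])],
                      a2 = tree$ref1[-(1:2)][!is.na(tree$ref1[-(1:2)])],
                      stringsAsFactors = FALSE)
  bonds <- rbind(bonds, data.frame(a1 = tree$atom[2], a2 = tree$ref1[2]))
  # ring closure bonds (not built, listed for completeness)
  for (r in unique(atoms$residue)) {
    a <- paste(r, "C1"); o <- paste(r, "O5")
    if (a %in% ids && o %in% ids && !(r %in% c("T4", "X5")))
      bonds <- rbind(bonds, data.frame(a1 = a, a2 = o))
  }

  # anchored = placed with a fixed dihedral from anchored references
  anchored <- logical(nrow(tree)); names(anchored) <- ids
  for (i in seq_len(nrow(tree))) {
    refs <- c(tree$ref1[i], tree$ref2[i], tree$ref3[i])
    refs <- refs[!is.na(refs)]
    anchored[i] <- is.na(tree$torsion[i]) && all(anchored[refs])
  }

  els <- atoms$element
  topo <- structure(list(
    atoms = atoms, tree = tree, bonds = bonds,
    anchor = ids[anchored],
    torsion_atoms = torsion_atoms,
    carboxylate_oxygens = intersect(c("X5 O7A", "X5 O7B"), ids),
    aromatic_carbons = intersect(paste("X5", paste0("C", 7:12)), ids),
    hbond_donors = ids[els %in% c("O", "N")],
    hbond_acceptors = ids[els == "O"],
    stereocenters = stereocenters,
    n_residues = n_residues, modification = modification),
    class = "glyco_topology")
  topo
}

#' Names of the free torsions of a topology
#' @param topology a `glyco_topology`.
#' @return character vector in tree order.
#' @export
topology_torsions <- function(topology)
  unique(topology$tree$torsion[!is.na(topology$tree$torsion)])

#' @export
print.glyco_topology <- function(x, ...) {
  cat(sprintf("HA topology: %d residues (%s), %d atoms, %d free torsions, %d anchor atoms\n",
              x$n_residues, x$modification, nrow(x$atoms),
              length(topology_torsions(x)), length(x$anchor)))
  invisible(x)
}

#' Write a topology to JSON
#' @param topology a `glyco_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  x <- topology
  class(x) <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a topology from JSON written by [write_topology()]
#' @param path file path.
#' @return a `glyco_topology`.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$tree <- as.data.frame(x$tree, stringsAsFactors = FALSE)
  x$tree$torsion <- as.character(x$tree$torsion)
  x$tree$torsion[x$tree$torsion == "NA"] <- NA_character_
  x$atoms <- as.data.frame(x$atoms, stringsAsFactors = FALSE)
  x$bonds <- as.data.frame(x$bonds, stringsAsFactors = FALSE)
  x$stereocenters <- lapply(x$stereocenters, unlist)
  x$torsion_atoms <- lapply(x$torsion_atoms, unlist)
  structure(x, class = "glyco_topology")
}
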