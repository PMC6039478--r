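## Protein structure input: PDB via bio3d plus a delimited nonbonded
## parameter table (residue, atom, charge, sigma, epsilon).

.ring_templates <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HIE = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HID = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

#' Read a nonbonded parameter table
#'
#' Delimited text (tab or comma) with header columns `resid`, `atom`,
#' `charge`, `sigma`, `epsilon`: partial charge in e, Lennard-Jones sigma in
#' Angstrom and epsilon in kcal/mol per (residue name, atom name) pair. A
#' table covering TIP3P water and a minimal amino-acid set ships in
#' `system.file("extdata", "ff_params.tsv", package = "waterpharm")`.
#'
#' @param path file path.
#' @return data.frame with the five columns above.
#' @export
read_param_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("resid", "atom", "charge", "sigma", "epsilon")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  tab[need]
}

## Polarity classes from element + geometry: H within 1.3 A of N/O is a
## polar donor hydrogen; N and O are acceptors; C, S and halogens are
## nonpolar; anything else (including aliphatic H) is "other".
.assign_polarity <- function(atoms) {
  el <- toupper(atoms$element)
  pol <- rep("other", nrow(atoms))
  pol[el %in% c("N", "O")] <- "polar-acceptor"
  pol[el %in% c("C", "S", "F", "CL", "BR", "I")] <- "nonpolar"
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  h_idx <- which(el == "H")
  no_idx <- which(el %in% c("N", "O"))
  donors <- data.frame(h = integer(0), heavy = integer(0))
  if (length(h_idx) && length(no_idx)) {
    for (i in h_idx) {
      d2 <- colSums((t(xyz[no_idx, , drop = FALSE]) - xyz[i, ])^2)
      j <- which.min(d2)
      if (d2[j] <= 1.3^2) {
        pol[i] <- "polar-donor-H"
        donors <- rbind(donors, data.frame(h = i, heavy = no_idx[j]))
      }
    }
  }
  list(polarity = pol, donors = donors)
}

.detect_rings <- function(atoms) {
  rings <- data.frame(resno = integer(0), cx = numeric(0), cy = numeric(0),
                      cz = numeric(0), nx = numeric(0), ny = numeric(0),
                      nz = numeric(0))
  members <- list()
  for (rn in unique(atoms$resno)) {
    sel <- atoms$resno == rn
    resname <- atoms$resid[sel][1]
    tmpl <- .ring_templates[[resname]]
    if (is.null(tmpl)) next
    for (ring_atoms in tmpl) {
      idx <- which(sel & atoms$elety %in% ring_atoms)
      if (length(idx) != length(ring_atoms)) next
      X <- as.matrix(atoms[idx, c("x", "y", "z")])
      ctr <- colMeans(X)
      nrm <- plane_normal(X)
      rings <- rbind(rings, data.frame(resno = rn, cx = ctr[1], cy = ctr[2],
                                       cz = ctr[3], nx = nrm[1], ny = nrm[2],
                                       nz = nrm[3]))
      members[[length(members) + 1L]] <- idx
    }
  }
  rings$members <- members
  rings
}

#' Construct a protein structure from an atom table
#'
#' Low-level constructor used by the readers and the synthetic-scene
#' generator. Polarity classes, donor hydrogen pairings and aromatic rings
#' (PHE/TYR/TRP/HIS residue templates) are derived here.
#'
#' @param atoms data.frame with columns `eleno`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z`, `charge`, `sigma`, `epsilon`.
#' @return object of class `protein_structure`: list with `atoms` (the table
#'   plus a `polarity` column), `rings` (centroid + unit normal per detected
#'   aromatic ring) and `donors` (polar H / heavy-atom index pairs).
#' @export
protein_structure <- function(atoms) {
  need <- c("eleno", "resno", "resid", "elety", "element",
            "x", "y", "z", "charge", "sigma", "epsilon")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in protein atoms")
  pol <- .assign_polarity(atoms)
  atoms$polarity <- pol$polarity
  structure(list(atoms = atoms, rings = .detect_rings(atoms),
                 donors = pol$donors),
            class = "protein_structure")
}

#' Read a protein structure from PDB plus a parameter table
#'
#' Parses a standard single-model PDB (via \pkg{bio3d}) and attaches partial
#' charges and Lennard-Jones parameters from the table. Water residues must
#' not appear in the protein file; use [read_water_frames()] for trajectories.
#'
#' @param path PDB file path.
#' @param params parameter-table path (see [read_param_table()]) or an
#'   already-read parameter data.frame.
#' @return `protein_structure` object.
#' @export
read_protein <- function(path, params) {
  if (is.character(params)) params <- read_param_table(params)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(at$resid %in% c("HOH", "WAT", "TIP3", "SOL")))
    stop("HOH found in protein file: water belongs in the trajectory; ",
         "use read_water_frames()")
  element <- at$elesy
  if (is.null(element) || any(is.na(element) | element == ""))
    element <- substr(gsub("[0-9]", "", trimws(at$elety)), 1, 1)
  atoms <- data.frame(eleno = at$eleno, resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety), element = trimws(element),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  key <- paste(atoms$resid, atoms$elety)
  pkey <- paste(params$resid, params$atom)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("no nonbonded parameters for atom(s): ", paste(bad, collapse = ", "))
  }
  atoms$charge <- params$charge[idx]
  atoms$sigma <- params$sigma[idx]
  atoms$epsilon <- params$epsilon[idx]
  protein_structure(atoms)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      nrow(x$rings), "aromatic ring(s),",
      nrow(x$donors), "polar donor H\n")
  invisible(x)
}
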