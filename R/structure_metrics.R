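# Geometry-only metrics on coordinate files: labelled-residue Cb-Cb
# distances, lateral-gate widths, and minimum side-chain contact distances.
# Atom-level distances are in Angstrom; lateral-gate summaries in nm.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read a coordinate file into a structure model
#'
#' Parses a PDB file (via bio3d) into a flat atom table. Only the first
#' model of multi-model files is used; for alternate locations the
#' highest-occupancy conformer is kept, ties resolved in favour of
#' alt-loc 'A'. Hydrogens are dropped.
#'
#' @param path Path to a PDB file.
#' @return Object of class `structure_model`: data frame with columns
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`; attribute
#'   `source` records the path.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[!grepl("^H", trimws(a$elety)), , drop = FALSE]
  if ("alt" %in% names(a) && any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$chain, a$resno, a$elety)
    keep <- rep(TRUE, nrow(a))
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      occ <- a$o[rows]; occ[is.na(occ)] <- 1
      best <- rows[order(-occ, a$alt[rows])][1]
      keep[setdiff(rows, best)] <- FALSE
    }
    a <- a[keep, , drop = FALSE]
  }
  structure_model(a$chain, a$resno, a$resid, trimws(a$elety),
                  a$x, a$y, a$z, source = path)
}

#' Construct a structure model from atom vectors
#'
#' Useful for building synthetic test structures in code.
#'
#' @param chain,resno,resid,elety,x,y,z Parallel atom attribute vectors
#'   (chain id, residue number, residue name, atom name, coordinates in
#'   Angstrom).
#' @param source Identifier recorded on the object.
#' @return A `structure_model`.
#' @export
structure_model <- function(chain, resno, resid, elety, x, y, z,
                            source = "in-memory") {
  d <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                  resid = as.character(resid),
                  elety = as.character(elety),
                  x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (any(!is.finite(c(d$x, d$y, d$z)))) {
    stop_invalid("coordinates must be finite")
  }
  attr(d, "source") <- source
  class(d) <- c("structure_model", "data.frame")
  d
}

get_atom <- function(struct, chain, resno, atom_name, cb_fallback = TRUE) {
  rows <- struct[struct$chain == chain & struct$resno == resno, ,
                 drop = FALSE]
  if (nrow(rows) == 0) {
    stop_invalid("residue ", chain, "/", resno, " not found")
  }
  hit <- rows[rows$elety == atom_name, , drop = FALSE]
  if (nrow(hit) == 0 && atom_name == "CB" && cb_fallback) {
    # glycine has no Cb; fall back to Ca
    hit <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(hit) > 0) {
      message("residue ", chain, "/", resno,
              ": no CB atom, using CA instead")
    }
  }
  if (nrow(hit) == 0) {
    stop_invalid("atom ", atom_name, " not found in residue ",
                 chain, "/", resno)
  }
  as.numeric(hit[1, c("x", "y", "z")])
}

#' Distance between named atoms of two residues
#'
#' Euclidean distance in Angstrom between `atom_name` atoms of two sites,
#' e.g. the Cb-Cb separation of a labelled cysteine pair. For glycine a
#' requested Cb silently falls back to Ca (with a message).
#'
#' @param struct A `structure_model`.
#' @param siteA,siteB Sites as `list(chain =, resno =)` or a length-2
#'   vector `c(chain, resno)`.
#' @param atom_name Atom name (default `"CB"`).
#' @return Distance in Angstrom.
#' @export
residue_pair_distance <- function(struct, siteA, siteB,
                                  atom_name = "CB") {
  stopifnot(inherits(struct, "structure_model"))
  site <- function(s) {
    if (is.list(s)) list(chain = s$chain, resno = as.integer(s$resno))
    else list(chain = as.character(s[1]), resno = as.integer(s[2]))
  }
  a <- site(siteA); b <- site(siteB)
  pa <- get_atom(struct, a$chain, a$resno, atom_name)
  pb <- get_atom(struct, b$chain, b$resno, atom_name)
  sqrt(sum((pa - pb)^2))
}

#' Lateral-gate width from residue pairs across the gate
#'
#' Distances between residue pairs spanning the interface between the
#' channel's TM2/3 and TM7 helices; the default pairs 124/275, 127/278
#' and 130/282 follow the Thermotoga numbering used for the gate. Atom
#' distances are measured in Angstrom and reported in nm, with their
#' mean, matching the usual axis convention of gate-width plots.
#'
#' @param struct A `structure_model`.
#' @param pairs List of length-2 residue-number vectors (default
#'   `list(c(124, 275), c(127, 278), c(130, 282))`).
#' @param chain Chain id holding the channel residues.
#' @param atom_name Atom to measure between (default `"CA"`).
#' @return List with `per_pair` (named nm distances) and `mean_nm`.
#' @export
lateral_gate_width <- function(struct,
                               pairs = list(c(124, 275), c(127, 278),
                                            c(130, 282)),
                               chain = "A", atom_name = "CA") {
  d <- vapply(pairs, function(p) {
    residue_pair_distance(struct, c(chain, p[1]), c(chain, p[2]),
                          atom_name = atom_name) / 10
  }, numeric(1))
  names(d) <- vapply(pairs, function(p) paste(p, collapse = "/"),
                     character(1))
  list(per_pair = d, mean_nm = mean(d))
}

#' Minimum side-chain heavy-atom distance between two residues
#'
#' Minimum over all pairs of side-chain heavy atoms (backbone N, CA, C,
#' O excluded), e.g. for salt-bridge contact analysis.
#'
#' @param struct A `structure_model`.
#' @param residueA,residueB Sites as for [residue_pair_distance()].
#' @return Minimum distance in Angstrom.
#' @export
min_sidechain_distance <- function(struct, residueA, residueB) {
  stopifnot(inherits(struct, "structure_model"))
  side_atoms <- function(s) {
    ch <- if (is.list(s)) s$chain else as.character(s[1])
    rn <- if (is.list(s)) as.integer(s$resno) else as.integer(s[2])
    rows <- struct[struct$chain == ch & struct$resno == rn &
                     !(struct$elety %in% BACKBONE_ATOMS), , drop = FALSE]
    if (nrow(rows) == 0) {
      stop_invalid("residue ", ch, "/", rn, " has no side-chain atoms")
    }
    as.matrix(rows[, c("x", "y", "z")])
  }
  a <- side_atoms(residueA); b <- side_atoms(residueB)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}
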