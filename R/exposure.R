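# Solvent exposure: Shrake-Rupley SASA and the embedded-position mask -------

#' Van der Waals radii used by the surface engine
#'
#' Heavy-atom radii in Angstrom; hydrogens are ignored throughout
#' (heavy-atom SASA, the convention of classic surface servers).
#' @export
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

# heavy side-chain atom counts for completeness flagging
SIDE_CHAIN_SIZE <- c(
  ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5, GLU = 5, GLY = 0,
  HIS = 6, ILE = 4, LEU = 4, LYS = 5, MET = 4, PHE = 7, PRO = 3, SER = 2,
  THR = 3, TRP = 10, TYR = 8, VAL = 3
)

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Random-coil side-chain reference areas (Angstrom^2)
#'
#' Per-residue side-chain solvent-accessible surface area of residue X in an
#' extended Gly-X-Gly tripeptide, computed with this package's own surface
#' engine (probe 1.4 A, 960 quadrature points, heavy atoms, packaged van der
#' Waals radii) on idealized residue geometries. These normalize observed
#' side-chain areas into exposure ratios; glycine has no heavy side-chain
#' atom, so its entry is unused and set to NA. Override with your own table
#' via the `coil_refs` argument of the exposure functions if you prefer
#' another convention.
#' @export
COIL_SIDE_CHAIN_REF <- c(
  ALA =  46.3, ARG = 186.2, ASN = 100.9, ASP = 100.4, CYS =  80.1,
  GLN = 127.3, GLU = 128.2, GLY =    NA, HIS = 125.8, ILE = 109.9,
  LEU = 123.2, LYS = 147.4, MET = 136.2, PHE = 153.2, PRO =  67.7,
  SER =  62.1, THR =  87.5, TRP = 196.5, TYR = 170.6, VAL =  94.7
)

#' Bundle atoms into a structure
#'
#' @param atoms data.frame with columns `atom` (PDB atom name), `element`,
#'   `resno`, `resname`, `chain`, `x`, `y`, `z` (Angstrom).
#' @param radii named van der Waals radii; defaults to [VDW_RADII].
#' @return An object of class `atom_structure`.
#' @export
atom_structure <- function(atoms, radii = VDW_RADII) {
  needed <- c("atom", "element", "resno", "resname", "chain", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) stop("atoms lack column(s): ",
                                paste(missing, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  if (any(radii <= 0)) stop("radii must be positive")
  atoms$element <- toupper(atoms$element)
  structure(list(atoms = atoms, radii = radii), class = "atom_structure")
}

#' @export
print.atom_structure <- function(x, ...) {
  cat(sprintf("<atom_structure> %d atoms, %d residue(s)\n", nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Read ATOM records from a PDB file
#'
#' HETATM records and hydrogens are dropped. All chains present are kept, so
#' exposure is computed in the context of whatever assembly the file holds.
#'
#' @param path PDB file.
#' @param radii forwarded to [atom_structure()].
#' @return An `atom_structure`.
#' @export
read_pdb_structure <- function(path, radii = VDW_RADII) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- toupper(trimws(a$elesy))
  fallback <- toupper(substr(trimws(a$elety), 1, 1))
  elem[!nzchar(elem)] <- fallback[!nzchar(elem)]
  keep <- elem != "H"
  atom_structure(data.frame(
    atom = trimws(a$elety)[keep], element = elem[keep],
    resno = a$resno[keep], resname = trimws(a$resid)[keep],
    chain = a$chain[keep], x = a$x[keep], y = a$y[keep], z = a$z[keep],
    stringsAsFactors = FALSE), radii = radii)
}

#' Write a structure as a PDB file
#'
#' @param s an `atom_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resname, eleno = seq_len(nrow(a)),
                   elety = a$atom, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

# deterministic golden-spiral quadrature points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Solvent-accessible surface area, Shrake-Rupley quadrature
#'
#' Rolls a spherical probe over the heavy atoms: each atom is inflated by the
#' probe radius and sampled on a deterministic golden-spiral point set; a
#' point is accessible when outside every neighbouring inflated sphere. The
#' per-atom area is the accessible fraction of the inflated sphere.
#'
#' @param s an `atom_structure`.
#' @param probe_radius probe radius in Angstrom (water, 1.4).
#' @param n_points quadrature points per atom (>= 12). 960 points keep the
#'   quadrature error comfortably inside 1% on isolated spheres.
#' @return Numeric vector of per-atom areas (Angstrom^2), same order as the
#'   atom table.
#' @export
sasa <- function(s, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(s, "atom_structure"))
  n_points <- as.integer(n_points)
  if (n_points < 12L) stop("n_points must be >= 12")
  a <- s$atoms
  unknown <- setdiff(unique(a$element), names(s$radii))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "),
         " (atoms ", paste(which(a$element %in% unknown), collapse = ","), ")")
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- unname(s$radii[a$element]) + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  areas <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      areas[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      accessible <- accessible & (dj >= R[j]^2)
      if (!any(accessible)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * sum(accessible) / n_points
  }
  areas
}

#' Side-chain exposure of one residue
#'
#' Sums SASA over the residue's non-backbone heavy atoms and normalizes by
#' the residue's random-coil reference to give the exposure ratio. Glycine
#' has no heavy side-chain atom and reports area 0. A residue with fewer
#' side-chain atoms than its amino acid should carry is computed over the
#' atoms present and flagged incomplete.
#'
#' @param s an `atom_structure`.
#' @param position residue number (`resno`).
#' @param chain chain id; required when the structure has several chains.
#' @param coil_refs named reference areas, defaults to [COIL_SIDE_CHAIN_REF].
#' @param probe_radius,n_points forwarded to [sasa()].
#' @param atom_sasa optional precomputed per-atom areas (to avoid recomputing
#'   the whole structure per residue).
#' @return One-row data.frame: `position`, `resname`, `side_chain_sasa`,
#'   `coil_ref`, `exposure_ratio`, `incomplete`.
#' @export
side_chain_exposure <- function(s, position, chain = NULL,
                                coil_refs = COIL_SIDE_CHAIN_REF,
                                probe_radius = 1.4, n_points = 960L,
                                atom_sasa = NULL) {
  stopifnot(inherits(s, "atom_structure"))
  a <- s$atoms
  if (is.null(chain)) {
    chains <- unique(a$chain)
    if (length(chains) > 1) stop("structure has several chains; pick one")
    chain <- chains
  }
  sel <- which(a$resno == position & a$chain == chain)
  if (length(sel) == 0) stop("no residue ", position, " in chain ", chain)
  resname <- unique(a$resname[sel])[1]
  if (is.null(atom_sasa)) atom_sasa <- sasa(s, probe_radius, n_points)
  side <- sel[!a$atom[sel] %in% BACKBONE_ATOMS]
  sc_sasa <- if (length(side) == 0) 0 else sum(atom_sasa[side])
  expected <- SIDE_CHAIN_SIZE[[resname]]
  incomplete <- !is.null(expected) && length(side) < expected
  if (incomplete) {
    warning("residue ", resname, position, " chain ", chain, ": only ",
            length(side), "/", expected, " side-chain atoms present")
  }
  ref <- if (resname %in% names(coil_refs)) coil_refs[[resname]] else NA_real_
  ratio <- if (identical(resname, "GLY")) 0 else sc_sasa / ref
  data.frame(position = position, resname = resname,
             side_chain_sasa = sc_sasa, coil_ref = ref,
             exposure_ratio = ratio, incomplete = incomplete,
             stringsAsFactors = FALSE)
}

#' Exposure profile over a set of reference positions
#'
#' @inheritParams side_chain_exposure
#' @param positions residue numbers to profile (default: all 27 helix
#'   positions of [helix_definition()]).
#' @return data.frame, one row per position, class `exposure_profile`.
#' @export
exposure_profile <- function(s, positions = helix_positions(helix_definition()),
                             chain = NULL, coil_refs = COIL_SIDE_CHAIN_REF,
                             probe_radius = 1.4, n_points = 960L) {
  atom_sasa <- sasa(s, probe_radius, n_points)
  rows <- lapply(positions, function(p) {
    side_chain_exposure(s, p, chain = chain, coil_refs = coil_refs,
                        atom_sasa = atom_sasa)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("exposure_profile", class(out))
  out
}

#' Positions classified as embedded
#'
#' A position is embedded when its side-chain exposure ratio is strictly
#' below the threshold (default 15%). Called without a profile, returns the
#' packaged authoritative mask {71, 75, 78, 134, 138, 141} of
#' [helix_definition()].
#'
#' @param profile an [exposure_profile()] data.frame, or `NULL` for the
#'   packaged default mask.
#' @param threshold exposure-ratio cutoff, strict inequality.
#' @return Sorted integer vector of embedded positions.
#' @export
embedded_positions <- function(profile = NULL, threshold = 0.15) {
  if (is.null(profile)) return(helix_definition()$embedded)
  stopifnot(all(c("position", "exposure_ratio") %in% names(profile)))
  sort(as.integer(profile$position[profile$exposure_ratio < threshold]))
}
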