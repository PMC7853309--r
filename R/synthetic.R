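# Seeded generators for synthetic fixtures -----------------------------------
# Everything here is synthetic: score-targeted helix slices, error-bearing
# clone sets, toy structures with analytically known surface areas, and trees
# with a planted number of trait losses. Fixed seed => identical output.

#' Generate helix slices with a controlled hydrophobicity score
#'
#' Draws a target score per record from N(mean, sd), then fills the 21
#' scored positions greedily: at each step the residue whose hydropathy is
#' closest to the per-position ideal (remaining sum / remaining positions)
#' is chosen, with a small seeded jitter breaking near-ties and alphabetical
#' order breaking exact ones; the last two positions are chosen jointly by
#' enumeration so the final sum lands within 0.5 of the target. Masked
#' (embedded) positions are filled with random residues, which downstream
#' scoring must ignore.
#'
#' @param n number of records.
#' @param mean,sd target score distribution; `mean` must lie in the
#'   achievable range `[21*min(scale), 21*max(scale)]`.
#' @param hd a [helix_definition()].
#' @param scale a [hydrophobicity_scale()].
#' @param seed integer seed.
#' @param prefix record-id prefix.
#' @return List with one element per record: `record` (a protein
#'   [seq_record()] of the 27 slice residues), `slice` (a [helix_slice()])
#'   and `target` (the drawn target score).
#' @export
gen_helix_slices <- function(n, mean, sd, hd = helix_definition(),
                             scale = hydrophobicity_scale(), seed = 1L,
                             prefix = "sim") {
  vals <- scale$values
  n_scored <- length(helix_positions(hd)) - length(hd$embedded)
  lo <- n_scored * min(vals); hi <- n_scored * max(vals)
  if (mean < lo || mean > hi) {
    stop("mean ", mean, " outside achievable range [", lo, ", ", hi, "]")
  }
  set.seed(as.integer(seed))
  positions <- helix_positions(hd)
  masked <- positions %in% hd$embedded
  out <- vector("list", n)
  for (i in seq_len(n)) {
    target <- min(hi, max(lo, stats::rnorm(1, mean, sd)))
    res <- character(n_scored)
    s <- target
    for (k in seq_len(n_scored - 2L)) {
      m <- n_scored - k + 1L           # positions still to fill
      feasible <- names(vals)[s - vals >= (m - 1) * min(vals) &
                              s - vals <= (m - 1) * max(vals)]
      ideal <- s / m
      dist <- abs(vals[feasible] - ideal) + stats::runif(length(feasible), 0, 0.04)
      pick <- feasible[order(dist, feasible)][1]
      res[k] <- pick
      s <- s - vals[[pick]]
    }
    pairs <- expand.grid(a = names(vals), b = names(vals),
                         stringsAsFactors = FALSE)
    gap <- abs(s - vals[pairs$a] - vals[pairs$b])
    best <- pairs[order(gap, pairs$a, pairs$b)[1], ]
    res[n_scored - 1L] <- best$a
    res[n_scored] <- best$b
    achieved <- sum(vals[res])
    if (abs(achieved - target) > 0.5) {
      stop("generator failed to land within 0.5 of target ", target)
    }
    symbols <- character(length(positions))
    symbols[masked] <- sample(names(vals), sum(masked), replace = TRUE)
    symbols[!masked] <- res
    id <- sprintf("%s%03d", prefix, i)
    slice <- helix_slice(id, symbols, positions, hd)
    out[[i]] <- list(
      record = seq_record(id, paste(symbols, collapse = ""), kind = "protein",
                          description = sprintf("synthetic slice target=%.2f",
                                                target)),
      slice = slice, target = target)
  }
  out
}

#' Generate a clone set with sequencing errors
#'
#' Each true sequence is copied `n_clones` times; every base mutates
#' independently to one of the three other bases with probability
#' `error_rate`, mimicking sporadic PCR/Sanger errors.
#'
#' @param true_seqs list of nucleotide [seq_record()]s.
#' @param n_clones clones per true sequence.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param strain_id strain label for the resulting [clone_set()].
#' @return A [clone_set()].
#' @export
gen_clone_set <- function(true_seqs, n_clones, error_rate = 0, seed = 1L,
                          strain_id = "sim") {
  if (inherits(true_seqs, "seq_record")) true_seqs <- list(true_seqs)
  stopifnot(n_clones >= 1, error_rate >= 0, error_rate < 1)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  clones <- list()
  for (ts in true_seqs) {
    stopifnot(ts$kind == "nucleotide")
    chars <- strsplit(ts$symbols, "")[[1]]
    for (k in seq_len(n_clones)) {
      mutated <- chars
      hit <- which(stats::runif(length(chars)) < error_rate & chars %in% bases)
      for (h in hit) {
        mutated[h] <- sample(setdiff(bases, chars[h]), 1)
      }
      clones[[length(clones) + 1L]] <-
        seq_record(sprintf("%s_clone%02d", ts$id, k),
                   paste(mutated, collapse = ""), kind = "nucleotide")
    }
  }
  clone_set(strain_id, clones)
}

# place atom D from reference atoms A-B-C, bond |C-D|, angle B-C-D (deg),
# dihedral A-B-C-D (deg); standard internal-coordinate (NeRF) construction
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# extended Gly-Ala-Gly tripeptide, heavy atoms, idealized geometry
build_gly_ala_gly <- function() {
  atoms <- list()
  add <- function(name, element, resno, resname, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atom = name, element = element, resno = resno, resname = resname,
      chain = "A", x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
    xyz
  }
  # residue 1 (GLY): seed the frame explicitly
  N1  <- add("N", "N", 1, "GLY", c(0, 0, 0))
  CA1 <- add("CA", "C", 1, "GLY", c(1.458, 0, 0))
  C1  <- add("C", "C", 1, "GLY",
             c(1.458 + 1.525 * cos((180 - 111) * pi / 180),
               1.525 * sin((180 - 111) * pi / 180), 0))
  O1  <- add("O", "O", 1, "GLY", place_atom(N1, CA1, C1, 1.231, 120.5, 0))
  # residue 2 (ALA), extended backbone (phi = psi = omega = 180)
  N2  <- add("N", "N", 2, "ALA", place_atom(N1, CA1, C1, 1.329, 116.2, 180))
  CA2 <- add("CA", "C", 2, "ALA", place_atom(CA1, C1, N2, 1.458, 121.7, 180))
  C2  <- add("C", "C", 2, "ALA", place_atom(C1, N2, CA2, 1.525, 111.0, 180))
  O2  <- add("O", "O", 2, "ALA", place_atom(N2, CA2, C2, 1.231, 120.5, 0))
  CB2 <- add("CB", "C", 2, "ALA", place_atom(O2, C2, CA2, 1.530, 110.1, 122.6))
  # residue 3 (GLY)
  N3  <- add("N", "N", 3, "GLY", place_atom(N2, CA2, C2, 1.329, 116.2, 180))
  CA3 <- add("CA", "C", 3, "GLY", place_atom(CA2, C2, N3, 1.458, 121.7, 180))
  C3  <- add("C", "C", 3, "GLY", place_atom(C2, N3, CA3, 1.525, 111.0, 180))
  O3  <- add("O", "O", 3, "GLY", place_atom(N3, CA3, C3, 1.231, 120.5, 0))
  add("OXT", "O", 3, "GLY", place_atom(N3, CA3, C3, 1.231, 120.5, 180))
  do.call(rbind, atoms)
}

#' Toy structures with analytically known surface areas
#'
#' Fixture kinds:
#' \describe{
#'   \item{single_atom}{one carbon at the origin; SASA is the closed form
#'     `4*pi*(r+probe)^2`.}
#'   \item{two_spheres}{two carbons at center distance `d`; per-sphere SASA
#'     follows the spherical-cap formula `4*pi*R^2 - 2*pi*R*(R - d/2)` for
#'     `d < 2R`.}
#'   \item{shell_buried}{a central carbon fully enclosed by a dense spherical
#'     shell of carbons; the central atom's SASA is exactly 0.}
#'   \item{gly_ala_gly}{an extended Gly-Ala-Gly tripeptide with idealized
#'     geometry, the construct defining the random-coil exposure reference.}
#' }
#'
#' @param kind one of the fixture kinds above.
#' @param d center distance for `two_spheres` (Angstrom).
#' @return An [atom_structure()].
#' @export
gen_toy_structure <- function(kind = c("single_atom", "two_spheres",
                                       "shell_buried", "gly_ala_gly"),
                              d = 3.0) {
  kind <- match.arg(kind)
  dummy <- function(n, x, y, z, resno) {
    data.frame(atom = paste0("C", seq_len(n)), element = "C", resno = resno,
               resname = "DUM", chain = "A", x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  }
  atoms <- switch(kind,
    single_atom = dummy(1, 0, 0, 0, 1),
    two_spheres = rbind(dummy(1, 0, 0, 0, 1), dummy(1, d, 0, 0, 2)),
    shell_buried = {
      shell <- sphere_points(200) * 3.0
      rbind(dummy(1, 0, 0, 0, 1),
            dummy(200, shell[, 1], shell[, 2], shell[, 3], 2))
    },
    gly_ala_gly = build_gly_ala_gly())
  atom_structure(atoms)
}

#' Generate a random tree with a planted number of trait losses
#'
#' Draws a random rooted binary topology, starts with every tip
#' pyrenoid-present and flips tips to absent one at a time, keeping a flip
#' only if it raises the parsimony minimum by exactly one. The resulting
#' states therefore have `fitch_min_changes` equal to `n_losses` by
#' construction.
#'
#' @param n_tips number of tips (>= 2).
#' @param n_losses planted number of loss events.
#' @param seed integer seed.
#' @return List with `tree` ([ape::phylo]) and `traits` (named vector).
#' @export
gen_trait_tree <- function(n_tips, n_losses, seed = 1L) {
  stopifnot(n_tips >= 2, n_losses >= 0)
  if (n_losses > floor(n_tips / 2)) {
    stop("cannot plant ", n_losses, " independent losses on ", n_tips, " tips")
  }
  set.seed(as.integer(seed))
  tree <- ape::rtree(n_tips, br = NULL)
  tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
  traits <- stats::setNames(rep("present", n_tips), tree$tip.label)
  planted <- 0L
  for (tip in sample(tree$tip.label)) {
    if (planted == n_losses) break
    trial <- traits
    trial[tip] <- "absent"
    if (fitch_min_changes(tree, trial) == planted + 1L) {
      traits <- trial
      planted <- planted + 1L
    }
  }
  if (planted < n_losses) {
    stop("could not plant ", n_losses, " losses on this topology")
  }
  list(tree = tree, traits = traits)
}
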