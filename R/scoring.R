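# Helix hydrophobicity scoring ----------------------------------------------

#' Summed hydrophobicity of the exposed helix positions
#'
#' The core statistic: the sum of per-residue hydropathy over the helix A/B
#' positions that are not embedded (21 positions under the default mask).
#' A gap or ambiguous `X` at a scored position contributes 0 and raises a
#' flag; `n_scored` counts the positions that actually contributed, so
#' callers can drop incomplete slices.
#'
#' @param slice a [helix_slice()].
#' @param hd a [helix_definition()] supplying the embedded mask.
#' @param scale a [hydrophobicity_scale()].
#' @return List with `score`, `n_scored`, `flags` (character vector, possibly
#'   empty, from {"gap-in-window", "ambiguous-residue"}).
#' @export
helix_hydrophobicity <- function(slice, hd = helix_definition(),
                                 scale = hydrophobicity_scale()) {
  stopifnot(inherits(slice, "helix_slice"))
  scored <- !slice$positions %in% hd$embedded
  symbols <- slice$symbols[scored]
  flags <- character()
  if (any(symbols == "-")) flags <- c(flags, "gap-in-window")
  if (any(symbols == "X")) flags <- c(flags, "ambiguous-residue")
  contributes <- symbols %in% names(scale$values)
  score <- sum(scale$values[symbols[contributes]])
  list(score = unname(score), n_scored = sum(contributes), flags = flags)
}

#' Build a Table-1-style score table
#'
#' One row per sequence, in input order, carrying the metadata needed for the
#' group comparison. Scores are kept at full precision; round for display.
#'
#' @param slices list of [helix_slice()]s.
#' @param meta data.frame with one row per slice: columns `species`, `strain`,
#'   `accession`, `pyrenoid` (values "present"/"absent"/"unknown"). Row order
#'   matches `slices`.
#' @param hd a [helix_definition()].
#' @param scale a [hydrophobicity_scale()].
#' @return data.frame with columns species, strain, accession, pyrenoid,
#'   score, n_scored, flags.
#' @export
score_table <- function(slices, meta, hd = helix_definition(),
                        scale = hydrophobicity_scale()) {
  if (inherits(slices, "helix_slice")) slices <- list(slices)
  stopifnot(nrow(meta) == length(slices))
  ids <- vapply(slices, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  needed <- c("species", "strain", "accession", "pyrenoid")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) stop("meta lacks column(s): ",
                                paste(missing, collapse = ", "))
  bad <- setdiff(unique(meta$pyrenoid), c("present", "absent", "unknown"))
  if (length(bad) > 0) stop("pyrenoid status must be present/absent/unknown, got: ",
                            paste(bad, collapse = ", "))
  res <- lapply(slices, helix_hydrophobicity, hd = hd, scale = scale)
  data.frame(
    species = meta$species, strain = meta$strain, accession = meta$accession,
    pyrenoid = meta$pyrenoid,
    score = vapply(res, `[[`, numeric(1), "score"),
    n_scored = vapply(res, `[[`, integer(1), "n_scored"),
    flags = vapply(res, function(r) paste(r$flags, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE
  )
}

#' Helix scores printed for the Reticulata group
#'
#' The packaged per-accession helix-A/B hydrophobicity table for the 32 rbcS
#' sequences of the five Chloromonas Reticulata-group species (accessions
#' LC547865-LC547896): 20 sequences from the three pyrenoid-containing
#' species and 12 from the two pyrenoid-lacking species. These published
#' values are the in-paper input for the group comparison; recomputing them
#' from scratch requires downloading the deposited sequences.
#'
#' @return data.frame with columns species, strain, accession, pyrenoid,
#'   score.
#' @export
reticulata_scores <- function() {
  read_tsv(system.file("extdata", "reticulata_helix_scores.tsv",
                       package = "pyrescore"))
}

#' The Reticulata-group species tree and pyrenoid states
#'
#' Packaged rooted species topology for the five Reticulata-group species
#' (ladder: typhlos basal, then difformis, then rosae sister to the
#' chlorococcoides+reticulata cherry) with the microscopy-based pyrenoid
#' presence/absence states. Outgroups (all pyrenoid-containing) justify the
#' present root state used by [count_losses()].
#'
#' @return List with `tree` ([ape::phylo]) and `traits` (named character
#'   vector of "present"/"absent" per tip).
#' @export
reticulata_tree <- function() {
  nwk <- readLines(system.file("extdata", "reticulata_tree.nwk",
                               package = "pyrescore"), warn = FALSE)
  tr <- read_tsv(system.file("extdata", "reticulata_pyrenoid.tsv",
                             package = "pyrescore"))
  list(tree = parse_newick(paste(nwk, collapse = "")),
       traits = stats::setNames(tr$pyrenoid, tr$tip))
}
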