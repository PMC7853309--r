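# Mapping RBCS homologs onto reference helix coordinates --------------------

#' Reference helix windows and buried-position mask
#'
#' RBCS helices A and B are defined on the numbering of the *Chlamydomonas
#' reinhardtii* RBCS1 precursor (transit peptide included; accession
#' XP_001702409): positions 68-80 (helix A, 13 residues) and 131-144
#' (helix B, 14 residues). Six of the 27 positions face the protein core
#' (side-chain exposure ratio below 15%) and are excluded from
#' hydrophobicity scoring: 71, 75, 78, 134, 138 and 141. This packaged mask
#' is the authoritative default; [embedded_positions()] can recompute one
#' from a structure.
#'
#' @param reference_id id of the reference precursor sequence.
#' @param helixA,helixB integer position vectors (1-based, inclusive).
#' @param embedded buried positions, a subset of the helix positions.
#' @return An object of class `helix_definition`.
#' @export
helix_definition <- function(reference_id = "XP_001702409",
                             helixA = 68:80, helixB = 131:144,
                             embedded = c(71, 75, 78, 134, 138, 141)) {
  helixA <- as.integer(helixA); helixB <- as.integer(helixB)
  embedded <- as.integer(embedded)
  if (length(intersect(helixA, helixB)) > 0) stop("helix windows overlap")
  if (!all(embedded %in% c(helixA, helixB))) {
    stop("embedded positions must lie inside the helix windows")
  }
  structure(list(reference_id = reference_id, helixA = helixA,
                 helixB = helixB, embedded = embedded),
            class = "helix_definition")
}

#' @export
print.helix_definition <- function(x, ...) {
  cat(sprintf("<helix_definition> ref %s; helix A %d-%d, helix B %d-%d; %d embedded, %d scored\n",
              x$reference_id, min(x$helixA), max(x$helixA),
              min(x$helixB), max(x$helixB), length(x$embedded),
              length(c(x$helixA, x$helixB)) - length(x$embedded)))
  invisible(x)
}

helix_positions <- function(hd) c(hd$helixA, hd$helixB)

#' One sequence's helix residues in reference coordinates
#'
#' @param id record id the slice came from.
#' @param symbols character vector, one residue letter (or `-` for a query
#'   deletion) per helix position, ordered helix A then helix B.
#' @param positions the matching reference positions.
#' @param hd the [helix_definition()] the slice was cut with.
#' @return An object of class `helix_slice`.
#' @export
helix_slice <- function(id, symbols, positions, hd = helix_definition()) {
  positions <- as.integer(positions)
  expected <- helix_positions(hd)
  if (length(symbols) != length(expected) || !identical(positions, expected)) {
    stop("slice must carry one symbol for each of the ",
         length(expected), " helix positions")
  }
  symbols <- toupper(symbols)
  bad <- setdiff(unique(symbols), PROTEIN_LETTERS)
  if (length(bad) > 0) stop("invalid slice symbol(s): ", paste(bad, collapse = ", "))
  structure(list(id = id, symbols = symbols, positions = positions),
            class = "helix_slice")
}

#' @export
print.helix_slice <- function(x, ...) {
  cat(sprintf("<helix_slice> %s: %s\n", x$id, paste(x$symbols, collapse = "")))
  invisible(x)
}

#' Globally align a query RBCS to the reference
#'
#' Needleman-Wunsch with BLOSUM62, affine gaps (open 10, extend 0.5) and free
#' terminal gaps, so mature-protein queries lacking the transit peptide still
#' map cleanly onto the precursor numbering. RBCS homologs are well over 60%
#' identical, so the helix mapping is insensitive to the exact scoring
#' constants; they are fixed for determinism.
#'
#' @param query,reference gap-free protein [seq_record()]s.
#' @return A `position_map`: the aligned (reference position, query index)
#'   pairs plus both sequence lengths.
#' @export
align_to_reference <- function(query, reference) {
  stopifnot(inherits(query, "seq_record"), inherits(reference, "seq_record"))
  for (r in list(query, reference)) {
    if (nchar(r$symbols) == 0) stop("empty sequence: ", r$id)
    if (grepl("-", r$symbols, fixed = TRUE)) {
      stop("sequence '", r$id, "' contains gaps; supply ungapped sequences")
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query$symbols),
    subject = Biostrings::AAString(reference$symbols),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "overlap")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qi <- Biostrings::pattern(aln)@range@start - 1L
  ri <- Biostrings::subject(aln)@range@start - 1L
  ref_pos <- integer(0); query_pos <- integer(0)
  for (k in seq_along(pa)) {
    qgap <- pa[k] == "-"; rgap <- sa[k] == "-"
    if (!qgap) qi <- qi + 1L
    if (!rgap) ri <- ri + 1L
    if (!qgap && !rgap) {
      ref_pos <- c(ref_pos, ri); query_pos <- c(query_pos, qi)
    }
  }
  structure(list(pairs = data.frame(ref_pos = ref_pos, query_pos = query_pos),
                 query_id = query$id, reference_id = reference$id,
                 query_length = nchar(query$symbols),
                 reference_length = nchar(reference$symbols)),
            class = "position_map")
}

#' Cut the 27-residue helix slice out of a mapped query
#'
#' @param query the protein [seq_record()] that was aligned.
#' @param pm a `position_map` from [align_to_reference()].
#' @param hd a [helix_definition()].
#' @return A [helix_slice()]; `-` marks helix positions the query lacks.
#' @export
extract_helix_slice <- function(query, pm, hd = helix_definition()) {
  stopifnot(inherits(pm, "position_map"))
  wanted <- helix_positions(hd)
  if (pm$reference_length < max(wanted)) {
    stop("reference (", pm$reference_length,
         " aa) is shorter than the last helix position (", max(wanted), ")")
  }
  idx <- pm$pairs$query_pos[match(wanted, pm$pairs$ref_pos)]
  symbols <- ifelse(is.na(idx), "-",
                    substring(query$symbols, idx, idx))
  helix_slice(query$id, symbols, wanted, hd)
}

#' Cut the helix slice from a pre-aligned pair
#'
#' For inputs that are already aligned (equal-length gapped strings), e.g.
#' published alignment panels. A `.` in the query means "same residue as the
#' reference at this column"; a `-` is a deletion.
#'
#' @param aligned_query,aligned_reference equal-length aligned strings
#'   (character scalars or [seq_record()]s with gaps).
#' @param hd a [helix_definition()].
#' @param id id for the resulting slice.
#' @return A [helix_slice()].
#' @export
slice_from_alignment <- function(aligned_query, aligned_reference,
                                 hd = helix_definition(), id = "query") {
  q <- if (inherits(aligned_query, "seq_record")) aligned_query$symbols else toupper(aligned_query)
  r <- if (inherits(aligned_reference, "seq_record")) aligned_reference$symbols else toupper(aligned_reference)
  if (nchar(q) != nchar(r)) {
    stop("aligned strings differ in length (", nchar(q), " vs ", nchar(r), ")")
  }
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  wanted <- helix_positions(hd)
  symbols <- rep("-", length(wanted))
  ref_pos <- 0L
  for (k in seq_along(rs)) {
    if (rs[k] == "-") next  # query insertion column: no reference coordinate
    ref_pos <- ref_pos + 1L
    hit <- match(ref_pos, wanted)
    if (!is.na(hit)) {
      symbols[hit] <- if (qs[k] == ".") rs[k] else qs[k]
    }
  }
  if (ref_pos < max(wanted)) {
    stop("aligned reference covers only ", ref_pos,
         " positions; helix windows end at ", max(wanted))
  }
  helix_slice(id, symbols, wanted, hd)
}
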