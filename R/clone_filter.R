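# Sanger clone-consensus filtering ------------------------------------------

#' Bundle Sanger clones from one strain and locus
#'
#' @param strain_id strain label.
#' @param clones non-empty list of [seq_record()]s of the same kind.
#' @return An object of class `clone_set`.
#' @export
clone_set <- function(strain_id, clones) {
  if (inherits(clones, "seq_record")) clones <- list(clones)
  if (length(clones) == 0) stop("clone set for '", strain_id, "' is empty")
  stopifnot(all(vapply(clones, inherits, logical(1), "seq_record")))
  kinds <- unique(vapply(clones, `[[`, character(1), "kind"))
  if (length(kinds) != 1) stop("clones mix alphabets: ",
                               paste(kinds, collapse = ", "))
  structure(list(strain_id = strain_id, clones = clones), class = "clone_set")
}

#' Admit only sequences seen identically in several clones
#'
#' PCR and Sanger sequencing introduce sporadic errors, so a sequence is
#' trusted only when the identical string is observed in at least
#' `min_support` independent clones. Comparison is exact full-length string
#' equality after uppercasing; clones differing by a single base, or by
#' terminal trimming, count as distinct (callers pre-trim to a common window
#' first). Output is deduplicated and sorted by support (descending), then
#' sequence (ascending).
#'
#' @param cs a [clone_set()].
#' @param min_support minimum number of identical clones (default 2).
#' @return A data.frame with columns `sequence`, `support`, and `id` (the id
#'   of the first clone carrying that sequence). Zero rows when nothing
#'   reaches support.
#' @export
consensus_filter <- function(cs, min_support = 2L) {
  stopifnot(inherits(cs, "clone_set"))
  min_support <- as.integer(min_support)
  if (min_support < 1L) stop("min_support must be >= 1")
  seqs <- toupper(vapply(cs$clones, `[[`, character(1), "symbols"))
  ids <- vapply(cs$clones, `[[`, character(1), "id")
  counts <- table(seqs)
  keep <- names(counts)[counts >= min_support]
  out <- data.frame(
    sequence = keep,
    support = as.integer(counts[keep]),
    id = vapply(keep, function(s) ids[match(s, seqs)], character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$support, out$sequence), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Kept clone sequences as records
#'
#' Convenience wrapper turning [consensus_filter()] output back into
#' [seq_record()]s (one per kept sequence, support in the description).
#'
#' @inheritParams consensus_filter
#' @return List of [seq_record()]s.
#' @export
consensus_records <- function(cs, min_support = 2L) {
  kept <- consensus_filter(cs, min_support)
  kind <- cs$clones[[1]]$kind
  lapply(seq_len(nrow(kept)), function(i) {
    seq_record(kept$id[i], kept$sequence[i], kind = kind,
               description = sprintf("strain=%s support=%d", cs$strain_id,
                                     kept$support[i]))
  })
}
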