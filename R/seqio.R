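# Sequence, tree and table I/O ----------------------------------------------

PROTEIN_LETTERS    <- c(names(KYTE_DOOLITTLE), "X", "-", "*")
NUCLEOTIDE_LETTERS <- c("A", "C", "G", "T", "N", "-")

#' Create a sequence record
#'
#' Minimal container for one FASTA record: an id, an optional free-text
#' description, the residue/base letters (uppercased; `-` allowed as gap) and
#' the alphabet kind. `U` is normalized to `T` in nucleotide records because
#' mRNA-derived accessions are common inputs.
#'
#' @param id non-empty record identifier (first whitespace-delimited token of
#'   a FASTA header).
#' @param symbols character scalar with the sequence letters.
#' @param kind `"protein"` or `"nucleotide"`; default guesses from the letters.
#' @param description remainder of the FASTA header, possibly empty.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, symbols, kind = NULL, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("record id must be a non-empty string")
  }
  symbols <- toupper(symbols)
  if (is.null(kind)) {
    letters <- unique(strsplit(symbols, "")[[1]])
    kind <- if (all(letters %in% c("A", "C", "G", "T", "U", "N", "-"))) {
      "nucleotide"
    } else {
      "protein"
    }
  }
  kind <- match.arg(kind, c("protein", "nucleotide"))
  if (kind == "nucleotide") symbols <- gsub("U", "T", symbols, fixed = TRUE)
  allowed <- if (kind == "protein") PROTEIN_LETTERS else NUCLEOTIDE_LETTERS
  bad <- setdiff(unique(strsplit(symbols, "")[[1]]), allowed)
  if (length(bad) > 0) {
    stop("record '", id, "': invalid ", kind, " symbol(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, description = description,
                 symbols = symbols, kind = kind),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s (%d %s symbols)\n", x$kind, x$id,
              nchar(x$symbols), if (x$kind == "protein") "aa" else "nt"))
  invisible(x)
}

#' Read a FASTA file
#'
#' Returns the records in file order. The file must be well-formed: the first
#' non-blank line starts a header, and every header carries an id. Errors
#' name the offending line.
#'
#' @param path path to a FASTA file.
#' @param kind forwarded to [seq_record()]; default guesses per record.
#' @return A list of [seq_record()] objects.
#' @export
read_fasta <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0) stop("FASTA parse error: ", path, " is empty")
  if (!startsWith(trimws(lines[content[1]]), ">")) {
    stop("FASTA parse error at line ", content[1],
         ": expected '>' header, got '", lines[content[1]], "'")
  }
  records <- list()
  id <- NULL; desc <- ""; chunks <- character()
  flush <- function() {
    if (!is.null(id)) {
      records[[length(records) + 1L]] <<-
        seq_record(id, paste(chunks, collapse = ""), kind = kind,
                   description = desc)
    }
  }
  for (i in content) {
    line <- trimws(lines[i])
    if (startsWith(line, ">")) {
      flush()
      header <- sub("^>", "", line)
      if (!nzchar(trimws(header))) {
        stop("FASTA parse error at line ", i, ": empty header")
      }
      id <- sub("\\s.*$", "", trimws(header))
      desc <- trimws(sub("^\\S+\\s*", "", trimws(header)))
      chunks <- character()
    } else {
      chunks <- c(chunks, gsub("\\s", "", line))
    }
  }
  flush()
  records
}

#' Write records as canonical 60-column FASTA
#'
#' @param records a list of [seq_record()]s (a single record is accepted).
#' @param path output path.
#' @param width wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  out <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$description)) {
      paste0(">", r$id, " ", r$description)
    } else {
      paste0(">", r$id)
    }
    n <- nchar(r$symbols)
    starts <- seq(1L, max(n, 1L), by = width)
    body <- if (n == 0) character() else
      substring(r$symbols, starts, pmin(starts + width - 1L, n))
    c(header, body)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code via Biostrings. The frame offset is dropped from the
#' 5' end, a trailing incomplete codon is dropped with a warning, stop codons
#' render as `*`, and any codon made ambiguous by `N` renders as `X`.
#'
#' @param cds a nucleotide [seq_record()].
#' @param frame 0, 1 or 2 bases skipped before the first codon.
#' @return A protein [seq_record()] (id suffixed `_translation`).
#' @export
translate_cds <- function(cds, frame = 0L) {
  stopifnot(inherits(cds, "seq_record"), cds$kind == "nucleotide")
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  s <- substr(cds$symbols, frame + 1L, nchar(cds$symbols))
  if (nchar(s) < 3L) stop("fewer than one codon after applying frame")
  remainder <- nchar(s) %% 3L
  if (remainder > 0L) {
    s <- substr(s, 1L, nchar(s) - remainder)
    warning("dropped ", remainder, " trailing base(s) (incomplete codon)")
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X"))
  seq_record(paste0(cds$id, "_translation"), aa, kind = "protein",
             description = sprintf("frame %d translation of %s", frame, cds$id))
}

#' Parse a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: checks balanced
#' parentheses and the terminating semicolon up front, and rejects duplicate
#' tip labels. Branch lengths are parsed but ignored by the parsimony layer.
#'
#' @param text Newick string.
#' @return An [ape::phylo] tree (rooted as written).
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- cumsum((strsplit(text, "")[[1]] == "(") -
                  (strsplit(text, "")[[1]] == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    stop("Newick parse error: unbalanced parentheses")
  }
  if (!grepl(";\\s*$", text)) stop("Newick parse error: missing ';'")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: unreadable tree")
  if (anyDuplicated(tree$tip.label)) {
    stop("Newick parse error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' Length of a CDS window after codon deletions
#'
#' Bookkeeping for amplicon windows given as 1-based inclusive CDS
#' coordinates, minus whole-codon deletions relative to the reference. The
#' clone-verification window 156-465 of the reference rbcS CDS, carrying a
#' one-codon deletion, spans 307 bases.
#'
#' @param start,end 1-based inclusive CDS coordinates.
#' @param deleted_codons whole codons absent from the amplicon.
#' @return Integer number of bases.
#' @export
cds_window_length <- function(start, end, deleted_codons = 0L) {
  stopifnot(start >= 1, end >= start, deleted_codons >= 0)
  as.integer(end - start + 1L - 3L * deleted_codons)
}

# internal TSV helpers: header row, tab separation, UTF-8, no quoting
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
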