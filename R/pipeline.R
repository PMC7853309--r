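# End-to-end pipeline --------------------------------------------------------

#' Read a plain-text key=value pipeline config
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Recognized keys mirror the [run_pipeline()] arguments (`query_fasta`,
#' `reference_fasta`, `meta_tsv`, `tree_nwk`, `traits_tsv`, `out_dir`,
#' `seed`, `threshold`).
#'
#' @param path config file.
#' @return Named list of strings.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("config parse error at: ", lines[bad][1])
  stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, character(1), 1))
}

#' Run the full helix-hydrophobicity analysis
#'
#' Wires the stages together: read the reference and query proteins, map
#' each query onto the reference numbering, cut and score the helix slices,
#' compare pyrenoid-present vs -absent groups, and (when a tree and trait
#' table are given) count pyrenoid losses by parsimony. Writes
#' `scores.tsv`, `comparison.json`, `losses.json` and `run_log.txt` into
#' `out_dir`; reruns with the same inputs and seed are byte-identical.
#' On error, partially written outputs are removed and the failing stage is
#' named.
#'
#' @param query_fasta FASTA of query RBCS proteins (ids matched against the
#'   metadata `accession` column).
#' @param reference_fasta FASTA whose first record is the reference precursor.
#' @param meta_tsv TSV with columns `accession`, `species`, `strain`,
#'   `pyrenoid`.
#' @param out_dir output directory, created if needed.
#' @param tree_nwk,traits_tsv optional Newick tree and tip-trait TSV
#'   (columns `tip`, `pyrenoid`) for the loss count.
#' @param hd a [helix_definition()].
#' @param scale a [hydrophobicity_scale()].
#' @param seed seed forwarded to the comparison's Monte Carlo fallback.
#' @param root_state root constraint for [count_losses()].
#' @return List of class `pipeline_report`: `scores`, `comparison`,
#'   `losses` (or NULL), `paths`.
#' @export
run_pipeline <- function(query_fasta, reference_fasta, meta_tsv, out_dir,
                         tree_nwk = NULL, traits_tsv = NULL,
                         hd = helix_definition(),
                         scale = hydrophobicity_scale(), seed = NULL,
                         root_state = "present") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- stage("read-inputs", {
    if (is.null(tree_nwk) != is.null(traits_tsv)) {
      stop("tree_nwk and traits_tsv must be given together")
    }
    list(queries = read_fasta(query_fasta, kind = "protein"),
         reference = read_fasta(reference_fasta, kind = "protein")[[1]],
         meta = read_tsv(meta_tsv))
  })
  scores <- stage("score", {
    meta <- inputs$meta
    ids <- vapply(inputs$queries, `[[`, character(1), "id")
    hit <- match(ids, meta$accession)
    if (anyNA(hit)) {
      stop("no metadata for record(s): ", paste(ids[is.na(hit)], collapse = ", "))
    }
    slices <- lapply(inputs$queries, function(q) {
      extract_helix_slice(q, align_to_reference(q, inputs$reference), hd)
    })
    score_table(slices, meta[hit, , drop = FALSE], hd, scale)
  })
  comparison <- stage("compare", compare_groups(scores, seed = seed))
  losses <- if (!is.null(tree_nwk)) {
    stage("losses", {
      tree <- parse_newick(paste(readLines(tree_nwk, warn = FALSE),
                                 collapse = ""))
      count_losses(tree, read_trait_table(traits_tsv),
                   root_state = root_state)
    })
  }
  paths <- stage("write-outputs", {
    p <- c(scores = file.path(out_dir, "scores.tsv"),
           comparison = file.path(out_dir, "comparison.json"),
           log = file.path(out_dir, "run_log.txt"))
    write_tsv(scores, p[["scores"]]); written <<- c(written, p[["scores"]])
    jsonlite::write_json(comparison_report(comparison), p[["comparison"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, p[["comparison"]])
    if (!is.null(losses)) {
      p[["losses"]] <- file.path(out_dir, "losses.json")
      jsonlite::write_json(list(min_changes = losses$min_changes,
                                loss_counts = losses$loss_counts,
                                gain_counts = losses$gain_counts,
                                root_state = losses$root_state,
                                model = losses$model),
                           p[["losses"]], auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      written <<- c(written, p[["losses"]])
    }
    writeLines(c(
      paste0("pyrescore version: ", as.character(utils::packageVersion("pyrescore"))),
      paste0("seed: ", if (is.null(seed)) "none" else seed),
      paste0("scale: ", scale$name),
      paste0("reference: ", inputs$reference$id),
      paste0("embedded mask: ", paste(hd$embedded, collapse = ",")),
      paste0("records scored: ", nrow(scores)),
      paste0("comparison method: ", comparison$test$method),
      paste0("p value: ", format(comparison$test$p_value))
    ), p[["log"]])
    p
  })
  structure(list(scores = scores, comparison = comparison, losses = losses,
                 paths = paths),
            class = "pipeline_report")
}

comparison_report <- function(cmp) {
  list(p_hat = cmp$test$p_hat, statistic = cmp$test$statistic,
       dof = cmp$test$dof, p_value = cmp$test$p_value,
       method = cmp$test$method,
       summaries = list(present = cmp$present, absent = cmp$absent))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report —", nrow(x$scores), "sequences scored\n")
  print(x$comparison)
  if (!is.null(x$losses)) print(x$losses)
  invisible(x)
}
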