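# Hydropathy scales ---------------------------------------------------------

#' Kyte-Doolittle hydropathy values
#'
#' The classic per-residue hydropathy scale (Kyte & Doolittle 1982), used to
#' score the exposed positions of RBCS helices A and B. Values are
#' dimensionless; positive means hydrophobic (Ile 4.5) and negative
#' hydrophilic (Arg -4.5). Ala is 1.8 and Pro is -1.6, the two residues whose
#' swap at reference position 131 separates sister species with and without
#' pyrenoids.
#'
#' @format Named numeric vector over the 20 standard one-letter residue codes.
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Construct a hydrophobicity scale
#'
#' A scale is a named list with a `name` and a complete residue -> score map.
#' The default is Kyte-Doolittle; alternative scales can be supplied as any
#' named numeric vector covering the 20 standard residues.
#'
#' @param values named numeric vector, one entry per standard residue letter.
#' @param name scale label used in reports.
#' @return An object of class `hydrophobicity_scale`.
#' @export
hydrophobicity_scale <- function(values = KYTE_DOOLITTLE, name = "Kyte-Doolittle") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  names(values) <- toupper(names(values))
  missing <- setdiff(names(KYTE_DOOLITTLE), names(values))
  if (length(missing) > 0) {
    stop("scale does not cover residues: ", paste(missing, collapse = ", "))
  }
  structure(list(name = name, values = values[names(KYTE_DOOLITTLE)]),
            class = "hydrophobicity_scale")
}

#' Look up the hydropathy of one residue
#'
#' Case-insensitive lookup. Gap (`-`) and ambiguity (`X`) characters are
#' deliberately not in the scale: the scoring layer decides their
#' contribution, so asking for them here is an error.
#'
#' @param residue single one-letter residue code.
#' @param scale a [hydrophobicity_scale()].
#' @return The scalar hydropathy value.
#' @export
#' @examples
#' kd_value("A") # 1.8
#' kd_value("P") # -1.6
kd_value <- function(residue, scale = hydrophobicity_scale()) {
  stopifnot(is.character(residue), length(residue) == 1L, nchar(residue) == 1L)
  r <- toupper(residue)
  if (!r %in% names(scale$values)) {
    stop("no hydropathy value for symbol '", residue, "'")
  }
  unname(scale$values[[r]])
}

#' @export
print.hydrophobicity_scale <- function(x, ...) {
  cat("Hydrophobicity scale:", x$name, "\n")
  print(x$values)
  invisible(x)
}
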