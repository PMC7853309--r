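# Parsimony counting of pyrenoid losses -------------------------------------

STATES <- c("present", "absent")

check_traits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be a named vector (tip -> state)")
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing) > 0) stop("tips missing from traits: ",
                                paste(missing, collapse = ", "))
  bad <- setdiff(unique(unname(traits[tree$tip.label])), STATES)
  if (length(bad) > 0) stop("states must be 'present'/'absent', got: ",
                            paste(bad, collapse = ", "))
  traits[tree$tip.label]
}

children_list <- function(tree) {
  n_nodes <- max(tree$edge)
  kids <- vector("list", n_nodes)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    kids[[p]] <- c(kids[[p]], c)
  }
  kids
}

# Sankoff-style DP: cost[v, s] = minimum changes in the subtree of v given
# state s at v. Unit substitution cost reproduces Fitch counting and handles
# multifurcations exactly; a Dollo model forbids regain (absent -> present).
subtree_costs <- function(tree, traits, model = "fitch") {
  traits <- check_traits(tree, traits)
  n_tips <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  trans <- matrix(c(0, 1, 1, 0), 2, 2,
                  dimnames = list(STATES, STATES))  # from (row) to (col)
  if (model == "dollo") trans["absent", "present"] <- Inf
  kids <- children_list(tree)
  cost <- matrix(Inf, n_nodes, 2, dimnames = list(NULL, STATES))
  for (i in seq_len(n_tips)) cost[i, traits[[tree$tip.label[i]]]] <- 0
  # postorder: process internal nodes deepest-first
  ord <- rev(unique(tree$edge[order(tree$edge[, 1]), 1]))
  depth <- numeric(n_nodes)
  for (k in seq_len(nrow(tree$edge))) {
    depth[tree$edge[k, 2]] <- depth[tree$edge[k, 1]] + 1
  }
  internal <- which(lengths(kids) > 0)
  for (v in internal[order(depth[internal], decreasing = TRUE)]) {
    for (s in 1:2) {
      tot <- 0
      for (c in kids[[v]]) tot <- tot + min(trans[s, ] + cost[c, ])
      cost[v, s] <- tot
    }
  }
  list(cost = cost, kids = kids, trans = trans,
       root = n_tips + 1L, n_tips = n_tips, traits = traits)
}

#' Minimum number of state changes (Fitch parsimony)
#'
#' @param tree rooted [ape::phylo] tree (multifurcations allowed).
#' @param traits named character vector, tip label -> "present"/"absent".
#' @return Integer minimum change count over all internal labelings.
#' @export
fitch_min_changes <- function(tree, traits) {
  dp <- subtree_costs(tree, traits, model = "fitch")
  as.integer(min(dp$cost[dp$root, ]))
}

# enumerate every minimum-change labeling below `root` given its state,
# returning per-labeling loss and gain counts (cap guards explosion)
enumerate_optima <- function(dp, cap = 100000L) {
  # returns, for node v in state s, a data.frame of (losses, gains) over all
  # optimal labelings of v's subtree; memoized
  memo <- new.env(parent = emptyenv())
  rec <- function(v, s) {
    key <- paste0(v, ".", s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    kids <- dp$kids[[v]]
    if (length(kids) == 0) {
      out <- data.frame(losses = 0L, gains = 0L)
    } else {
      out <- data.frame(losses = 0L, gains = 0L)
      for (c in kids) {
        opts <- dp$trans[s, ] + dp$cost[c, ]
        best <- which(opts == min(opts))
        child_tabs <- lapply(best, function(t) {
          tab <- rec(c, t)
          tab$losses <- tab$losses + as.integer(s == 1L && t == 2L)
          tab$gains <- tab$gains + as.integer(s == 2L && t == 1L)
          tab
        })
        child_all <- unique(do.call(rbind, child_tabs))
        out <- unique(merge(out, child_all, by = NULL) |>
                        (\(m) data.frame(losses = m$losses.x + m$losses.y,
                                         gains = m$gains.x + m$gains.y))())
        if (nrow(out) > cap) stop("too many distinct optima to enumerate")
      }
    }
    memo[[key]] <- out
    out
  }
  rec
}

# one optimal labeling, chosen deterministically (prefer "present" on ties)
one_labeling <- function(dp, root_state_idx) {
  n_nodes <- nrow(dp$cost)
  lab <- character(n_nodes)
  assign_node <- function(v, s) {
    lab[v] <<- STATES[s]
    for (c in dp$kids[[v]]) {
      opts <- dp$trans[s, ] + dp$cost[c, ]
      assign_node(c, which.min(opts))
    }
  }
  assign_node(dp$root, root_state_idx)
  lab
}

#' Count trait-loss events under parsimony
#'
#' Enumerates every minimum-change internal labeling whose root carries
#' `root_state` (the outgroup condition; pyrenoid-containing outgroups fix
#' the root at "present") and reports the set of loss counts (edges going
#' present -> absent) achieved across them. When several optima disagree,
#' `loss_counts` has more than one element.
#'
#' The default model is Dollo (regain forbidden): the pyrenoid is a complex
#' microcompartment whose re-evolution after loss is not considered, and the
#' no-regain assumption is what makes "how many times was it lost" a
#' well-posed question. Under unordered Fitch parsimony (`model = "fitch"`)
#' equally parsimonious loss-then-regain labelings can enter the enumeration
#' and widen `loss_counts`; on the packaged Reticulata topology Fitch yields
#' {1, 2} while Dollo yields the unambiguous {2}.
#'
#' @inheritParams fitch_min_changes
#' @param root_state state fixed at the root, default "present".
#' @param model "dollo" (regain forbidden, default) or "fitch" (unordered,
#'   regain allowed).
#' @return List of class `trait_reconstruction`: `min_changes` (minimum given
#'   the root constraint), `loss_counts` (sorted integer set), `gain_counts`,
#'   `optima` (data.frame of distinct loss/gain pairs across the optimal
#'   labelings), `labeling` (one optimal node labeling, tips first),
#'   `root_state`, `model`.
#' @export
count_losses <- function(tree, traits, root_state = "present",
                         model = c("dollo", "fitch")) {
  model <- match.arg(model)
  root_state <- match.arg(root_state, STATES)
  dp <- subtree_costs(tree, traits, model = model)
  s0 <- match(root_state, STATES)
  min_changes <- dp$cost[dp$root, s0]
  if (!is.finite(min_changes)) {
    stop("no labeling with root '", root_state, "' under the ", model, " model")
  }
  rec <- enumerate_optima(dp)
  tab <- rec(dp$root, s0)
  structure(list(min_changes = as.integer(min_changes),
                 loss_counts = sort(unique(tab$losses)),
                 gain_counts = sort(unique(tab$gains)),
                 optima = unique(tab),
                 labeling = one_labeling(dp, s0),
                 root_state = root_state, model = model),
            class = "trait_reconstruction")
}

#' @export
print.trait_reconstruction <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction (%s, root %s): %d change(s); losses {%s}, gains {%s}\n",
              x$model, x$root_state, x$min_changes,
              paste(x$loss_counts, collapse = ","),
              paste(x$gain_counts, collapse = ",")))
  invisible(x)
}

#' Read a tip-trait table
#'
#' TSV with columns `tip` and `pyrenoid` ("present"/"absent").
#'
#' @param path TSV path.
#' @return Named character vector.
#' @export
read_trait_table <- function(path) {
  tr <- read_tsv(path)
  if (!all(c("tip", "pyrenoid") %in% names(tr))) {
    stop("trait table needs columns 'tip' and 'pyrenoid'")
  }
  stats::setNames(tr$pyrenoid, tr$tip)
}
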