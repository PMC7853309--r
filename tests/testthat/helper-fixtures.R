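# shared fixtures and independent oracles (all built in code)

# deterministic synthetic 170-aa "precursor" reference; helix windows are
# whatever residues happen to sit at positions 68-80 and 131-144
make_reference <- function(seed = 101, length = 170) {
  set.seed(seed)
  aa <- names(KYTE_DOOLITTLE)
  seq_record("ref_precursor", paste(sample(aa, length, replace = TRUE),
                                    collapse = ""), kind = "protein")
}

ref_slice_symbols <- function(ref, hd = helix_definition()) {
  pos <- c(hd$helixA, hd$helixB)
  substring(ref$symbols, pos, pos)
}

mutate_at <- function(record, pos, letter) {
  s <- strsplit(record$symbols, "")[[1]]
  s[pos] <- letter
  seq_record(record$id, paste(s, collapse = ""), kind = record$kind,
             description = record$description)
}

# --- independent Brunner-Munzel oracles (pair counting, no midranks) -------

oracle_bm_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ph <- (sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))) / (n1 * n2)
  P <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n2, 0)
  Q <- vapply(y, function(yi) (sum(x < yi) + 0.5 * sum(x == yi)) / n1, 0)
  s2 <- stats::var(Q) / n2 + stats::var(P) / n1
  if (s2 == 0) return(NA_real_)
  (ph - 0.5) / sqrt(s2)
}

oracle_perm_p <- function(x, y, statistic = oracle_bm_stat) {
  pooled <- c(x, y); N <- length(pooled); n1 <- length(x)
  obs <- abs(statistic(x, y))
  cs <- utils::combn(N, n1)
  st <- apply(cs, 2, function(i) abs(statistic(pooled[i], pooled[-i])))
  mean(st >= obs - 1e-12, na.rm = TRUE)
}

oracle_p_hat <- function(x, y) {
  (sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))) / (length(x) * length(y))
}

# --- brute-force parsimony oracle: try every internal labeling -------------

oracle_min_changes <- function(tree, traits) {
  n_tips <- length(tree$tip.label)
  n_int <- tree$Nnode
  states <- c("present", "absent")
  tip_state <- traits[tree$tip.label]
  best <- Inf
  grid <- expand.grid(rep(list(1:2), n_int))
  for (g in seq_len(nrow(grid))) {
    lab <- c(unname(tip_state), states[as.integer(grid[g, ])])
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  as.integer(best)
}

oracle_loss_counts <- function(tree, traits, root_state = "present",
                               allow_regain = FALSE) {
  n_tips <- length(tree$tip.label)
  states <- c("present", "absent")
  tip_state <- traits[tree$tip.label]
  root <- n_tips + 1L
  grid <- expand.grid(rep(list(1:2), tree$Nnode))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    lab <- c(unname(tip_state), states[as.integer(grid[g, ])])
    if (lab[root] != root_state) return(NULL)
    losses <- sum(lab[tree$edge[, 1]] == "present" &
                  lab[tree$edge[, 2]] == "absent")
    gains <- sum(lab[tree$edge[, 1]] == "absent" &
                 lab[tree$edge[, 2]] == "present")
    if (!allow_regain && gains > 0) return(NULL)
    c(changes = losses + gains, losses = losses, gains = gains)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  mn <- min(tab[, "changes"])
  list(min_changes = mn,
       loss_counts = sort(unique(tab[tab[, "changes"] == mn, "losses"])))
}

random_trait_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_tips, br = NULL)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  traits <- stats::setNames(sample(c("present", "absent"), n_tips,
                                   replace = TRUE), tree$tip.label)
  list(tree = tree, traits = traits)
}
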