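# Independent oracles used by the property and acceptance tests. These stay
# deliberately dumb: exhaustive enumeration over labelings, direct
# path-length computation on trees — never the pruning/parsimony code paths
# they are checking.

# minimum number of 1->0 edges over all single-origin labelings consistent
# with the observed leaf states (NA leaves are free); NULL if the family has
# no present leaf
oracle_dollo_min_losses <- function(leaf_states, tree) {
  n <- length(tree$label)
  lv <- leaf_ids(tree)
  fixed <- lv[!is.na(leaf_states[tree$label[lv]])]
  if (!any(leaf_states[tree$label[fixed]] == 1)) return(0L)
  free <- c(setdiff(seq_len(n), lv), setdiff(lv, fixed))
  nm <- 2^length(free)
  ST <- matrix(0L, n, nm)
  ST[fixed, ] <- leaf_states[tree$label[fixed]]
  for (k in seq_along(free))
    ST[free[k], ] <- bitwAnd(bitwShiftR(seq_len(nm) - 1L, k - 1L), 1L)
  gains <- integer(nm); losses <- integer(nm)
  for (v in seq_len(n)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    gains <- gains + (ST[v, ] == 1L & ST[p, ] == 0L)
    losses <- losses + (ST[v, ] == 0L & ST[p, ] == 1L)
  }
  valid <- (gains + ST[tree$root, ]) == 1L
  min(losses[valid])
}

# log-likelihood by exhaustive sum over internal labelings
oracle_loglik <- function(leaf_states, tree, model, default_brlen = 1) {
  bl <- ifelse(is.na(tree$brlen), default_brlen, tree$brlen)
  n <- length(tree$label)
  lv <- leaf_ids(tree)
  known <- lv[!is.na(leaf_states[tree$label[lv]])]
  free <- c(setdiff(seq_len(n), lv), setdiff(lv, known))
  nm <- 2^length(free)
  ST <- matrix(0L, n, nm)
  ST[known, ] <- leaf_states[tree$label[known]]
  for (k in seq_along(free))
    ST[free[k], ] <- bitwAnd(bitwShiftR(seq_len(nm) - 1L, k - 1L), 1L)
  pr <- ifelse(ST[tree$root, ] == 1L, model$prior, 1 - model$prior)
  for (v in seq_len(n)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    P <- transition_matrix(model, bl[v])
    pr <- pr * P[cbind(ST[p, ] + 1L, ST[v, ] + 1L)]
  }
  log(sum(pr))
}

# exact leaf-to-leaf path-length matrix of a tree with branch lengths
oracle_additive_matrix <- function(tree, default_brlen = 1) {
  d <- node_depths(tree, default = default_brlen)
  lv <- leaf_ids(tree)
  labs <- tree$label[lv]
  anc <- lapply(seq_along(tree$label),
                function(v) c(v, c1aprofiler:::ancestors_of(tree, v)))
  D <- matrix(0, length(lv), length(lv), dimnames = list(labs, labs))
  for (i in seq_along(lv)) for (j in seq_len(i - 1L)) {
    a <- lv[i]; b <- lv[j]
    com <- anc[[a]][anc[[a]] %in% anc[[b]]][1]
    D[i, j] <- D[j, i] <- d[a] + d[b] - 2 * d[com]
  }
  D
}

# pad aligned families of different lengths into one alignment
pad_alignment <- function(...) {
  groups <- list(...)
  L <- max(vapply(groups, function(g) nchar(g[[1]]), numeric(1)))
  out <- unlist(lapply(groups, function(g)
    vapply(g, function(s) paste0(s, strrep("-", L - nchar(s))), character(1))))
  out
}

random_protein <- function(len, seed = NULL) {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

merged_eukaryote_matrix <- function(tree = reference_tree("eukaryota")) {
  restrict_to_leaves(
    merge_matrices(reference_table("table1"), reference_table("table2")),
    tree)
}
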