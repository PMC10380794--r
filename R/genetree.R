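# Desk-scale gene trees: Poisson-corrected protein distances, the
# Saitou-Nei neighbor-joining agglomeration, and nonparametric bootstrap.
#
# This is deliberately NOT a maximum-likelihood reimplementation (WAG+I+G4
# model selection and ML search stay out of scope); trees are used here only
# for family-monophyly checks and for placing horizontally transferred
# sequences next to their donors, and NJ on corrected distances supports
# both.

#' Uncorrected p-distance between two aligned sequences
#'
#' Only columns where both sequences carry a residue are compared; gap/gap
#' and gap/residue columns are skipped.
#'
#' @param a,b aligned sequences (equal-length strings; `-` is the gap)
#' @return list with `p` (mismatch proportion) and `sites` (comparable sites)
#' @export
pdistance <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  if (length(va) != length(vb))
    stop("aligned sequences must have equal length")
  ok <- va != "-" & vb != "-"
  n <- sum(ok)
  if (n == 0L) stop("undefined distance: no comparable sites")
  list(p = sum(va[ok] != vb[ok]) / n, sites = n)
}

#' Poisson correction of a p-distance
#'
#' d = -ln(1 - p), with saturated proportions capped at `cap` to keep
#' distances finite.
#'
#' @param p mismatch proportion in `[0, 1]`
#' @param cap saturation cap applied before correcting
#' @return corrected distance in substitutions/site
#' @export
poisson_correct <- function(p, cap = 0.95) {
  stopifnot(all(p >= 0), all(p <= 1))
  capped <- p > cap
  p[capped] <- cap
  d <- -log(1 - p)
  attr(d, "capped") <- sum(capped)
  d
}

#' Corrected distance matrix from a protein alignment
#'
#' @param aln named character vector of equal-length aligned sequences
#' @param cap saturation cap (see [poisson_correct()])
#' @return symmetric numeric matrix (substitutions/site) with attribute
#'   `"capped"` = number of saturated pairs that were capped
#' @export
alignment_distances <- function(aln, cap = 0.95) {
  ids <- names(aln)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(aln)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  ncap <- 0L
  chars <- lapply(aln, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    va <- chars[[i]]; vb <- chars[[j]]
    ok <- va != "-" & vb != "-"
    if (!any(ok)) stop("undefined distance: no comparable sites between ",
                       ids[i], " and ", ids[j])
    p <- sum(va[ok] != vb[ok]) / sum(ok)
    d <- poisson_correct(p, cap)
    ncap <- ncap + attr(d, "capped")
    D[i, j] <- D[j, i] <- as.numeric(d)
  }
  attr(D, "capped") <- ncap
  D
}

#' Diagnose a distance matrix
#'
#' Reports (does not fix) asymmetries and triangle-inequality violations.
#' @param D square numeric matrix
#' @return list with `symmetric` flag and a data.frame of triangle
#'   violations (i, j, k with d(i,j) > d(i,k) + d(k,j))
#' @export
check_distances <- function(D) {
  sym <- isTRUE(all.equal(D, t(D), tolerance = 1e-12))
  viol <- list()
  n <- nrow(D)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && k != i && k != j && D[i, j] > D[i, k] + D[k, j] + 1e-12)
      viol[[length(viol) + 1L]] <- data.frame(i = rownames(D)[i],
                                              j = rownames(D)[j],
                                              k = rownames(D)[k])
  }
  list(symmetric = sym,
       triangle_violations = if (length(viol)) do.call(rbind, viol)
                             else data.frame(i = character(0),
                                             j = character(0),
                                             k = character(0)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration; ties in the Q criterion break to the
#' first (row-major) minimal pair so results are deterministic. Negative
#' branch-length estimates are clamped to zero; the number of clamped
#' branches is recorded in attribute `"clamped"` of the result. The returned
#' tree is unrooted in spirit: its "root" is the final three-way (or, for two
#' taxa, two-way) join.
#'
#' @param D symmetric distance matrix with row/col names (>= 3 taxa)
#' @return a taxtree
#' @export
neighbor_joining <- function(D) {
  n0 <- nrow(D)
  if (n0 < 3L) stop("neighbor joining needs at least 3 taxa")
  ids <- rownames(D)
  # node bookkeeping for the growing taxtree
  label <- ids; parent <- rep(NA_integer_, n0); brlen <- rep(NA_real_, n0)
  active <- seq_len(n0)      # node indices of current clusters
  Dm <- D
  rownames(Dm) <- colnames(Dm) <- as.character(active)
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  while (length(active) > 3L) {
    r <- nrow(Dm)
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    di <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    dj <- Dm[i, j] - di
    u <- length(label) + 1L
    label <- c(label, ""); parent <- c(parent, NA_integer_)
    brlen <- c(brlen, NA_real_)
    ni <- as.integer(rownames(Dm)[i]); nj <- as.integer(rownames(Dm)[j])
    parent[ni] <- u; brlen[ni] <- clamp(di)
    parent[nj] <- u; brlen[nj] <- clamp(dj)
    newd <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    nm <- c(rownames(Dm)[keep], as.character(u))
    rownames(Dm2) <- colnames(Dm2) <- nm
    Dm <- Dm2
    active <- c(setdiff(active, c(ni, nj)), u)
  }
  root <- length(label) + 1L
  label <- c(label, ""); parent <- c(parent, NA_integer_)
  brlen <- c(brlen, NA_real_)
  nodes <- as.integer(rownames(Dm))
  if (length(active) == 3L) {
    # three-point formulas
    d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
    l <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
           (d13 + d23 - d12) / 2)
    for (k in 1:3) { parent[nodes[k]] <- root; brlen[nodes[k]] <- clamp(l[k]) }
  } else {   # exactly two clusters remain (possible only when n0 == 2)
    for (k in 1:2) { parent[nodes[k]] <- root
                     brlen[nodes[k]] <- clamp(Dm[1, 2] / 2) }
  }
  tr <- new_taxtree(label, parent, brlen)
  attr(tr, "clamped") <- clamped
  tr
}

#' Nontrivial bipartitions of a tree's leaf set
#'
#' Each internal edge is represented canonically as the sorted leaf set on
#' the side NOT containing the alphabetically first leaf, joined with `|`.
#'
#' @param tree a taxtree
#' @return character vector of split keys
#' @export
tree_splits <- function(tree) {
  lv <- sort(leaf_labels(tree))
  ref <- lv[1]; nl <- length(lv)
  out <- character(0)
  for (v in seq_along(tree$label)) {
    if (v == tree$root || length(tree$children[[v]]) == 0L) next
    s <- clade_leaves(tree, v)
    if (ref %in% s) s <- setdiff(lv, s)
    if (length(s) >= 2L && length(s) <= nl - 2L)
      out <- c(out, paste(sort(s), collapse = "|"))
  }
  unique(out)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Bootstrap support for neighbor-joining splits
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each nontrivial split of the point-estimate
#' tree the fraction of replicates containing it. Reproducible for a fixed
#' seed.
#'
#' @param aln named character vector of aligned sequences
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed integer seed
#' @param cap saturation cap for distances
#' @return list with `tree` (point NJ tree), `support` (data.frame of split
#'   keys and supports in `[0, 1]`)
#' @export
nj_bootstrap <- function(aln, n_reps = 100, seed = 1, cap = 0.95) {
  stopifnot(n_reps >= 1)
  point <- neighbor_joining(alignment_distances(aln, cap))
  splits <- tree_splits(point)
  counts <- setNames(numeric(length(splits)), splits)
  L <- nchar(aln[[1]])
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(mat) <- names(aln)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- setNames(apply(mat[, cols, drop = FALSE], 1, paste,
                                collapse = ""), names(aln))
      rep_tree <- neighbor_joining(alignment_distances(rep_aln, cap))
      hits <- splits %in% tree_splits(rep_tree)
      counts[hits] <- counts[hits] + 1
    }
  })
  list(tree = point,
       support = data.frame(split = splits,
                            support = as.numeric(counts) / n_reps,
                            stringsAsFactors = FALSE))
}

#' Newick string of a bootstrap result, supports as internal labels
#' @param boot result of [nj_bootstrap()]
#' @param digits digits for support values
#' @return Newick string
#' @export
bootstrap_newick <- function(boot, digits = 2) {
  tr <- boot$tree
  sup <- setNames(boot$support$support, boot$support$split)
  lv <- sort(leaf_labels(tr)); ref <- lv[1]
  for (v in seq_along(tr$label)) {
    if (v == tr$root || length(tr$children[[v]]) == 0L) next
    s <- clade_leaves(tr, v)
    if (ref %in% s) s <- setdiff(lv, s)
    key <- paste(sort(s), collapse = "|")
    if (key %in% names(sup))
      tr$label[v] <- format(round(sup[[key]], digits), nsmall = 0)
  }
  write_newick(tr)
}

#' Check whether a set of leaves is monophyletic
#' @param tree a taxtree
#' @param leaves character vector of leaf labels
#' @return TRUE iff the MRCA's clade contains exactly `leaves`
#' @export
is_monophyletic <- function(tree, leaves) {
  m <- mrca(tree, leaves)
  setequal(clade_leaves(tree, attr(m, "id")), leaves)
}
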