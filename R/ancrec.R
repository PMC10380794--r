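# Ancestral gene-content reconstruction on a rooted taxonomy tree.
#
# Two routes are provided and cross-checked in the tests:
#  * Dollo parsimony — each family originates exactly once (at the MRCA of
#    the taxa that carry it) and is subsequently only lost; the reconstruction
#    minimizes the number of losses. This is the primary method: the
#    inference logic of the source analysis is exactly of this form.
#  * A two-state (absent/present) continuous-time Markov gain/loss model with
#    likelihood by Felsenstein pruning and marginal posteriors by the
#    up-down recursion; rates can be fitted by maximum likelihood.
# Unknown cells are missing data in both: Dollo lets them float with the
# reconstruction, the ML model gives them partial likelihood (1,1).

#' Two-state gain/loss model
#'
#' @param gain rate 0->1 per unit branch length
#' @param loss rate 1->0 per unit branch length
#' @param prior root prior of state "present"; default the stationary
#'   frequency gain/(gain+loss)
#' @return object of class `gainloss_model`
#' @export
gainloss_model <- function(gain, loss, prior = gain / (gain + loss)) {
  stopifnot(is.finite(gain), is.finite(loss), gain >= 0, loss >= 0,
            gain + loss > 0, prior >= 0, prior <= 1)
  structure(list(gain = gain, loss = loss, prior = prior),
            class = "gainloss_model")
}

#' Transition probability matrix of the gain/loss chain
#'
#' Closed form for the 2x2 chain: rows are the starting state
#' (absent, present), columns the ending state; rows sum to one for any t.
#'
#' @param model a gainloss_model
#' @param t branch length (>= 0)
#' @return 2x2 matrix, rows/cols named `c("absent","present")`
#' @export
transition_matrix <- function(model, t) {
  a <- model$gain; b <- model$loss; s <- a + b
  e <- exp(-s * t)
  m <- matrix(c((b + a * e) / s, (a - a * e) / s,
                (b - b * e) / s, (a + b * e) / s),
              2, 2, byrow = TRUE,
              dimnames = list(c("absent", "present"),
                              c("absent", "present")))
  m
}

new_ancmap <- function(tree, families, states, posterior, gain_node, events,
                       method, model = NULL) {
  structure(list(tree = tree, families = families, states = states,
                 posterior = posterior, gain_node = gain_node,
                 events = events, method = method, model = model),
            class = "ancmap")
}

#' @export
print.ancmap <- function(x, ...) {
  cat("ancmap (", x$method, "): ", length(x$families), " families on ",
      length(leaf_ids(x$tree)), " leaves; ",
      sum(x$events$type == "gain"), " gains, ",
      sum(x$events$type == "loss"), " losses\n", sep = "")
  invisible(x)
}

# matrix of leaf states aligned to tree leaves: 1/0/NA, leaves x families
leaf_state_matrix <- function(m, tree) {
  lv <- leaf_labels(tree)
  extra <- setdiff(rownames(m), lv)
  if (length(extra))
    stop("matrix taxa not found among tree leaves: ",
         paste(extra, collapse = ", "),
         " (use restrict_to_leaves() first)")
  out <- matrix(NA_integer_, length(lv), ncol(m),
                dimnames = list(lv, colnames(m)))
  out[rownames(m), ] <- m
  out
}

#' Dollo parsimony reconstruction
#'
#' Per family: the gain is placed at the MRCA of the present taxa; a node is
#' present iff it lies on the minimal subtree connecting them; one loss is
#' charged per maximal branch from a present node into a subtree with no
#' present (and at least one known-absent) leaf. Subtrees containing only
#' unknown leaves inherit their parent's state and generate no events. A
#' family with no present leaf is absent everywhere with zero events.
#'
#' @param m a phymat whose taxa are all leaves of `tree`
#' @param tree a rooted taxtree
#' @return an `ancmap` with per-node states, per-family gain nodes and a
#'   branch-mapped event table
#' @export
dollo_reconstruct <- function(m, tree) {
  if (ncol(m) == 0L) stop("no families to reconstruct")
  ls <- leaf_state_matrix(m, tree)
  n <- length(tree$label)
  lv <- leaf_ids(tree)
  po <- postorder(tree)
  fams <- colnames(m)
  states <- matrix(0L, n, length(fams), dimnames = list(NULL, fams))
  gain_node <- setNames(rep(NA_integer_, length(fams)), fams)
  ev <- list()
  for (f in fams) {
    x <- setNames(rep(NA_integer_, n), NULL)
    x[lv] <- ls[tree$label[lv], f]
    haspres <- logical(n)   # any present leaf in subtree
    hasknown <- logical(n)  # any known (0/1) leaf in subtree
    for (v in po) {
      ch <- tree$children[[v]]
      if (length(ch) == 0L) {
        haspres[v] <- isTRUE(x[v] == 1L)
        hasknown[v] <- !is.na(x[v])
      } else {
        haspres[v] <- any(haspres[ch])
        hasknown[v] <- any(hasknown[ch])
      }
    }
    if (!haspres[tree$root]) next   # absent everywhere, no events
    g <- local({
      pres_leaves <- tree$label[lv][which(ls[tree$label[lv], f] == 1L)]
      attr(mrca(tree, pres_leaves), "id")
    })
    gain_node[f] <- g
    under <- logical(n); under[g] <- TRUE
    st <- integer(n)
    for (v in rev(po)) {   # preorder
      p <- tree$parent[v]
      if (!is.na(p) && under[p]) under[v] <- TRUE
      if (v == g) { st[v] <- 1L; next }
      if (!under[v]) { st[v] <- 0L; next }
      if (haspres[v]) st[v] <- 1L
      else if (!hasknown[v]) st[v] <- st[p]   # unconstrained: follow parent
      else st[v] <- 0L
    }
    states[, f] <- st
    ev[[length(ev) + 1L]] <- data.frame(
      parent = if (is.na(tree$parent[g])) NA_character_
               else node_name(tree, tree$parent[g]),
      child = node_name(tree, g), family = f, type = "gain",
      stringsAsFactors = FALSE)
    for (v in seq_len(n)) {
      p <- tree$parent[v]
      if (is.na(p) || !under[v]) next
      if (st[p] == 1L && st[v] == 0L && hasknown[v])
        ev[[length(ev) + 1L]] <- data.frame(
          parent = node_name(tree, p), child = node_name(tree, v),
          family = f, type = "loss", stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(parent = character(0), child = character(0),
                            family = character(0), type = character(0))
  new_ancmap(tree, fams, states, NULL, gain_node, events, "dollo")
}

# stable displayable node name (label, or #index for unlabeled internals)
node_name <- function(tree, v) {
  if (tree$label[v] != "") tree$label[v] else paste0("#", v)
}

node_from_name <- function(tree, name) {
  if (grepl("^#[0-9]+$", name)) as.integer(sub("^#", "", name))
  else node_id(tree, name)
}

# ---- maximum likelihood ----------------------------------------------------

# pruning partials for all families at once; returns list(L0, L1, logscale)
prune_partials <- function(ls, tree, model, bl) {
  n <- length(tree$label); nf <- ncol(ls)
  L0 <- matrix(1, n, nf); L1 <- matrix(1, n, nf)
  logscale <- rep(0, nf)
  lv <- leaf_ids(tree)
  for (v in lv) {
    s <- ls[tree$label[v], ]
    L0[v, ] <- ifelse(is.na(s), 1, ifelse(s == 0L, 1, 0))
    L1[v, ] <- ifelse(is.na(s), 1, ifelse(s == 1L, 1, 0))
  }
  for (v in postorder(tree)) {
    ch <- tree$children[[v]]
    if (length(ch) == 0L) next
    acc0 <- rep(1, nf); acc1 <- rep(1, nf)
    for (c0 in ch) {
      P <- transition_matrix(model, bl[c0])
      m0 <- P[1, 1] * L0[c0, ] + P[1, 2] * L1[c0, ]
      m1 <- P[2, 1] * L0[c0, ] + P[2, 2] * L1[c0, ]
      acc0 <- acc0 * m0; acc1 <- acc1 * m1
    }
    sc <- pmax(acc0, acc1)
    sc[sc == 0] <- 1
    L0[v, ] <- acc0 / sc; L1[v, ] <- acc1 / sc
    logscale <- logscale + log(sc)
  }
  list(L0 = L0, L1 = L1, logscale = logscale)
}

#' Log-likelihood of a phyletic matrix under a gain/loss model
#'
#' @param m phymat over tree leaves
#' @param tree rooted taxtree
#' @param model gainloss_model
#' @param default_brlen substitute for missing branch lengths
#' @return numeric vector of per-family log-likelihoods
#' @export
gainloss_loglik <- function(m, tree, model, default_brlen = 1) {
  ls <- leaf_state_matrix(m, tree)
  bl <- ifelse(is.na(tree$brlen), default_brlen, tree$brlen)
  if (any(bl[-tree$root] <= 0)) stop("branch lengths must be positive")
  pr <- prune_partials(ls, tree, model, bl)
  r <- tree$root
  ll <- log((1 - model$prior) * pr$L0[r, ] + model$prior * pr$L1[r, ]) +
    pr$logscale
  if (any(!is.finite(ll)))
    stop("non-finite likelihood for family: ",
         paste(colnames(m)[!is.finite(ll)], collapse = ", "))
  setNames(ll, colnames(m))
}

golden_section_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c0 <- b - gr * (b - a); d0 <- a + gr * (b - a)
  fc <- f(c0); fd <- f(d0)
  while (b - a > tol) {
    if (fc >= fd) { b <- d0; d0 <- c0; fd <- fc
                    c0 <- b - gr * (b - a); fc <- f(c0) }
    else { a <- c0; c0 <- d0; fc <- fd
           d0 <- a + gr * (b - a); fd <- f(d0) }
  }
  (a + b) / 2
}

#' Fit gain/loss rates by maximum likelihood
#'
#' Coordinate-wise golden-section search on log10 rates, deterministic start
#' at (0.1, 0.1); the root prior is the stationary frequency of the current
#' rates throughout. Derivative-free and bounded: robust for a two-parameter
#' problem.
#'
#' @param m phymat over tree leaves
#' @param tree rooted taxtree
#' @param lower,upper rate bounds
#' @param tol convergence tolerance on log10 rates
#' @return fitted `gainloss_model` with attribute `"loglik"`
#' @export
fit_gainloss <- function(m, tree, lower = 1e-4, upper = 100, tol = 1e-6) {
  obj <- function(lg, ll) {
    mod <- gainloss_model(10^lg, 10^ll)
    sum(gainloss_loglik(m, tree, mod))
  }
  lg <- -1; ll <- -1
  for (it in 1:100) {
    lg2 <- golden_section_max(function(x) obj(x, ll),
                              log10(lower), log10(upper), tol)
    ll2 <- golden_section_max(function(x) obj(lg2, x),
                              log10(lower), log10(upper), tol)
    if (max(abs(lg2 - lg), abs(ll2 - ll)) < tol) { lg <- lg2; ll <- ll2; break }
    lg <- lg2; ll <- ll2
  }
  mod <- gainloss_model(10^lg, 10^ll)
  attr(mod, "loglik") <- sum(gainloss_loglik(m, tree, mod))
  mod
}

#' Maximum-likelihood ancestral reconstruction
#'
#' Marginal posterior of "present" at every node by the up-down recursion.
#' States are the posteriors thresholded at 0.5; an exact tie is reported as
#' unknown (NA), never silently as present. Events are branches on which the
#' thresholded state changes.
#'
#' @param m phymat over tree leaves
#' @param tree rooted taxtree
#' @param model a `gainloss_model`; `"fit"` to estimate one shared rate pair
#'   from all families first; or `"fit_per_family"` to fit and reconstruct
#'   each family under its own rates (families differ widely in turnover, so
#'   this is the appropriate mode for cross-checking a parsimony
#'   reconstruction family by family)
#' @param default_brlen substitute for missing branch lengths
#' @return an `ancmap` with a `posterior` matrix (nodes x families)
#' @export
ml_reconstruct <- function(m, tree, model = "fit", default_brlen = 1) {
  if (identical(model, "fit_per_family")) {
    parts <- lapply(colnames(m), function(f) {
      mf <- phymat(m[, f, drop = FALSE])
      ml_reconstruct(mf, tree, fit_gainloss(mf, tree), default_brlen)
    })
    asm <- parts[[1]]
    asm$families <- colnames(m)
    asm$states <- do.call(cbind, lapply(parts, `[[`, "states"))
    asm$posterior <- do.call(cbind, lapply(parts, `[[`, "posterior"))
    asm$gain_node <- do.call(c, lapply(parts, `[[`, "gain_node"))
    asm$events <- do.call(rbind, lapply(parts, `[[`, "events"))
    asm$model <- lapply(parts, `[[`, "model")
    return(asm)
  }
  if (identical(model, "fit")) model <- fit_gainloss(m, tree)
  stopifnot(inherits(model, "gainloss_model"))
  ls <- leaf_state_matrix(m, tree)
  bl <- ifelse(is.na(tree$brlen), default_brlen, tree$brlen)
  if (any(bl[-tree$root] <= 0)) stop("branch lengths must be positive")
  n <- length(tree$label); nf <- ncol(m)
  pr <- prune_partials(ls, tree, model, bl)
  # outside pass: G[v, s] = P(data outside subtree(v) | state(v) = s),
  # renormalized per node (only the posterior ratio matters)
  G0 <- matrix(0, n, nf); G1 <- matrix(0, n, nf)
  G0[tree$root, ] <- 1 - model$prior
  G1[tree$root, ] <- model$prior
  for (v in rev(postorder(tree))) {      # preorder: parents first
    ch <- tree$children[[v]]
    if (length(ch) == 0L) next
    msg0 <- vector("list", length(ch)); msg1 <- vector("list", length(ch))
    for (k in seq_along(ch)) {
      c0 <- ch[k]
      P <- transition_matrix(model, bl[c0])
      msg0[[k]] <- P[1, 1] * pr$L0[c0, ] + P[1, 2] * pr$L1[c0, ]
      msg1[[k]] <- P[2, 1] * pr$L0[c0, ] + P[2, 2] * pr$L1[c0, ]
    }
    for (k in seq_along(ch)) {
      c0 <- ch[k]
      sib0 <- rep(1, nf); sib1 <- rep(1, nf)
      for (j in seq_along(ch)) if (j != k) {
        sib0 <- sib0 * msg0[[j]]; sib1 <- sib1 * msg1[[j]]
      }
      top0 <- G0[v, ] * sib0   # P(outside, state(v)=absent)
      top1 <- G1[v, ] * sib1
      P <- transition_matrix(model, bl[c0])
      g0 <- top0 * P[1, 1] + top1 * P[2, 1]
      g1 <- top0 * P[1, 2] + top1 * P[2, 2]
      z <- g0 + g1; z[z == 0] <- 1
      G0[c0, ] <- g0 / z; G1[c0, ] <- g1 / z
    }
  }
  num1 <- G1 * pr$L1
  num0 <- G0 * pr$L0
  post <- num1 / (num0 + num1)
  colnames(post) <- colnames(m)
  states <- matrix(NA_integer_, n, nf, dimnames = list(NULL, colnames(m)))
  states[post > 0.5] <- 1L
  states[post < 0.5] <- 0L
  ev <- list()
  gain_node <- setNames(rep(NA_integer_, nf), colnames(m))
  for (f in colnames(m)) {
    st <- states[, f]
    for (v in seq_len(n)) {
      p <- tree$parent[v]
      pstate <- if (is.na(p)) 0L else st[p]
      if (is.na(st[v]) || is.na(pstate)) next
      if (pstate == 0L && st[v] == 1L) {
        ev[[length(ev) + 1L]] <- data.frame(
          parent = if (is.na(p)) NA_character_ else node_name(tree, p),
          child = node_name(tree, v), family = f, type = "gain",
          stringsAsFactors = FALSE)
        if (is.na(gain_node[f])) gain_node[f] <- v
      } else if (pstate == 1L && st[v] == 0L) {
        ev[[length(ev) + 1L]] <- data.frame(
          parent = node_name(tree, p), child = node_name(tree, v),
          family = f, type = "loss", stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(parent = character(0), child = character(0),
                            family = character(0), type = character(0))
  new_ancmap(tree, colnames(m), states, post, gain_node, events, "ml", model)
}

#' Ancestral states at a set of named nodes
#'
#' @param asm an `ancmap`
#' @param level character vector of node labels (internal or leaf)
#' @return a phymat of the reconstructed states at those nodes (ML posteriors
#'   thresholded at 0.5; exact ties are unknown)
#' @export
supergroup_states <- function(asm, level) {
  ids <- vapply(level, function(l) node_id(asm$tree, l), integer(1))
  phymat(matrix(asm$states[ids, , drop = FALSE], length(ids),
                dimnames = list(level, asm$families)))
}

#' Count branch-mapped gain/loss events for one family
#'
#' @param asm an `ancmap`
#' @param family family label
#' @param within optional clade label restricting the count to branches whose
#'   child node lies inside that clade (the clade's stem branch included)
#' @return named integer vector `c(gains =, losses =)`
#' @export
count_events <- function(asm, family, within = NULL) {
  if (!family %in% asm$families) stop("family not reconstructed: ", family)
  ev <- asm$events[asm$events$family == family, , drop = FALSE]
  if (!is.null(within)) {
    top <- node_id(asm$tree, within)   # errors on unknown clade
    inside <- clade_node_ids(asm$tree, top)
    keep <- vapply(ev$child, function(nm)
      node_from_name(asm$tree, nm) %in% inside, logical(1))
    ev <- ev[keep, , drop = FALSE]
  }
  c(gains = sum(ev$type == "gain"), losses = sum(ev$type == "loss"))
}

clade_node_ids <- function(tree, top) {
  acc <- integer(0); stack <- top
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    acc <- c(acc, v); stack <- c(stack, tree$children[[v]])
  }
  acc
}

#' Reconstructed state of one node for one family
#' @param asm an `ancmap`
#' @param node node label
#' @param family family label
#' @return 1, 0 or NA
#' @export
node_state <- function(asm, node, family) {
  unname(asm$states[node_id(asm$tree, node), family])
}
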