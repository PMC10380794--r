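# Rooted taxonomy trees with named internal ancestors.
#
# The reference trees used for ancestral gene-content reconstruction need
# three things that rule out a plain ape::phylo: polytomies wherever the
# branching order is deliberately left open, singleton "stem" nodes (FECA sits
# on the branch between the archaeal relatives of eukaryotes and LECA), and
# internal labels that are first-class query handles (LECA, Amorphea, ...).
# A taxtree is therefore a flat parent-pointer structure.

#' Construct a taxtree from parallel node vectors
#'
#' Nodes are indexed 1..n. Leaves are nodes without children. Internal nodes
#' may carry labels ("" means unlabeled); leaf labels must be unique and
#' nonempty.
#'
#' @param label character vector of node labels ("" allowed for internals)
#' @param parent integer vector of parent indices (NA for the root)
#' @param brlen numeric vector of branch lengths to the parent (NA allowed;
#'   defaults to 1 when used by reconstruction methods)
#' @return an object of class `taxtree`
#' @keywords internal
new_taxtree <- function(label, parent, brlen) {
  n <- length(label)
  stopifnot(length(parent) == n, length(brlen) == n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  root <- which(is.na(parent))
  tr <- structure(
    list(label = label, parent = as.integer(parent), brlen = as.numeric(brlen),
         children = children, root = as.integer(root)),
    class = "taxtree")
  validate_taxtree(tr)
  tr
}

#' Validate taxtree invariants
#'
#' Checks: exactly one root, unique nonempty leaf labels, unique internal
#' labels among the labeled internals, branch lengths nonnegative.
#' @param tree a taxtree
#' @return the tree, invisibly; errors otherwise
#' @export
validate_taxtree <- function(tree) {
  if (length(tree$root) != 1L)
    stop("tree must have exactly one root, found ", length(tree$root))
  lv <- leaf_ids(tree)
  ll <- tree$label[lv]
  if (any(ll == "")) stop("every leaf must be labeled")
  if (anyDuplicated(ll))
    stop("duplicate leaf label(s): ",
         paste(unique(ll[duplicated(ll)]), collapse = ", "))
  il <- tree$label[setdiff(seq_along(tree$label), lv)]
  il <- il[il != ""]
  if (anyDuplicated(il))
    stop("duplicate internal label(s): ",
         paste(unique(il[duplicated(il)]), collapse = ", "))
  if (any(!is.na(tree$brlen) & tree$brlen < 0))
    stop("negative branch length")
  invisible(tree)
}

#' @export
print.taxtree <- function(x, ...) {
  cat("taxtree:", length(leaf_ids(x)), "leaves,",
      length(x$label) - length(leaf_ids(x)), "internal nodes\n")
  nm <- named_ancestors(x)
  if (length(nm)) cat("named ancestors:", paste(nm, collapse = ", "), "\n")
  invisible(x)
}

#' Node indices of all leaves
#' @param tree a taxtree
#' @return integer vector of node indices
#' @export
leaf_ids <- function(tree) which(lengths(tree$children) == 0L)

#' Leaf labels in node-index order
#' @param tree a taxtree
#' @return character vector
#' @export
leaf_labels <- function(tree) tree$label[leaf_ids(tree)]

#' Labels of labeled internal nodes
#' @param tree a taxtree
#' @return character vector
#' @export
named_ancestors <- function(tree) {
  ids <- setdiff(seq_along(tree$label), leaf_ids(tree))
  l <- tree$label[ids]
  l[l != ""]
}

#' Resolve a node label to its index
#' @param tree a taxtree
#' @param label node label (leaf or internal)
#' @return integer node index
#' @export
node_id <- function(tree, label) {
  i <- which(tree$label == label)
  if (length(i) == 0L) stop("unknown node label: ", label)
  if (length(i) > 1L) stop("ambiguous node label: ", label)
  i
}

#' Postorder traversal (children before parents)
#' @param tree a taxtree
#' @return integer vector of node indices
#' @export
postorder <- function(tree) {
  n <- length(tree$label)
  out <- integer(n); k <- 0L
  stack <- c(tree$root); emit <- integer(n); ei <- 0L
  # iterative DFS producing reverse preorder, then flip
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ei <- ei + 1L; emit[ei] <- v
    stack <- c(stack, tree$children[[v]])
  }
  rev(emit[seq_len(ei)])
}

#' Leaf set of the clade below a node
#' @param tree a taxtree
#' @param node node index or label
#' @return character vector of leaf labels
#' @export
clade_leaves <- function(tree, node) {
  v <- if (is.character(node)) node_id(tree, node) else as.integer(node)
  acc <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree$children[[x]]
    if (length(ch) == 0L) acc <- c(acc, x) else stack <- c(stack, ch)
  }
  tree$label[acc]
}

ancestors_of <- function(tree, v) {
  out <- integer(0)
  while (!is.na(tree$parent[v])) { v <- tree$parent[v]; out <- c(out, v) }
  out
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree a taxtree
#' @param leaves nonempty character vector of leaf labels
#' @return the label of the MRCA node (its index is attached as attribute
#'   `"id"`); for a single leaf the leaf itself
#' @export
mrca <- function(tree, leaves) {
  if (length(leaves) == 0L) stop("need at least one leaf")
  ids <- vapply(leaves, function(l) node_id(tree, l), integer(1))
  bad <- !(ids %in% leaf_ids(tree))
  if (any(bad)) stop("not a leaf: ", paste(leaves[bad], collapse = ", "))
  cur <- ids[1]
  anc1 <- c(cur, ancestors_of(tree, cur))
  for (v in ids[-1]) {
    path <- c(v, ancestors_of(tree, v))
    anc1 <- anc1[anc1 %in% path]
  }
  id <- anc1[1]          # lowest shared, since paths are leaf-to-root ordered
  structure(tree$label[id], id = id)
}

#' Assign a leaf to its clade at a named partition level
#'
#' `level` is a set of internal (or leaf) labels whose clades partition the
#' leaves of interest; returns the unique member whose clade contains `leaf`.
#'
#' @param tree a taxtree
#' @param leaf leaf label
#' @param level character vector of node labels
#' @return the covering level label
#' @export
clade_of <- function(tree, leaf, level) {
  node_id(tree, leaf)    # existence check
  hits <- level[vapply(level, function(a) leaf %in% clade_leaves(tree, a),
                       logical(1))]
  if (length(hits) == 0L)
    stop("leaf ", leaf, " is not covered by any level node")
  if (length(hits) > 1L)
    stop("level nodes are nested over leaf ", leaf, ": ",
         paste(hits, collapse = ", "))
  hits[[1]]
}

# ---- Newick I/O -------------------------------------------------------------

#' Parse a Newick string into a taxtree
#'
#' Supports polytomies, singleton internal nodes, quoted labels
#' (single quotes, doubled quote escapes), internal-node labels and branch
#' lengths. Unbalanced parentheses are reported with the 1-based character
#' offset of the offending parenthesis.
#'
#' @param text a single Newick string (must end in `;`)
#' @return a taxtree
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  # balance pre-check with offsets, ignoring quoted stretches
  depth <- 0L; inq <- FALSE; opens <- integer(0)
  for (i in seq_along(chars)) {
    c0 <- chars[i]
    if (inq) { if (c0 == "'") inq <- FALSE; next }
    if (c0 == "'") { inq <- TRUE; next }
    if (c0 == "(") { depth <- depth + 1L; opens <- c(opens, i) }
    if (c0 == ")") {
      if (depth == 0L)
        stop("Newick parse error: unbalanced ')' at character offset ", i)
      depth <- depth - 1L; opens <- opens[-length(opens)]
    }
  }
  if (depth > 0L)
    stop("Newick parse error: unbalanced '(' at character offset ",
         opens[length(opens)])

  env <- new.env()
  env$pos <- 1L; env$chars <- chars; env$n <- length(chars)
  env$label <- character(0); env$parent <- integer(0); env$brlen <- numeric(0)

  peek <- function() if (env$pos > env$n) NA_character_ else env$chars[env$pos]
  advance <- function() env$pos <- env$pos + 1L
  skip_ws <- function() while (!is.na(peek()) && grepl("[ \t\r\n]", peek())) advance()

  read_label <- function() {
    skip_ws()
    if (identical(peek(), "'")) {
      advance()
      out <- character(0)
      repeat {
        c0 <- peek()
        if (is.na(c0)) stop("Newick parse error: unterminated quoted label")
        advance()
        if (c0 == "'") {
          if (identical(peek(), "'")) { out <- c(out, "'"); advance() }
          else break
        } else out <- c(out, c0)
      }
      paste(out, collapse = "")
    } else {
      out <- character(0)
      repeat {
        c0 <- peek()
        if (is.na(c0) || c0 %in% c("(", ")", ",", ":", ";", "[", "]") ||
            grepl("[ \t\r\n]", c0)) break
        out <- c(out, c0); advance()
      }
      paste(out, collapse = "")
    }
  }

  read_brlen <- function() {
    skip_ws()
    if (!identical(peek(), ":")) return(NA_real_)
    advance(); skip_ws()
    out <- character(0)
    repeat {
      c0 <- peek()
      if (is.na(c0) || !grepl("[-+0-9.eE]", c0)) break
      out <- c(out, c0); advance()
    }
    v <- suppressWarnings(as.numeric(paste(out, collapse = "")))
    if (is.na(v))
      stop("Newick parse error: bad branch length at character offset ", env$pos)
    v
  }

  new_node <- function(lab, par, bl) {
    env$label <- c(env$label, lab)
    env$parent <- c(env$parent, par)
    env$brlen <- c(env$brlen, bl)
    length(env$label)
  }

  parse_clade <- function(par) {
    skip_ws()
    if (identical(peek(), "(")) {
      advance()
      me <- new_node("", par, NA_real_)
      repeat {
        parse_clade(me)
        skip_ws()
        if (identical(peek(), ",")) { advance(); next }
        if (identical(peek(), ")")) { advance(); break }
        stop("Newick parse error: expected ',' or ')' at character offset ",
             env$pos)
      }
      env$label[me] <- read_label()
      env$brlen[me] <- read_brlen()
      me
    } else {
      lab <- read_label()
      if (lab == "")
        stop("Newick parse error: empty leaf label at character offset ",
             env$pos)
      new_node(lab, par, read_brlen())
    }
  }

  parse_clade(NA_integer_)
  skip_ws()
  if (!identical(peek(), ";"))
    stop("Newick parse error: expected ';' at character offset ", env$pos)
  advance(); skip_ws()
  if (env$pos <= env$n)
    stop("Newick parse error: trailing characters at offset ", env$pos)
  new_taxtree(env$label, env$parent, env$brlen)
}

#' Read a Newick file
#' @param path path to a file containing one Newick tree
#' @return a taxtree
#' @export
read_newick_file <- function(path) {
  read_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

quote_label <- function(l) {
  if (grepl("[ ()\\[\\]:;,']", l))
    paste0("'", gsub("'", "''", l), "'")
  else l
}

#' Serialize a taxtree to Newick
#'
#' @param tree a taxtree
#' @param file optional path; when given the string is also written there
#' @param digits significant digits for branch lengths
#' @return the Newick string, invisibly when `file` is given
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  fmt <- function(v) {
    lab <- quote_label(tree$label[v])
    bl <- tree$brlen[v]
    tail <- if (is.na(bl)) "" else paste0(":", format(bl, digits = digits,
                                                      scientific = FALSE))
    ch <- tree$children[[v]]
    if (length(ch) == 0L) paste0(lab, tail)
    else paste0("(", paste(vapply(ch, fmt, character(1)), collapse = ","),
                ")", lab, tail)
  }
  s <- paste0(fmt(tree$root), ";")
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

# ---- rooting ---------------------------------------------------------------

#' Reroot a tree on the branch above a named outgroup
#'
#' Places a new root on the branch above `outgroup` (leaf or internal label)
#' at fraction `position` of the way from `outgroup` toward its parent.
#' Rooting is semantic for Dollo reconstruction, so unrooted inputs should be
#' rerooted explicitly rather than guessed at.
#'
#' @param tree a taxtree
#' @param outgroup node label (or index)
#' @param position fraction of the outgroup branch below the new root
#' @return a rerooted taxtree (old root collapses away if it becomes a
#'   redundant unlabeled degree-two node)
#' @export
reroot <- function(tree, outgroup, position = 0.5) {
  x <- if (is.character(outgroup)) node_id(tree, outgroup) else as.integer(outgroup)
  if (x == tree$root) stop("cannot reroot at the current root")
  stopifnot(position >= 0, position <= 1)
  p <- tree$parent[x]
  n <- length(tree$label)
  R <- n + 1L
  blx <- tree$brlen[x]
  # undirected weighted adjacency; edge (v, parent[v]) has weight brlen[v]
  adj <- vector("list", n + 1L)
  addedge <- function(a, b, w) {
    adj[[a]][[length(adj[[a]]) + 1L]] <<- c(b, w)
    adj[[b]][[length(adj[[b]]) + 1L]] <<- c(a, w)
  }
  for (v in seq_len(n)) {
    pv <- tree$parent[v]
    if (is.na(pv) || (v == x && pv == p)) next
    addedge(v, pv, tree$brlen[v])
  }
  if (is.na(blx)) addedge(R, x, NA_real_) else addedge(R, x, blx * position)
  if (is.na(blx)) addedge(R, p, NA_real_) else addedge(R, p, blx * (1 - position))
  # orient everything away from R
  label <- c(tree$label, "")
  parent <- rep(NA_integer_, n + 1L)
  brlen <- rep(NA_real_, n + 1L)
  seen <- logical(n + 1L); seen[R] <- TRUE
  queue <- R
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (e in adj[[v]]) {
      w <- as.integer(e[1])
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        brlen[w] <- e[2]
        queue <- c(queue, w)
      }
    }
  }
  collapse_singletons(new_taxtree(label, parent, brlen))
}

# remove unlabeled internal nodes with exactly one child (can arise after
# rerooting); branch lengths are summed through
collapse_singletons <- function(tree) {
  repeat {
    sing <- which(lengths(tree$children) == 1L & tree$label == "" &
                    seq_along(tree$label) != tree$root)
    singr <- if (length(tree$children[[tree$root]]) == 1L &&
                 tree$label[tree$root] == "") tree$root else integer(0)
    drop <- c(sing, singr)
    if (length(drop) == 0L) return(tree)
    d <- drop[1]
    ch <- tree$children[[d]][1]
    if (d == tree$root) {
      tree$parent[ch] <- NA_integer_
      tree$root <- ch
      keep <- setdiff(seq_along(tree$label), d)
    } else {
      tree$parent[ch] <- tree$parent[d]
      tree$brlen[ch] <- sum(c(tree$brlen[ch], tree$brlen[d]), na.rm = TRUE)
      keep <- setdiff(seq_along(tree$label), d)
    }
    remap <- match(seq_along(tree$label), keep)
    tree <- new_taxtree(tree$label[keep],
                        remap[tree$parent[keep]],
                        tree$brlen[keep])
  }
}

#' Depth of every node (sum of branch lengths from the root)
#'
#' Missing branch lengths count as `default`.
#' @param tree a taxtree
#' @param default value used for NA branch lengths
#' @return numeric vector indexed by node
#' @export
node_depths <- function(tree, default = 1) {
  bl <- ifelse(is.na(tree$brlen), default, tree$brlen)
  d <- numeric(length(tree$label))
  for (v in rev(postorder(tree))) {   # preorder
    p <- tree$parent[v]
    d[v] <- if (is.na(p)) 0 else d[p] + bl[v]
  }
  d
}

#' Midpoint-root an (effectively unrooted) tree
#'
#' Finds the longest leaf-to-leaf path and places the root at its midpoint.
#' @param tree a taxtree (its current root is treated as arbitrary)
#' @return a rooted taxtree
#' @export
midpoint_root <- function(tree) {
  lv <- leaf_ids(tree)
  d <- node_depths(tree, default = 1)
  bl <- ifelse(is.na(tree$brlen), 1, tree$brlen)
  # pairwise leaf distances through the tree
  best <- c(NA, NA); bestd <- -Inf
  anc <- lapply(seq_along(tree$label), function(v) c(v, ancestors_of(tree, v)))
  for (i in seq_along(lv)) for (j in seq_len(i - 1L)) {
    a <- lv[i]; b <- lv[j]
    common <- anc[[a]][anc[[a]] %in% anc[[b]]][1]
    dd <- d[a] + d[b] - 2 * d[common]
    if (dd > bestd) { bestd <- dd; best <- c(a, b) }
  }
  a <- best[1]; b <- best[2]
  common <- anc[[a]][anc[[a]] %in% anc[[b]]][1]
  half <- bestd / 2
  # walk from the deeper end toward the common ancestor until passing half
  from <- if (d[a] - d[common] >= half) a else b
  acc <- 0; v <- from
  while (acc + bl[v] < half && tree$parent[v] != common) {
    acc <- acc + bl[v]; v <- tree$parent[v]
  }
  reroot(tree, v, position = (half - acc) / bl[v])
}
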