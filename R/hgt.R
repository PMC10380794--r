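# Horizontal gene transfer detection by conservation-anomaly scoring.
#
# The operating criterion: unusually high sequence conservation between
# distantly related organisms signals a transfer. Each query is scored as
#   anomaly = (best identity to any out-group sequence)
#           - (best identity to any in-group sequence, own species excluded)
# — the alien-index family of methods. The published analysis states the
# criterion qualitatively; the numeric flagging threshold (default 0.10
# identity units) is this package's explicit, configurable choice. Flagged
# calls are clustered into independent transfer events by donor/recipient
# identity plus monophyly on a gene tree.

#' Pairwise alignment identity matrix
#'
#' Global affine-gap alignments (match +2 / mismatch -1 / gap 11, 1);
#' identity is matches over aligned residue pairs, gap columns excluded.
#'
#' @param seqs named character vector of protein sequences
#' @return symmetric numeric matrix in `[0, 1]`
#' @export
pairwise_identity <- function(seqs) {
  m <- .pairwise_identity_matrix(unname(unlist(seqs)))
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' Conservation-anomaly scores for a set of query sequences
#'
#' @param seqs named character vector (names are taxa; one gene per taxon)
#' @param clades data.frame with columns `taxon`, `clade`, `domain`
#' @param level column of `clades` defining the in/out partition
#'   (default `"domain"`: e.g. eukaryote queries against prokaryote outgroup)
#' @param queries taxa to score (default: all)
#' @param identity optional precomputed [pairwise_identity()] matrix
#' @return data.frame of HGT calls: taxon, recipient (level label), clade,
#'   in_identity, out_identity, score, flagged (NA until [flag_calls()]),
#'   donor, event. Queries without an in-group comparator are returned with
#'   NA identities and attribute `"incomparable"` lists them.
#' @export
hgt_scores <- function(seqs, clades, level = "domain",
                       queries = names(seqs), identity = NULL) {
  stopifnot(all(c("taxon", "clade", "domain") %in% names(clades)),
            level %in% names(clades))
  missing <- setdiff(names(seqs), clades$taxon)
  if (length(missing))
    stop("taxa without clade assignment: ", paste(missing, collapse = ", "))
  if (is.null(identity)) identity <- pairwise_identity(seqs)
  grp <- setNames(clades[[level]], clades$taxon)[names(seqs)]
  fine <- setNames(clades$clade, clades$taxon)[names(seqs)]
  rows <- lapply(queries, function(q) {
    g <- grp[[q]]
    ingrp <- names(seqs)[grp == g & names(seqs) != q]
    outgrp <- names(seqs)[grp != g]
    if (length(ingrp) == 0L || length(outgrp) == 0L)
      return(data.frame(taxon = q, recipient = g, clade = fine[[q]],
                        in_identity = NA_real_, out_identity = NA_real_,
                        score = NA_real_, flagged = NA, donor = NA_character_,
                        event = NA_integer_, stringsAsFactors = FALSE))
    ini <- max(identity[q, ingrp])
    outi <- max(identity[q, outgrp])
    data.frame(taxon = q, recipient = g, clade = fine[[q]],
               in_identity = ini, out_identity = outi, score = outi - ini,
               flagged = NA, donor = NA_character_, event = NA_integer_,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  attr(calls, "incomparable") <- calls$taxon[is.na(calls$score)]
  calls
}

#' Flag calls at a score threshold
#'
#' Flagged iff score >= threshold (boundary inclusive, documented).
#' @param calls result of [hgt_scores()]
#' @param threshold anomaly-score cut-off in identity units
#' @return calls with `flagged` filled (NA scores stay NA)
#' @export
flag_calls <- function(calls, threshold = 0.10) {
  calls$flagged <- ifelse(is.na(calls$score), NA, calls$score >= threshold)
  attr(calls, "threshold") <- threshold
  calls
}

#' Donor clade of a flagged call from its gene-tree neighborhood
#'
#' Walks rootward from the query tip; the first neighboring tip set that
#' contains taxa outside the query's recipient group is the sister group,
#' and the donor is its majority `clade` label (ties -> `"ambiguous"`).
#'
#' @param taxon flagged query taxon (a tip of `tree`)
#' @param tree gene taxtree containing the query and donor references
#' @param clades clade table (taxon/clade/domain)
#' @param level recipient-group column used during scoring
#' @return donor clade label
#' @export
donor_clade <- function(taxon, tree, clades, level = "domain") {
  grp <- setNames(clades[[level]], clades$taxon)
  fine <- setNames(clades$clade, clades$taxon)
  v <- node_id(tree, taxon)
  if (!v %in% leaf_ids(tree)) stop("placement error: ", taxon,
                                   " is not a tip of the gene tree")
  g <- grp[[taxon]]
  seen <- taxon
  while (!is.na(tree$parent[v])) {
    p <- tree$parent[v]
    added <- setdiff(clade_leaves(tree, p), seen)
    seen <- c(seen, added)
    foreign <- added[!is.na(grp[added]) & grp[added] != g]
    if (length(foreign)) {
      tab <- sort(table(fine[foreign]), decreasing = TRUE)
      if (length(tab) > 1L && tab[1] == tab[2]) return("ambiguous")
      return(names(tab)[1])
    }
    v <- p
  }
  "ambiguous"
}

#' Cluster flagged calls into independent transfer events
#'
#' Single linkage: two flagged calls join iff they share the same
#' (donor, recipient) pair and are monophyletic together on the gene tree —
#' every same-recipient-group tip inside their spanning clade is itself a
#' flagged call with the same donor and recipient (donor-side tips are the
#' expected context and do not break monophyly).
#'
#' @param calls flagged calls (only rows with `flagged == TRUE` are used)
#' @param tree gene taxtree containing every flagged call as a tip
#' @param clades clade table
#' @param level recipient-group column
#' @param recipient_col column of `calls` naming the recipient label used in
#'   the linkage key: `"recipient"` (scoring-level group) or `"clade"`
#' @return list with `calls` (event ids filled) and `events`
#'   (one row per inferred independent transfer)
#' @export
cluster_events <- function(calls, tree, clades, level = "domain",
                           recipient_col = "recipient") {
  fl <- calls[!is.na(calls$flagged) & calls$flagged, , drop = FALSE]
  if (nrow(fl) == 0L)
    return(list(calls = calls,
                events = data.frame(event = integer(0), donor = character(0),
                                    recipient = character(0),
                                    n_calls = integer(0))))
  absent <- setdiff(fl$taxon, leaf_labels(tree))
  if (length(absent))
    stop("placement error: flagged call(s) not on the gene tree: ",
         paste(absent, collapse = ", "))
  fl$donor <- vapply(fl$taxon, donor_clade, character(1),
                     tree = tree, clades = clades, level = level)
  grp <- setNames(clades[[level]], clades$taxon)
  n <- nrow(fl)
  # union-find
  par <- seq_len(n)
  find <- function(i) { while (par[i] != i) i <- par[i]; i }
  join <- function(i, j) { ri <- find(i); rj <- find(j)
                           if (ri != rj) par[rj] <<- ri }
  ok_pair <- function(i, j) {
    if (fl$donor[i] != fl$donor[j]) return(FALSE)
    if (fl[[recipient_col]][i] != fl[[recipient_col]][j]) return(FALSE)
    sub <- clade_leaves(tree, attr(mrca(tree, c(fl$taxon[i], fl$taxon[j])),
                                   "id"))
    samegrp <- sub[!is.na(grp[sub]) & grp[sub] == grp[[fl$taxon[i]]]]
    extraneous <- setdiff(samegrp,
                          fl$taxon[fl$donor == fl$donor[i] &
                                   fl[[recipient_col]] ==
                                     fl[[recipient_col]][i]])
    length(extraneous) == 0L
  }
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (ok_pair(i, j)) join(i, j)
  roots <- vapply(seq_len(n), find, integer(1))
  fl$event <- as.integer(factor(roots, levels = unique(roots)))
  calls$event <- NA_integer_; calls$donor <- NA_character_
  idx <- match(fl$taxon, calls$taxon)
  calls$event[idx] <- fl$event
  calls$donor[idx] <- fl$donor
  events <- do.call(rbind, lapply(split(fl, fl$event), function(g)
    data.frame(event = g$event[1], donor = g$donor[1],
               recipient = g[[recipient_col]][1], n_calls = nrow(g),
               stringsAsFactors = FALSE)))
  rownames(events) <- NULL
  list(calls = calls, events = events)
}

#' Native vs transferred fractions for a scored clade
#'
#' Fractions are over scored sequences and sum to one; queries without an
#' in-group comparator are reported separately, not folded in.
#'
#' @param calls flagged calls for one clade
#' @return named numeric `c(native =, transferred =)` with attribute
#'   `"incomparable"` (count of unscorable sequences)
#' @export
origin_fractions <- function(calls) {
  scored <- calls[!is.na(calls$flagged), , drop = FALSE]
  if (nrow(scored) == 0L) stop("empty summary: no scored sequences")
  tf <- mean(scored$flagged)
  structure(c(native = 1 - tf, transferred = tf),
            incomparable = sum(is.na(calls$flagged)))
}

#' Read a packaged or user clade table
#' @param path TSV with columns taxon, clade, domain
#' @return data.frame
#' @export
read_clades <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Run the full HGT pipeline on the packaged five-case fixture
#'
#' @param threshold flagging threshold
#' @return result of [cluster_events()] plus the raw calls
#' @export
five_hgt_cases_analysis <- function(threshold = 0.10) {
  seqs <- read_fasta(c1a_extdata("hgt", "five_cases.fasta"))
  clades <- read_clades(c1a_extdata("hgt", "five_cases_clades.tsv"))
  tree <- read_newick_file(c1a_extdata("hgt", "five_cases_genetree.nwk"))
  euk <- clades$taxon[clades$domain == "Eukaryota"]
  calls <- flag_calls(hgt_scores(seqs, clades, level = "domain",
                                 queries = euk), threshold)
  cluster_events(calls, tree, clades, level = "domain",
                 recipient_col = "recipient")
}
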