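# Phyletic presence/absence/unknown matrices.
#
# A phymat is an integer matrix with taxa as rows and gene families as
# columns; cells are 1 (present), 0 (absent) or NA (unknown). The published
# distribution tables are binary; the third state exists because sequence
# databases differ wildly in coverage, so "no hit in a thin transcriptome"
# must stay distinguishable from "absent from a complete genome".
# Reconstruction treats unknown as missing data, never as absence.

#' The eight ancestral eukaryotic C1A families, in reporting order
#' @export
ANCESTRAL_FAMILIES <- c("cathB", "cathC", "cathX", "cathL",
                        "cathF", "cathH", "p26_29", "type1_long")

#' Full closed family vocabulary (extensible via `extra` arguments downstream)
#' @export
FAMILY_VOCABULARY <- c(ANCESTRAL_FAMILIES, "cathO", "vWFA_C1", "C1A_generic")

#' Construct a phyletic matrix
#'
#' @param states integer matrix (1/0/NA) with rownames = taxa and
#'   colnames = families
#' @return an object of class `phymat`
#' @export
phymat <- function(states) {
  states <- as.matrix(states)
  if (is.null(rownames(states)) && nrow(states) > 0)
    stop("taxa (rownames) required")
  if (is.null(colnames(states))) stop("families (colnames) required")
  if (anyDuplicated(rownames(states)))
    stop("duplicate taxon label(s): ",
         paste(unique(rownames(states)[duplicated(rownames(states))]),
               collapse = ", "))
  if (anyDuplicated(colnames(states)))
    stop("duplicate family label(s)")
  storage.mode(states) <- "integer"
  ok <- is.na(states) | states %in% c(0L, 1L)
  if (!all(ok)) stop("cell states must be 1, 0 or NA")
  structure(states, class = c("phymat", "matrix"))
}

#' @export
print.phymat <- function(x, ...) {
  cat("phymat:", nrow(x), "taxa x", ncol(x), "families\n")
  m <- matrix(ifelse(is.na(x), "?", ifelse(x == 1L, "1", "0")),
              nrow(x), dimnames = dimnames(x))
  print(m, quote = FALSE)
  invisible(x)
}

#' Read a phyletic matrix from TSV
#'
#' Format: header row of family labels, leading taxon column, cells in
#' `1` / `0` / `?` (unknown). Ragged rows and illegal tokens are format
#' errors naming the offending row/column.
#'
#' @param path TSV path
#' @return a phymat
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- cells[[1]]
  fams <- hdr[-1]
  ncol_exp <- length(hdr)
  taxa <- character(length(cells) - 1L)
  out <- matrix(NA_integer_, length(cells) - 1L, length(fams),
                dimnames = list(NULL, fams))
  for (i in seq_along(cells)[-1]) {
    row <- cells[[i]]
    if (length(row) != ncol_exp)
      stop("format error: row ", i, " has ", length(row),
           " fields, expected ", ncol_exp)
    taxa[i - 1L] <- row[1]
    for (j in seq_along(fams)) {
      tok <- row[j + 1L]
      out[i - 1L, j] <-
        if (tok == "1") 1L else if (tok == "0") 0L
        else if (tok == "?") NA_integer_
        else stop("format error: illegal cell token '", tok,
                  "' at row '", row[1], "', column '", fams[j], "'")
    }
  }
  rownames(out) <- taxa
  phymat(out)
}

#' Write a phyletic matrix to TSV (round-trips through [read_matrix()])
#' @param m a phymat
#' @param path output path
#' @return `path`, invisibly
#' @export
write_matrix <- function(m, path) {
  tok <- matrix(ifelse(is.na(m), "?", as.character(m)), nrow(m))
  lines <- c(paste(c("taxon", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], tok[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Merge two phyletic matrices
#'
#' Union of taxa and families. Cells known in one input are taken from it;
#' cells absent from both become unknown. A cell known in both inputs with
#' conflicting states is an error (all conflicts are listed).
#'
#' @param a,b phymat objects
#' @return merged phymat
#' @export
merge_matrices <- function(a, b) {
  taxa <- union(rownames(a), rownames(b))
  fams <- union(colnames(a), colnames(b))
  out <- matrix(NA_integer_, length(taxa), length(fams),
                dimnames = list(taxa, fams))
  fill <- function(m) {
    v <- matrix(NA_integer_, length(taxa), length(fams),
                dimnames = list(taxa, fams))
    v[rownames(m), colnames(m)] <- m
    v
  }
  va <- fill(a); vb <- fill(b)
  conflict <- !is.na(va) & !is.na(vb) & va != vb
  if (any(conflict)) {
    idx <- which(conflict, arr.ind = TRUE)
    stop("conflicting states for cell(s): ",
         paste(paste0(taxa[idx[, 1]], "/", fams[idx[, 2]]), collapse = ", "))
  }
  out[!is.na(va)] <- va[!is.na(va)]
  out[!is.na(vb)] <- vb[!is.na(vb)]
  phymat(out)
}

#' Build a presence/absence matrix from classifier assignments
#'
#' A cell is present iff at least one assignment maps the taxon to the
#' family; cells of surveyed taxa with no assignment are absent; taxa not in
#' `surveyed` are unknown.
#'
#' @param assignments data.frame with columns `taxon` and `family` (rows with
#'   family `"unclassified"` are ignored)
#' @param surveyed character vector of taxa whose absence is informative
#' @param families family vocabulary (columns of the result)
#' @return a phymat over `surveyed` plus any assigned taxa
#' @export
matrix_from_assignments <- function(assignments,
                                    surveyed,
                                    families = ANCESTRAL_FAMILIES) {
  assignments <- assignments[assignments$family != "unclassified", ,
                             drop = FALSE]
  bad <- setdiff(unique(assignments$family), families)
  if (length(bad))
    stop("unknown family label(s): ", paste(bad, collapse = ", "))
  taxa <- union(surveyed, unique(assignments$taxon))
  out <- matrix(NA_integer_, length(taxa), length(families),
                dimnames = list(taxa, families))
  out[surveyed, ] <- 0L
  for (i in seq_len(nrow(assignments)))
    out[assignments$taxon[i], assignments$family[i]] <- 1L
  phymat(out)
}

#' Drop matrix rows that are not leaves of a tree
#'
#' The published tables carry rows for higher groups (e.g. supergroup header
#' rows) alongside their member lineages; reconstruction operates on leaf
#' taxa only, so those rows must be set aside first.
#'
#' @param m a phymat
#' @param tree a taxtree
#' @return phymat restricted to `leaf_labels(tree)`
#' @export
restrict_to_leaves <- function(m, tree) {
  keep <- intersect(rownames(m), leaf_labels(tree))
  phymat(m[keep, , drop = FALSE])
}

# ---- packaged reference data ----------------------------------------------

#' Path to a packaged data file
#' @param ... path components under `extdata`
#' @return file path
#' @export
c1a_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "c1aprofiler", mustWork = TRUE)
  p
}

#' Load a packaged reference tree
#' @param name one of "eukaryota", "prokaryota", "combined"
#' @return a taxtree
#' @export
reference_tree <- function(name = c("eukaryota", "prokaryota", "combined")) {
  name <- match.arg(name)
  read_newick_file(c1a_extdata("trees", paste0(name, ".nwk")))
}

#' Load a packaged distribution table
#'
#' Tables "table1" (eukaryote supergroups x 8 ancestral families), "table2"
#' (Obazoa detail, 10 families), "table3" (prokaryote phyla x short/
#' multidomain C1A), "table5" (ancestral supergroup states) and "table6"
#' (LUCA/FECA/LECA content) as shipped transcriptions.
#'
#' @param name table name
#' @return a phymat
#' @export
reference_table <- function(name = c("table1", "table2", "table3",
                                     "table5", "table6")) {
  name <- match.arg(name)
  read_matrix(c1a_extdata("matrices", paste0(name, ".tsv")))
}

#' Derive the generic C1A presence character for prokaryote tree leaves
#'
#' Scores each prokaryote leaf present for `C1A_generic` iff either the
#' single-domain or the multidomain column of the shipped prokaryote table is
#' present. The phylum row for Pseudomonadota is expanded to the three
#' proteobacterial leaves of the backbone tree (all scored present, as short
#' C1A peptidases are reported from alpha-, gamma- and delta-proteobacteria).
#'
#' @param table3 prokaryote table (defaults to the shipped transcription)
#' @return one-column phymat keyed by prokaryote leaf names
#' @export
prokaryote_c1a_matrix <- function(table3 = reference_table("table3")) {
  tr <- reference_tree("prokaryota")
  lv <- leaf_labels(tr)
  expand <- list(Pseudomonadota = c("Alphaproteobacteria",
                                    "Gammaproteobacteria",
                                    "Deltaproteobacteria"))
  pres <- as.integer(rowSums(table3 == 1L, na.rm = TRUE) > 0)
  names(pres) <- rownames(table3)
  out <- setNames(rep(NA_integer_, length(lv)), lv)
  for (t in names(pres)) {
    if (t %in% names(expand)) {
      out[expand[[t]]] <- pres[[t]]
    } else if (t %in% lv) {
      out[t] <- pres[[t]]
    }
  }
  phymat(matrix(out, ncol = 1, dimnames = list(names(out), "C1A_generic")))
}

#' Add the generic C1A character to a eukaryote matrix
#'
#' A eukaryote taxon carries some C1A peptidase iff any family column is
#' present; unknown-only rows stay unknown.
#'
#' @param m eukaryote phymat (any family columns)
#' @return `m` with a `C1A_generic` column appended
#' @export
add_eukaryote_c1a <- function(m) {
  anyp <- as.integer(rowSums(m == 1L, na.rm = TRUE) > 0)
  allna <- rowSums(!is.na(m)) == 0
  anyp[allna] <- NA_integer_
  merge_matrices(m, phymat(matrix(anyp, ncol = 1,
                                  dimnames = list(rownames(m), "C1A_generic"))))
}
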