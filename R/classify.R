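# Profile-based assignment of protein sequences to C1A orthologous families.
#
# The original survey placed sequences by iterative BLAST searches against
# public databases; that is not reproducible at desk scale, so each family is
# modeled instead as a position-specific score matrix (log-odds with
# pseudocounts) built from a packaged seed alignment, and sequences are
# scored by profile-global / sequence-local affine-gap dynamic programming.
# The E-value acceptance cut-off of 1e-5 is retained as the significance
# threshold; absolute E-values are Karlin-Altschul-shaped but not calibrated
# (only threshold behaviour is load-bearing).

#' @useDynLib c1aprofiler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

encode_seq <- function(seq) {
  v <- match(strsplit(seq, "")[[1]], AA20) - 1L
  v[is.na(v)] <- -1L     # X / unknown residues
  as.integer(v)
}

#' Build a family profile from an aligned seed set
#'
#' Log-odds scores are `log2((count + pseudocount) / (n + 20 pseudocount) /
#' background)` per column and residue; columns with more than 50% gaps are
#' dropped. The catalytic triad columns are auto-located as the first fully
#' conserved Cys column, the first fully conserved His column after it, and
#' the first fully conserved Asn column after that.
#'
#' @param seeds named character vector of aligned sequences (>= 3, equal
#'   lengths; `-` is the gap)
#' @param family family label
#' @param pseudocount per-residue pseudocount
#' @param background background residue frequency (uniform 1/20 by default)
#' @param gap_open,gap_ext affine gap penalties used when scoring
#' @return object of class `family_profile`
#' @export
build_profile <- function(seeds, family, pseudocount = 0.5,
                          background = 1 / 20,
                          gap_open = 11, gap_ext = 1) {
  if (length(seeds) < 3L) stop("need at least 3 seed sequences")
  lens <- nchar(seeds)
  if (length(unique(lens)) != 1L)
    stop("seeds are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, strsplit(unname(seeds), ""))
  gapfrac <- colMeans(mat == "-")
  keep <- gapfrac <= 0.5
  mat <- mat[, keep, drop = FALSE]
  L <- ncol(mat)
  if (L == 0L) stop("profile error: all columns gapped")
  scores <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  conserved <- character(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    res <- col[col != "-" & col != "X"]
    counts <- table(factor(res, levels = AA20))
    n <- length(res)
    scores[j, ] <- log2((as.numeric(counts) + pseudocount) /
                          (n + 20 * pseudocount) / background)
    conserved[j] <- if (n == nrow(mat) && length(unique(res)) == 1L)
      res[1] else ""
  }
  cpos <- which(conserved == "C")
  triad <- NULL
  for (ci in cpos) {
    hi <- which(conserved == "H" & seq_len(L) > ci)[1]
    if (is.na(hi)) next
    ni <- which(conserved == "N" & seq_len(L) > hi)[1]
    if (is.na(ni)) next
    triad <- c(ci, hi, ni)
    break
  }
  if (is.null(triad))
    stop("profile error: no conserved C..H..N triad columns in family ",
         family)
  structure(list(family = family, scores = scores, triad = triad,
                 gap_open = gap_open, gap_ext = gap_ext,
                 background = background, length = L,
                 consensus = apply(mat, 2, function(col) {
                   r <- col[col != "-"]
                   names(sort(table(r), decreasing = TRUE))[1]
                 })),
            class = "family_profile")
}

#' @export
print.family_profile <- function(x, ...) {
  cat("family_profile '", x$family, "': ", x$length,
      " columns, triad at ", paste(x$triad, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Score a sequence against a family profile
#'
#' Profile-global, sequence-local affine-gap alignment: every profile column
#' must be consumed, the sequence may be entered and left freely.
#'
#' @param profile a family_profile
#' @param seq protein sequence (string)
#' @return list with `score`, `cat_residues` (residues aligned to the triad
#'   columns, `-` for deletions), `start`/`end` (covered sequence interval)
#' @export
score_profile <- function(profile, seq) {
  stopifnot(nchar(seq) > 0)
  enc <- encode_seq(seq)
  r <- .glocal_profile_align(profile$scores, enc, profile$gap_open,
                             profile$gap_ext, as.integer(profile$triad))
  chars <- strsplit(seq, "")[[1]]
  catres <- vapply(r$cat_seq_pos, function(p)
    if (p >= 1) chars[p] else "-", character(1))
  list(score = r$score, cat_residues = catres,
       start = r$start, end = r$end)
}

#' Karlin-Altschul-shaped significance of a profile score
#'
#' `E = K * m * n * 2^(-score)`; monotone decreasing in the score. K is fixed
#' (0.1) and the scale factor lambda is absorbed into the bit-like scores.
#'
#' @param score bit-like alignment score
#' @param seq_len sequence length m (> 0)
#' @param db_size effective database size n (> 0)
#' @param K Karlin-Altschul prefactor
#' @return E-value-like significance in (0, Inf)
#' @export
significance <- function(score, seq_len, db_size, K = 0.1) {
  if (seq_len <= 0 || db_size <= 0)
    stop("seq_len and db_size must be positive")
  stopifnot(is.finite(score))
  K * seq_len * db_size * 2^(-score)
}

#' Classification configuration defaults
#'
#' @param e_cutoff significance acceptance threshold (the survey's 1e-5)
#' @param margin_min minimum best-vs-runner-up score margin; ties below it
#'   are reported "unclassified", never broken arbitrarily
#' @param db_size effective database size for E-values
#' @param long_range inclusive length window for the type-1-long class
#' @param min_coverage minimum fraction of the sequence covered by the hit
#'   before the multidomain class is assigned
#' @return named list
#' @export
classify_config <- function(e_cutoff = 1e-5, margin_min = 5,
                            db_size = 1e6, long_range = c(450, 700),
                            min_coverage = 0.4) {
  list(e_cutoff = e_cutoff, margin_min = margin_min, db_size = db_size,
       long_range = long_range, min_coverage = min_coverage)
}

#' Assign a sequence to its best-scoring family
#'
#' Accepted iff the best hit is significant (E <= cutoff) and beats the
#' runner-up by at least the margin; otherwise the family is
#' `"unclassified"`. `triad_ok` requires Cys and His at the first two triad
#' columns and Asn or Asp at the third (the third triad member varies across
#' families). The length class is `long_type1` for a single-hit sequence in
#' the long window, `multidomain` when a second disjoint significant hit
#' exists or the hit covers less than 40% of the sequence, else `short`.
#'
#' @param id sequence id
#' @param taxon taxon label
#' @param seq protein sequence
#' @param profiles named list of family_profile objects (>= 2)
#' @param i29_profile optional propeptide profile for `has_I29`
#' @param config see [classify_config()]
#' @return one-row data.frame (id, taxon, family, score, runner_up, margin,
#'   evalue, triad_ok, has_I29, length_class)
#' @export
assign_family <- function(id, taxon, seq, profiles, i29_profile = NULL,
                          config = classify_config()) {
  stopifnot(length(profiles) >= 2L)
  hits <- lapply(profiles, score_profile, seq = seq)
  sc <- vapply(hits, `[[`, numeric(1), "score")
  ord <- order(sc, decreasing = TRUE)
  best <- names(profiles)[ord[1]]; runner <- names(profiles)[ord[2]]
  margin <- sc[ord[1]] - sc[ord[2]]
  ev <- significance(sc[ord[1]], nchar(seq), config$db_size)
  accepted <- ev <= config$e_cutoff && margin >= config$margin_min
  besthit <- hits[[ord[1]]]
  triad_ok <- accepted &&
    besthit$cat_residues[1] == "C" && besthit$cat_residues[2] == "H" &&
    besthit$cat_residues[3] %in% c("N", "D")
  has_i29 <- if (is.null(i29_profile)) NA else
    detect_i29(seq, i29_profile, config)
  len <- nchar(seq)
  length_class <- "short"
  if (accepted && besthit$start >= 1) {
    cov <- (besthit$end - besthit$start + 1) / len
    # second disjoint hit: mask the covered interval and rescore
    chars <- strsplit(seq, "")[[1]]
    chars[besthit$start:besthit$end] <- "X"
    second <- score_profile(profiles[[ord[1]]], paste(chars, collapse = ""))
    second_sig <- significance(second$score, len, config$db_size) <=
      config$e_cutoff
    if (second_sig || cov < config$min_coverage) {
      length_class <- "multidomain"
    } else if (len >= config$long_range[1] && len <= config$long_range[2]) {
      length_class <- "long_type1"
    }
  }
  data.frame(id = id, taxon = taxon,
             family = if (accepted) best else "unclassified",
             score = unname(sc[ord[1]]), runner_up = runner,
             margin = unname(margin), evalue = ev,
             triad_ok = triad_ok, has_I29 = has_i29,
             length_class = length_class, stringsAsFactors = FALSE)
}

#' Detect the I29 inhibitory propeptide in the N-terminal region
#'
#' True iff the I29 profile aligns significantly within the first 40% of the
#' sequence. Sequences shorter than 60 residues cannot carry a scorable
#' propeptide and return FALSE.
#'
#' @param seq protein sequence
#' @param i29_profile propeptide profile
#' @param config see [classify_config()]
#' @return logical
#' @export
detect_i29 <- function(seq, i29_profile, config = classify_config()) {
  len <- nchar(seq)
  if (len < 60) return(FALSE)
  window <- substr(seq, 1, floor(0.4 * len))
  if (nchar(window) < 1) return(FALSE)
  hit <- score_profile(i29_profile, window)
  significance(hit$score, nchar(window), config$db_size) <= config$e_cutoff
}

#' Build all packaged family profiles from the shipped seed alignments
#'
#' @param include_i29 also return the propeptide profile (as attribute
#'   `"i29"`)
#' @return named list of family_profile objects
#' @export
load_family_profiles <- function(include_i29 = TRUE) {
  dir <- c1a_extdata("seeds")
  fams <- setdiff(sub("\\.fasta$", "", list.files(dir, pattern = "\\.fasta$")),
                  "i29")
  profs <- lapply(fams, function(f)
    build_profile(read_fasta(file.path(dir, paste0(f, ".fasta"))), f))
  names(profs) <- fams
  if (include_i29)
    attr(profs, "i29") <- build_i29_profile(
      read_fasta(file.path(dir, "i29.fasta")))
  profs
}

# the propeptide has no catalytic triad; bypass triad detection by building
# the PSSM directly
build_i29_profile <- function(seeds, gap_open = 11, gap_ext = 1,
                              pseudocount = 0.5, background = 1 / 20) {
  mat <- do.call(rbind, strsplit(unname(seeds), ""))
  L <- ncol(mat)
  scores <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    res <- mat[, j][mat[, j] != "-"]
    counts <- table(factor(res, levels = AA20))
    scores[j, ] <- log2((as.numeric(counts) + pseudocount) /
                          (length(res) + 20 * pseudocount) / background)
  }
  structure(list(family = "i29", scores = scores, triad = c(1L, 2L, 3L),
                 gap_open = gap_open, gap_ext = gap_ext,
                 background = background, length = L,
                 consensus = apply(mat, 2, function(c0)
                   names(sort(table(c0[c0 != "-"]), decreasing = TRUE))[1])),
            class = "family_profile")
}

#' Classify every sequence of a FASTA file
#'
#' @param seqs named character vector of protein sequences (or FASTA path)
#' @param taxa named character vector mapping sequence id to taxon; ids
#'   missing from it fall back to the id itself
#' @param profiles named list of family profiles (default: packaged)
#' @param config see [classify_config()]
#' @return data.frame of assignments, one row per sequence
#' @export
classify_sequences <- function(seqs, taxa = NULL,
                               profiles = load_family_profiles(),
                               config = classify_config()) {
  if (length(seqs) == 1L && file.exists(seqs)) seqs <- read_fasta(seqs)
  i29 <- attr(profiles, "i29")
  rows <- lapply(names(seqs), function(id) {
    taxon <- if (!is.null(taxa) && id %in% names(taxa)) taxa[[id]] else id
    assign_family(id, taxon, seqs[[id]], profiles, i29, config)
  })
  do.call(rbind, rows)
}

#' Translate a coding DNA sequence (standard code, frame 1)
#'
#' Convenience utility only; six-frame searching is out of scope.
#' @param dna DNA string
#' @return protein string (stop codons as `*`)
#' @export
translate_dna <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAString(dna)))
}
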