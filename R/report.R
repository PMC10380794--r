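# Pipeline orchestration and table rendering.
#
# A single configuration list (or JSON file) drives the stages
# classify -> matrix -> ancrec -> genetree -> hgt -> tables; each run writes
# a manifest (effective config, input hashes, seed, package version,
# per-stage status/timings) so deterministic stages are reproducible
# byte-for-byte.

#' Render an ancestral-state table at named nodes
#'
#' One row per requested node, one column per family. When
#' `resolve_generic` is TRUE the unresolved `C1A_generic` character is
#' reported absent wherever at least one named family is present at that
#' node: the generic character means "a C1A peptidase not yet resolved into
#' the named families", so family-level presence supersedes it (this is how
#' a LUCA/FECA/LECA content table is read).
#'
#' @param asm an `ancmap`
#' @param nodes character vector of node labels
#' @param resolve_generic apply the supersession rule to `C1A_generic`
#' @return a phymat (rows = nodes)
#' @export
render_ancestral_table <- function(asm, nodes, resolve_generic = TRUE) {
  for (nd in nodes) node_id(asm$tree, nd)   # lookup errors early
  tab <- supergroup_states(asm, nodes)
  if (resolve_generic && "C1A_generic" %in% colnames(tab)) {
    named <- setdiff(colnames(tab), "C1A_generic")
    if (length(named)) {
      anynamed <- rowSums(tab[, named, drop = FALSE] == 1L, na.rm = TRUE) > 0
      gen <- tab[, "C1A_generic"]
      gen[anynamed & !is.na(gen) & gen == 1L] <- 0L
      tab[, "C1A_generic"] <- gen
    }
  }
  tab
}

#' Reconstruct the combined LUCA/FECA/LECA content table
#'
#' Merges the packaged eukaryote tables with the prokaryote C1A character,
#' adds the derived generic character for eukaryote leaves, runs Dollo on
#' the combined tree and renders the named nodes.
#'
#' @param nodes nodes to report
#' @return list(table = rendered phymat, asm = the reconstruction)
#' @export
combined_content_table <- function(nodes = c("LECA", "FECA",
                                             "Alphaproteobacteria",
                                             "Cyanobacteria",
                                             "Deltaproteobacteria",
                                             "Archaea", "LUCA")) {
  tree <- reference_tree("combined")
  euk <- merge_matrices(reference_table("table1"), reference_table("table2"))
  euk <- restrict_to_leaves(euk, tree)
  euk <- add_eukaryote_c1a(euk)
  prok <- prokaryote_c1a_matrix()
  m <- merge_matrices(euk, prok)
  asm <- dollo_reconstruct(m, tree)
  list(table = render_ancestral_table(asm, nodes), asm = asm)
}

#' Reconstruct the eukaryote supergroup ancestral-state table
#'
#' Dollo on the merged eukaryote distribution tables over the packaged
#' eukaryote taxonomy, reported at the same nodes as the published
#' ancestral-state table.
#'
#' @param nodes nodes to report
#' @param families families to report (default: the eight ancestral ones)
#' @return list(table = rendered phymat, asm = the reconstruction)
#' @export
supergroup_content_table <- function(nodes = c("Diaphoretickes", "Amorphea",
                                               "CRuMs", "Ancyromonadida",
                                               "Malawimonadida", "Discoba",
                                               "Metamonada", "LECA"),
                                     families = ANCESTRAL_FAMILIES) {
  tree <- reference_tree("eukaryota")
  m <- merge_matrices(reference_table("table1"), reference_table("table2"))
  m <- restrict_to_leaves(m, tree)
  asm <- dollo_reconstruct(m, tree)
  tab <- render_ancestral_table(asm, nodes, resolve_generic = FALSE)
  list(table = phymat(tab[, families, drop = FALSE]), asm = asm)
}

log_line <- function(con, stage, level, msg) {
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, level, msg)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Run the analysis pipeline
#'
#' @param config a list (or path to a JSON file) with elements:
#'   `out_dir` (required), `stages` (subset of classify, matrix, ancrec,
#'   genetree, hgt, tables; empty = manifest-only run), `fasta`, `taxa_map`
#'   (TSV id/taxon), `matrix`, `tree` (paths), `method` ("dollo"/"ml"),
#'   `nodes` (for tables), `clades` (TSV for hgt), `hgt_threshold`,
#'   `bootstrap`, `seed`
#' @return the output directory, invisibly; outputs and `manifest.json`
#'   inside it
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(!is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% character(0)
  seed <- config$seed %||% 1L
  logcon <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(logcon))
  manifest <- list(config = config, seed = seed,
                   version = as.character(utils::packageVersion("c1aprofiler")),
                   inputs = list(), stages = list(), outputs = list())
  for (f in intersect(c("fasta", "taxa_map", "matrix", "tree", "clades"),
                      names(config))) {
    manifest$inputs[[f]] <- list(path = config[[f]],
                                 md5 = unname(tools::md5sum(config[[f]])))
  }
  state <- list()
  run_stage <- function(stage, fun) {
    t0 <- Sys.time()
    log_line(logcon, stage, "INFO", "start")
    res <- tryCatch(fun(), error = function(e) {
      log_line(logcon, stage, "ERROR", conditionMessage(e))
      stop("pipeline halted at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[stage]] <<- list(
      status = "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    log_line(logcon, stage, "INFO", "done")
    res
  }
  emit <- function(name, path) manifest$outputs[[name]] <<-
    list(path = path, md5 = unname(tools::md5sum(path)))

  if ("classify" %in% stages) {
    state$assignments <- run_stage("classify", function() {
      seqs <- read_fasta(config$fasta)
      taxa <- if (!is.null(config$taxa_map)) {
        tm <- utils::read.table(config$taxa_map, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        setNames(tm$taxon, tm$id)
      } else NULL
      a <- classify_sequences(seqs, taxa)
      p <- file.path(out, "assignments.tsv")
      utils::write.table(a, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("assignments", p)
      a
    })
  }
  if ("matrix" %in% stages) {
    state$matrix <- run_stage("matrix", function() {
      a <- state$assignments
      if (is.null(a)) stop("matrix stage requires classify output")
      surveyed <- unique(a$taxon)
      fams <- intersect(FAMILY_VOCABULARY, unique(a$family))
      m <- matrix_from_assignments(a, surveyed,
                                   families = union(ANCESTRAL_FAMILIES, fams))
      p <- file.path(out, "content.tsv")
      write_matrix(m, p)
      emit("content", p)
      m
    })
  }
  if ("ancrec" %in% stages) {
    state$asm <- run_stage("ancrec", function() {
      m <- if (!is.null(state$matrix)) state$matrix
           else read_matrix(config$matrix)
      tree <- read_newick_file(config$tree)
      m <- restrict_to_leaves(m, tree)
      asm <- if (identical(config$method %||% "dollo", "ml"))
        ml_reconstruct(m, tree) else dollo_reconstruct(m, tree)
      sp <- file.path(out, "ancestral_states.tsv")
      st <- asm$states
      rownames(st) <- vapply(seq_len(nrow(st)), function(v)
        node_name(asm$tree, v), character(1))
      utils::write.table(st, sp, sep = "\t", quote = FALSE)
      ep <- file.path(out, "events.tsv")
      utils::write.table(asm$events, ep, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("ancestral_states", sp); emit("events", ep)
      asm
    })
  }
  if ("genetree" %in% stages) {
    state$genetree <- run_stage("genetree", function() {
      aln <- read_fasta(config$fasta)
      boot <- nj_bootstrap(aln, n_reps = config$bootstrap %||% 1000,
                           seed = seed)
      p <- file.path(out, "genetree.nwk")
      writeLines(bootstrap_newick(boot), p)
      emit("genetree", p)
      boot
    })
  }
  if ("hgt" %in% stages) {
    state$hgt <- run_stage("hgt", function() {
      seqs <- read_fasta(config$fasta)
      clades <- read_clades(config$clades)
      lvl <- config$hgt_level %||% "domain"
      calls <- flag_calls(hgt_scores(seqs, clades, level = lvl),
                          config$hgt_threshold %||% 0.10)
      inc <- attr(calls, "incomparable")
      if (length(inc))
        log_line(logcon, "hgt", "WARN",
                 paste("incomparable sequences:", paste(inc, collapse = ",")))
      tree <- if (!is.null(state$genetree)) state$genetree$tree
              else if (!is.null(config$tree)) read_newick_file(config$tree)
              else neighbor_joining(alignment_distances(seqs))
      cl <- cluster_events(calls, tree, clades, level = lvl)
      cp <- file.path(out, "hgt_calls.tsv")
      utils::write.table(cl$calls, cp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      ep <- file.path(out, "hgt_events.tsv")
      utils::write.table(cl$events, ep, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("hgt_calls", cp); emit("hgt_events", ep)
      cl
    })
  }
  if ("tables" %in% stages) {
    run_stage("tables", function() {
      asm <- state$asm
      if (is.null(asm)) {
        m <- read_matrix(config$matrix)
        tree <- read_newick_file(config$tree)
        asm <- dollo_reconstruct(restrict_to_leaves(m, tree), tree)
      }
      nodes <- config$nodes %||% named_ancestors(asm$tree)
      tab <- render_ancestral_table(asm, nodes)
      p <- file.path(out, "ancestral_table.tsv")
      write_matrix(tab, p)
      emit("ancestral_table", p)
      tab
    })
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
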