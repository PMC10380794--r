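# Synthetic-data generation: binary gene-family content evolving on a rooted
# species tree under a gain/loss chain with optional cross-clade transfers,
# and protein sequences evolving by equal-exchangeability (Poisson)
# substitution along the same tree. Every stage of the pipeline gets a
# generator whose truth is recorded, so classification, reconstruction,
# gene-tree and HGT tests all have an exact oracle.
#
# All randomness is funnelled through with_seed(); a configuration plus a
# seed fully determines every output byte.

ALPHA17 <- setdiff(AA20, c("C", "H", "N"))
I29_FAMILIES <- c("cathL", "cathH", "cathF", "p26_29")

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Evolve a protein sequence by Poisson substitution
#'
#' Equal-exchangeability 20-state chain: a site retains its residue with
#' probability `1/20 + (19/20) exp(-(20/19) d)` over divergence `d`
#' (expected substitutions/site), otherwise it takes a uniform different
#' residue. Positions in `fixed` (the catalytic triad) never change.
#'
#' @param seq protein string
#' @param d expected substitutions per site
#' @param fixed integer positions exempt from substitution
#' @return evolved protein string
#' @export
evolve_seq <- function(seq, d, fixed = integer(0)) {
  chars <- strsplit(seq, "")[[1]]
  q <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * d)
  hit <- which(stats::runif(length(chars)) > q)
  hit <- setdiff(hit, fixed)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# ---- family archetypes -----------------------------------------------------

FAMILY_GEOMETRY <- list(
  cathB       = list(len = 254, c1_start = 1),
  cathC       = list(len = 233, c1_start = 1),
  cathX       = list(len = 242, c1_start = 1),
  cathL       = list(len = 221, c1_start = 1),
  cathF       = list(len = 233, c1_start = 1),
  cathH       = list(len = 227, c1_start = 1),
  p26_29      = list(len = 360, c1_start = 131),  # LolA/EPDR fused N-terminal
  type1_long  = list(len = NA,  c1_start = 261),  # length drawn in [500, 650]
  cathO       = list(len = 230, c1_start = 1),
  vWFA_C1     = list(len = 430, c1_start = 181)   # vWFA fused N-terminal
)

#' Deterministic family archetype sequences
#'
#' One ancestral sequence per family with the catalytic Cys/His/Asn placed
#' at papain-like relative positions inside the C1 domain. Non-catalytic
#' archetype positions avoid C/H/N so the conserved-triad auto-detection in
#' profile building is identifiable by construction; substitutions during
#' evolution still introduce those letters freely.
#'
#' @return named list with `seq` (string) and `triad` (positions) per family,
#'   plus an `i29` propeptide element (no triad)
#' @export
family_archetypes <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    out <- with_seed(73001L, {
      res <- list()
      for (k in seq_along(FAMILY_GEOMETRY)) {
        fam <- names(FAMILY_GEOMETRY)[k]
        g <- FAMILY_GEOMETRY[[fam]]
        len <- if (is.na(g$len)) sample(500:650, 1) else g$len
        domlen <- len - g$c1_start + 1
        s <- strsplit(random_seq(len, ALPHA17), "")[[1]]
        triad <- c(g$c1_start + 24,
                   g$c1_start + round(0.62 * domlen),
                   g$c1_start + round(0.62 * domlen) + 40)
        s[triad] <- c("C", "H", "N")
        res[[fam]] <- list(seq = paste(s, collapse = ""), triad = triad)
      }
      res$i29 <- list(seq = random_seq(62, ALPHA17), triad = integer(0))
      res
    })
    cache <<- out
    out
  }
})

# ---- random species trees --------------------------------------------------

#' Simulate an ultrametric Yule species tree
#'
#' Forward birth process; total depth is rescaled to `depth`.
#'
#' @param n number of leaves
#' @param depth root-to-tip depth after rescaling
#' @param prefix leaf label prefix
#' @return a taxtree
#' @export
yule_tree <- function(n, depth = 1, prefix = "t") {
  stopifnot(n >= 2)
  label <- c(""); parent <- c(NA_integer_); btime <- c(0)
  # pending lineages: (parent node id, start time)
  pend_par <- c(1L, 1L); pend_t0 <- c(0, 0)
  t <- 0; k <- 2L
  while (k < n) {
    t <- t + stats::rexp(1, rate = k)
    i <- sample.int(k, 1)
    label <- c(label, ""); parent <- c(parent, pend_par[i])
    btime <- c(btime, t)
    newid <- length(label)
    pend_par <- c(pend_par[-i], newid, newid)
    pend_t0 <- c(pend_t0[-i], t, t)
    k <- k + 1L
  }
  T_end <- t + stats::rexp(1, rate = k)
  nint <- length(label)
  for (i in seq_len(k)) {
    label <- c(label, paste0(prefix, i))
    parent <- c(parent, pend_par[i])
    btime <- c(btime, T_end)
  }
  brlen <- numeric(length(label))
  for (v in seq_along(label))
    brlen[v] <- if (is.na(parent[v])) NA_real_ else btime[v] - btime[parent[v]]
  sc <- depth / T_end
  new_taxtree(label, parent, ifelse(is.na(brlen), NA, brlen * sc))
}

# ---- configuration ---------------------------------------------------------

#' Simulation configuration
#'
#' Defaults describe the regime used throughout the tests: a 20-leaf Yule
#' tree of unit depth, loss-dominated content evolution (gain 0.05, loss 0.3
#' per unit branch), sequences at 0.3 substitutions/site root-to-tip, and
#' zymogens (I29 propeptide) emitted for the cathepsin-L-like families.
#'
#' @param seed mandatory integer seed
#' @param tree a taxtree, or NULL to draw a Yule tree
#' @param n_taxa,depth Yule tree size and depth when `tree` is NULL
#' @param gain,loss content gain/loss rates per unit branch length
#' @param root_state `"present"`, `"stationary"`, or a node label at which
#'   every family is gained
#' @param families character vector of family labels to simulate
#' @param subst_rate substitutions/site per unit branch length
#' @param zymogen emit I29 propeptide for the I29-bearing families
#' @param transfers list of transfer events, each
#'   `list(family=, donor=, recipient=, divergence=)` (donor and recipient
#'   are leaf labels; divergence is post-transfer substitutions/site)
#' @return SimConfig list
#' @export
sim_config <- function(seed, tree = NULL, n_taxa = 20, depth = 1,
                       gain = 0.05, loss = 0.3, root_state = "present",
                       families = ANCESTRAL_FAMILIES, subst_rate = 0.3,
                       zymogen = TRUE, transfers = list()) {
  stopifnot(!missing(seed), gain >= 0, loss >= 0, subst_rate >= 0)
  list(seed = as.integer(seed), tree = tree, n_taxa = n_taxa, depth = depth,
       gain = gain, loss = loss, root_state = root_state,
       families = families, subst_rate = subst_rate, zymogen = zymogen,
       transfers = transfers)
}

# ---- content ---------------------------------------------------------------

#' Simulate binary family content down a species tree
#'
#' Each family evolves independently as a two-state chain with the configured
#' rates. The full truth (state at every node, every flip event on every
#' branch) is recorded.
#'
#' @param config see [sim_config()]
#' @return list with `tree`, `matrix` (leaf phymat), `states` (node x family
#'   truth), `events` (data.frame parent/child/family/type)
#' @export
simulate_content <- function(config) {
  with_seed(config$seed, {
    tree <- if (is.null(config$tree))
      yule_tree(config$n_taxa, config$depth) else config$tree
    bl <- ifelse(is.na(tree$brlen), 1, tree$brlen)
    model <- gainloss_model(max(config$gain, 1e-12),
                            max(config$loss, 1e-12))
    n <- length(tree$label)
    fams <- config$families
    states <- matrix(0L, n, length(fams), dimnames = list(NULL, fams))
    ev <- list()
    gain_at <- if (!config$root_state %in% c("present", "stationary"))
      node_id(tree, config$root_state) else NA_integer_
    for (f in fams) {
      st <- integer(n)
      for (v in rev(postorder(tree))) {       # preorder
        p <- tree$parent[v]
        if (is.na(p)) {
          st[v] <- if (config$root_state == "present") 1L
                   else if (config$root_state == "stationary")
                     stats::rbinom(1, 1, model$prior)
                   else if (!is.na(gain_at) && v == gain_at) 1L else 0L
          next
        }
        if (!is.na(gain_at) && v == gain_at) { st[v] <- 1L }
        else {
          P <- transition_matrix(model, bl[v])
          st[v] <- stats::rbinom(1, 1, P[st[p] + 1L, 2])
        }
        if (st[v] != st[p])
          ev[[length(ev) + 1L]] <- data.frame(
            parent = node_name(tree, p), child = node_name(tree, v),
            family = f, type = if (st[v] == 1L) "gain" else "loss",
            stringsAsFactors = FALSE)
      }
      states[, f] <- st
    }
    for (tr in config$transfers) {
      r <- node_id(tree, tr$recipient)
      states[r, tr$family] <- 1L
    }
    lv <- leaf_ids(tree)
    m <- phymat(matrix(states[lv, , drop = FALSE], length(lv),
                       dimnames = list(tree$label[lv], fams)))
    list(tree = tree, matrix = m, states = states,
         events = if (length(ev)) do.call(rbind, ev)
                  else data.frame(parent = character(0), child = character(0),
                                  family = character(0), type = character(0)))
  })
}

# ---- sequences -------------------------------------------------------------

#' Simulate protein sequences for simulated content
#'
#' One archetype per family sits at the root; sequences evolve by Poisson
#' substitution along the species tree (catalytic triad positions held
#' fixed) and are emitted for every (leaf, family) cell that is present.
#' I29-bearing families are emitted as zymogens (propeptide + mature) when
#' `config$zymogen` is TRUE. Transfers copy the donor leaf's gene and evolve
#' it by the configured residual divergence before placing it in the
#' recipient.
#'
#' @param config see [sim_config()]
#' @param content result of [simulate_content()]
#' @return list with `seqs` (named character vector, ids `taxon|family`) and
#'   `truth` (data.frame id/taxon/family/has_i29/origin)
#' @export
simulate_sequences <- function(config, content) {
  with_seed(config$seed + 1000L, {
    tree <- content$tree
    bl <- ifelse(is.na(tree$brlen), 1, tree$brlen)
    arch <- family_archetypes()
    lv <- leaf_ids(tree)
    seqs <- character(0); truth <- list()
    leafseq <- list()
    for (f in config$families) {
      a <- arch[[f]]
      zym <- config$zymogen && f %in% I29_FAMILIES
      rootseq <- if (zym) paste0(arch$i29$seq, a$seq) else a$seq
      fixed <- if (zym) a$triad + nchar(arch$i29$seq) else a$triad
      node_seq <- character(length(tree$label))
      for (v in rev(postorder(tree))) {     # preorder
        p <- tree$parent[v]
        node_seq[v] <- if (is.na(p)) rootseq
                       else evolve_seq(node_seq[p],
                                       config$subst_rate * bl[v], fixed)
      }
      leafseq[[f]] <- setNames(node_seq[lv], tree$label[lv])
      for (v in lv) {
        taxon <- tree$label[v]
        if (content$matrix[taxon, f] != 1L) next
        id <- paste0(taxon, "|", f)
        seqs[id] <- node_seq[v]
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, taxon = taxon, family = f, has_i29 = zym,
          origin = "vertical", stringsAsFactors = FALSE)
      }
    }
    for (tr in config$transfers) {
      id <- paste0(tr$recipient, "|", tr$family)
      donorseq <- leafseq[[tr$family]][[tr$donor]]
      a <- arch[[tr$family]]
      zym <- config$zymogen && tr$family %in% I29_FAMILIES
      fixed <- if (zym) a$triad + nchar(arch$i29$seq) else a$triad
      seqs[id] <- evolve_seq(donorseq, tr$divergence, fixed)
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, taxon = tr$recipient, family = tr$family, has_i29 = zym,
        origin = "hgt", stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[!duplicated(truth$id, fromLast = TRUE), , drop = FALSE]
    list(seqs = seqs, truth = truth)
  })
}

# ---- HGT regimes -----------------------------------------------------------

#' Simulate one HGT benchmark replicate
#'
#' A recipient clade of `n_native` species evolving vertically from a
#' recipient ancestor, a deeply diverged donor pool, and `n_transfer` recent
#' transfers each from its own independent donor lineage (independent events,
#' matching how transfers are counted). Donor-recipient clade divergence is
#' `2 * deep` substitutions/site.
#'
#' @param seed integer seed
#' @param n_native,n_transfer,n_donor_refs counts
#' @param deep divergence from the shared gene ancestor to each clade root
#' @param native_depth within-recipient-clade divergence
#' @param donor_spread donor-lineage divergence below the donor ancestor
#' @param post residual divergence after the transfer
#' @param len gene length
#' @return list(seqs, clades, truth) — `clades` has columns
#'   taxon/clade/domain; `truth$origin` is "vertical" or "hgt"
#' @export
sim_hgt_replicate <- function(seed, n_native = 12, n_transfer = 3,
                              n_donor_refs = 3, deep = 0.6,
                              native_depth = 0.35, donor_spread = 0.5,
                              post = 0.05, len = 240) {
  with_seed(seed, {
    root <- random_seq(len)
    rec_anc <- evolve_seq(root, deep)
    don_anc <- evolve_seq(root, deep)
    seqs <- character(0); rows <- list()
    add <- function(taxon, seq, clade, domain, origin) {
      seqs[taxon] <<- seq
      rows[[length(rows) + 1L]] <<- data.frame(
        taxon = taxon, clade = clade, domain = domain, origin = origin,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_native))
      add(paste0("Native_sp", i), evolve_seq(rec_anc, native_depth),
          "Recipient", "Eukaryota", "vertical")
    for (i in seq_len(n_transfer)) {
      d <- evolve_seq(don_anc, donor_spread)
      add(paste0("DonorRef_t", i), evolve_seq(d, post),
          paste0("DonorLineage", i), "Bacteria", "vertical")
      add(paste0("Transfer_sp", i), evolve_seq(d, post),
          "Recipient", "Eukaryota", "hgt")
    }
    for (i in seq_len(n_donor_refs))
      add(paste0("DonorRef_x", i),
          evolve_seq(evolve_seq(don_anc, donor_spread), post),
          paste0("DonorOther", i), "Bacteria", "vertical")
    clades <- do.call(rbind, rows)
    list(seqs = seqs, clades = clades[, c("taxon", "clade", "domain")],
         truth = clades[, c("taxon", "origin")])
  })
}

#' Synthetic archaeal C1A origin mixture ("archaea_default")
#'
#' `n` archaeal species each carrying one short C1A peptidase; a configured
#' fraction of them horizontally acquired, each from its own independent
#' bacterial donor lineage whose close reference is in the database. The
#' transferred fraction is part of the configuration — it is data the
#' detector must recover, not something it is told.
#'
#' @param seed integer seed
#' @param n number of archaeal sequences
#' @param transferred configured transferred fraction (default 0.56)
#' @param len gene length
#' @return list(seqs, clades, truth, config)
#' @export
sim_archaea_default <- function(seed, n = 200, transferred = 0.56,
                                len = 230) {
  n_hgt <- round(n * transferred)
  n_nat <- n - n_hgt
  with_seed(seed, {
    root <- random_seq(len)
    arch_anc <- evolve_seq(root, 0.6)
    bact_anc <- evolve_seq(root, 0.6)
    seqs <- character(0); rows <- list()
    add <- function(taxon, seq, clade, domain, origin) {
      seqs[taxon] <<- seq
      rows[[length(rows) + 1L]] <<- data.frame(
        taxon = taxon, clade = clade, domain = domain, origin = origin,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_nat))
      add(paste0("Archaeon_nat", i), evolve_seq(arch_anc, 0.35),
          "Archaea", "Archaea", "vertical")
    for (i in seq_len(n_hgt)) {
      d <- evolve_seq(bact_anc, 0.5)
      add(paste0("Bacterium_ref", i), evolve_seq(d, 0.05),
          paste0("BactLineage", i), "Bacteria", "vertical")
      add(paste0("Archaeon_hgt", i), evolve_seq(d, 0.05),
          "Archaea", "Archaea", "hgt")
    }
    clades <- do.call(rbind, rows)
    list(seqs = seqs, clades = clades[, c("taxon", "clade", "domain")],
         truth = clades[, c("taxon", "origin")],
         config = list(n = n, transferred = transferred))
  })
}

# ---- packaged synthetic fixtures -------------------------------------------

# seed alignments for the family profiles: archetype + 5 copies at 0.15
# substitutions/site, catalytic triad held fixed
make_seed_alignments <- function(dir) {
  arch <- family_archetypes()
  paths <- character(0)
  for (k in seq_along(arch)) {
    fam <- names(arch)[k]
    a <- arch[[k]]
    seeds <- with_seed(81000L + k, {
      s <- c(a$seq, vapply(1:5, function(i)
        evolve_seq(a$seq, 0.15, a$triad), character(1)))
      setNames(s, paste0(fam, "_seed", 1:6))
    })
    p <- file.path(dir, paste0(fam, ".fasta"))
    write_fasta(seeds, p)
    paths <- c(paths, p)
  }
  paths
}

FIVE_CASES <- list(
  list(donor = "Cyanobacteria",
       recipients = c(Rotifer_sp1 = "Rotifera", Rotifer_sp2 = "Rotifera")),
  list(donor = "Bacteroidetes",
       recipients = c(Ascomycota_c2_sp1 = "Ascomycota")),
  list(donor = "Planctomycetota",
       recipients = c(GreenAlga_sp1 = "Chlorophyta",
                      GreenAlga_sp2 = "Chlorophyta",
                      Chytrid_sp1 = "Chytridiomycota",
                      Chytrid_sp2 = "Chytridiomycota")),
  list(donor = "Streptomycetes",
       recipients = c(Ascomycota_c4_sp1 = "Ascomycota",
                      Ascomycota_c4_sp2 = "Ascomycota")),
  list(donor = "Gammaproteobacteria",
       recipients = c(Dinoflagellate_sp1 = "Dinoflagellata",
                      Dinoflagellate_sp2 = "Dinoflagellata"))
)

# synthetic encoding of the five independent bacteria->eukaryote transfer
# cases: per case one bacterial donor lineage with two close references and
# 1-4 recipient species whose copies diverged independently after the
# transfer (donor lineages evolve slowly relative to post-transfer copies,
# so the conservation anomaly stays visible even between co-recipients)
make_five_hgt_cases <- function(dir) {
  natives <- c(Metazoa_sp1 = "Metazoa", Metazoa_sp2 = "Metazoa",
               Fungus_sp1 = "Ascomycota", Plant_sp1 = "Chloroplastida",
               Stramenopile_sp1 = "Stramenopiles", Discoba_sp1 = "Discoba",
               Amoebozoa_sp1 = "Amoebozoa", Haptophyte_sp1 = "Haptophyta")
  out <- with_seed(9001L, {
    len <- 240
    root <- random_seq(len)
    euk_anc <- evolve_seq(root, 1.0)
    seqs <- character(0); rows <- list()
    add <- function(taxon, seq, clade, domain, origin) {
      seqs[taxon] <<- seq
      rows[[length(rows) + 1L]] <<- data.frame(
        taxon = taxon, clade = clade, domain = domain, origin = origin,
        stringsAsFactors = FALSE)
    }
    for (t in names(natives))
      add(t, evolve_seq(euk_anc, 0.35), natives[[t]], "Eukaryota", "vertical")
    for (case in FIVE_CASES) {
      b <- evolve_seq(root, 0.4)
      for (i in 1:2)
        add(paste0(case$donor, "_sp", i), evolve_seq(b, 0.05),
            case$donor, "Bacteria", "vertical")
      for (t in names(case$recipients))
        add(t, evolve_seq(b, 0.35), case$recipients[[t]], "Eukaryota", "hgt")
    }
    for (i in 1:2)
      add(paste0("OtherBacterium_sp", i),
          evolve_seq(evolve_seq(root, 0.4), 0.05),
          "OtherBacteria", "Bacteria", "vertical")
    list(seqs = seqs, rows = do.call(rbind, rows))
  })
  tree <- neighbor_joining(alignment_distances(out$seqs))
  fpath <- file.path(dir, "five_cases.fasta")
  cpath <- file.path(dir, "five_cases_clades.tsv")
  tpath <- file.path(dir, "five_cases_genetree.nwk")
  write_fasta(out$seqs, fpath)
  utils::write.table(out$rows[, c("taxon", "clade", "domain")], cpath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(tree, tpath)
  c(fpath, cpath, tpath)
}
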