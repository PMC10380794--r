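# Conservation-anomaly HGT detection, event clustering, origin fractions.

test_that("vertical genes score negative, transfers score high (seed 23)", {
  sim <- sim_hgt_replicate(seed = 23)
  calls <- hgt_scores(sim$seqs, sim$clades, level = "domain",
                      queries = sim$clades$taxon[sim$clades$domain ==
                                                   "Eukaryota"])
  truth <- setNames(sim$truth$origin, sim$truth$taxon)
  expect_true(all(calls$score[truth[calls$taxon] == "vertical"] < 0))
  expect_true(all(calls$score[truth[calls$taxon] == "hgt"] > 0.1))
})

test_that("a sequence identical to an in-group member scores <= 0", {
  seqs <- c(q = strrep("ACDEFGHIKL", 20),
            twin = strrep("ACDEFGHIKL", 20),
            far = random_protein(200))
  clades <- data.frame(taxon = c("q", "twin", "far"),
                       clade = c("CladeA", "CladeA", "CladeB"),
                       domain = c("Euk", "Euk", "Bact"))
  calls <- hgt_scores(seqs, clades, queries = "q")
  expect_lte(calls$score, 0)
  expect_equal(calls$in_identity, 1)
})

test_that("queries without in-group comparators are reported incomparable", {
  seqs <- c(q = random_protein(100), other = random_protein(100))
  clades <- data.frame(taxon = c("q", "other"),
                       clade = c("A", "B"), domain = c("A", "B"))
  calls <- hgt_scores(seqs, clades, queries = "q")
  expect_true(is.na(calls$score))
  expect_equal(attr(calls, "incomparable"), "q")
})

test_that("flagging is a >= threshold rule", {
  calls <- data.frame(taxon = c("a", "b", "c"),
                      recipient = "E", clade = "E",
                      in_identity = 0.5, out_identity = 0.5,
                      score = c(0.25, 0.10, -0.3),
                      flagged = NA, donor = NA_character_,
                      event = NA_integer_)
  fl <- flag_calls(calls, threshold = 0.10)
  expect_equal(fl$flagged, c(TRUE, TRUE, FALSE))
})

test_that("clustering merges co-transfers and separates distinct events", {
  # hand-built gene tree: two donors, recipients in two clades
  tree <- read_newick(paste0(
    "(((r1:0.1,r2:0.1):0.1,(d1a:0.05,d1b:0.05):0.1):0.5,",
    "((s1:0.1,(d2a:0.05,d2b:0.05):0.1):0.1,n1:0.8):0.5,n2:0.9)root;"))
  clades <- data.frame(
    taxon = c("r1", "r2", "s1", "n1", "n2", "d1a", "d1b", "d2a", "d2b"),
    clade = c("Rotifera", "Rotifera", "Fungi", "Metazoa", "Plants",
              "Cyanobacteria", "Cyanobacteria", "Streptomycetes",
              "Streptomycetes"),
    domain = c(rep("Eukaryota", 5), rep("Bacteria", 4)))
  calls <- data.frame(taxon = c("r1", "r2", "s1"),
                      recipient = "Eukaryota",
                      clade = c("Rotifera", "Rotifera", "Fungi"),
                      in_identity = 0.4, out_identity = 0.9, score = 0.5,
                      flagged = TRUE, donor = NA_character_,
                      event = NA_integer_)
  cl <- cluster_events(calls, tree, clades)
  expect_equal(nrow(cl$events), 2L)
  expect_setequal(cl$events$donor, c("Cyanobacteria", "Streptomycetes"))
  # same donor but different recipient clades -> 2 events at clade rank
  calls2 <- calls
  calls2$clade[3] <- "Fungi"
  clades2 <- clades; clades2$clade[6:9] <- "Cyanobacteria"
  cl2 <- cluster_events(calls2, tree, clades2, recipient_col = "clade")
  expect_equal(nrow(cl2$events), 2L)
  # one cluster when all calls share donor, recipient and a clean clade
  cl3 <- cluster_events(calls[1:2, ], tree, clades)
  expect_equal(nrow(cl3$events), 1L)
  expect_equal(cl3$events$n_calls, 2L)
  # calls missing from the tree are a placement error
  calls4 <- calls; calls4$taxon[1] <- "ghost"
  expect_error(cluster_events(calls4, tree, clades), "placement error")
})

test_that("the packaged five-case fixture yields exactly five events", {
  res <- five_hgt_cases_analysis()
  expect_equal(nrow(res$events), 5L)
  expect_setequal(res$events$donor,
                  c("Cyanobacteria", "Bacteroidetes", "Planctomycetota",
                    "Streptomycetes", "Gammaproteobacteria"))
  expect_true(all(res$events$recipient == "Eukaryota"))
  # the cyanobacteria -> rotifer case covers both rotifer species
  rot <- res$calls[res$calls$taxon %in% c("Rotifer_sp1", "Rotifer_sp2"), ]
  expect_true(all(rot$flagged))
  expect_true(all(rot$score > 0.1))
  expect_equal(length(unique(rot$event)), 1L)
})

test_that("clustering is coarser at the scoring level than at clade rank", {
  seqs <- read_fasta(c1a_extdata("hgt", "five_cases.fasta"))
  clades <- read_clades(c1a_extdata("hgt", "five_cases_clades.tsv"))
  tree <- read_newick_file(c1a_extdata("hgt", "five_cases_genetree.nwk"))
  euk <- clades$taxon[clades$domain == "Eukaryota"]
  calls <- flag_calls(hgt_scores(seqs, clades, queries = euk))
  coarse <- cluster_events(calls, tree, clades)
  fine <- cluster_events(calls, tree, clades, recipient_col = "clade")
  expect_lte(nrow(coarse$events), nrow(fine$events))
  expect_lte(nrow(fine$events), sum(calls$flagged, na.rm = TRUE))
})

test_that("origin fractions sum to one and match arithmetic", {
  calls <- data.frame(taxon = letters[1:10], recipient = "A", clade = "A",
                      in_identity = 0.5, out_identity = 0.5,
                      score = c(rep(0.5, 4), rep(-0.5, 6)),
                      flagged = c(rep(TRUE, 4), rep(FALSE, 6)),
                      donor = NA_character_, event = NA_integer_)
  fr <- origin_fractions(calls)
  expect_equal(as.numeric(fr), c(0.6, 0.4))
  expect_equal(sum(fr), 1)
  calls$flagged <- FALSE
  expect_equal(as.numeric(origin_fractions(calls)), c(1, 0))
  expect_error(origin_fractions(calls[0, ]), "empty summary")
})

test_that("detector has >= 0.9 precision and recall (20 replicates)", {
  tp <- fp <- fn <- 0
  for (r in 1:20) {
    sim <- sim_hgt_replicate(seed = 31 + r)
    euk <- sim$clades$taxon[sim$clades$domain == "Eukaryota"]
    calls <- flag_calls(hgt_scores(sim$seqs, sim$clades, queries = euk))
    truth <- setNames(sim$truth$origin, sim$truth$taxon)[calls$taxon]
    tp <- tp + sum(calls$flagged & truth == "hgt")
    fp <- fp + sum(calls$flagged & truth == "vertical")
    fn <- fn + sum(!calls$flagged & truth == "hgt")
  }
  expect_gte(tp / (tp + fn), 0.9)   # recall
  expect_gte(tp / (tp + fp), 0.9)   # precision
})
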