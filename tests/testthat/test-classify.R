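# Profile construction and sequence classification.

profiles <- load_family_profiles()
i29_profile <- attr(profiles, "i29")

test_that("profile scores follow the pseudocount log-odds formula", {
  seeds <- setNames(rep("ACDEFGHIKN", 4), paste0("s", 1:4))
  prof <- build_profile(seeds, "toy", pseudocount = 0.5, background = 0.05)
  # single-cell formula: count 4 of 4, pseudocount 0.5
  expect_equal(unname(prof$scores[1, "A"]), log2((4.5 / 14) / 0.05))
  # consensus dominance: in every column the consensus letter outscores all
  cons <- strsplit("ACDEFGHIKN", "")[[1]]
  for (j in seq_along(cons)) {
    others <- setdiff(colnames(prof$scores), cons[j])
    expect_true(all(prof$scores[j, cons[j]] > prof$scores[j, others]))
  }
  expect_equal(prof$triad, c(2L, 7L, 10L))
})

test_that("profile building enforces its preconditions", {
  expect_error(build_profile(c(a = "ACD", b = "ACD"), "x"), "at least 3")
  expect_error(build_profile(c(a = "ACD", b = "ACDE", d = "ACD"), "x"),
               "not aligned")
  # no triad columns
  expect_error(build_profile(setNames(rep("AAAA", 3), letters[1:3]), "x"),
               "triad")
})

test_that("packaged seed alignments yield triad-anchored profiles", {
  arch <- family_archetypes()
  for (f in names(profiles)) {
    p <- profiles[[f]]
    expect_length(p$triad, 3L)
    expect_equal(p$consensus[p$triad], c("C", "H", "N"), info = f)
    expect_equal(unname(p$triad), unname(arch[[f]]$triad), info = f)
  }
})

test_that("scoring a consensus sequence attains the per-column maximum", {
  p <- profiles$cathL
  consensus <- paste(p$consensus, collapse = "")
  r <- score_profile(p, consensus)
  expect_equal(r$score, sum(apply(p$scores, 1, max)))
  expect_equal(r$cat_residues, c("C", "H", "N"))
  expect_equal(r$start, 1L)
  expect_equal(r$end, nchar(consensus))
})

test_that("shuffling destroys the profile signal (100 shuffles)", {
  withr::local_seed(7)
  p <- profiles$cathB
  consensus <- paste(p$consensus, collapse = "")
  ref <- score_profile(p, consensus)$score
  chars <- strsplit(consensus, "")[[1]]
  for (i in 1:100) {
    shuf <- paste(sample(chars), collapse = "")
    expect_lt(score_profile(p, shuf)$score, ref)
  }
})

test_that("an all-X sequence cannot score positively", {
  p <- profiles$cathB
  expect_lte(score_profile(p, strrep("X", 300))$score, 0)
})

test_that("significance has the Karlin-Altschul form", {
  e10 <- significance(10, 300, 1e6)
  e20 <- significance(20, 300, 1e6)
  expect_equal(e10 / e20, 2^10)
  expect_equal(significance(10, 300, 2e6), 2 * e10)
  # closed-form threshold score at E = 1e-5
  thr <- log2(0.1 * 300 * 1e6 / 1e-5)
  expect_lt(significance(thr + 1e-9, 300, 1e6), 1e-5)
  expect_gt(significance(thr - 1e-9, 300, 1e6), 1e-5)
  expect_error(significance(10, 0, 1e6), "positive")
  expect_error(significance(10, 300, -1), "positive")
})

test_that("every seed sequence assigns to its own family with margin", {
  dir <- c1a_extdata("seeds")
  for (f in names(profiles)) {
    seeds <- read_fasta(file.path(dir, paste0(f, ".fasta")))
    for (id in names(seeds)[c(1, 4)]) {   # archetype + one mutated copy
      a <- assign_family(id, "x", seeds[[id]], profiles, i29_profile)
      expect_equal(a$family, f, info = id)
      expect_gt(a$margin, 0)
      expect_true(a$triad_ok)
    }
  }
})

test_that("simulated sequences classify to their true families", {
  cfg <- sim_config(seed = 3, n_taxa = 6,
                    families = c("cathB", "cathL", "p26_29"), loss = 0.2)
  ct <- simulate_content(cfg)
  sq <- simulate_sequences(cfg, ct)
  res <- classify_sequences(sq$seqs,
                            taxa = setNames(sq$truth$taxon, sq$truth$id),
                            profiles = profiles)
  expect_equal(res$family, sq$truth$family)
  expect_true(all(res$triad_ok))
  expect_equal(res$has_I29, sq$truth$has_i29)
})

test_that("type-1-long sequences get the long_type1 length class", {
  arch <- family_archetypes()
  len <- nchar(arch$type1_long$seq)
  expect_gte(len, 500); expect_lte(len, 650)
  a <- assign_family("q", "x", arch$type1_long$seq, profiles, i29_profile)
  expect_equal(a$family, "type1_long")
  expect_equal(a$length_class, "long_type1")
})

test_that("random sequences stay unclassified (50 replicates)", {
  withr::local_seed(11)
  for (i in 1:50) {
    seq <- random_protein(sample(150:400, 1))
    a <- assign_family(paste0("rnd", i), "x", seq, profiles)
    expect_equal(a$family, "unclassified")
    expect_gt(a$evalue, 1e-5)
  }
})

test_that("significance is strictly monotone in score", {
  s <- seq(-50, 400, by = 10)
  e <- vapply(s, significance, numeric(1), seq_len = 300, db_size = 1e6)
  expect_true(all(diff(e) < 0))
})

test_that("I29 propeptide detection distinguishes zymogen from mature", {
  cfg <- sim_config(seed = 8, n_taxa = 4, families = "cathL", loss = 0)
  ct <- simulate_content(cfg)
  zym <- simulate_sequences(cfg, ct)
  cfgm <- sim_config(seed = 8, n_taxa = 4, families = "cathL", loss = 0,
                     zymogen = FALSE)
  mat <- simulate_sequences(cfgm, simulate_content(cfgm))
  for (s in zym$seqs) expect_true(detect_i29(s, i29_profile))
  for (s in mat$seqs) expect_false(detect_i29(s, i29_profile))
  expect_false(detect_i29("ACDEFG", i29_profile))   # shorter than 60
})

test_that("a fused two-domain sequence is classed multidomain", {
  arch <- family_archetypes()
  fused <- paste0(arch$cathL$seq, arch$cathL$seq)
  a <- assign_family("fused", "x", fused, profiles, i29_profile)
  expect_equal(a$family, "cathL")
  expect_equal(a$length_class, "multidomain")
})
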