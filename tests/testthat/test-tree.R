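# Newick parsing, tree queries, rooting.

test_that("read_newick parses minimal trees and branch lengths", {
  tr <- read_newick("((A,B),C);")
  expect_s3_class(tr, "taxtree")
  expect_equal(sort(leaf_labels(tr)), c("A", "B", "C"))
  expect_equal(length(tr$label), 5L)              # 3 leaves + 2 internals
  expect_equal(length(leaf_ids(tr)), 3L)

  tr2 <- read_newick("(A:1,B:2)R:0;")
  expect_equal(tr2$label[tr2$root], "R")
  expect_equal(tr2$brlen[node_id(tr2, "A")], 1)
  expect_equal(tr2$brlen[node_id(tr2, "B")], 2)
})

test_that("quoted labels and singleton internal nodes are supported", {
  tr <- read_newick("(('Genus species':1,B:2)'inner node':0.5,C)R;")
  expect_true("Genus species" %in% leaf_labels(tr))
  expect_equal(clade_of(tr, "B", "inner node"), "inner node")
  expect_error(clade_of(tr, "B", c("inner node", "R")), "nested")
  # singleton stem node (as FECA in the combined taxonomy)
  tr2 <- read_newick("((A,B)L)S;")
  expect_equal(tr2$label[tr2$root], "S")
  expect_equal(length(tr2$children[[tr2$root]]), 1L)
})

test_that("parse errors are located and duplicates rejected", {
  expect_error(read_newick("((A,B),C));"), "offset")
  expect_error(read_newick("((A,(B,C);"), "offset")
  expect_error(read_newick("((A,B),A);"), "duplicate leaf")
})

test_that("write_newick round-trips all packaged trees", {
  for (nm in c("eukaryota", "prokaryota", "combined")) {
    tr <- reference_tree(nm)
    s <- write_newick(tr)
    tr2 <- read_newick(s)
    expect_identical(write_newick(tr2), s)
    expect_identical(leaf_labels(tr2), leaf_labels(tr))
    expect_identical(named_ancestors(tr2), named_ancestors(tr))
  }
})

test_that("mrca handles singletons, pairs and full leaf sets", {
  tr <- read_newick("((A,B)ab,C)r;")
  expect_equal(as.character(mrca(tr, "A")), "A")
  expect_equal(as.character(mrca(tr, c("A", "C"))), "r")
  expect_equal(as.character(mrca(tr, c("A", "B"))), "ab")
  expect_error(mrca(tr, "Z"), "unknown node")
  expect_error(mrca(tr, character(0)), "at least one")

  euk <- reference_tree("eukaryota")
  expect_equal(as.character(mrca(euk, leaf_labels(euk))), "LECA")
  # the distribution-table lineages coalesce in LECA
  t1 <- reference_table("table1")
  rows <- intersect(rownames(t1), leaf_labels(euk))
  expect_equal(as.character(mrca(euk, rows)), "LECA")
})

test_that("mrca is stable under adding descendants of the result", {
  euk <- reference_tree("eukaryota")
  m1 <- mrca(euk, c("Rhizaria", "Amoebozoa"))
  more <- union(c("Rhizaria", "Amoebozoa"),
                sample(clade_leaves(euk, as.character(m1)), 4))
  expect_equal(as.character(mrca(euk, more)), as.character(m1))
})

test_that("clade_of matches the supergroup structure of the reference tree", {
  euk <- reference_tree("eukaryota")
  level <- c("Diaphoretickes", "Amorphea", "Excavata")
  expect_equal(clade_of(euk, "Rhizaria", level), "Diaphoretickes")
  expect_equal(clade_of(euk, "Metamonada", level), "Excavata")
  expect_equal(clade_of(euk, "Fungi", level), "Amorphea")
  # degenerate one-clade partition
  expect_equal(clade_of(euk, "Rhizaria", "LECA"), "LECA")
  # every leaf is covered by exactly one supergroup
  for (lf in leaf_labels(euk))
    expect_true(clade_of(euk, lf, level) %in% level)
  # coverage error when the level misses the leaf
  expect_error(clade_of(euk, "Rhizaria", c("Amorphea", "Excavata")),
               "not covered")
})

test_that("validation enforces the structural invariants", {
  expect_error(c1aprofiler:::new_taxtree(c("A", "B"), c(NA, NA), c(NA, NA)),
               "exactly one root")
  expect_error(read_newick("((A,B)x,(C,D)x)r;"), "duplicate internal")
  expect_error(read_newick("(A:-1,B:1)r;"), "negative branch")
})

test_that("reroot places the root on the chosen branch", {
  tr <- read_newick("((A:1,B:1)ab:2,(C:1,D:1)cd:2)r;")
  rr <- reroot(tr, "C")
  expect_equal(sort(leaf_labels(rr)), c("A", "B", "C", "D"))
  # C now hangs directly below the root, on a split branch
  expect_equal(rr$parent[node_id(rr, "C")], rr$root)
  expect_equal(rr$brlen[node_id(rr, "C")], 0.5)
  # total branch length is conserved
  s <- function(t) sum(t$brlen, na.rm = TRUE)
  expect_equal(s(rr), s(tr))
})

test_that("midpoint rooting balances the longest leaf path", {
  tr <- read_newick("((A:5,B:1)ab:2,(C:1,D:1)cd:2)r;")
  mr <- midpoint_root(tr)
  d <- node_depths(mr, default = 1)
  lv <- leaf_ids(mr)
  # the longest leaf path is A<->C = 5+2+2+1 = 10; after midpoint rooting
  # the deepest leaf sits at exactly half of it
  expect_equal(max(d[lv]), 5)
})
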