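# Packaged reference data: transcriptions of the published phyletic
# distribution tables and the backbone taxonomies they sit on.
#
# The shipped files under inst/extdata are generated by make_fixture() and
# covered by golden tests, so any edit to a transcription is a deliberate,
# visible act.
#
# Encoding notes:
#  * bold header rows of the source tables (supergroups, phylum groups) are
#    kept as matrix rows; reconstruction drops them via restrict_to_leaves()
#    because they name internal nodes of the backbone trees;
#  * the one blank cell in the Obazoa table (Tunicaraptor x cathC, printed
#    with neither symbol) is encoded unknown ("?") rather than absent;
#  * branch lengths are omitted in the backbone trees; methods that need them
#    default every branch to 1.0.

tbl <- function(rows, fams) {
  states <- do.call(rbind, lapply(rows, function(r) {
    v <- strsplit(r[[2]], "")[[1]]
    out <- rep(NA_integer_, length(v))
    out[v == "1"] <- 1L; out[v == "0"] <- 0L
    out
  }))
  rownames(states) <- vapply(rows, `[[`, character(1), 1)
  colnames(states) <- fams
  phymat(states)
}

fixture_table1 <- function() {
  tbl(list(
    list("Diaphoretickes",   "11111111"),
    list("Chloroplastida",   "11111110"),
    list("Glaucophyta",      "11111110"),
    list("Rhodophyta",       "11111110"),
    list("Picozoa",          "11110010"),
    list("Cryptista",        "11111110"),
    list("Haptophyta",       "11111111"),
    list("Centroheliozoa",   "11111111"),
    list("Provora",          "11111100"),
    list("Hemimastigophora", "11111011"),
    list("Telonemia",        "11111000"),
    list("Stramenopiles",    "11111111"),
    list("Alveolata",        "11111111"),
    list("Rhizaria",         "11111111"),
    list("Amorphea",         "11111111"),
    list("Amoebozoa",        "11111111"),
    list("Obazoa",           "11111111"),
    list("CRuMs",            "11111100"),
    list("Ancyromonadida",   "11111010"),
    list("Malawimonadida",   "11111010"),
    list("Excavata",         "11111111"),
    list("Discoba",          "11111111"),
    list("Metamonada",       "11111011")
  ), ANCESTRAL_FAMILIES)
}

fixture_table2 <- function() {
  fams <- c("cathB", "cathC", "cathX", "cathL", "cathF", "cathH", "cathO",
            "p26_29", "type1_long", "vWFA_C1")
  tbl(list(
    list("Opisthokonta",     "1111111111"),
    list("Metazoa",          "1111111101"),
    list("Choanoflagellata", "1111101101"),
    list("Filasterea",       "1111101000"),
    list("Tunicaraptor",     "1?11101010"),
    list("Pluriformea",      "1111011100"),
    list("Ichthyosporea",    "1111101100"),
    list("Rotosphaerida",    "0000000000"),
    list("Fungi",            "0000000001"),
    list("Breviatea",        "1111100110"),
    list("Apusozoa",         "1001111100"),
    list("Basal_metazoans",  "1111111101"),
    list("Bilateria",        "1111111101"),
    list("Protostomia",      "1111111101"),
    list("Deuterostomia",    "1111111101")
  ), fams)
}

fixture_table3 <- function() {
  rows <- c("Bacteria", "Acidobacteria", "Aquificae", "Atribacterota",
            "Caldiserica_Cryosericota", "Calditrichaeota", "Chrysiogenetes",
            "Coprothermobacterota", "Deferribacteres", "Desulfobacterota",
            "Dictyoglomi", "Elusimicrobia", "FCB_group",
            "Bacteroidetes_Chlorobi", "Fibrobacteres", "Gemmatimonadetes",
            "Fusobacteria", "Myxococcota", "Nitrospinae_Tectomicrobia",
            "Nitrospirae", "Pseudomonadota", "PVC_group", "Chlamydiae",
            "Lentisphaerae", "Planctomycetota", "Verrucomicrobia",
            "Spirochaetes", "Synergistetes", "Terrabacteria_group",
            "Actinomycetota", "Bacillota", "Chloroflexi", "Cyanobacteria",
            "Deinococcus_Thermus", "Tenericutes", "Thermodesulfobacteria",
            "Thermotogae", "Bacteria_candidate_phyla",
            "Archaea", "Asgard_group", "Thermoplasmatota", "DPANN_group",
            "Euryarchaeota", "TACK_group")
  tbl(lapply(rows, function(r)
        list(r, if (r == "Dictyoglomi") "00" else "11")),
      c("single_domain", "multidomain"))
}

fixture_table5 <- function() {
  tbl(list(
    list("Diaphoretickes", "11111111"),
    list("Amorphea",       "11111111"),
    list("CRuMs",          "11111100"),
    list("Ancyromonadida", "11111010"),
    list("Malawimonadida", "11111010"),
    list("Discoba",        "11111111"),
    list("Metamonada",     "11111011"),
    list("LECA",           "11111111")
  ), ANCESTRAL_FAMILIES)
}

fixture_table6 <- function() {
  tbl(list(
    list("LECA",                "011111111"),
    list("FECA",                "100000000"),
    list("Alphaproteobacteria", "100000000"),
    list("Cyanobacteria",       "100000000"),
    list("Deltaproteobacteria", "100000000"),
    list("Archaea",             "100000000"),
    list("LUCA",                "100000000")
  ), c("C1A_generic", ANCESTRAL_FAMILIES))
}

fixture_newick_eukaryota <- function() {
  paste0(
    "((Chloroplastida,Glaucophyta,Rhodophyta,Picozoa,Cryptista,Haptophyta,",
    "Centroheliozoa,Provora,Hemimastigophora,Telonemia,Stramenopiles,",
    "Alveolata,Rhizaria)Diaphoretickes,",
    "(Amoebozoa,",
    "(((Basal_metazoans,(Protostomia,Deuterostomia)Bilateria)Metazoa,",
    "Choanoflagellata,Filasterea,Tunicaraptor,Pluriformea,Ichthyosporea,",
    "Rotosphaerida,Fungi)Opisthokonta,Breviatea,Apusozoa)Obazoa,",
    "CRuMs,Ancyromonadida,Malawimonadida)Amorphea,",
    "(Discoba,Metamonada)Excavata)LECA;")
}

fixture_newick_bacteria_clade <- function() {
  paste0(
    "(Acidobacteria,Aquificae,Atribacterota,Caldiserica_Cryosericota,",
    "Calditrichaeota,Chrysiogenetes,Coprothermobacterota,Deferribacteres,",
    "Desulfobacterota,Dictyoglomi,Elusimicrobia,",
    "(Bacteroidetes_Chlorobi,Fibrobacteres,Gemmatimonadetes)FCB_group,",
    "Fusobacteria,Myxococcota,Nitrospinae_Tectomicrobia,Nitrospirae,",
    "(Alphaproteobacteria,Gammaproteobacteria,Deltaproteobacteria)",
    "Pseudomonadota,",
    "(Chlamydiae,Lentisphaerae,Planctomycetota,Verrucomicrobia)PVC_group,",
    "Spirochaetes,Synergistetes,",
    "(Actinomycetota,Bacillota,Chloroflexi,Cyanobacteria,Deinococcus_Thermus,",
    "Tenericutes)Terrabacteria_group,",
    "Thermodesulfobacteria,Thermotogae,Bacteria_candidate_phyla)Bacteria")
}

fixture_newick_archaea_clade <- function() {
  "(Asgard_group,Thermoplasmatota,DPANN_group,Euryarchaeota,TACK_group)Archaea"
}

fixture_newick_prokaryota <- function() {
  paste0("(", fixture_newick_bacteria_clade(), ",",
         fixture_newick_archaea_clade(), ")LUCA;")
}

# FECA is a singleton stem node between the archaeal relatives of eukaryotes
# and LECA: the first eukaryote carried one C1A progenitor, and the eight
# ancestral families arise on the FECA->LECA stem.
fixture_newick_combined <- function() {
  euk <- sub(";$", "", fixture_newick_eukaryota())
  paste0("(", fixture_newick_bacteria_clade(), ",(",
         fixture_newick_archaea_clade(), ",(", euk,
         ")FECA)Archaea_Eukaryota)LUCA;")
}

#' Write a packaged fixture
#'
#' Regenerates one of the shipped data files. Table and tree fixtures are
#' literal transcriptions; `"seed_alignments"`, `"five_hgt_cases"` and
#' `"archaea_default"` are synthetic constructions produced by the simulator
#' under fixed internal seeds (see the simulate module).
#'
#' @param name one of "table1", "table2", "table3", "table5", "table6",
#'   "trees", "seed_alignments", "five_hgt_cases"
#' @param dir output directory root (defaults to a temporary directory; the
#'   shipped copies live under `inst/extdata`)
#' @return character vector of written paths
#' @export
make_fixture <- function(name, dir = tempfile("fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub <- function(d) {
    p <- file.path(dir, d)
    dir.create(p, recursive = TRUE, showWarnings = FALSE)
    p
  }
  tables <- list(table1 = fixture_table1, table2 = fixture_table2,
                 table3 = fixture_table3, table5 = fixture_table5,
                 table6 = fixture_table6)
  if (name %in% names(tables)) {
    path <- file.path(sub("matrices"), paste0(name, ".tsv"))
    write_matrix(tables[[name]](), path)
    return(path)
  }
  if (name == "trees") {
    d <- sub("trees")
    paths <- c(eukaryota = file.path(d, "eukaryota.nwk"),
               prokaryota = file.path(d, "prokaryota.nwk"),
               combined = file.path(d, "combined.nwk"))
    writeLines(fixture_newick_eukaryota(), paths["eukaryota"])
    writeLines(fixture_newick_prokaryota(), paths["prokaryota"])
    writeLines(fixture_newick_combined(), paths["combined"])
    return(paths)
  }
  if (name == "seed_alignments") return(make_seed_alignments(sub("seeds")))
  if (name == "five_hgt_cases") return(make_five_hgt_cases(sub("hgt")))
  stop("unknown fixture name: ", name)
}
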