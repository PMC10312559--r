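# Small in-code fixtures: a hand-built taxonomy store and convenience
# wrappers around the package's synthetic-corpus generator.

# Hand-built taxdump with two congeneric fish species (Badis assamensis /
# Badis badis) plus an environmental record lacking mid-rank taxonomy.
write_toy_taxdump <- function(dir = tempfile("taxdump")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tsuperkingdom\t|",
    "10\t|\t2\t|\tphylum\t|",
    "11\t|\t10\t|\tclass\t|",
    "12\t|\t11\t|\torder\t|",
    "13\t|\t12\t|\tfamily\t|",
    "14\t|\t13\t|\tgenus\t|",
    "15\t|\t14\t|\tspecies\t|",
    "16\t|\t14\t|\tspecies\t|",
    "20\t|\t2\t|\tspecies\t|",   # env record: phylum..genus missing
    "30\t|\t12\t|\tfamily\t|",
    "31\t|\t30\t|\tgenus\t|",
    "32\t|\t31\t|\tspecies\t|")
  names_ <- c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "2\t|\tEukaryota\t|\t\t|\tscientific name\t|",
    "10\t|\tChordata\t|\t\t|\tscientific name\t|",
    "11\t|\tActinopteri\t|\t\t|\tscientific name\t|",
    "12\t|\tAnabantiformes\t|\t\t|\tscientific name\t|",
    "13\t|\tBadidae\t|\t\t|\tscientific name\t|",
    "14\t|\tBadis\t|\t\t|\tscientific name\t|",
    "15\t|\tBadis assamensis\t|\t\t|\tscientific name\t|",
    "15\t|\tsome synonym\t|\t\t|\tsynonym\t|",
    "16\t|\tBadis badis\t|\t\t|\tscientific name\t|",
    "20\t|\tuncultured eukaryote\t|\t\t|\tscientific name\t|",
    "30\t|\tOsphronemidae\t|\t\t|\tscientific name\t|",
    "31\t|\tTrichogaster\t|\t\t|\tscientific name\t|",
    "32\t|\tTrichogaster fasciata\t|\t\t|\tscientific name\t|")
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(names_, file.path(dir, "names.dmp"))
  dir
}

toy_store <- function(acc2taxid = NULL, membership = NULL) {
  dir <- write_toy_taxdump()
  a2t <- NULL
  if (!is.null(acc2taxid)) {
    a2t <- file.path(dir, "acc2taxid.tsv")
    writeLines(paste(names(acc2taxid), acc2taxid, sep = "\t"), a2t)
  }
  mem <- NULL
  if (!is.null(membership)) {
    mem <- file.path(dir, "membership.tsv")
    utils::write.table(membership, mem, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  load_taxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"),
               acc2taxid = a2t, membership = mem)
}

BADIS_ASSAMENSIS <- c(superkingdom = "Eukaryota", phylum = "Chordata",
                      class = "Actinopteri", order = "Anabantiformes",
                      family = "Badidae", genus = "Badis",
                      species = "Badis assamensis")
BADIS_BADIS <- replace(BADIS_ASSAMENSIS, "species", "Badis badis")

FIXTURE_PRIMERS <- primer_set("ACGTTCGAWCTGCAGGTCAT", "TGCATCGRAGTCCTAGGACT",
                              name = "synthetic")

# Standard small expansion-scale fixture used by several test files.
small_fixture <- function(rng_seed = 11, ...) {
  generate_fixture(
    fixture_spec(n_genera = 4, species_per_genus = 2,
                 accessions_per_species = 2, rng_seed = rng_seed, ...),
    tempfile("fixture"))
}

fixture_corpus <- function(truth) read_fasta(truth$paths$corpus)

STRICT_SIM <- similarity_params(min_percent_identity = 85, max_evalue = 10,
                                min_query_coverage = 0.8)
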