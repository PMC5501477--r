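# Small fixtures built in code.

toy_taxonomy <- function() {
  load_taxonomy(tibble::tibble(
    name = c("Perciformes", "Percoidei", "Percidae"),
    rank = c("order", "suborder", "family"),
    parent = c("", "Perciformes", "Percoidei"),
    flags = ""
  ))
}

# Two orders under one series, each with two families; tip labels follow the
# Family_Genus_species_Code convention and the tree is a calibrated
# chronogram with supports.
two_order_fixture <- function() {
  txt <- paste0(
    "(((Aidae_Ga_s1_C1:10,Aidae_Ga_s2_C2:10)100:10,",
    "(Bidae_Gb_s1_C3:15,Bidae_Gb_s2_C4:15)95:5)92:20,",
    "((Cidae_Gc_s1_C5:12,Cidae_Gc_s2_C6:12)88:18,",
    "(Didae_Gd_s1_C7:20,Didae_Gd_s2_C8:20)100:10)97:10)99;"
  )
  tree <- parse_newick(txt)
  taxonomy <- load_taxonomy(tibble::tibble(
    name = c("Seraria", "OrdAiformes", "OrdBiformes",
             "Aidae", "Bidae", "Cidae", "Didae"),
    rank = c("series", "order", "order", rep("family", 4)),
    parent = c("", "Seraria", "Seraria",
               "OrdAiformes", "OrdAiformes", "OrdBiformes", "OrdBiformes"),
    flags = c("", "corroborated", "", "", "", "", "")
  ))
  list(tree = tree, taxonomy = taxonomy)
}

fixture_classification_path <- function() {
  system.file("extdata", "percomorph_classification.tsv", package = "fishtol")
}
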