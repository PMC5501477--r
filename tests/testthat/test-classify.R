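test_that("supra-family taxa follow the branching order of the tree", {
  fx <- two_order_fixture()
  ord <- phylogenetic_order(fx$taxonomy, fx$tree)
  expect_equal(ord$name[1], "Seraria")
  # OrdAiformes' crown branches off first in stored child order
  expect_lt(match("OrdAiformes", ord$name), match("OrdBiformes", ord$name))
  expect_true(all(match(ord$parent[-1], ord$name) < seq_len(nrow(ord))[-1]))
})

test_that("families list alphabetically under their parent", {
  tree <- parse_newick(paste0(
    "((Zeidae_Z_s_C1:5,(Parazenidae_P_s_C2:3,Zeniontidae_Zn_s_C3:3):2)90:5,",
    "Out_O_s_C4:10);"
  ))
  tax <- load_taxonomy(tibble::tibble(
    name = c("Zeiformes", "Zeiodei", "Parazenidae", "Zeidae", "Zeniontidae",
             "Outidae"),
    rank = c("order", "suborder", "family", "family", "family", "family"),
    parent = c("", "Zeiformes", "Zeiodei", "Zeiodei", "Zeiodei", "Zeiformes"),
    flags = ""
  ))
  tree$tip.label[4] <- "Outidae_O_s_C4"
  ord <- phylogenetic_order(tax, tree)
  fam_block <- ord$name[ord$parent == "Zeiodei"]
  expect_equal(fam_block, c("Parazenidae", "Zeidae", "Zeniontidae"))
})

test_that("a single-order taxonomy keeps taxonomy row order", {
  tax <- toy_taxonomy()
  ord <- phylogenetic_order(tax, tree = NULL)
  expect_equal(ord$name, tax$name)
  expect_equal(ord$depth, c(0L, 1L, 2L))
})

test_that("unsampled taxa slot in after their declared anchor", {
  fx <- two_order_fixture()
  tax <- load_taxonomy(tibble::tibble(
    name = c("Seraria", "OrdAiformes", "OrdBiformes", "OrdCiformes",
             "Aidae", "Bidae", "Cidae", "Didae"),
    rank = c("series", "order", "order", "order", rep("family", 4)),
    parent = c("", "Seraria", "Seraria", "Seraria",
               "OrdAiformes", "OrdAiformes", "OrdBiformes", "OrdBiformes"),
    flags = "",
    anchor = c("", "", "", "OrdAiformes", "", "", "", "")
  ))
  rep <- validate_all(tax, fx$tree)
  ord <- phylogenetic_order(tax, fx$tree, rep)
  sup <- ord$name[ord$rank == "order"]
  expect_equal(sup, c("OrdAiformes", "OrdCiformes", "OrdBiformes"))

  tax_bad <- tax
  tax_bad$anchor[tax_bad$name == "OrdCiformes"] <- ""
  expect_error(phylogenetic_order(tax_bad, fx$tree, validate_all(tax_bad, fx$tree)),
               class = "fishtol_order_error")
})

test_that("rendering produces the annotated indented text", {
  fx <- two_order_fixture()
  rep <- validate_all(fx$taxonomy, fx$tree)
  cls <- render_classification(fx$taxonomy, fx$tree, rep)
  expect_equal(cls$lines[1], "Series Seraria (99%)")
  expect_equal(cls$lines[2], "  Order OrdAiformes (92%)")
  expect_equal(cls$lines[3], "    Family Aidae")
  expect_true(all(grepl("^    Family ", cls$lines[c(3, 4, 6, 7)])))
})

test_that("provisional quotes, non-monophyly and incertae sedis annotate", {
  tax <- load_taxonomy(tibble::tibble(
    name = c("Carangaria", "Menidae", "Pleuronectiformes", "\"Cyclopsettidae\""),
    rank = c("series", "family", "order", "family"),
    parent = c("", "Carangaria", "Carangaria", "Pleuronectiformes"),
    flags = c("", "incertae_sedis", "non_monophyletic_declared", "")
  ))
  cls <- render_classification(tax)
  expect_equal(cls$lines, c(
    "Series Carangaria",
    "  Family Menidae (incertae sedis in Carangaria)",
    "  Order Pleuronectiformes (not monophyletic)",
    "    Family \"Cyclopsettidae\""
  ))
})

test_that("render -> load round-trips the taxonomy", {
  fx <- two_order_fixture()
  rep <- validate_all(fx$taxonomy, fx$tree)
  cls <- render_classification(fx$taxonomy, fx$tree, rep)
  d <- withr::local_tempdir()
  write_classification(cls, d)
  back <- load_taxonomy(file.path(d, "classification.tsv"))
  expect_identical(back, cls$taxonomy)
  expect_setequal(back$name, fx$taxonomy$name)
})

test_that("identical inputs give byte-identical serializations", {
  fx <- two_order_fixture()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_classification(render_classification(fx$taxonomy, fx$tree), d1)
  write_classification(render_classification(fx$taxonomy, fx$tree), d2)
  for (f in c("classification.txt", "classification.tsv", "counts.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("counts: identities hold and empty taxonomies count zero", {
  empty <- load_taxonomy(tibble::tibble(
    name = character(), rank = character(), parent = character(),
    flags = character()
  ))
  cnt0 <- counts_summary(empty)
  expect_true(all(as.numeric(cnt0) == 0))

  tax <- load_taxonomy(fixture_classification_path())
  cnt <- counts_summary(tax)
  expect_equal(cnt$families_total, cnt$families_examined + cnt$families_unexamined)
  expect_lte(cnt$incertae_sedis_families, cnt$families_total)

  fx <- two_order_fixture()
  rep <- validate_all(fx$taxonomy, fx$tree)
  cnt2 <- counts_summary(fx$taxonomy, rep)
  expect_equal(cnt2$families_examined, 4L)
  expect_equal(cnt2$orders, 2L)
})

test_that("every flagged family carries its note in the text rendering", {
  sim <- plant_taxonomy(simulate_backbone(60, seed = 31), n_families = 8,
                        k_nonmono = 2, n_series = 1, n_orders = 2,
                        n_suborders = 0, seed = 31)
  rep <- validate_all(sim$taxonomy, sim$tree)
  cls <- render_classification(sim$taxonomy, sim$tree, rep)
  for (fam in sim$truth$planted_nonmono) {
    line <- grep(paste0("Family ", fam, " "), cls$lines, value = TRUE)
    expect_length(line, 1)
    expect_match(line, "not monophyletic")
  }
})
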