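test_that("monophyly assessment matches the four-leaf bipartition oracle", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  sets <- oracle_clade_sets(tr)
  for (tips in all_subsets(c("A", "B", "C", "D"))) {
    got <- assess_monophyly(tr, tips)
    want <- oracle_assess(sets, tips)
    expect_equal(got$status, want$status, info = paste(tips, collapse = ","))
    expect_equal(got$intruders, want$intruders)
  }
  expect_equal(assess_monophyly(tr, c("A", "C"))$intruders, c("B", "D"))
  expect_equal(assess_monophyly(tr, "A")$status, "monotypic")
  expect_equal(assess_monophyly(tr, character(0))$status, "unsampled")
  expect_error(assess_monophyly(tr, c("A", "Z")),
               class = "fishtol_validation_error")
})

test_that("pruning the reported intruders restores monophyly", {
  withr::with_seed(42, {
    for (i in 1:25) {
      tr <- simulate_backbone(sample(6:20, 1), seed = i)
      tips <- sample(tr$tip.label, sample(2:4, 1))
      res <- assess_monophyly(tr, tips)
      if (res$status == "non_monophyletic") {
        pruned <- ape::drop.tip(tr, res$intruders)
        expect_equal(assess_monophyly(pruned, tips)$status, "monophyletic")
      }
    }
  })
})

test_that("MRCA support is returned exactly and absence is NA", {
  tr <- parse_newick("((A:1,B:1)100:1,C:2);")
  expect_equal(support_at_mrca(tr, c("A", "B")), 100)
  tr2 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_true(is.na(support_at_mrca(tr2, c("A", "B"))))
  err <- expect_error(support_at_mrca(tr, c("A", "Q")),
                      class = "fishtol_validation_error")
  expect_match(conditionMessage(err), "Q")
  expect_error(support_at_mrca(tr, "A"))
})

test_that("planted clade supports are recovered at every named clade", {
  sim <- plant_taxonomy(simulate_backbone(60, seed = 8), n_families = 9,
                        n_series = 2, n_orders = 3, n_suborders = 2, seed = 8)
  for (i in seq_len(nrow(sim$truth$clade_supports))) {
    row <- sim$truth$clade_supports[i, ]
    tips <- sim$tree$tip.label[
      phangorn::Descendants(sim$tree, row$node, "tips")[[1]]
    ]
    expect_equal(support_at_mrca(sim$tree, tips), row$support, info = row$name)
  }
})

test_that("the endorsement rule is strict at 90 and honors corroboration", {
  expect_equal(endorse_taxon("monophyletic", 100, FALSE), "endorsed")
  expect_equal(endorse_taxon("monophyletic", 91, FALSE), "endorsed")
  expect_equal(endorse_taxon("monophyletic", 90, FALSE), "not_endorsed")
  expect_equal(endorse_taxon("monophyletic", 42, TRUE),
               "endorsed_by_corroboration")
  expect_equal(endorse_taxon("monophyletic", 42, FALSE), "not_endorsed")
  expect_equal(endorse_taxon("monophyletic", NA, TRUE),
               "endorsed_by_corroboration")
  expect_equal(endorse_taxon("non_monophyletic", 95, TRUE),
               "endorsed_by_corroboration")
  expect_equal(endorse_taxon("non_monophyletic", 95, FALSE), "not_endorsed")
  expect_equal(endorse_taxon("monotypic", NA, FALSE), "not_applicable")
  expect_equal(endorse_taxon("unsampled", NA, TRUE), "not_applicable")
})

test_that("validate_all derives tip sets transitively and summarizes", {
  fx <- two_order_fixture()
  rep <- validate_all(fx$taxonomy, fx$tree)
  taxa <- tidy(rep)
  expect_equal(nrow(taxa), 7L)
  expect_true(all(taxa$status[taxa$rank != "family"] == "monophyletic"))
  expect_equal(taxa$n_tips_sampled[taxa$name == "Seraria"], 8L)
  expect_equal(taxa$mrca_support[taxa$name == "Seraria"], 99)
  expect_equal(taxa$mrca_support[taxa$name == "OrdAiformes"], 92)
  # order A: monophyletic at 92% -> endorsed outright; series too
  expect_equal(taxa$endorsement[taxa$name == "OrdAiformes"], "endorsed")
  expect_true(all(taxa$endorsement[taxa$rank == "family"] == "not_applicable"))
  g <- glance(rep)
  expect_equal(g$families_total, 4L)
  expect_equal(g$families_examined, 4L)
  expect_equal(g$families_non_monophyletic, 0L)
})

test_that("suborder tip sets equal the union of their families when coherent", {
  sim <- plant_taxonomy(simulate_backbone(80, seed = 13), n_families = 12,
                        n_series = 2, n_orders = 4, n_suborders = 2, seed = 13)
  rep <- validate_all(sim$taxonomy, sim$tree)
  taxa <- tidy(rep)
  fams <- parse_tip_label(sim$tree)
  for (nm in taxa$name[taxa$rank == "suborder"]) {
    kids <- sim$taxonomy$name[sim$taxonomy$parent == nm &
                                sim$taxonomy$rank == "family"]
    union_tips <- fams$label[fams$family %in% kids]
    row <- taxa[taxa$name == nm, ]
    if (row$status == "monophyletic" && length(union_tips) >= 2) {
      clade <- sim$tree$tip.label[
        phangorn::Descendants(sim$tree, row$mrca, "tips")[[1]]
      ]
      expect_setequal(clade, union_tips)
    }
  }
})

test_that("outgroup tips are excluded from unions and reported", {
  fx <- two_order_fixture()
  tree <- fx$tree
  tree$tip.label[tree$tip.label == "Didae_Gd_s2_C8"] <- "Sharkidae_Gx_s1_C9"
  expect_warning(rep <- validate_all(fx$taxonomy, tree), "Sharkidae")
  expect_equal(rep$outgroup_tips, "Sharkidae_Gx_s1_C9")
  taxa <- tidy(rep)
  expect_equal(taxa$n_tips_sampled[taxa$name == "Didae"], 1L)
  expect_equal(taxa$status[taxa$name == "Didae"], "monotypic")
  expect_error(validate_all(fx$taxonomy, tree, on_missing_family = "error"),
               class = "fishtol_validation_error")
})

test_that("tidy/glance/autoplot expose the report", {
  fx <- two_order_fixture()
  rep <- validate_all(fx$taxonomy, fx$tree)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 1L)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})
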