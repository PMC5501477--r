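test_that("check_ultrametric measures leaf-depth deviation", {
  expect_true(is_ultrametric(parse_newick("(A:1,B:1);")))
  res <- check_ultrametric(parse_newick("(A:1,B:1.2);"), rel_tol = 1e-6)
  expect_false(res$is_ultrametric)
  expect_equal(res$max_deviation, 0.1)
  expect_equal(res$mean_depth, 1.1)
  expect_error(check_ultrametric(ape::read.tree(text = "(A,B);")),
               class = "fishtol_validation_error")
})

test_that("mean-path smoothing follows the recursive rule", {
  # hand computation: leaf depths 2, 2, 3 -> root age 7/3; AB ancestor
  # allocates half of each parent->leaf path below it -> age 7/6
  sm <- smooth_to_ultrametric(parse_newick("((A:1,B:1):1,C:3);"))
  expect_true(is_ultrametric(sm, 1e-9))
  ages <- node_ages(sm)
  expect_equal(ages[4], 7 / 3, tolerance = 1e-12)
  expect_equal(ages[5], 7 / 6, tolerance = 1e-12)
})

test_that("smoothing fixes ultrametric trees and is idempotent", {
  tr <- simulate_backbone(25, root_age = 100, seed = 11)
  sm <- smooth_to_ultrametric(tr)
  expect_identical(sm$edge, tr$edge)
  expect_equal(sm$edge.length, tr$edge.length, tolerance = 1e-12)

  don <- simulate_donor(25, crown_age = 50, rate_noise_sigma = 0.4, seed = 3)
  s1 <- smooth_to_ultrametric(don$tree)
  s2 <- smooth_to_ultrametric(s1)
  expect_true(is_ultrametric(s1, 1e-9))
  expect_identical(s1$edge, don$tree$edge)
  expect_equal(s2$edge.length, s1$edge.length, tolerance = 1e-12)

  # ages strictly decrease root-to-leaf when branch lengths are positive
  ages <- node_ages(s1)
  expect_true(all(ages[s1$edge[, 1]] > ages[s1$edge[, 2]]))

  expect_error(smooth_to_ultrametric(parse_newick("A;")),
               class = "fishtol_validation_error")
})

test_that("rescaling is linear and composes", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  r <- rescale_to_age(tr, 100)
  expect_equal(crown_age(r), 100, tolerance = 1e-9)
  expect_equal(r$edge.length, tr$edge.length * 50)
  expect_equal(rescale_to_age(tr, crown_age(tr))$edge.length, tr$edge.length)

  tr2 <- simulate_backbone(15, root_age = 80, seed = 5)
  a <- rescale_to_age(rescale_to_age(tr2, 40), 70)
  b <- rescale_to_age(tr2, 70)
  expect_equal(a$edge.length, b$edge.length, tolerance = 1e-9)
  expect_equal(node_ages(rescale_to_age(tr2, 160)), node_ages(tr2) * 2,
               tolerance = 1e-9)

  expect_error(rescale_to_age(parse_newick("(A:1,B:2);"), 10),
               class = "fishtol_validation_error")
})

test_that("grafting rescales the donor and keeps the tree ultrametric", {
  bb <- parse_newick("((A:10,B:10)90:10,C:20);")
  dn <- smooth_to_ultrametric(parse_newick("((x:1,y:1):1,z:2);"))
  out <- graft_clade(bb, c("A", "B"), dn)
  expect_setequal(out$tip.label, c("x", "y", "z", "C"))
  expect_equal(crown_age(out), 20, tolerance = 1e-9)
  expect_true(is_ultrametric(out, 1e-9))
  expect_equal(unname(node_ages(out)[ape::getMRCA(out, c("x", "y", "z"))]), 10,
               tolerance = 1e-9)
})

test_that("grafting a clade onto itself reproduces the backbone", {
  bb <- simulate_backbone(12, root_age = 100, seed = 21)
  node <- length(bb$tip.label) + 3L
  tips <- bb$tip.label[phangorn::Descendants(bb, node, "tips")[[1]]]
  donor <- ape::keep.tip(bb, tips)
  out <- graft_clade(bb, tips, donor)
  expect_setequal(out$tip.label, bb$tip.label)
  a0 <- node_ages(bb)[ape::getMRCA(bb, tips)]
  a1 <- node_ages(out)[ape::getMRCA(out, tips)]
  expect_equal(a1, a0, tolerance = 1e-9)
  expect_true(is_ultrametric(out, 1e-9))
})

test_that("graft errors: negative stem, non-monophyletic selector, collisions", {
  bb <- parse_newick("((A:10,B:10)90:10,C:20);")
  dn <- smooth_to_ultrametric(parse_newick("((x:1,y:1):1,z:2);"))
  expect_error(graft_clade(bb, c("A", "B"), dn, crown_age = 25),
               class = "fishtol_negative_stem_error")
  expect_warning(
    out <- graft_clade(bb, c("A", "B"), dn, crown_age = 25, squeeze = TRUE)
  )
  expect_true(is_ultrametric(out, 1e-9))
  expect_equal(unname(node_ages(out)[ape::getMRCA(out, c("x", "y", "z"))]),
               0.99 * 20, tolerance = 1e-9)

  bb2 <- parse_newick("(((A:5,B:5)80:5,D:10)90:10,C:20);")
  expect_error(graft_clade(bb2, c("A", "D"), dn),
               class = "fishtol_nonmono_attachment_error")
  forced <- suppressWarnings(graft_clade(bb2, c("A", "D"), dn, force = TRUE))
  expect_equal(attr(forced, "displaced"), "B")
  expect_setequal(forced$tip.label, c("x", "y", "z", "C"))

  dn2 <- smooth_to_ultrametric(parse_newick("((C:1,y:1):1,z:2);"))
  expect_error(graft_clade(bb, c("A", "B"), dn2),
               class = "fishtol_validation_error")
  expect_error(graft_clade(bb, c("A", "B", "C"), dn),
               class = "fishtol_selector_error")
})

test_that("grafting by clade annotation selects the named clade", {
  bb <- parse_newick("((A:10,B:10)Cypriniformes:10,C:20);")
  dn <- smooth_to_ultrametric(parse_newick("((x:1,y:1):1,z:2);"))
  out <- graft_clade(bb, "Cypriniformes", dn, crown_age = 8)
  expect_setequal(out$tip.label, c("x", "y", "z", "C"))
  expect_equal(unname(node_ages(out)[ape::getMRCA(out, c("x", "y", "z"))]), 8,
               tolerance = 1e-9)
})

test_that("crown-node support falls back from donor to backbone", {
  bb <- parse_newick("((A:10,B:10)90:10,C:20);")
  dn_unl <- smooth_to_ultrametric(parse_newick("((x:1,y:1):1,z:2);"))
  out <- graft_clade(bb, c("A", "B"), dn_unl)
  m <- ape::getMRCA(out, c("x", "y", "z"))
  expect_equal(node_support(out)[m - length(out$tip.label)], 90)

  # a donor whose root carries its own support keeps it at the crown, and
  # interior donor supports ride along
  dn_lab <- parse_newick("((x:1,y:1)77:1,z:2)88;")
  out2 <- graft_clade(bb, c("A", "B"), smooth_to_ultrametric(dn_lab))
  m2 <- ape::getMRCA(out2, c("x", "y", "z"))
  expect_equal(node_support(out2)[m2 - length(out2$tip.label)], 88)
  mxy <- ape::getMRCA(out2, c("x", "y"))
  expect_equal(node_support(out2)[mxy - length(out2$tip.label)], 77)
})

test_that("calibration tables load and drive multi-clade grafts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "clade_name\ttips\tcrown_age_ma",
    "CladeAB\tA;B\t8",
    "CladeCD\tC;D\t12"
  ), f)
  cal <- read_calibration_table(f)
  expect_equal(cal$crown_age_ma, c(8, 12))
  expect_equal(cal$tips[[1]], c("A", "B"))

  bb <- parse_newick("(((A:10,B:10):10,(C:15,D:15):5)95:10,E:30);")
  donors <- list(
    CladeAB = smooth_to_ultrametric(parse_newick("(a1:1,(a2:0.5,a3:0.5):0.5);")),
    CladeCD = smooth_to_ultrametric(parse_newick("(c1:1,c2:1);"))
  )
  out <- graft_clades(bb, donors, cal)
  expect_setequal(out$tip.label, c("a1", "a2", "a3", "c1", "c2", "E"))
  expect_true(is_ultrametric(out, 1e-9))
  expect_equal(unname(node_ages(out)[ape::getMRCA(out, c("a1", "a2"))]), 8,
               tolerance = 1e-9)
})
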