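# Chronogram operations: ultrametricity checks, the deterministic mean-path
# smoother, crown-age rescaling, and grafting of donor crown subtrees onto a
# calibrated backbone.

node_depths <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop_fishtol("tree has missing branch lengths",
                 class = "fishtol_validation_error")
  }
  ape::node.depth.edgelength(tree)
}

#' Root-relative node ages of an ultrametric tree
#'
#' Ages in Myr before present: tips are at (numerically) zero, the root at
#' the tree height.  Height is taken as the maximum root-to-tip path length.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric vector over all nodes (tips `1..Ntip`, then internals).
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

#' Crown age (root height) of a tree
#'
#' @inheritParams node_ages
#' @return The root-to-tip height in Myr.
#' @export
crown_age <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)])
}

#' Check a tree for ultrametricity
#'
#' A chronogram must have all extant tips equidistant from the root.  The
#' tree passes when the largest absolute deviation of a leaf depth from the
#' mean leaf depth is at most `rel_tol` times the mean leaf depth.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param rel_tol Relative tolerance (fraction of the mean leaf depth).
#' @return A one-row tibble with `is_ultrametric`, `max_deviation` (Myr) and
#'   `mean_depth` (Myr).  The deviation is reported whether or not the tree
#'   passes.
#' @seealso [is_ultrametric()] for the bare predicate.
#' @export
#' @examples
#' check_ultrametric(parse_newick("(A:1,B:1.2);"), rel_tol = 1e-6)
check_ultrametric <- function(tree, rel_tol = 1e-9) {
  d <- node_depths(tree)
  leaf <- d[seq_along(tree$tip.label)]
  m <- mean(leaf)
  dev <- max(abs(leaf - m))
  tibble(
    is_ultrametric = dev <= rel_tol * m || (m == 0 && dev == 0),
    max_deviation = dev,
    mean_depth = m
  )
}

#' @rdname check_ultrametric
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-9) {
  check_ultrametric(tree, rel_tol)$is_ultrametric
}

#' Smooth a tree to ultrametricity by the recursive mean-path rule
#'
#' A deterministic alternative to penalized-likelihood rate smoothing for
#' time-scaling donor subtrees whose branch lengths carry rate noise.  The
#' root age is set to the mean root-to-leaf path length of the input.  Then,
#' processing nodes root-to-leaf, each node `v` with parent `p` receives age
#' `age(p) * mean over descendant leaves l of (d(v,l) / d(p,l))`, where `d`
#' is path length in the input tree -- each leaf votes for the proportion of
#' the parent-to-leaf path that lies below `v`, and the node takes the mean
#' vote.  Tips land exactly at age zero, ages decrease monotonically
#' root-to-leaf (strictly so when all branch lengths are positive), topology
#' and labels are untouched, and already-ultrametric trees are returned
#' unchanged up to floating-point rounding (the map is idempotent).
#'
#' @param tree A rooted `phylo` with at least two tips and branch lengths.
#' @return An ultrametric `phylo` with the same topology.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:3);")
#' smooth_to_ultrametric(tr)  # root height 2.5, AB ancestor at age 1.25
smooth_to_ultrametric <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 2) {
    stop_fishtol("cannot smooth a tree with fewer than two leaves",
                 class = "fishtol_validation_error")
  }
  d <- node_depths(tree)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  parent <- integer(ntot)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  desc <- phangorn::Descendants(tree, seq_len(ntot), type = "tips")

  frac <- numeric(ntot)
  for (v in seq_len(ntot)) {
    if (v == root) next
    l <- desc[[v]]
    den <- d[l] - d[parent[v]]
    num <- d[l] - d[v]
    r <- ifelse(den <= 0, 1, num / den)
    frac[v] <- mean(r)
  }

  age <- numeric(ntot)
  age[root] <- mean(d[seq_len(ntip)])
  ro <- ape::reorder.phylo(tree, "cladewise")  # preorder: parents first
  for (e in seq_len(nrow(ro$edge))) {
    v <- ro$edge[e, 2]
    age[v] <- age[ro$edge[e, 1]] * frac[v]
  }

  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  out
}

#' Rescale an ultrametric tree to a target crown age
#'
#' Multiplies every branch length by `target_crown_age / crown_age(tree)`,
#' the linear map that places the root (crown) node at the secondary
#' calibration age.
#'
#' @param tree An ultrametric `phylo`.
#' @param target_crown_age Target root height in Ma (> 0).
#' @param rel_tol Ultrametricity tolerance applied to the input.
#' @return The rescaled `phylo`.
#' @export
rescale_to_age <- function(tree, target_crown_age, rel_tol = 1e-8) {
  if (!is.numeric(target_crown_age) || target_crown_age <= 0) {
    stop_fishtol("target_crown_age must be a positive age in Ma")
  }
  if (!is_ultrametric(tree, rel_tol)) {
    stop_fishtol(
      "tree is not ultrametric; smooth_to_ultrametric() it before rescaling",
      class = "fishtol_validation_error"
    )
  }
  h <- crown_age(tree)
  if (h <= 0) {
    stop_fishtol("tree has zero root height; cannot rescale",
                 class = "fishtol_validation_error")
  }
  tree$edge.length <- tree$edge.length * (target_crown_age / h)
  tree
}

#' Read a secondary-calibration table
#'
#' Tab-separated with columns `clade_name`, `tips` (semicolon-separated tip
#' labels, optional per row) and `crown_age_ma`.  Each row names a backbone
#' clade -- either by a clade annotation present in the backbone or by an
#' explicit tip set -- and assigns it a secondary crown-age calibration.
#'
#' @param file Path to the TSV.
#' @return A tibble with `clade_name` (character), `tips` (list of character
#'   vectors) and `crown_age_ma` (numeric).
#' @export
read_calibration_table <- function(file) {
  raw <- readr::read_tsv(file, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("clade_name", "crown_age_ma")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_fishtol(paste0("calibration table missing columns: ",
                        paste(miss, collapse = ", ")))
  }
  tips <- if ("tips" %in% names(raw)) raw$tips else rep(NA_character_, nrow(raw))
  out <- tibble(
    clade_name = raw$clade_name,
    tips = lapply(tips, function(x) {
      if (is.na(x) || !nzchar(x)) character(0) else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    }),
    crown_age_ma = as.numeric(raw$crown_age_ma)
  )
  if (anyNA(out$crown_age_ma) || any(out$crown_age_ma <= 0)) {
    stop_fishtol("crown_age_ma must be positive for every calibration entry")
  }
  bad <- vapply(out$tips, function(t) length(t) == 1, logical(1))
  if (any(bad)) {
    stop_fishtol(paste0("calibration tip sets must name at least two tips: ",
                        paste(out$clade_name[bad], collapse = ", ")))
  }
  out
}

resolve_clade <- function(tree, selector) {
  ntip <- length(tree$tip.label)
  if (length(selector) == 1 && !selector %in% tree$tip.label) {
    ann <- clade_annotations(tree)
    hit <- which(!is.na(ann) & ann == selector)
    if (length(hit) == 0) {
      stop_fishtol(
        sprintf("clade selector '%s' matches no tip and no clade annotation",
                selector),
        class = "fishtol_selector_error"
      )
    }
    if (length(hit) > 1) {
      stop_fishtol(sprintf("clade annotation '%s' is not unique", selector),
                   class = "fishtol_selector_error")
    }
    node <- ntip + hit
    return(list(node = node,
                tips = tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]))
  }
  missing <- setdiff(selector, tree$tip.label)
  if (length(missing)) {
    stop_fishtol(paste0("selector tips not in tree: ",
                        paste(missing, collapse = ", ")),
                 class = "fishtol_selector_error")
  }
  if (length(selector) < 2) {
    stop_fishtol("clade selectors must resolve to at least two tips",
                 class = "fishtol_selector_error")
  }
  node <- ape::getMRCA(tree, selector)
  list(node = node,
       tips = tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]])
}

#' Graft a time-scaled donor subtree onto a calibrated backbone
#'
#' Replaces a backbone clade (the MRCA of the selected tips together with
#' all of its descendants) by an ultrametric donor tree.  The donor is
#' rescaled so that its root -- the crown node of the grafted clade -- sits
#' at `crown_age`; the stem branch is set to the difference between the
#' backbone parent-node age and the crown age, so the grafted tree stays
#' ultrametric.  All branch lengths and support labels outside the replaced
#' clade are untouched (bit-identical).  The crown node keeps the donor's
#' root support when present, otherwise it inherits the backbone's.
#'
#' @param backbone Ultrametric backbone `phylo`.
#' @param selector Either a character vector of backbone tip labels (their
#'   MRCA clade is replaced) or a single clade-annotation name.
#' @param donor Ultrametric donor `phylo` (smooth it first if needed).
#' @param crown_age Crown age in Ma for the grafted clade; default (`NULL`)
#'   keeps the backbone age of the replaced clade's crown node.
#' @param squeeze When the requested crown age reaches or exceeds the
#'   parent-node age, rescale the donor to 0.99 x the parent age with a
#'   warning instead of failing.
#' @param force Attach at the MRCA even when the selected tips are not
#'   monophyletic; the intruding tips are displaced (removed) and reported
#'   in the `"displaced"` attribute and a warning.
#' @return The grafted ultrametric `phylo`; tip set = backbone tips minus
#'   the replaced clade's tips plus the donor's tips.
#' @export
#' @examples
#' bb <- parse_newick("((A:10,B:10)90:10,C:20);")
#' dn <- parse_newick("((x:1,y:1):1,z:2);")
#' out <- graft_clade(bb, c("A", "B"), smooth_to_ultrametric(dn))
#' sort(out$tip.label); crown_age(out)
graft_clade <- function(backbone, selector, donor, crown_age = NULL,
                        squeeze = FALSE, force = FALSE) {
  if (!is_ultrametric(backbone, 1e-8)) {
    stop_fishtol("backbone is not ultrametric",
                 class = "fishtol_validation_error")
  }
  if (!is_ultrametric(donor, 1e-8)) {
    stop_fishtol(
      "donor is not ultrametric; smooth_to_ultrametric() it before grafting",
      class = "fishtol_validation_error"
    )
  }
  ntip <- length(backbone$tip.label)
  sel <- resolve_clade(backbone, selector)
  m <- sel$node
  clade_tips <- sel$tips
  if (is.character(selector) && all(selector %in% backbone$tip.label)) {
    intr <- setdiff(clade_tips, selector)
    if (length(intr)) {
      if (!force) {
        stop_fishtol(
          paste0(
            "selector tips are not monophyletic in the backbone; ",
            "their MRCA also contains: ", paste(sort(intr), collapse = ", "),
            " (use force = TRUE to attach at the MRCA anyway)"
          ),
          class = "fishtol_nonmono_attachment_error"
        )
      }
      warn(paste0("attaching at the MRCA displaces tips: ",
                  paste(sort(intr), collapse = ", ")))
    }
    displaced <- sort(intr)
  } else {
    displaced <- character(0)
  }
  if (m == ntip + 1L) {
    stop_fishtol("selected clade is the whole backbone; cannot graft at the root",
                 class = "fishtol_selector_error")
  }

  collisions <- intersect(donor$tip.label, setdiff(backbone$tip.label, clade_tips))
  if (length(collisions)) {
    shown <- sort(collisions)
    if (length(shown) > 10) {
      shown <- c(shown[1:10], sprintf("... (%d total)", length(collisions)))
    }
    stop_fishtol(
      paste0("donor tip labels collide with backbone tips outside the ",
             "replaced clade: ", paste(shown, collapse = ", ")),
      class = "fishtol_validation_error"
    )
  }

  ages <- node_ages(backbone)
  parent <- backbone$edge[match(m, backbone$edge[, 2]), 1]
  parent_age <- ages[parent]
  target <- crown_age %||% ages[m]
  if (target >= parent_age) {
    if (squeeze) {
      warn(sprintf(
        "crown age %.6g >= parent node age %.6g; squeezing donor to %.6g",
        target, parent_age, 0.99 * parent_age
      ))
      target <- 0.99 * parent_age
    } else {
      stop_fishtol(
        sprintf(
          paste0("negative stem for clade [%s]: requested crown age %.6g Ma ",
                 ">= backbone parent node age %.6g Ma"),
          paste(utils::head(clade_tips, 3), collapse = ","), target, parent_age
        ),
        class = "fishtol_negative_stem_error"
      )
    }
  }
  stem <- parent_age - target
  donor <- rescale_to_age(donor, target)

  # Crown-node support: donor root label wins; else inherit the backbone's.
  if (length(donor$tip.label) >= 2) {
    broot_lab <- if (!is.null(backbone$node.label)) backbone$node.label[m - ntip] else ""
    if (is.null(donor$node.label)) {
      donor$node.label <- rep("", donor$Nnode)
    }
    if ((is.na(donor$node.label[1]) || !nzchar(donor$node.label[1])) &&
        !is.na(broot_lab) && nzchar(broot_lab)) {
      donor$node.label[1] <- broot_lab
    }
  }

  # Collapse the replaced clade to a placeholder tip, then splice the donor
  # newick in textually at full precision so every branch length outside the
  # clade survives the round trip bit-exactly.
  placeholder <- "xxFISHTOLGRAFTSLOTxx"
  rep_tip <- clade_tips[[1]]
  pruned <- if (length(clade_tips) > 1) {
    ape::drop.tip(backbone, setdiff(clade_tips, rep_tip))
  } else {
    backbone
  }
  pruned$tip.label[pruned$tip.label == rep_tip] <- placeholder
  s <- write_newick(pruned, digits = NULL)

  donor_str <- if (length(donor$tip.label) == 1) {
    quote_label(donor$tip.label)
  } else {
    newick_clade_string(donor, digits = NULL)
  }
  s2 <- sub(
    paste0(placeholder, ":[0-9eE.+-]+"),
    paste0(donor_str, ":", sprintf("%.17g", stem)),
    s,
    fixed = FALSE
  )
  out <- parse_newick(s2)
  if (length(displaced)) attr(out, "displaced") <- displaced
  out
}

#' Graft several calibrated donor clades in sequence
#'
#' Convenience wrapper applying [graft_clade()] once per calibration row.
#'
#' @param backbone Ultrametric backbone `phylo`.
#' @param donors Named list of ultrametric donor trees; names must match
#'   `calibrations$clade_name`.
#' @param calibrations Tibble as returned by [read_calibration_table()]; an
#'   empty `tips` entry means the clade is selected by its annotation name,
#'   and `crown_age_ma = NA` keeps the backbone crown age.
#' @inheritParams graft_clade
#' @return The fully grafted `phylo`.
#' @export
graft_clades <- function(backbone, donors, calibrations, squeeze = FALSE) {
  for (i in seq_len(nrow(calibrations))) {
    nm <- calibrations$clade_name[[i]]
    if (!nm %in% names(donors)) {
      stop_fishtol(sprintf("no donor tree supplied for clade '%s'", nm))
    }
    sel <- calibrations$tips[[i]]
    if (length(sel) == 0) sel <- nm
    age <- calibrations$crown_age_ma[[i]]
    if (is.na(age)) age <- NULL
    backbone <- graft_clade(backbone, sel, donors[[nm]],
                            crown_age = age, squeeze = squeeze)
  }
  backbone
}
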