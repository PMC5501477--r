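# Seeded generators: calibrated pure-birth backbones, rate-noisy donor
# subtrees with known true node ages, and taxonomies planted over tree
# clades with known non-monophyletic and incertae sedis families.  Every
# generator is bit-reproducible from (parameters, seed).

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate a calibrated backbone chronogram
#'
#' A pure-birth (Yule) tree conditioned on `n_tips`, rescaled so the root
#' sits at `root_age`, with every internal node labeled by an integer
#' bootstrap support drawn uniformly from `support_range`.  Extinction adds
#' nothing the downstream pipeline exercises, so the generator stays
#' pure-birth.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per Myr (only shapes relative node
#'   depths; the tree is rescaled to `root_age`).
#' @param root_age Crown age of the backbone in Ma.
#' @param support_range Integer bounds `[lo, hi]` for uniform support draws.
#' @param seed Integer seed; identical seeds give identical newick strings.
#' @return An ultrametric `phylo` with support node labels.
#' @export
#' @examples
#' bb <- simulate_backbone(8, seed = 1)
#' check_ultrametric(bb)
simulate_backbone <- function(n_tips, birth_rate = 0.05, root_age = 368,
                              support_range = c(50, 100), seed = NULL) {
  if (n_tips < 2) stop_fishtol("n_tips must be at least 2")
  if (root_age <= 0) stop_fishtol("root_age must be positive")
  if (birth_rate <= 0) stop_fishtol("birth_rate must be positive")
  if (length(support_range) != 2 || support_range[1] > support_range[2] ||
      support_range[1] < 0 || support_range[2] > 100) {
    stop_fishtol("support_range must be [lo, hi] within [0, 100]")
  }
  with_seed_maybe(seed, {
    phy <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    phy$edge.length <- phy$edge.length * (root_age / crown_age(phy))
    phy$node.label <- as.character(
      sample(seq(support_range[1], support_range[2]), phy$Nnode, replace = TRUE)
    )
    phy
  })
}

#' Simulate a donor crown subtree with branch-rate noise
#'
#' A pure-birth chronogram scaled to `crown_age`, with each branch length
#' multiplied by an independent lognormal factor (`meanlog = 0`,
#' `sdlog = rate_noise_sigma`) to emulate an independently inferred,
#' non-clocklike source tree.  `rate_noise_sigma = 0` returns the exact
#' chronogram.  The noise-free node ages are returned alongside, so
#' smoothing accuracy can be measured against truth.
#'
#' @param n_tips Number of tips (>= 2).
#' @param crown_age True crown age in Ma.
#' @param rate_noise_sigma Lognormal sigma of the branch-rate noise (>= 0).
#' @param seed Integer seed.
#' @return List with `tree` (noisy `phylo`), `true_tree` (the exact
#'   chronogram) and `true_ages` (tibble `node`, `age` over all nodes).
#' @export
simulate_donor <- function(n_tips, crown_age, rate_noise_sigma = 0.1,
                           seed = NULL) {
  if (n_tips < 2) stop_fishtol("n_tips must be at least 2")
  if (crown_age <= 0) stop_fishtol("crown_age must be positive")
  if (rate_noise_sigma < 0) stop_fishtol("rate_noise_sigma must be >= 0")
  with_seed_maybe(seed, {
    phy <- ape::rphylo(n_tips, birth = 0.1, death = 0)
    phy$edge.length <- phy$edge.length * (crown_age / crown_age(phy))
    true_ages <- tibble(
      node = seq_len(n_tips + phy$Nnode),
      age = node_ages(phy)
    )
    noisy <- phy
    noisy$edge.length <- phy$edge.length *
      rlnorm(nrow(phy$edge), meanlog = 0, sdlog = rate_noise_sigma)
    list(tree = noisy, true_tree = phy, true_ages = true_ages)
  })
}

# --- clade partitioning -----------------------------------------------------

clade_tip_counts <- function(tree) {
  lengths(phangorn::Descendants(tree, seq_len(length(tree$tip.label) + tree$Nnode),
                                type = "tips"))
}

children_map <- function(tree) {
  split(tree$edge[, 2], tree$edge[, 1])
}

# Split the clade at `node` (and recursively its pieces) into `k` blocks,
# every block a clade (possibly a single tip -- monotypic taxa are real, but
# splits that leave a lone tip are taken only when nothing else is left).
# Random choices use the current RNG stream; the split picks a splittable
# block with probability proportional to its tip count, keeping block sizes
# roughly balanced.
split_clade_blocks <- function(tree, node, k, counts, kids) {
  ntip <- length(tree$tip.label)
  blocks <- node
  while (length(blocks) < k) {
    splittable <- blocks[blocks > ntip]
    if (!length(splittable)) {
      stop_fishtol(
        sprintf("cannot partition clade into %d blocks", k),
        class = "fishtol_infeasible_error"
      )
    }
    clean <- splittable[vapply(splittable, function(b) {
      all(counts[kids[[as.character(b)]]] >= 2)
    }, logical(1))]
    pool <- if (length(clean)) clean else splittable
    b <- if (length(pool) == 1) pool else sample(pool, 1, prob = counts[pool])
    blocks <- c(setdiff(blocks, b), kids[[as.character(b)]])
  }
  blocks
}

# Largest-remainder allocation of `total` units across blocks proportional
# to `weights`, respecting per-block minima and maxima.
allocate_units <- function(total, weights, minimum, maximum) {
  k <- length(weights)
  if (sum(minimum) > total || sum(maximum) < total) {
    stop_fishtol("infeasible allocation of taxa across clades",
                 class = "fishtol_infeasible_error")
  }
  alloc <- pmin(pmax(round(total * weights / sum(weights)), minimum), maximum)
  while (sum(alloc) != total) {
    if (sum(alloc) < total) {
      room <- which(alloc < maximum)
      i <- room[which.max(weights[room] / (alloc[room] + 1))]
      alloc[i] <- alloc[i] + 1
    } else {
      room <- which(alloc > minimum)
      i <- room[which.min(weights[room] / alloc[room])]
      alloc[i] <- alloc[i] - 1
    }
  }
  alloc
}

#' Plant a ranked taxonomy over a tree with known ground truth
#'
#' Partitions the leaves into `n_families` contiguous clades (monotypic
#' families are permitted, as in real classifications), relabels tips to the
#' `Family<i>_Genus<i>_sp<j>_C<t>` convention, and aggregates families into
#' suborders, orders, series and a division root with rank-conformant
#' suffixes.  Non-monophyly is planted
#' by swapping one tip label between `k_nonmono` disjoint pairs of
#' neighboring families -- a taxonomy-vs-tree conflict, exactly how real
#' non-monophyly manifests to the validator -- so each swap makes both
#' families of the pair non-monophyletic (the planted truth set has
#' `2 * k_nonmono` families).  `m_incertae` further families (disjoint from
#' the swapped ones) are re-parented from their order to the enclosing
#' series and flagged `incertae_sedis`.
#'
#' @param tree An ultrametric `phylo` (e.g. from [simulate_backbone()] or a
#'   grafted tree); its tip labels are replaced.
#' @param n_families Number of families (`2 * n_families <= Ntip`).
#' @param k_nonmono Number of swapped pairs (`2 * k_nonmono + m_incertae <=
#'   n_families`).
#' @param m_incertae Number of incertae sedis families.
#' @param n_series,n_orders,n_suborders Higher-rank counts; defaults scale
#'   with `n_families` roughly as in the bony-fish classification (about one
#'   series per 45 families, one order per 6, one suborder per 5).
#' @param seed Integer seed.
#' @return List with `tree` (relabeled), `taxonomy` (`fish_taxonomy`) and
#'   `truth`: `planted_nonmono`, `planted_incertae`, `clade_supports`
#'   (tibble of supra-family taxon supports read off the tree),
#'   `counts` (orders, suborders, families) and `seed`.
#' @export
#' @examples
#' sim <- plant_taxonomy(simulate_backbone(40, seed = 2), n_families = 6,
#'                       k_nonmono = 1, seed = 2)
#' sim$truth$planted_nonmono
plant_taxonomy <- function(tree, n_families, k_nonmono = 0, m_incertae = 0,
                           n_series = NULL, n_orders = NULL,
                           n_suborders = NULL, seed = NULL) {
  ntip <- length(tree$tip.label)
  if (2 * n_families > ntip) {
    stop_fishtol("n_families must be at most half the number of leaves",
                 class = "fishtol_infeasible_error")
  }
  if (k_nonmono >= n_families || 2 * k_nonmono + m_incertae > n_families) {
    stop_fishtol("infeasible k_nonmono / m_incertae for this n_families",
                 class = "fishtol_infeasible_error")
  }
  n_series <- n_series %||% max(1L, round(n_families / 45))
  n_orders <- n_orders %||% max(n_series, round(n_families / 6))
  n_suborders <- n_suborders %||% (2 * max(0L, round(n_families / 10)))
  if (n_orders < n_series || n_families < n_orders || n_suborders == 1) {
    stop_fishtol("need n_series <= n_orders <= n_families and n_suborders != 1",
                 class = "fishtol_infeasible_error")
  }

  with_seed_maybe(seed, {
    counts <- clade_tip_counts(tree)
    kids <- children_map(tree)
    root <- ntip + 1L
    pos <- preorder_positions(tree)

    series_nodes <- split_clade_blocks(tree, root, n_series, counts, kids)
    series_nodes <- series_nodes[order(pos[series_nodes])]

    ord_alloc <- allocate_units(
      n_orders, counts[series_nodes],
      minimum = rep(1, n_series),
      maximum = counts[series_nodes]
    )
    order_nodes <- integer(0)
    order_series <- integer(0)
    for (s in seq_along(series_nodes)) {
      blocks <- split_clade_blocks(tree, series_nodes[s], ord_alloc[s], counts, kids)
      order_nodes <- c(order_nodes, blocks)
      order_series <- c(order_series, rep(s, length(blocks)))
    }
    o <- order(pos[order_nodes])
    order_nodes <- order_nodes[o]
    order_series <- order_series[o]

    # Subdivide some orders into suborders until the requested total is hit;
    # each subdivided order contributes >= 2 (one gets 3 when the target is
    # odd).  Family leaves then hang off suborders where they exist,
    # otherwise directly off their order.
    sub_nodes <- integer(0)
    sub_order <- integer(0)
    leaf_nodes <- order_nodes         # blocks families are carved from
    leaf_order <- seq_along(order_nodes)
    leaf_sub <- rep(NA_integer_, length(order_nodes))
    remaining <- n_suborders
    divisible <- seq_along(order_nodes)
    while (remaining > 0) {
      # every subdivided order contributes >= 2 suborders; an odd target gets
      # one 3-way split first so the remainder stays even
      k <- if (remaining %% 2 == 1) 3 else 2
      cand <- divisible[vapply(divisible, function(i) {
        ch <- kids[[as.character(order_nodes[i])]]
        !is.null(ch) && length(ch) >= 2
      }, logical(1))]
      if (length(cand) > 1) cand <- sample(cand)
      blocks <- NULL
      for (i in cand) {
        blocks <- tryCatch(
          split_clade_blocks(tree, order_nodes[i], k, counts, kids),
          fishtol_infeasible_error = function(e) NULL
        )
        if (!is.null(blocks)) break
      }
      if (is.null(blocks)) {
        stop_fishtol("cannot place the requested number of suborders",
                     class = "fishtol_infeasible_error")
      }
      blocks <- blocks[order(pos[blocks])]
      idx <- length(sub_nodes) + seq_along(blocks)
      sub_nodes <- c(sub_nodes, blocks)
      sub_order <- c(sub_order, rep(i, length(blocks)))
      drop <- which(leaf_order == i & is.na(leaf_sub))
      leaf_nodes <- c(leaf_nodes[-drop], blocks)
      leaf_order <- c(leaf_order[-drop], rep(i, length(blocks)))
      leaf_sub <- c(leaf_sub[-drop], idx)
      divisible <- setdiff(divisible, i)
      remaining <- remaining - k
    }
    o <- order(pos[leaf_nodes])
    leaf_nodes <- leaf_nodes[o]
    leaf_order <- leaf_order[o]
    leaf_sub <- leaf_sub[o]

    fam_alloc <- allocate_units(
      n_families, counts[leaf_nodes],
      minimum = rep(1, length(leaf_nodes)),
      maximum = counts[leaf_nodes]
    )
    fam_nodes <- integer(0)
    fam_leaf <- integer(0)
    for (b in seq_along(leaf_nodes)) {
      blocks <- if (fam_alloc[b] == 1) leaf_nodes[b] else {
        split_clade_blocks(tree, leaf_nodes[b], fam_alloc[b], counts, kids)
      }
      blocks <- blocks[order(pos[blocks])]
      fam_nodes <- c(fam_nodes, blocks)
      fam_leaf <- c(fam_leaf, rep(b, length(blocks)))
    }

    # Relabel tips family by family.
    desc <- phangorn::Descendants(tree, fam_nodes, type = "tips")
    new_labels <- tree$tip.label
    for (f in seq_along(fam_nodes)) {
      tips <- sort(desc[[f]])
      new_labels[tips] <- sprintf("Family%d_Genus%d_sp%d_C%d",
                                  f, f, seq_along(tips), tips)
    }
    out_tree <- tree
    out_tree$tip.label <- new_labels

    # Plant non-monophyly: swap one tip label between adjacent families.
    fam_sizes <- lengths(desc)
    pair_ok <- which(fam_sizes[-length(fam_nodes)] >= 2 & fam_sizes[-1] >= 2)
    planted_nonmono <- character(0)
    if (k_nonmono > 0) {
      # leftmost-first gives a maximum disjoint set of adjacent pairs; the
      # planted pairs are a random subset of it
      maxset <- integer(0)
      last <- -2L
      for (p in sort(pair_ok)) {
        if (p > last + 1L) {
          maxset <- c(maxset, p)
          last <- p
        }
      }
      if (length(maxset) < k_nonmono) {
        stop_fishtol(
          "not enough disjoint neighboring family pairs to plant non-monophyly",
          class = "fishtol_infeasible_error"
        )
      }
      chosen <- if (length(maxset) == 1) maxset else sample(maxset, k_nonmono)
      for (p in sort(chosen)) {
        a <- sample(desc[[p]], 1)
        b <- sample(desc[[p + 1]], 1)
        tmp <- out_tree$tip.label[a]
        out_tree$tip.label[a] <- out_tree$tip.label[b]
        out_tree$tip.label[b] <- tmp
        planted_nonmono <- c(planted_nonmono,
                             sprintf("Family%d", c(p, p + 1)))
      }
      planted_nonmono <- sort(unique(planted_nonmono))
    }

    # Taxonomy rows in classification order.
    division <- "Synthopterygii"
    rows <- list(tibble(name = division, rank = "division", parent = "",
                        flags = ""))
    sup <- node_support(tree)
    clade_sup <- list()
    swap_pair_fams <- planted_nonmono
    incertae_pool <- setdiff(seq_along(fam_nodes),
                             which(sprintf("Family%d", seq_along(fam_nodes)) %in%
                                     swap_pair_fams))
    # never take the last family of a suborder/order, so no supra-family
    # taxon is emptied by the re-parenting
    parent_key <- ifelse(is.na(leaf_sub[fam_leaf]),
                         paste0("O", leaf_order[fam_leaf]),
                         paste0("S", leaf_sub[fam_leaf]))
    fam_count <- table(parent_key)
    incertae <- integer(0)
    if (m_incertae > 0) {
      for (f in sample(incertae_pool)) {
        if (length(incertae) == m_incertae) break
        if (fam_count[[parent_key[f]]] >= 2) {
          incertae <- c(incertae, f)
          fam_count[[parent_key[f]]] <- fam_count[[parent_key[f]]] - 1
        }
      }
      if (length(incertae) < m_incertae) {
        stop_fishtol("cannot place the requested incertae sedis families",
                     class = "fishtol_infeasible_error")
      }
      incertae <- sort(incertae)
    }

    for (s in seq_along(series_nodes)) {
      ser_name <- sprintf("Ser%daria", s)
      rows[[length(rows) + 1]] <- tibble(name = ser_name, rank = "series",
                                         parent = division, flags = "")
      clade_sup[[length(clade_sup) + 1]] <-
        tibble(name = ser_name, node = series_nodes[s],
               support = sup[series_nodes[s] - ntip])
      for (i in which(order_series == s)) {
        ord_name <- sprintf("Ord%diformes", i)
        rows[[length(rows) + 1]] <- tibble(name = ord_name, rank = "order",
                                           parent = ser_name, flags = "")
        clade_sup[[length(clade_sup) + 1]] <-
          tibble(name = ord_name, node = order_nodes[i],
                 support = sup[order_nodes[i] - ntip])
        for (j in which(sub_order == i)) {
          sub_name <- sprintf("Sub%doidei", j)
          rows[[length(rows) + 1]] <- tibble(name = sub_name, rank = "suborder",
                                             parent = ord_name, flags = "")
          clade_sup[[length(clade_sup) + 1]] <-
            tibble(name = sub_name, node = sub_nodes[j],
                   support = sup[sub_nodes[j] - ntip])
        }
        for (f in which(fam_leaf %in% which(leaf_order == i))) {
          b <- fam_leaf[f]
          fam_parent <- if (is.na(leaf_sub[b])) ord_name else {
            sprintf("Sub%doidei", leaf_sub[b])
          }
          is_incertae <- f %in% incertae
          rows[[length(rows) + 1]] <- tibble(
            name = sprintf("Family%d", f), rank = "family",
            parent = if (is_incertae) ser_name else fam_parent,
            flags = if (is_incertae) "incertae_sedis" else ""
          )
        }
      }
    }

    taxonomy <- load_taxonomy(bind_rows(rows))
    truth <- list(
      planted_nonmono = planted_nonmono,
      planted_incertae = sprintf("Family%d", incertae),
      clade_supports = bind_rows(clade_sup),
      counts = c(orders = length(order_nodes),
                 suborders = length(sub_nodes),
                 families = length(fam_nodes)),
      seed = seed
    )
    list(tree = out_tree, taxonomy = taxonomy, truth = truth)
  })
}

#' Study-scale synthetic preset
#'
#' An end-to-end fixture at the scale of the published bony-fish time tree:
#' a calibrated backbone, four taxonomically dense donor clades grafted at
#' their backbone crown ages, and a planted taxonomy of 410 families in 72
#' orders, 79 suborders and 9 series with 30 incertae sedis families and
#' 12 planted label-swap pairs.  Everything derives deterministically from
#' `seed`.
#'
#' @param seed Integer seed.
#' @param n_total Total tips of the grafted tree (default 1990).
#' @param n_backbone Backbone tips before grafting.
#' @param rate_noise_sigma Donor branch-rate noise.
#' @param n_families,n_orders,n_suborders,n_series,k_nonmono,m_incertae
#'   Taxonomy shape; defaults mirror the published classification's totals.
#' @return List with `tree`, `taxonomy`, `truth`, `backbone`, `donor_sizes`.
#' @export
simulate_study <- function(seed, n_total = 1990, n_backbone = 420,
                           rate_noise_sigma = 0.1, n_families = 410,
                           n_orders = 72, n_suborders = 79, n_series = 9,
                           k_nonmono = 12, m_incertae = 30) {
  backbone <- simulate_backbone(n_backbone, seed = seed)
  counts <- clade_tip_counts(backbone)
  ntip <- length(backbone$tip.label)

  # Four disjoint donor slots of moderate size, picked deterministically.
  slot_nodes <- withr::with_seed(seed + 1L, {
    cand <- which(counts >= 6 & counts <= 40 & seq_along(counts) > ntip)
    chosen <- integer(0)
    for (nd in sample(cand)) {
      tips_nd <- phangorn::Descendants(backbone, nd, "tips")[[1]]
      taken <- unlist(lapply(chosen, function(c0) {
        phangorn::Descendants(backbone, c0, "tips")[[1]]
      }))
      if (!length(intersect(tips_nd, taken))) chosen <- c(chosen, nd)
      if (length(chosen) == 4) break
    }
    if (length(chosen) < 4) {
      stop_fishtol("could not find four disjoint donor slots")
    }
    chosen
  })
  slot_sizes <- counts[slot_nodes]
  donor_total <- n_total - ntip + sum(slot_sizes)
  donor_sizes <- allocate_units(
    donor_total, c(0.2, 0.25, 0.4, 0.15),
    minimum = rep(2, 4), maximum = rep(donor_total, 4)
  )

  tree <- backbone
  for (i in seq_len(4)) {
    slot_tips <- backbone$tip.label[
      phangorn::Descendants(backbone, slot_nodes[i], "tips")[[1]]
    ]
    donor <- simulate_donor(donor_sizes[i], crown_age = 100,
                            rate_noise_sigma = rate_noise_sigma,
                            seed = seed + 1L + i)
    donor$tree$tip.label <- sprintf("d%d_%s", i, donor$tree$tip.label)
    smoothed <- smooth_to_ultrametric(donor$tree)
    tree <- graft_clade(tree, slot_tips, smoothed, crown_age = NULL)
  }

  planted <- plant_taxonomy(tree, n_families = n_families,
                            k_nonmono = k_nonmono, m_incertae = m_incertae,
                            n_series = n_series, n_orders = n_orders,
                            n_suborders = n_suborders, seed = seed + 7L)
  c(planted, list(backbone = backbone, donor_sizes = donor_sizes))
}

#' Node-age recovery of the mean-path smoother under rate noise
#'
#' For each noise level, simulates donors with known true node ages,
#' smooths the noisy trees, rescales them to the true crown age, and
#' records the root-mean-square error of recovered internal-node ages.
#'
#' @param sigmas Noise levels to sweep.
#' @param n_seeds Replicates per level.
#' @param n_tips Donor size.
#' @param crown_age True crown age in Ma.
#' @param seed Base seed; replicate `r` of level `s` uses
#'   `seed + 1000 * s + r`.
#' @return A tibble (`sigma`, `seed`, `rmse`) of class
#'   `age_recovery`; `autoplot()` draws the recovery curve.
#' @export
age_recovery_experiment <- function(sigmas = c(0, 0.05, 0.1, 0.3),
                                    n_seeds = 100, n_tips = 20,
                                    crown_age = 100, seed = 1) {
  grid <- tidyr::expand_grid(s = seq_along(sigmas), r = seq_len(n_seeds))
  res <- purrr::pmap_dfr(grid, function(s, r) {
    sd_seed <- seed + 1000L * s + r
    don <- simulate_donor(n_tips, crown_age, rate_noise_sigma = sigmas[s],
                          seed = sd_seed)
    sm <- rescale_to_age(smooth_to_ultrametric(don$tree), crown_age)
    internal <- (n_tips + 1):(n_tips + don$tree$Nnode)
    err <- node_ages(sm)[internal] - don$true_ages$age[internal]
    tibble(sigma = sigmas[s], seed = sd_seed, rmse = sqrt(mean(err^2)))
  })
  class(res) <- c("age_recovery", class(res))
  res
}

#' @rdname age_recovery_experiment
#' @param object An `age_recovery` tibble.
#' @param ... Unused.
#' @export
autoplot.age_recovery <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$sigma), y = .data$rmse)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "branch-rate noise sigma (lognormal)",
                  y = "internal node-age RMSE (Myr)") +
    ggplot2::theme_minimal()
}
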