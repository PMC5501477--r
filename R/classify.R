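# Rendering the validated taxonomy as the ranked classification:
# phylogenetic order down to the subordinal rank, families alphabetical
# within their parent, plus the summary counts.

# Preorder first-visit position of every node under the stored child order.
preorder_positions <- function(tree) {
  ntip <- length(tree$tip.label)
  ro <- ape::reorder.phylo(tree, "cladewise")
  visit <- c(ntip + 1L, ro$edge[, 2])
  pos <- integer(ntip + tree$Nnode)
  pos[visit] <- seq_along(visit)
  pos
}

#' Order taxa by the branching order of the tree
#'
#' Supra-family taxa are emitted in the order their MRCA nodes are first
#' reached by a depth-first preorder traversal of the tree with its stored
#' child order; ties (two taxa attaching to the same node, as happens at
#' polytomies) break by older crown age first, then alphabetically.
#' Unsampled taxa are inserted immediately after the sibling named in their
#' `anchor` column.  Families are listed alphabetically under their parent;
#' a parent's family block (e.g. the order-level incertae sedis families of
#' a series) precedes its ranked children, matching the printed layout of
#' the classification.
#'
#' @param taxonomy A `fish_taxonomy` tibble.
#' @param tree A `phylo` whose tips follow the `Family_Genus_species_Code`
#'   convention, or `NULL` to keep taxonomy row order among ranked siblings.
#' @param report Optional `monophyly_report` from [validate_all()] (computed
#'   on the fly when omitted and a tree is given).
#' @return A tibble (`name`, `rank`, `parent`, `depth`) in classification
#'   order: every parent precedes its children.
#' @export
phylogenetic_order <- function(taxonomy, tree = NULL, report = NULL) {
  n <- nrow(taxonomy)
  pos <- rep(NA_real_, n)
  age <- rep(NA_real_, n)

  if (!is.null(tree)) {
    if (is.null(report)) {
      report <- validate_all(taxonomy, tree, on_missing_family = "warn")
    }
    ppos <- preorder_positions(tree)
    ages <- node_ages(tree)
    hit <- !is.na(report$taxa$mrca)
    pos[hit] <- ppos[report$taxa$mrca[hit]]
    age[hit] <- ages[report$taxa$mrca[hit]]
  } else {
    pos <- seq_len(n)  # taxonomy row order
    age <- rep(0, n)
  }

  kids_of <- split(seq_len(n), factor(taxonomy$parent,
                                      levels = unique(c("", taxonomy$parent))))
  order_siblings <- function(idx) {
    if (!length(idx)) return(integer(0))
    fam <- idx[taxonomy$rank[idx] == "family"]
    oth <- idx[taxonomy$rank[idx] != "family"]
    fam <- fam[order(taxonomy$name[fam])]
    sampled <- oth[!is.na(pos[oth])]
    sampled <- sampled[order(pos[sampled], -age[sampled], taxonomy$name[sampled])]
    unsampled <- setdiff(oth, sampled)
    out <- sampled
    for (u in unsampled) {
      anc <- taxonomy$anchor[u]
      at <- match(anc, taxonomy$name[out])
      if (!nzchar(anc) || is.na(at)) {
        stop_fishtol(
          sprintf(
            "taxon '%s' has no MRCA in the tree and no sibling anchor to place it",
            taxonomy$name[u]
          ),
          class = "fishtol_order_error"
        )
      }
      out <- append(out, u, after = at)
    }
    c(fam, out)
  }

  emit <- integer(0)
  depth <- integer(n)
  walk <- function(idx, d) {
    for (i in order_siblings(idx)) {
      emit <<- c(emit, i)
      depth[i] <<- d
      kids <- kids_of[[taxonomy$name[i]]]
      if (!is.null(kids)) walk(kids, d + 1L)
    }
  }
  roots <- which(!nzchar(taxonomy$parent))
  walk(roots, 0L)

  tibble(
    name = taxonomy$name[emit],
    rank = taxonomy$rank[emit],
    parent = taxonomy$parent[emit],
    depth = depth[emit]
  )
}

format_support <- function(s) {
  if (is.na(s)) return("")
  if (abs(s - round(s)) < 1e-9) sprintf(" (%d%%)", as.integer(round(s))) else sprintf(" (%.3g%%)", s)
}

#' Render the ranked classification
#'
#' Produces the indented text classification (rank prefix, two-space indent
#' per depth, support percentages after supra-family names when available,
#' non-monophyly and incertae-sedis notes, quoted provisional names) plus a
#' flat taxonomy table that round-trips through [load_taxonomy()], and the
#' counts summary.
#'
#' @inheritParams phylogenetic_order
#' @return A `classification` object: list with `entries` (ordered tibble
#'   with a rendered `text` column), `lines` (the text serialization),
#'   `taxonomy` (reordered `fish_taxonomy`) and `counts` (see
#'   [counts_summary()]).
#' @seealso [write_classification()]
#' @export
render_classification <- function(taxonomy, tree = NULL, report = NULL) {
  if (!is.null(tree) && is.null(report)) {
    report <- validate_all(taxonomy, tree, on_missing_family = "warn")
  }
  ord <- phylogenetic_order(taxonomy, tree, report)
  ridx <- match(paste(ord$name, ord$rank), paste(taxonomy$name, taxonomy$rank))
  tax_ord <- taxonomy[ridx, ]
  tax_ord$row <- seq_len(nrow(tax_ord))
  class(tax_ord) <- c("fish_taxonomy", class(tibble()))

  rep_idx <- if (!is.null(report)) {
    match(paste(ord$name, ord$rank), paste(report$taxa$name, report$taxa$rank))
  } else {
    rep(NA_integer_, nrow(ord))
  }

  lines <- character(nrow(ord))
  for (i in seq_len(nrow(ord))) {
    fl <- tax_ord$flags[[i]]
    nm <- ord$name[i]
    if ("provisional" %in% fl) nm <- paste0("\"", nm, "\"")
    notes <- ""
    if (ord$rank[i] != "family" && !is.na(rep_idx[i])) {
      notes <- paste0(notes, format_support(report$taxa$mrca_support[rep_idx[i]]))
    }
    non_mono <- "non_monophyletic_declared" %in% fl ||
      (!is.na(rep_idx[i]) && report$taxa$status[rep_idx[i]] == "non_monophyletic")
    if (non_mono) notes <- paste0(notes, " (not monophyletic)")
    if ("incertae_sedis" %in% fl) {
      anc <- taxon_ancestors(taxonomy, ord$name[i])
      ser <- anc[taxonomy$rank[match(anc, taxonomy$name)] == "series"][1]
      notes <- paste0(notes, sprintf(" (incertae sedis in %s)", ser))
    }
    if ("sedis_mutabilis" %in% fl) notes <- paste0(notes, " (sedis mutabilis)")
    if ("not_examined" %in% fl ||
        (!is.na(rep_idx[i]) && report$taxa$status[rep_idx[i]] == "unsampled")) {
      notes <- paste0(notes, " (not examined)")
    }
    rank_lab <- paste0(toupper(substring(ord$rank[i], 1, 1)),
                       substring(ord$rank[i], 2))
    lines[i] <- paste0(strrep("  ", ord$depth[i]), rank_lab, " ", nm, notes)
  }

  structure(
    list(
      entries = mutate(ord, text = lines),
      lines = lines,
      taxonomy = tax_ord,
      counts = counts_summary(taxonomy, report)
    ),
    class = "classification"
  )
}

#' @export
print.classification <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}

#' Write a rendered classification to disk
#'
#' Three files: `classification.txt` (indented text),
#' `classification.tsv` (flat table; `load_taxonomy()` reads it back) and
#' `counts.json`.
#'
#' @param x A `classification` from [render_classification()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_classification <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(x$lines, file.path(dir, "classification.txt"), useBytes = TRUE)
  write_taxonomy(x$taxonomy, file.path(dir, "classification.tsv"))
  jsonlite::write_json(as.list(x$counts), file.path(dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Summary counts of a classification
#'
#' Counts orders, suborders, series and families; when a
#' [validate_all()] report is supplied, examined/unexamined and
#' non-monophyletic families are taken from tree sampling status, otherwise
#' from the `not_examined` and `non_monophyletic_declared` flags.  Incertae
#' sedis families are counted over all families carrying the flag,
#' including not-examined ones attached to a series.
#'
#' @inheritParams phylogenetic_order
#' @param report Optional `monophyly_report`.
#' @return A one-row tibble: `orders`, `suborders`, `series_count`,
#'   `families_total`, `families_examined`, `families_unexamined`,
#'   `families_non_monophyletic`, `incertae_sedis_families`.
#' @export
#' @examples
#' tax <- load_taxonomy(fishtol_example("percomorph_classification.tsv"))
#' counts_summary(tax)
counts_summary <- function(taxonomy, report = NULL) {
  isf <- taxonomy$rank == "family"
  has_flag <- function(flag) {
    vapply(taxonomy$flags, function(f) flag %in% f, logical(1))
  }
  if (!is.null(report)) {
    fam_rep <- report$taxa[report$taxa$rank == "family", ]
    st <- fam_rep$status[match(taxonomy$name[isf], fam_rep$name)]
    examined <- sum(st != "unsampled")
    nonmono <- sum(st == "non_monophyletic")
  } else {
    examined <- sum(isf & !has_flag("not_examined"))
    nonmono <- sum(isf & has_flag("non_monophyletic_declared"))
  }
  tibble(
    orders = sum(taxonomy$rank == "order"),
    suborders = sum(taxonomy$rank == "suborder"),
    series_count = sum(taxonomy$rank == "series"),
    families_total = sum(isf),
    families_examined = examined,
    families_unexamined = sum(isf) - examined,
    families_non_monophyletic = nonmono,
    incertae_sedis_families = sum(isf & has_flag("incertae_sedis"))
  )
}

#' Incertae sedis families grouped by their series
#'
#' @param taxonomy A `fish_taxonomy` tibble.
#' @return A tibble (`series`, `n`, `families` list-column) with one row per
#'   series that hosts order-level incertae sedis families.
#' @export
#' @examples
#' tax <- load_taxonomy(fishtol_example("percomorph_classification.tsv"))
#' incertae_sedis_summary(tax)
incertae_sedis_summary <- function(taxonomy) {
  isf <- taxonomy$rank == "family" &
    vapply(taxonomy$flags, function(f) "incertae_sedis" %in% f, logical(1))
  fams <- taxonomy$name[isf]
  ser <- vapply(fams, function(nm) {
    anc <- taxon_ancestors(taxonomy, nm)
    ranks <- taxonomy$rank[match(anc, taxonomy$name)]
    hit <- which(ranks == "series")
    if (length(hit)) anc[hit[1]] else NA_character_
  }, character(1))
  df <- tibble(family = fams, series = unname(ser))
  out <- summarise(group_by(df, .data$series),
                   n = dplyr::n(),
                   families = list(sort(.data$family)))
  arrange(as_tibble(out), .data$series)
}

#' Provisional (quoted) family names
#'
#' @param taxonomy A `fish_taxonomy` tibble.
#' @return Sorted character vector of families flagged `provisional`.
#' @export
provisional_families <- function(taxonomy) {
  isf <- taxonomy$rank == "family" &
    vapply(taxonomy$flags, function(f) "provisional" %in% f, logical(1))
  sort(taxonomy$name[isf])
}
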