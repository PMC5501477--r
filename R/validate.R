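# Monophyly assessment of named taxa against the grafted chronogram, MRCA
# support extraction, and the endorsement rule for order-level and
# supraordinal taxa.

#' Assess monophyly of a tip set
#'
#' A taxon is monophyletic when the most recent common ancestor (MRCA) of
#' its sampled tips contains exactly those tips; any other leaf below the
#' MRCA is an intruder.  Zero tips give status `"unsampled"`, a single tip
#' `"monotypic"` (both trivially intruder-free).
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (may be empty).
#' @return A list with `status` (one of `"monophyletic"`,
#'   `"non_monophyletic"`, `"monotypic"`, `"unsampled"`), `intruders`
#'   (lexicographically sorted character vector), `mrca` (node id or `NA`)
#'   and `n_tips`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' assess_monophyly(tr, c("A", "C"))$intruders
assess_monophyly <- function(tree, tips) {
  tips <- unique(tips)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop_fishtol(paste0("tips not in tree: ", paste(missing, collapse = ", ")),
                 class = "fishtol_validation_error")
  }
  if (length(tips) == 0) {
    return(list(status = "unsampled", intruders = character(0),
                mrca = NA_integer_, n_tips = 0L))
  }
  if (length(tips) == 1) {
    return(list(status = "monotypic", intruders = character(0),
                mrca = match(tips, tree$tip.label), n_tips = 1L))
  }
  m <- ape::getMRCA(tree, tips)
  clade <- tree$tip.label[phangorn::Descendants(tree, m, "tips")[[1]]]
  intr <- sort(setdiff(clade, tips))
  list(
    status = if (length(intr)) "non_monophyletic" else "monophyletic",
    intruders = intr,
    mrca = m,
    n_tips = length(tips)
  )
}

#' Bootstrap support at the MRCA of a tip set
#'
#' @inheritParams assess_monophyly
#' @param tips Character vector of at least two tip labels.
#' @return The support percentage stored at the MRCA node, or `NA` when the
#'   node is unlabeled or carries a clade-name annotation.
#' @export
support_at_mrca <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop_fishtol(paste0("tips not in tree: ", paste(missing, collapse = ", ")),
                 class = "fishtol_validation_error")
  }
  if (length(unique(tips)) < 2) {
    stop_fishtol("support_at_mrca() needs at least two distinct tips")
  }
  m <- ape::getMRCA(tree, unique(tips))
  node_support(tree)[m - length(tree$tip.label)]
}

#' Endorsement decision for an order-level or supraordinal taxon
#'
#' The endorsement rule: a monophyletic taxon whose MRCA bootstrap exceeds
#' 90 percent (strictly) is `"endorsed"`; a monophyletic taxon with lower or
#' absent support, or a non-monophyletic taxon whose incongruence is not
#' substantially rejected, can be `"endorsed_by_corroboration"` when the
#' taxonomy asserts consistent recovery by independent studies
#' (`corroborated` flag); anything else is `"not_endorsed"`.  Monotypic and
#' unsampled taxa are `"not_applicable"` -- there is no clade to support.
#'
#' @param status Monophyly status from [assess_monophyly()].
#' @param support MRCA bootstrap percentage, or `NA` when absent.
#' @param corroborated Logical: does the taxonomy carry the `corroborated`
#'   flag for this taxon?
#' @return One of `"endorsed"`, `"endorsed_by_corroboration"`,
#'   `"not_endorsed"`, `"not_applicable"`.  Vectorized over its arguments.
#' @export
#' @examples
#' endorse_taxon("monophyletic", 100, FALSE)
#' endorse_taxon("monophyletic", 42, TRUE)
endorse_taxon <- function(status, support, corroborated = FALSE) {
  n <- max(length(status), length(support), length(corroborated))
  status <- rep_len(status, n)
  support <- rep_len(support, n)
  corroborated <- rep_len(corroborated, n)
  vapply(seq_len(n), function(i) {
    s <- status[[i]]
    if (s == "monophyletic") {
      if (!is.na(support[[i]]) && support[[i]] > 90) return("endorsed")
      if (isTRUE(corroborated[[i]])) return("endorsed_by_corroboration")
      return("not_endorsed")
    }
    if (s == "non_monophyletic") {
      if (isTRUE(corroborated[[i]])) return("endorsed_by_corroboration")
      return("not_endorsed")
    }
    "not_applicable"
  }, character(1))
}

# Descendant family names per taxonomy row (transitive closure down the
# parent links).
taxonomy_family_map <- function(taxonomy) {
  pidx <- match(taxonomy$parent, taxonomy$name)
  fam_rows <- which(taxonomy$rank == "family")
  out <- vector("list", nrow(taxonomy))
  for (i in seq_len(nrow(taxonomy))) out[[i]] <- character(0)
  for (i in fam_rows) {
    out[[i]] <- taxonomy$name[i]
    j <- i
    while (nzchar(taxonomy$parent[j])) {
      j <- pidx[j]
      out[[j]] <- c(out[[j]], taxonomy$name[i])
    }
  }
  out
}

#' Validate every named taxon against a tree
#'
#' Derives each family's tip set from the parsed tip labels (first label
#' token = family) and each higher taxon's tip set as the union over its
#' descendant families, then assesses monophyly, extracts MRCA support and
#' applies the endorsement rule ([endorse_taxon()]) to every order-level and
#' supraordinal taxon.  Families are exempt from endorsement
#' (`"not_applicable"`): they are only flagged monophyletic or not.  Tips
#' whose family is absent from the taxonomy (e.g. outgroups) are excluded
#' from all unions and reported separately.
#'
#' @param taxonomy A `fish_taxonomy` tibble (see [load_taxonomy()]).
#' @param tree A `phylo` whose tip labels follow the
#'   `Family_Genus_species_Code` convention.
#' @param on_missing_family `"warn"` (default) or `"error"` when tip
#'   families are absent from the taxonomy.
#' @return A `monophyly_report`: list with `taxa` (tibble: one row per
#'   taxon with `name`, `rank`, `n_tips_sampled`, `status`, `mrca_support`,
#'   `intruders` list-column, `mrca`, `endorsement`), `summary` (family and
#'   incertae-sedis counters) and `outgroup_tips`.  Use [tidy()] /
#'   [glance()] to extract the per-taxon table or the one-row summary.
#' @export
validate_all <- function(taxonomy, tree,
                         on_missing_family = c("warn", "error")) {
  on_missing_family <- match.arg(on_missing_family)
  ann <- parse_tip_label(tree$tip.label)
  fam_names <- taxonomy$name[taxonomy$rank == "family"]

  foreign <- !ann$family %in% fam_names
  outgroup_tips <- ann$label[foreign]
  missing_fams <- sort(unique(ann$family[foreign]))
  if (length(missing_fams)) {
    msg <- paste0("tip families absent from the taxonomy (treated as ",
                  "outgroups): ", paste(missing_fams, collapse = ", "))
    if (on_missing_family == "error") {
      stop_fishtol(msg, class = "fishtol_validation_error")
    }
    warn(msg)
  }

  tips_by_family <- split(ann$label[!foreign], ann$family[!foreign])
  fam_map <- taxonomy_family_map(taxonomy)

  n <- nrow(taxonomy)
  status <- character(n)
  support <- rep(NA_real_, n)
  intruders <- vector("list", n)
  mrca <- rep(NA_integer_, n)
  n_tips <- integer(n)
  sup_all <- node_support(tree)
  ntip <- length(tree$tip.label)

  for (i in seq_len(n)) {
    tips <- unlist(tips_by_family[fam_map[[i]]], use.names = FALSE)
    res <- assess_monophyly(tree, tips %||% character(0))
    status[i] <- res$status
    intruders[[i]] <- res$intruders
    mrca[i] <- res$mrca
    n_tips[i] <- res$n_tips
    if (res$n_tips >= 2) support[i] <- sup_all[res$mrca - ntip]
  }

  corro <- vapply(taxonomy$flags, function(f) "corroborated" %in% f, logical(1))
  endorsement <- endorse_taxon(status, support, corro)
  endorsement[taxonomy$rank == "family"] <- "not_applicable"

  taxa <- tibble(
    name = taxonomy$name,
    rank = taxonomy$rank,
    n_tips_sampled = n_tips,
    status = status,
    mrca_support = support,
    intruders = intruders,
    mrca = mrca,
    endorsement = endorsement
  )

  isf <- taxonomy$rank == "family"
  is_is <- vapply(taxonomy$flags, function(f) "incertae_sedis" %in% f, logical(1))
  is_fams <- taxonomy$name[isf & is_is]
  series_of <- vapply(is_fams, function(nm) {
    anc <- taxon_ancestors(taxonomy, nm)
    ranks <- taxonomy$rank[match(anc, taxonomy$name)]
    hit <- which(ranks == "series")
    if (length(hit)) anc[hit[1]] else NA_character_
  }, character(1))
  incertae <- tibble(family = is_fams, series = unname(series_of))

  summary <- list(
    families_total = sum(isf),
    families_examined = sum(isf & status != "unsampled"),
    families_unexamined = sum(isf & status == "unsampled"),
    families_non_monophyletic = sum(isf & status == "non_monophyletic"),
    families_monotypic = sum(isf & status == "monotypic"),
    incertae_sedis_families = nrow(incertae),
    incertae_sedis_by_series = incertae
  )

  structure(
    list(taxa = taxa, summary = summary, outgroup_tips = outgroup_tips,
         n_tree_tips = ntip),
    class = "monophyly_report"
  )
}

#' @export
print.monophyly_report <- function(x, ...) {
  s <- x$summary
  cat("Monophyly report:", nrow(x$taxa), "taxa against a",
      x$n_tree_tips, "tip tree\n")
  cat(sprintf(
    "  families: %d total, %d examined, %d unexamined, %d non-monophyletic\n",
    s$families_total, s$families_examined, s$families_unexamined,
    s$families_non_monophyletic
  ))
  cat(sprintf("  incertae sedis families: %d; outgroup tips: %d\n",
              s$incertae_sedis_families, length(x$outgroup_tips)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-taxon monophyly table
#'
#' @param x A `monophyly_report`.
#' @param ... Unused.
#' @return The per-taxon tibble (one row per named taxon).
#' @export
tidy.monophyly_report <- function(x, ...) x$taxa

#' One-row summary of a monophyly report
#'
#' @inheritParams tidy.monophyly_report
#' @return A one-row tibble of the family counters.
#' @export
glance.monophyly_report <- function(x, ...) {
  s <- x$summary
  tibble(
    families_total = s$families_total,
    families_examined = s$families_examined,
    families_unexamined = s$families_unexamined,
    families_non_monophyletic = s$families_non_monophyletic,
    families_monotypic = s$families_monotypic,
    incertae_sedis_families = s$incertae_sedis_families,
    outgroup_tips = length(x$outgroup_tips)
  )
}

#' Plot a monophyly report
#'
#' Stacked counts of monophyly status per rank.
#'
#' @param object A `monophyly_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.monophyly_report <- function(object, ...) {
  df <- object$taxa
  df$rank <- factor(df$rank, levels = FISHTOL_RANKS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "taxa", fill = "monophyly") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
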