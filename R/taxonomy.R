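# The ranked taxonomy model: loading/writing the classification table,
# hierarchy checks, and rank-ending lint.

FISHTOL_FLAGS <- c(
  "provisional", "incertae_sedis", "not_examined", "corroborated",
  "sedis_mutabilis", "non_monophyletic_declared"
)

strip_name_quotes <- function(x) {
  gsub('^["“”]+|["“”]+$', "", x)
}

#' Load a ranked taxonomy table
#'
#' Reads the classification table (TSV with header columns `name`, `rank`,
#' `parent`, `flags`, optionally `anchor`) or validates an equivalent data
#' frame.  Names surrounded by quotation marks denote provisional taxa that
#' await formal description; the quotes are stripped and the `provisional`
#' flag set.  `flags` is a semicolon-separated subset of `provisional`,
#' `incertae_sedis`, `not_examined`, `corroborated`, `sedis_mutabilis`,
#' `non_monophyletic_declared`.  `anchor` names the sibling taxon after
#' which an unsampled taxon is placed when ordering the classification.
#'
#' Validation enforces: known ranks (see [rank_levels()]); unique
#' (name, rank) pairs; resolvable, acyclic parent links of equal-or-higher
#' rank; and that every family descends from an order, or carries
#' `incertae_sedis` and descends from a series.
#'
#' @param x Path to a TSV file, or a data frame with the columns above.
#' @return A `fish_taxonomy` tibble with columns `name`, `rank`, `parent`,
#'   `flags` (list of character vectors), `anchor`, `row` (source row,
#'   kept as the ordering tiebreak).
#' @export
#' @examples
#' tax <- load_taxonomy(tibble::tibble(
#'   name = c("Perciformes", "Percoidei", "Percidae"),
#'   rank = c("order", "suborder", "family"),
#'   parent = c("", "Perciformes", "Percoidei"),
#'   flags = ""
#' ))
#' tax
load_taxonomy <- function(x) {
  if (is.character(x) && length(x) == 1) {
    raw <- readr::read_tsv(
      x, col_types = readr::cols(.default = "c"),
      quote = "", na = character(), progress = FALSE
    )
  } else if (is.data.frame(x)) {
    raw <- as_tibble(x)
    raw[] <- lapply(raw, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    })
  } else {
    stop_fishtol("load_taxonomy() needs a file path or a data frame")
  }

  need <- c("name", "rank", "parent", "flags")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_fishtol(paste0("taxonomy table missing columns: ",
                        paste(miss, collapse = ", ")))
  }
  n <- nrow(raw)
  if (!"anchor" %in% names(raw)) raw$anchor <- ""

  bad_rank <- which(!raw$rank %in% FISHTOL_RANKS)
  if (length(bad_rank)) {
    stop_fishtol(
      sprintf("unknown rank '%s' at row %d", raw$rank[bad_rank[1]], bad_rank[1]),
      class = "fishtol_taxonomy_error"
    )
  }

  name0 <- trimws(raw$name)
  quoted <- grepl('^["“].*["”]$', name0)
  name <- strip_name_quotes(name0)
  parent <- strip_name_quotes(trimws(raw$parent))

  flags <- lapply(seq_len(n), function(i) {
    f <- raw$flags[[i]]
    f <- if (nzchar(f)) trimws(strsplit(f, ";", fixed = TRUE)[[1]]) else character(0)
    f <- f[nzchar(f)]
    bad <- setdiff(f, FISHTOL_FLAGS)
    if (length(bad)) {
      stop_fishtol(
        sprintf("unknown flag '%s' at row %d", bad[1], i),
        class = "fishtol_taxonomy_error"
      )
    }
    if (quoted[i]) f <- c(f, "provisional")
    sort(unique(f))
  })

  tax <- tibble(
    name = name,
    rank = raw$rank,
    parent = parent,
    flags = flags,
    anchor = trimws(raw$anchor),
    row = seq_len(n)
  )

  dup <- duplicated(paste(tax$name, tax$rank, sep = "\r"))
  if (any(dup)) {
    stop_fishtol(
      paste0("duplicate (name, rank) entries: ",
             paste(unique(tax$name[dup]), collapse = ", ")),
      class = "fishtol_taxonomy_error"
    )
  }

  has_parent <- nzchar(tax$parent)
  pidx <- match(tax$parent, tax$name)
  multi <- tax$parent %in% tax$name[duplicated(tax$name)]
  if (any(has_parent & multi)) {
    stop_fishtol(
      paste0("ambiguous parent names (several taxa share the name): ",
             paste(unique(tax$parent[has_parent & multi]), collapse = ", ")),
      class = "fishtol_taxonomy_error"
    )
  }
  orphan <- which(has_parent & is.na(pidx))
  if (length(orphan)) {
    stop_fishtol(
      sprintf("orphan parent '%s' at row %d", tax$parent[orphan[1]], orphan[1]),
      class = "fishtol_taxonomy_error"
    )
  }

  ri <- rank_index(tax$rank)
  bad_order <- which(has_parent & ri[pidx] > ri)
  if (length(bad_order)) {
    i <- bad_order[1]
    stop_fishtol(
      sprintf("taxon '%s' (%s) has lower-ranked parent '%s' (%s)",
              tax$name[i], tax$rank[i], tax$parent[i], tax$rank[pidx[i]]),
      class = "fishtol_taxonomy_error"
    )
  }

  # Acyclic parent chains (cycles exhaust n steps).
  for (i in seq_len(n)) {
    j <- i
    for (step in seq_len(n + 1)) {
      if (!nzchar(tax$parent[j])) break
      j <- pidx[j]
      if (step > n) {
        stop_fishtol(sprintf("cycle in parent links involving '%s'", tax$name[i]),
                     class = "fishtol_taxonomy_error")
      }
    }
  }

  fam <- which(tax$rank == "family")
  for (i in fam) {
    anc_ranks <- tax$rank[ancestor_indices(tax, i, pidx)]
    ok <- "order" %in% anc_ranks ||
      ("incertae_sedis" %in% tax$flags[[i]] && "series" %in% anc_ranks)
    if (!ok) {
      stop_fishtol(
        sprintf(
          paste0("family '%s' has no order ancestor and is not flagged ",
                 "incertae_sedis under a series"),
          tax$name[i]
        ),
        class = "fishtol_taxonomy_error"
      )
    }
  }

  class(tax) <- c("fish_taxonomy", class(tibble()))
  tax
}

ancestor_indices <- function(tax, i, pidx = match(tax$parent, tax$name)) {
  out <- integer(0)
  j <- i
  while (nzchar(tax$parent[j])) {
    j <- pidx[j]
    out <- c(out, j)
  }
  out
}

#' Ancestor chain of a taxon
#'
#' @param taxonomy A `fish_taxonomy` tibble.
#' @param name Taxon name.
#' @return Character vector of ancestor names, nearest first.
#' @export
taxon_ancestors <- function(taxonomy, name) {
  i <- match(name, taxonomy$name)
  if (is.na(i)) stop_fishtol(sprintf("unknown taxon '%s'", name))
  taxonomy$name[ancestor_indices(taxonomy, i)]
}

#' Subset a taxonomy to a taxon and its descendants
#'
#' @inheritParams taxon_ancestors
#' @param ancestor Name of the enclosing taxon.
#' @return A `fish_taxonomy` tibble containing `ancestor` and everything
#'   below it, in source-row order.
#' @export
#' @examples
#' # series below the percomorph crown in the shipped classification extract:
#' tax <- load_taxonomy(fishtol_example("percomorph_classification.tsv"))
#' sum(subtaxa(tax, "Percomorphaceae")$rank == "series")
subtaxa <- function(taxonomy, ancestor) {
  if (!ancestor %in% taxonomy$name) {
    stop_fishtol(sprintf("unknown taxon '%s'", ancestor))
  }
  keep <- taxonomy$name == ancestor
  repeat {
    grow <- keep | taxonomy$parent %in% taxonomy$name[keep]
    if (identical(grow, keep)) break
    keep <- grow
  }
  out <- taxonomy[keep, ]
  class(out) <- c("fish_taxonomy", class(tibble()))
  out
}

#' Write a taxonomy table
#'
#' Inverse of [load_taxonomy()]: a round trip through
#' `load_taxonomy(write_taxonomy(tax, f))` reproduces the taxonomy exactly
#' (provisional status travels in the `flags` column).
#'
#' @param taxonomy A `fish_taxonomy` tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, file) {
  out <- tibble(
    name = taxonomy$name,
    rank = taxonomy$rank,
    parent = taxonomy$parent,
    flags = vapply(taxonomy$flags, paste, character(1), collapse = ";"),
    anchor = taxonomy$anchor
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Default rank-ending rules
#'
#' The suffix conventions the classification applies: orders end in
#' "-iformes", suborders in "-oidei", infraorders in "-ales" and divisions
#' in "-pterygii".  Series, cohort-level ranks and families carry no uniform
#' ending and are left unruled.  Rules are data: edit or extend the tibble
#' to change policy, and list exempt names per rank.
#'
#' @return A tibble with columns `rank`, `suffixes` (list), `exempt` (list).
#' @export
#' @examples
#' default_rank_rules()
default_rank_rules <- function() {
  tibble(
    rank = c("order", "suborder", "infraorder", "division"),
    suffixes = list("iformes", "oidei", "ales", "pterygii"),
    exempt = list(character(0), character(0), character(0), character(0))
  )
}

#' Lint taxon names against rank-ending conventions
#'
#' @param taxonomy A `fish_taxonomy` tibble.
#' @param rules Rank-ending rules; see [default_rank_rules()].
#' @return Tibble of violations (`name`, `rank`, `expected`) in taxonomy row
#'   order; zero rows when every ruled name conforms.
#' @export
#' @examples
#' tax <- load_taxonomy(tibble::tibble(
#'   name = c("Tetraodontiformes", "Ostracioidea"),
#'   rank = c("order", "suborder"),
#'   parent = c("", "Tetraodontiformes"),
#'   flags = ""
#' ))
#' check_rank_endings(tax)
check_rank_endings <- function(taxonomy, rules = default_rank_rules()) {
  out <- list()
  for (r in seq_len(nrow(rules))) {
    rk <- rules$rank[[r]]
    sufs <- rules$suffixes[[r]]
    if (length(sufs) == 0) next
    rows <- which(taxonomy$rank == rk & !taxonomy$name %in% rules$exempt[[r]])
    if (!length(rows)) next
    ok <- vapply(taxonomy$name[rows], function(nm) {
      any(endsWith(nm, sufs))
    }, logical(1))
    if (any(!ok)) {
      out[[length(out) + 1]] <- tibble(
        row = rows[!ok],
        name = taxonomy$name[rows[!ok]],
        rank = rk,
        expected = paste0("-", paste(sufs, collapse = " / -"))
      )
    }
  }
  if (!length(out)) {
    return(tibble(row = integer(), name = character(), rank = character(),
                  expected = character()))
  }
  arrange(bind_rows(out), .data$row)[, c("name", "rank", "expected", "row")]
}

#' Path to a shipped example data file
#'
#' @param file File name under the package's `extdata` directory; omit to
#'   list the available files.
#' @return Full path (or a character vector of file names).
#' @export
fishtol_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "fishtol")))
  }
  path <- system.file("extdata", file, package = "fishtol")
  if (!nzchar(path)) stop_fishtol(sprintf("no example file '%s'", file))
  path
}
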