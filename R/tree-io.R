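# Newick reading/writing in the chronogram dialect used throughout the
# package: branch lengths in Myr, internal-node labels that parse as numbers
# in [0, 100] interpreted as bootstrap support percentages, all other
# internal labels kept as clade-name annotations, and tip labels in the
# Family_Genus_species_Code convention.

#' Parse a newick chronogram
#'
#' Reads a single rooted newick statement into an [ape::read.tree()] `phylo`
#' object and validates it against the chronogram dialect: unique tip
#' labels, non-negative branch lengths, and percentage-scale support labels.
#' Internal-node labels that parse as numbers in `[0, 100]` are treated as
#' bootstrap support percentages (see [node_support()]); other labels are
#' kept as clade-name annotations.  Numeric internal labels strictly between
#' 0 and 1 are rejected as fraction-scale support rather than silently
#' rescaled.
#'
#' @param text Newick string terminated by `";"`.  Ignored when `file` is
#'   given.
#' @param file Optional path to a newick file (UTF-8).
#' @return A `phylo` object.  Underscores in labels are preserved verbatim.
#' @seealso [write_newick()], [node_support()], [parse_tip_label()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1)95:1,C:2);")
#' node_support(tr)
parse_newick <- function(text = NULL, file = NULL) {
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  }
  if (is.null(text) || !nzchar(trimws(text))) {
    stop_fishtol("empty newick input", class = "fishtol_parse_error")
  }
  check_newick_balance(text)
  if (!grepl(";", text, fixed = TRUE)) {
    stop_fishtol("newick statement must be terminated by ';'",
                 class = "fishtol_parse_error")
  }

  if (!grepl("(", text, fixed = TRUE)) {
    return(parse_single_leaf(text))
  }

  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop_fishtol("failed to parse newick input",
                 class = "fishtol_parse_error")
  }
  phy$tip.label <- unquote_label(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unquote_label(phy$node.label)
  validate_phylogeny(phy)
  phy
}

# Depth scan outside quoted labels; reports the 1-based character offset of
# the first unmatched parenthesis.
check_newick_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "'") {
      in_quote <- !in_quote
    } else if (!in_quote) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) {
          stop_fishtol(
            sprintf("unbalanced parentheses: unmatched ')' at character %d", i),
            class = "fishtol_parse_error"
          )
        }
      }
    }
  }
  if (depth != 0L) {
    stop_fishtol(
      sprintf(
        "unbalanced parentheses: %d '(' left open at end of input (character %d)",
        depth, length(chars)
      ),
      class = "fishtol_parse_error"
    )
  }
  invisible(TRUE)
}

# "A;" or "A:1.5;" -- a rooted tree with a single leaf.  ape's phylo format
# does not really cover this case, so a minimal one-edge phylo is built by
# hand; write_newick() round-trips it.
parse_single_leaf <- function(text) {
  body <- trimws(sub(";.*$", "", text))
  parts <- strsplit(body, ":", fixed = TRUE)[[1]]
  label <- unquote_label(trimws(parts[[1]]))
  if (!nzchar(label)) {
    stop_fishtol("single-leaf newick with empty label",
                 class = "fishtol_parse_error")
  }
  phy <- structure(
    list(
      edge = matrix(c(2L, 1L), nrow = 1),
      tip.label = label,
      Nnode = 1L
    ),
    class = "phylo", order = "cladewise"
  )
  if (length(parts) > 1) phy$edge.length <- as.numeric(parts[[2]])
  phy
}

unquote_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

# Dialect invariants shared by parse_newick() and the simulators.
validate_phylogeny <- function(phy) {
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) {
    stop_fishtol(
      paste0("duplicate leaf labels: ", paste(dup, collapse = ", ")),
      class = "fishtol_validation_error"
    )
  }
  if (!is.null(phy$edge.length)) {
    if (anyNA(phy$edge.length)) {
      stop_fishtol("missing branch lengths",
                   class = "fishtol_validation_error")
    }
    if (any(phy$edge.length < 0)) {
      stop_fishtol("negative branch lengths",
                   class = "fishtol_validation_error")
    }
  }
  labs <- phy$node.label
  if (!is.null(labs)) {
    num <- suppressWarnings(as.numeric(labs))
    frac <- !is.na(num) & num > 0 & num < 1
    if (any(frac)) {
      stop_fishtol(
        paste0(
          "internal labels look like fraction-scale support (in (0,1)): ",
          paste(unique(labs[frac]), collapse = ", "),
          "; supply percentages on the 0-100 scale"
        ),
        class = "fishtol_validation_error"
      )
    }
  }
  invisible(phy)
}

#' Bootstrap support stored at internal nodes
#'
#' Internal-node labels that parse as numbers in `[0, 100]` are support
#' percentages; everything else (clade-name annotations, empty labels) maps
#' to `NA`.  Absent support is `NA`, never 0.
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode`, in internal-node order
#'   (node `Ntip + i` is element `i`).
#' @export
#' @examples
#' node_support(parse_newick("((A:1,B:1)95:1,C:2)Teleostei;"))
node_support <- function(tree) {
  n <- tree$Nnode
  labs <- tree$node.label
  if (is.null(labs)) return(rep(NA_real_, n))
  num <- suppressWarnings(as.numeric(labs))
  ifelse(!is.na(num) & num >= 0 & num <= 100, num, NA_real_)
}

#' Clade-name annotations stored at internal nodes
#'
#' The complement of [node_support()]: internal labels that are not support
#' percentages, returned as a character vector with `NA` where the label is
#' empty or numeric.
#'
#' @inheritParams node_support
#' @return Character vector of length `tree$Nnode`.
#' @export
clade_annotations <- function(tree) {
  n <- tree$Nnode
  labs <- tree$node.label
  if (is.null(labs)) return(rep(NA_character_, n))
  sup <- node_support(tree)
  out <- ifelse(is.na(sup) & nzchar(labs), labs, NA_character_)
  as.character(out)
}

format_branch_length <- function(x, digits) {
  if (is.null(digits)) sprintf("%.17g", x) else formatC(x, digits = digits, format = "f")
}

quote_label <- function(x) {
  needs <- grepl("[][ ():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

# Newick text for the clade rooted at `node`, without a trailing branch
# length or ";".  Children are emitted in stored edge order; internal labels
# are carried verbatim.  This is the primitive graft_clade() splices with.
newick_clade_string <- function(tree, node = NULL, digits = 6) {
  ntip <- length(tree$tip.label)
  node <- node %||% (ntip + 1L)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  labs <- tree$node.label

  build <- function(v) {
    if (v <= ntip) return(quote_label(tree$tip.label[v]))
    rows <- kids[[as.character(v)]]
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      s <- build(child)
      if (has_len) s <- paste0(s, ":", format_branch_length(tree$edge.length[r], digits))
      s
    }, character(1))
    lab <- if (!is.null(labs)) labs[v - ntip] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(parts, collapse = ","), ")", quote_label(lab))
  }
  build(node)
}

#' Write a tree as newick text
#'
#' Support values and clade annotations are emitted as internal-node labels;
#' children are written in stored order (the order downstream classification
#' rendering relies on).
#'
#' @param tree A `phylo` object.
#' @param digits Decimal places for branch lengths (default 6).  `NULL`
#'   writes full double precision (`%.17g`), which round-trips branch
#'   lengths bit-exactly through [parse_newick()].
#' @param file Optional path; when given the string is also written there.
#' @return The newick string, invisibly when `file` is given.
#' @export
#' @examples
#' write_newick(parse_newick("((A:1,B:1)95:1,C:2);"), digits = 1)
write_newick <- function(tree, digits = 6, file = NULL) {
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    s <- paste0(
      quote_label(tree$tip.label),
      if (!is.null(tree$edge.length)) {
        paste0(":", format_branch_length(tree$edge.length[1], digits))
      },
      ";"
    )
  } else {
    s <- newick_clade_string(tree, digits = digits)
    if (!is.null(tree$root.edge)) {
      s <- paste0(s, ":", format_branch_length(tree$root.edge, digits))
    }
    s <- paste0(s, ";")
  }
  if (!is.null(file)) {
    writeLines(s, file, useBytes = TRUE)
    return(invisible(s))
  }
  s
}

#' Parse structured tip labels
#'
#' Tip labels follow the `Family_Genus_species_Code` convention: the first
#' underscore-separated token is the family, the second the genus, the third
#' the species epithet, and any remaining tokens (joined back with
#' underscores) the specimen code.  Three-token labels have an empty code.
#'
#' @param labels Character vector of tip labels (or a `phylo` object, whose
#'   tip labels are used).
#' @return A tibble with columns `label`, `family`, `genus`, `species`,
#'   `code`.
#' @export
#' @examples
#' parse_tip_label(c(
#'   "Percidae_Perca_fluviatilis_X123",
#'   "Gobiidae_Gobius_niger",
#'   "Cichlidae_Oreochromis_sp_A_T7"
#' ))
parse_tip_label <- function(labels) {
  if (inherits(labels, "phylo")) labels <- labels$tip.label
  parts <- strsplit(labels, "_", fixed = TRUE)
  bad <- vapply(parts, function(p) {
    length(p) < 3 || any(!nzchar(p[1:3]))
  }, logical(1))
  if (any(bad)) {
    stop_fishtol(
      paste0(
        "malformed tip labels (need Family_Genus_species[_Code]): ",
        paste(labels[bad], collapse = ", ")
      ),
      class = "fishtol_label_error"
    )
  }
  tibble(
    label = labels,
    family = vapply(parts, `[[`, character(1), 1),
    genus = vapply(parts, `[[`, character(1), 2),
    species = vapply(parts, `[[`, character(1), 3),
    code = vapply(parts, function(p) {
      if (length(p) > 3) paste(p[-(1:3)], collapse = "_") else ""
    }, character(1))
  )
}
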