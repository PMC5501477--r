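# Brute-force monophyly oracle, independent of the package's
# getMRCA/Descendants path: enumerate every clade's leaf set by direct
# recursion over the edge matrix, then find the smallest clade containing
# the query tips (clades are laminar, so the minimal containing clade is
# the MRCA clade).

oracle_clade_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", ntip + tree$Nnode)
  fill <- function(v) {
    if (v <= ntip) {
      sets[[v]] <<- tree$tip.label[v]
      return(sets[[v]])
    }
    s <- unlist(lapply(kids[[as.character(v)]], fill))
    sets[[v]] <<- s
    s
  }
  fill(ntip + 1L)
  sets
}

oracle_assess <- function(sets, tips) {
  if (length(tips) == 0) {
    return(list(status = "unsampled", intruders = character(0)))
  }
  if (length(tips) == 1) {
    return(list(status = "monotypic", intruders = character(0)))
  }
  containing <- Filter(function(s) all(tips %in% s), sets)
  best <- containing[[which.min(lengths(containing))]]
  intr <- sort(setdiff(best, tips))
  list(
    status = if (length(intr)) "non_monophyletic" else "monophyletic",
    intruders = intr
  )
}

# Bit-exact root-to-node path length (summed leaf-to-root, a fixed order
# independent of the edge-matrix layout).
path_depth <- function(tree, node) {
  s <- 0
  p <- node
  repeat {
    r <- match(p, tree$edge[, 2])
    if (is.na(r)) break
    s <- tree$edge.length[r] + s
    p <- tree$edge[r, 1]
  }
  s
}

# All non-empty subsets of a character vector (for exhaustive sweeps).
all_subsets <- function(x) {
  n <- length(x)
  lapply(seq_len(2^n - 1), function(mask) {
    x[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0]
  })
}
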