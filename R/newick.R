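# Bipartition bookkeeping -------------------------------------------------
#
# Support values (BV, PP) are keyed by bipartition rather than by node
# index, so they survive re-rooting and leaf reordering. The canonical key
# of a bipartition is the sorted, tab-joined label list of the side NOT
# containing the lexicographically smallest leaf of the tree.

bipart_key <- function(side, all_labels) {
  side <- as.character(side)
  ref <- min(all_labels)
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "\t")
}

# descendant tip labels for every node of a phylo, as a list indexed by
# node number (tips first, then internal nodes)
node_tip_sets <- function(phy) {
  n <- length(phy$tip.label)
  m <- phy$Nnode
  desc <- vector("list", n + m)
  for (i in seq_len(n)) desc[[i]] <- phy$tip.label[i]
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    desc[[eo[k, 1]]] <- c(desc[[eo[k, 1]]], desc[[eo[k, 2]]])
  }
  desc
}

# all non-trivial bipartition keys of a tree (internal edges only),
# as a named list: key -> tip set of the clade side in the stored rooting
tree_biparts <- function(phy) {
  n <- length(phy$tip.label)
  desc <- node_tip_sets(phy)
  root <- n + 1L
  internal_children <- phy$edge[, 2][phy$edge[, 2] > n]
  out <- list()
  for (nd in internal_children) {
    tips <- desc[[nd]]
    if (length(tips) >= 2 && length(tips) <= n - 2) {
      out[[bipart_key(tips, phy$tip.label)]] <- tips
    }
  }
  out
}

has_bipartition <- function(phy, leafset) {
  n <- length(phy$tip.label)
  leafset <- as.character(leafset)
  if (length(leafset) == 1 || length(leafset) == n - 1) return(TRUE)
  key <- bipart_key(leafset, phy$tip.label)
  key %in% names(tree_biparts(phy))
}

# Supported trees ----------------------------------------------------------

#' Phylogenetic tree with bipartition support values
#'
#' Wraps an `ape::phylo` topology together with optional bootstrap values
#' (BV, integer percent 0-100) and posterior probabilities (PP, 0-1), both
#' keyed by bipartition so that support survives re-rooting.
#'
#' @param phy An `ape::phylo` tree.
#' @param bv Named numeric vector of bootstrap percentages; names are
#'   internal bipartition keys (use [bipartition_support()] to query).
#' @param pp Named numeric vector of posterior probabilities.
#' @return A `supported_tree`.
#' @export
supported_tree <- function(phy, bv = numeric(0), pp = numeric(0)) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  if (length(bv) > 0 && (any(bv < 0) || any(bv > 100))) {
    stop("BV must lie in [0, 100]")
  }
  if (length(pp) > 0 && (any(pp < 0) || any(pp > 1))) {
    stop("PP must lie in [0, 1]")
  }
  structure(list(phy = phy, bv = bv, pp = pp), class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("Supported tree:", length(x$phy$tip.label), "leaves;",
      length(x$bv), "edges with BV;", length(x$pp), "with PP\n")
  invisible(x)
}

as_phylo <- function(tree) {
  if (inherits(tree, "supported_tree")) tree$phy else tree
}

#' Parse a Newick tree with support annotations
#'
#' Reads a Newick string (or a file containing one). Support values may be
#' encoded as bare internal-node labels — interpreted as bootstrap
#' percentages under `dialect = "bv"` or as posterior probabilities under
#' `dialect = "pp"` — and/or as bracketed comments of the form
#' `[&pp=0.99]` following the node label.
#'
#' @param x A Newick string or a path to a file containing one.
#' @param dialect How to interpret bare numeric internal-node labels.
#' @return A [supported_tree()].
#' @examples
#' tr <- parse_newick("((A:1,B:1)95:0.5,C:1,D:1);")
#' bipartition_support(tr, c("A", "B"))
#' @export
parse_newick <- function(x, dialect = c("bv", "pp")) {
  dialect <- match.arg(dialect)
  text <- if (length(x) == 1 && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    as.character(x)
  }
  if (lengths(regmatches(text, gregexpr("\\(", text))) !=
      lengths(regmatches(text, gregexpr("\\)", text)))) {
    stop("parse error: unbalanced parentheses (",
         lengths(regmatches(text, gregexpr("\\(", text))), " '(' vs ",
         lengths(regmatches(text, gregexpr("\\)", text))), " ')')")
  }
  # stash [&pp=...] comments inside the node label, drop other comments
  text2 <- gsub("(\\)[^,():;\\[]*)\\[&pp=([0-9.eE+-]+)\\]", "\\1@@\\2", text)
  text2 <- gsub("\\[[^]]*\\]", "", text2)
  phy <- tryCatch(ape::read.tree(text = text2),
                  error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("parse error: not a valid Newick string")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  n <- length(phy$tip.label)
  desc <- node_tip_sets(phy)
  bv <- pp <- numeric(0)
  labs <- phy$node.label
  if (!is.null(labs)) {
    for (j in seq_along(labs)) {
      lab <- labs[j]
      if (is.na(lab) || lab == "") next
      nd <- n + j
      tips <- desc[[nd]]
      if (length(tips) < 2 || length(tips) > n - 2) next
      key <- bipart_key(tips, phy$tip.label)
      parts <- strsplit(lab, "@@", fixed = TRUE)[[1]]
      bare <- parts[1]
      if (!is.na(bare) && bare != "" && !is.na(suppressWarnings(as.numeric(bare)))) {
        v <- as.numeric(bare)
        if (dialect == "bv") bv[key] <- v else pp[key] <- v
      }
      if (length(parts) > 1 && !is.na(suppressWarnings(as.numeric(parts[2])))) {
        pp[key] <- as.numeric(parts[2])
      }
    }
    phy$node.label <- NULL
  }
  supported_tree(phy, bv = bv, pp = pp)
}

#' Write a supported tree as Newick
#'
#' Bootstrap values are written as internal-node labels; posterior
#' probabilities as `[&pp=...]` comments after the label. Inverse of
#' [parse_newick()] up to bipartition equivalence.
#'
#' @param tree A `supported_tree` or `phylo`.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Number of digits for branch lengths.
#' @return The Newick string (invisibly if written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  st <- if (inherits(tree, "supported_tree")) tree else supported_tree(tree)
  phy <- st$phy
  n <- length(phy$tip.label)
  desc <- node_tip_sets(phy)
  labs <- character(phy$Nnode)
  for (j in seq_len(phy$Nnode)) {
    tips <- desc[[n + j]]
    if (length(tips) < 2 || length(tips) > n - 2) next
    key <- bipart_key(tips, phy$tip.label)
    lab <- ""
    if (key %in% names(st$bv)) lab <- format(st$bv[[key]], digits = 10)
    if (key %in% names(st$pp)) {
      lab <- paste0(lab, "@@PPOPEN", format(st$pp[[key]], digits = 10), "PPCLOSE")
    }
    labs[j] <- lab
  }
  phy$node.label <- labs
  txt <- ape::write.tree(phy, digits = digits)
  txt <- gsub("@@PPOPEN", "[&pp=", txt, fixed = TRUE)
  txt <- gsub("PPCLOSE", "]", txt, fixed = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Query the support of a bipartition
#'
#' Tests whether some internal edge of the tree splits exactly `leafset`
#' from the remaining leaves (the standard monophyly notion on unrooted
#' trees) and, if so, returns that edge's support values.
#'
#' @param tree A `supported_tree` or `phylo`.
#' @param leafset Character vector of leaf labels, a strict non-empty
#'   subset of the tree's leaves.
#' @return A list with `present` (logical), `bv` and `pp` (numeric or `NA`
#'   when absent). A singleton leafset is trivially present with no
#'   support values.
#' @export
bipartition_support <- function(tree, leafset) {
  st <- if (inherits(tree, "supported_tree")) tree else supported_tree(tree)
  phy <- st$phy
  leafset <- as.character(leafset)
  n <- length(phy$tip.label)
  if (!all(leafset %in% phy$tip.label)) {
    stop("leafset contains labels not in the tree: ",
         paste(setdiff(leafset, phy$tip.label), collapse = ", "))
  }
  if (length(leafset) < 1 || length(leafset) >= n) {
    stop("leafset must be a strict non-empty subset of the leaves")
  }
  if (length(leafset) == 1 || length(leafset) == n - 1) {
    return(list(present = TRUE, bv = NA_real_, pp = NA_real_))
  }
  key <- bipart_key(leafset, phy$tip.label)
  present <- key %in% names(tree_biparts(phy))
  list(
    present = present,
    bv = if (present && key %in% names(st$bv)) unname(st$bv[[key]]) else NA_real_,
    pp = if (present && key %in% names(st$pp)) unname(st$pp[[key]]) else NA_real_
  )
}
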