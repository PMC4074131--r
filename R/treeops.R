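#' Count leaves of a lineage group
#'
#' @param tree A `supported_tree` or `phylo`.
#' @param taxa A `taxon_table` resolving every leaf.
#' @param group A lineage group name (see [LINEAGE_GROUPS]).
#' @return Integer count of leaves whose lineage equals `group`.
#' @export
count_lineage <- function(tree, taxa, group) {
  stopifnot(group %in% LINEAGE_GROUPS)
  phy <- as_phylo(tree)
  sum(lineage_of(taxa, phy$tip.label) == group)
}

#' Test for a plastid-EGT tree shape with basal cyanobacteria
#'
#' A gene of cyanobacterial (plastid) origin should show the eukaryotic
#' homologs as a single clade with the cyanobacterial OTUs basal to them:
#' on the unrooted gene tree, the full eukaryote leaf set must form a
#' bipartition. Trees with fewer than `min_cyano` cyanobacterial OTUs do
#' not meet the minimum requirement for inferring a cyanobacterial origin
#' and fail the check.
#'
#' @param tree A `supported_tree` or `phylo` with at least one
#'   cyanobacterial and two eukaryotic leaves.
#' @param taxa A `taxon_table`.
#' @param min_cyano Minimum number of cyanobacterial OTUs (default 3).
#' @return Logical.
#' @export
cyano_basal_check <- function(tree, taxa, min_cyano = 3) {
  phy <- as_phylo(tree)
  lin <- lineage_of(taxa, phy$tip.label)
  cyano <- phy$tip.label[lin == "Cyanobacteria"]
  euk <- phy$tip.label[lin != "Cyanobacteria"]
  if (length(cyano) < 1 || length(euk) < 2) {
    stop("tree must contain at least 1 cyanobacterial and 2 eukaryotic leaves")
  }
  length(cyano) >= min_cyano && has_bipartition(phy, euk)
}

#' Classify the red/green affiliation of the chlorarachniophyte clade
#'
#' Deterministic typing of a gene tree that has passed the basal-
#' cyanobacteria filter. The tree is rooted on the cyanobacterial side;
#' if the chlorarachniophyte leaves are not monophyletic the tree is a
#' `SPLIT`. Otherwise enclosing clades are walked outward from the
#' chlorarachniophyte clade until the sister group contains at least one
#' classification-informative plastid lineage (Chloroplastida or a
#' red-lineage group); Glaucophyta, Euglenophyta and plastid-lacking OTUs
#' are context only and never stop the walk. The first informative sister
#' determines the class:
#'
#' * all informative members Chloroplastida -> `GREEN`
#' * red-lineage members in the majority of plastid-bearing leaves, with
#'   Rhodophyceae but no CASH -> `RED_TYPE`; CASH but no Rhodophyceae ->
#'   `CASH_TYPE`; both -> `AMBIGUOUS_RED`
#' * anything else -> `UNCLASSIFIED`
#'
#' The support (BV/PP) of the smallest clade uniting the
#' chlorarachniophytes with red-lineage OTUs is reported as the red-
#' affiliation support, and compared against `bv_strong`/`pp_strong`.
#'
#' @param tree A `supported_tree` (support values are read from it) or
#'   `phylo`.
#' @param taxa A `taxon_table`.
#' @param bv_strong Bootstrap percentage regarded as strong support.
#' @param pp_strong Posterior probability regarded as strong support.
#' @return An `affiliation_call`: list with `class`, `chlor_monophyletic`,
#'   `chlor_clade_bv`, `chlor_clade_pp`, `sister_composition`,
#'   `red_affiliation_bv`, `red_affiliation_pp`, `red_support_strong`.
#' @export
classify_affiliation <- function(tree, taxa, bv_strong = 75, pp_strong = 0.95) {
  st <- if (inherits(tree, "supported_tree")) tree else supported_tree(tree)
  phy <- st$phy
  labels <- phy$tip.label
  lin <- lineage_of(taxa, labels)
  pb <- plastid_bearing_of(taxa, labels)
  chl <- labels[lin == "Chlorarachniophyta"]
  if (length(chl) == 0) stop("no chlorarachniophyte leaves in tree")
  cyano <- labels[lin == "Cyanobacteria"]

  call <- list(
    class = "UNCLASSIFIED", chlor_monophyletic = NA,
    chlor_clade_bv = NA_real_, chlor_clade_pp = NA_real_,
    sister_composition = integer(0),
    red_affiliation_bv = NA_real_, red_affiliation_pp = NA_real_,
    red_support_strong = NA
  )

  mono <- length(chl) == 1 || has_bipartition(phy, chl)
  call$chlor_monophyletic <- mono
  if (length(chl) >= 2 && mono) {
    s <- bipartition_support(st, chl)
    call$chlor_clade_bv <- s$bv
    call$chlor_clade_pp <- s$pp
  }
  if (!mono) {
    call$class <- "SPLIT"
    return(structure(call, class = "affiliation_call"))
  }

  # root on the cyanobacterial side
  rphy <- if (length(cyano) > 0) {
    tryCatch(ape::root(phy, outgroup = cyano, resolve.root = TRUE),
             error = function(e) ape::root(phy, outgroup = cyano[1],
                                           resolve.root = TRUE))
  } else {
    phy
  }
  n <- length(rphy$tip.label)
  desc <- node_tip_sets(rphy)
  parent_of <- integer(n + rphy$Nnode)
  parent_of[rphy$edge[, 2]] <- rphy$edge[, 1]

  node <- if (length(chl) == 1) {
    match(chl, rphy$tip.label)
  } else {
    ape::getMRCA(rphy, chl)
  }

  informative <- c("Chloroplastida", RED_LINEAGE_GROUPS)
  lin_r <- lineage_of(taxa, rphy$tip.label)
  names(lin_r) <- rphy$tip.label
  pb_r <- plastid_bearing_of(taxa, rphy$tip.label)
  names(pb_r) <- rphy$tip.label

  sister <- NULL
  cur <- node
  repeat {
    par <- parent_of[cur]
    if (par == 0) break
    sis <- setdiff(desc[[par]], desc[[cur]])
    if (any(lin_r[sis] %in% informative)) {
      sister <- sis
      break
    }
    cur <- par
  }

  # support of the smallest clade uniting chlorarachniophytes with
  # red-lineage OTUs
  cur2 <- node
  repeat {
    par <- parent_of[cur2]
    if (par == 0) break
    cur2 <- par
    if (any(lin_r[desc[[cur2]]] %in% RED_LINEAGE_GROUPS)) break
  }
  uniting <- desc[[cur2]]
  if (any(lin_r[uniting] %in% RED_LINEAGE_GROUPS) &&
      length(uniting) >= 2 && length(uniting) <= length(labels) - 2) {
    s <- bipartition_support(st, uniting)
    if (s$present) {
      call$red_affiliation_bv <- s$bv
      call$red_affiliation_pp <- s$pp
    }
  }

  if (is.null(sister)) {
    call$class <- "UNCLASSIFIED"
    return(structure(call, class = "affiliation_call"))
  }

  comp <- table(lin_r[sister])
  call$sister_composition <- stats::setNames(as.integer(comp), names(comp))
  g <- sum(lin_r[sister] == "Chloroplastida")
  red <- sum(lin_r[sister] %in% RED_LINEAGE_GROUPS)
  r_rho <- sum(lin_r[sister] == "Rhodophyceae")
  r_cash <- sum(lin_r[sister] %in% CASH_GROUPS)
  n_pb <- sum(pb_r[sister] & lin_r[sister] != "Chlorarachniophyta")

  if (red == 0 && g > 0 && 2 * g > n_pb) {
    call$class <- "GREEN"
  } else if (red > 0 && 2 * red > n_pb) {
    call$class <- if (r_rho > 0 && r_cash == 0) "RED_TYPE"
      else if (r_cash > 0 && r_rho == 0) "CASH_TYPE"
      else "AMBIGUOUS_RED"
  } else {
    call$class <- "UNCLASSIFIED"
  }

  if (call$class %in% c("RED_TYPE", "CASH_TYPE", "AMBIGUOUS_RED")) {
    call$red_support_strong <-
      (!is.na(call$red_affiliation_bv) && call$red_affiliation_bv >= bv_strong) ||
      (!is.na(call$red_affiliation_pp) && call$red_affiliation_pp >= pp_strong)
  }
  structure(call, class = "affiliation_call")
}

#' @export
print.affiliation_call <- function(x, ...) {
  cat("Affiliation:", x$class, "\n")
  cat("  chlorarachniophytes monophyletic:", x$chlor_monophyletic,
      if (!is.na(x$chlor_clade_bv)) sprintf("(BV %.0f)", x$chlor_clade_bv),
      "\n")
  if (length(x$sister_composition) > 0) {
    cat("  informative sister:",
        paste(sprintf("%s x%d", names(x$sister_composition),
                      x$sister_composition), collapse = ", "), "\n")
  }
  if (!is.na(x$red_affiliation_bv) || !is.na(x$red_affiliation_pp)) {
    cat(sprintf("  red-affiliation support: BV %s / PP %s%s\n",
                ifelse(is.na(x$red_affiliation_bv), "-",
                       format(x$red_affiliation_bv)),
                ifelse(is.na(x$red_affiliation_pp), "-",
                       format(x$red_affiliation_pp)),
                ifelse(isTRUE(x$red_support_strong), " [strong]", "")))
  }
  invisible(x)
}

#' Enumerate all re-graft placements of a branch
#'
#' Prunes the subtree spanned by `leafset` (which must be monophyletic,
#' i.e. attachable as one branch) and re-attaches its stem to every edge
#' of the remaining unrooted tree. For a binary backbone with `m` leaves
#' this yields `2m - 3` pairwise distinct topologies, one of which is
#' bipartition-identical to the input. Branch lengths of the returned
#' topologies are unset; they are meant to be re-optimized before scoring.
#'
#' @param tree A `supported_tree` or `phylo`.
#' @param leafset Leaves of the branch to re-graft (e.g. the
#'   chlorarachniophyte OTUs).
#' @return A `multiPhylo` list of topologies, with attributes
#'   `attachment` (per placement, the backbone-side tip set of the edge it
#'   was grafted onto) and `identity` (logical, the placement matching the
#'   input topology).
#' @export
enumerate_regrafts <- function(tree, leafset) {
  phy <- as_phylo(tree)
  leafset <- as.character(leafset)
  n <- length(phy$tip.label)
  if (!all(leafset %in% phy$tip.label)) {
    stop("leafset contains labels not in the tree")
  }
  if (length(leafset) >= n - 2) {
    stop("fewer than 3 leaves would remain after pruning")
  }
  if (length(leafset) > 1 && !has_bipartition(phy, leafset)) {
    stop("chlorarachniophytes not monophyletic - re-grafting undefined")
  }
  # root outside the pruned group so it forms a proper clade
  og <- setdiff(phy$tip.label, leafset)[1]
  rphy <- ape::root(phy, outgroup = og, resolve.root = TRUE)
  back <- ape::unroot(ape::drop.tip(rphy, leafset))
  back$edge.length <- rep(1, nrow(back$edge))
  back$node.label <- NULL
  sub <- if (length(leafset) > 1) {
    s <- ape::keep.tip(rphy, leafset)
    s$edge.length <- rep(1, nrow(s$edge))
    s$node.label <- NULL
    s
  } else {
    NULL
  }
  desc_back <- node_tip_sets(back)
  input_topo <- ape::unroot(phy)
  input_topo$edge.length <- NULL

  out <- vector("list", nrow(back$edge))
  attach_side <- vector("list", nrow(back$edge))
  for (e in seq_len(nrow(back$edge))) {
    node <- back$edge[e, 2]
    tt <- if (is.null(sub)) {
      phytools::bind.tip(back, leafset, edge.length = 1,
                         where = node, position = 0.5)
    } else {
      s2 <- sub
      s2$root.edge <- 1
      ape::bind.tree(back, s2, where = node, position = 0.5)
    }
    tt <- ape::unroot(tt)
    tt$edge.length <- NULL
    out[[e]] <- tt
    attach_side[[e]] <- desc_back[[node]]
  }
  class(out) <- "multiPhylo"
  ident <- vapply(out, function(t) phangorn::RF.dist(t, input_topo) == 0,
                  logical(1))
  attr(out, "attachment") <- attach_side
  attr(out, "identity") <- ident
  out
}
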