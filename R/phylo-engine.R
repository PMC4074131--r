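#' Amino-acid substitution model specification
#'
#' Describes a WAG-family model: WAG exchangeabilities with either the WAG
#' stationary frequencies or empirical frequencies counted from the
#' alignment (`plus_F`), an optional proportion of invariant sites
#' (`p_inv`), and discrete-gamma rate heterogeneity with `n_cat`
#' equal-probability categories of shape `alpha`. `alpha` and `p_inv` act
#' as fixed values or as starting values when a fitting routine is asked
#' to optimize them.
#'
#' @param plus_F Use empirical amino-acid frequencies (+F).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param alpha Gamma shape (> 0).
#' @param n_cat Number of gamma rate categories (>= 1).
#' @return An `aa_model`.
#' @examples
#' substitution_model()                      # WAG+G4
#' substitution_model(p_inv = 0.1)           # WAG+I+G4
#' substitution_model(plus_F = TRUE, p_inv = 0.1)  # WAG+F+I+G4
#' @export
substitution_model <- function(plus_F = FALSE, p_inv = 0, alpha = 1,
                               n_cat = 4) {
  stopifnot(is.logical(plus_F), p_inv >= 0, p_inv < 1, alpha > 0, n_cat >= 1)
  structure(list(plus_F = plus_F, p_inv = p_inv, alpha = alpha,
                 n_cat = as.integer(n_cat)),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat("WAG", if (x$plus_F) "+F", if (x$p_inv > 0) "+I",
      if (x$n_cat > 1) paste0("+G", x$n_cat),
      sprintf("  (alpha=%.3g, p_inv=%.3g)\n", x$alpha, x$p_inv), sep = "")
  invisible(x)
}

#' Discrete gamma rate categories
#'
#' Equal-probability discretization of the gamma rate distribution, each
#' category represented by its conditional mean rate. The rates are
#' renormalized so their (equally weighted) mean is exactly 1, keeping
#' branch lengths in expected substitutions per site.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param n_cat Number of categories (>= 1).
#' @return List with `rates` and `weights`, both length `n_cat`.
#' @export
discretize_gamma <- function(alpha, n_cat = 4) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (n_cat < 1) stop("n_cat must be >= 1")
  n_cat <- as.integer(n_cat)
  if (n_cat == 1) return(list(rates = 1, weights = 1))
  r <- phangorn::discrete.gamma(alpha, n_cat)
  r <- as.numeric(r)
  r <- r / mean(r)
  list(rates = r, weights = rep(1 / n_cat, n_cat))
}

# internal: gene_family -> phyDat, collapsing all missing states to X
as_phyDat <- function(fam) {
  stopifnot(inherits(fam, "gene_family"))
  mat <- do.call(rbind, strsplit(fam$seqs, ""))
  rownames(mat) <- names(fam$seqs)
  mat[mat %in% c("B", "Z", "?", "*")] <- "X"
  phangorn::phyDat(mat, type = "AA")
}

# internal: build a pml fit for a family under an aa_model
pml_of <- function(phy, fam, model) {
  dat <- as_phyDat(fam)
  if (!setequal(phy$tip.label, names(fam$seqs))) {
    stop("tree leaves and alignment labels differ")
  }
  if (is.null(phy$edge.length)) {
    stop("tree must have branch lengths")
  }
  if (model$plus_F) {
    phangorn::pml(phy, dat, model = "WAG", bf = "empirical",
                  k = model$n_cat, shape = model$alpha, inv = model$p_inv)
  } else {
    phangorn::pml(phy, dat, model = "WAG",
                  k = model$n_cat, shape = model$alpha, inv = model$p_inv)
  }
}

expand_site_ll <- function(fit) {
  idx <- attr(fit$data, "index")
  as.numeric(fit$siteLik)[idx]
}

#' Per-site log-likelihoods of an alignment on a tree
#'
#' Computes the log-likelihood of every alignment column on a fixed tree
#' with fixed branch lengths under the given model. The site likelihood
#' mixes the invariant-site spike with the gamma rate categories; missing
#' states integrate over all residues. Row sums of a matrix of such
#' vectors reproduce total log-likelihoods, which is the input format of
#' the AU test.
#'
#' @param tree A `phylo` (or `supported_tree`) with branch lengths whose
#'   leaves match the alignment labels.
#' @param fam A `gene_family`.
#' @param model An [substitution_model()].
#' @return Numeric vector of length `fam$n_sites`.
#' @export
site_log_likelihoods <- function(tree, fam, model = substitution_model()) {
  fit <- pml_of(as_phylo(tree), fam, model)
  expand_site_ll(fit)
}

#' Optimize branch lengths on a fixed topology
#'
#' Maximum-likelihood branch lengths for a fixed topology, optionally
#' re-estimating the gamma shape and invariant proportion. Used to score
#' re-grafted candidate topologies, where the placement is fixed and only
#' lengths (and rate parameters) are free.
#'
#' @param tree A `phylo` or `supported_tree`; branch lengths present are
#'   used as starting values, otherwise 0.1 per edge.
#' @param fam A `gene_family`.
#' @param model An [substitution_model()].
#' @param optimize_rates Also optimize `alpha` (if `n_cat > 1`) and
#'   `p_inv` (if positive in `model`).
#' @return List with `tree` (branch lengths set), `log_lik`, `alpha`,
#'   `p_inv`, and `site_log_lik` (per-site vector at the optimum).
#' @export
optimize_branch_lengths <- function(tree, fam, model = substitution_model(),
                                    optimize_rates = FALSE) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  phy$edge.length[phy$edge.length <= 0] <- 1e-6
  fit <- pml_of(phy, fam, model)
  fit <- phangorn::optim.pml(
    fit, optEdge = TRUE, optNni = FALSE,
    optGamma = optimize_rates && model$n_cat > 1,
    optInv = optimize_rates && model$p_inv > 0,
    control = phangorn::pml.control(trace = 0)
  )
  if (!is.finite(fit$logLik)) stop("non-finite log-likelihood")
  list(tree = fit$tree, log_lik = fit$logLik, alpha = fit$shape,
       p_inv = fit$inv, site_log_lik = expand_site_ll(fit))
}

#' Infer a maximum-likelihood gene tree
#'
#' Neighbor-joining starting tree from WAG maximum-likelihood pairwise
#' distances, followed by NNI hill-climbing under the full model with
#' branch-length and rate-parameter optimization. Deterministic given
#' `seed`.
#'
#' @param fam A `gene_family` (>= 4 sequences for a resolved topology;
#'   with fewer, the trivial topology is returned flagged
#'   `attr(, "trivial")`).
#' @param model An [substitution_model()].
#' @param seed Integer seed.
#' @return An unrooted `phylo` with ML branch lengths and attributes
#'   `log_lik`, `alpha`, `p_inv`.
#' @export
infer_tree <- function(fam, model = substitution_model(), seed = 1) {
  set.seed(seed)
  dat <- as_phyDat(fam)
  k <- length(fam$seqs)
  if (k < 4) {
    tr <- ape::stree(k, tip.label = names(fam$seqs))
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    attr(tr, "trivial") <- TRUE
    return(tr)
  }
  dm <- phangorn::dist.ml(dat, model = "WAG")
  dmm <- as.matrix(dm)
  if (any(!is.finite(dmm))) {
    mx <- max(dmm[is.finite(dmm)], 1)
    dmm[!is.finite(dmm)] <- 2 * mx
    dm <- stats::as.dist(dmm)
  }
  tr0 <- ape::unroot(ape::nj(dm))
  tr0$edge.length[tr0$edge.length <= 0] <- 1e-6
  fit <- pml_of(tr0, fam, model)
  fit <- phangorn::optim.pml(
    fit, optNni = TRUE, optEdge = TRUE,
    optGamma = model$n_cat > 1, optInv = model$p_inv > 0,
    control = phangorn::pml.control(trace = 0)
  )
  tr <- fit$tree
  attr(tr, "log_lik") <- fit$logLik
  attr(tr, "alpha") <- fit$shape
  attr(tr, "p_inv") <- fit$inv
  tr
}

#' Nonparametric bootstrap support for a gene tree
#'
#' Re-samples alignment columns `n_rep` times, infers a tree from each
#' replicate, and annotates the point-estimate tree with the percentage of
#' replicates containing each of its bipartitions. Replicate trees are
#' searched either by the full ML route used for the point estimate
#' (`search = "ml"`: NNI hill-climb from the replicate's NJ tree) or by
#' the fast distance route (`search = "nj"`: WAG ML-distance
#' neighbor-joining), the latter intended for large screening runs.
#'
#' @param fam A `gene_family`.
#' @param model An [substitution_model()].
#' @param n_rep Number of bootstrap replicates (the screen default is
#'   1000; validation runs use 100-200).
#' @param seed Integer seed; fixes the resampling.
#' @param search Replicate tree search: `"ml"` or `"nj"`.
#' @return A [supported_tree()] whose `phy` is the ML point estimate and
#'   whose `bv` holds bootstrap percentages.
#' @export
bootstrap_support <- function(fam, model = substitution_model(),
                              n_rep = 100, seed = 1,
                              search = c("ml", "nj")) {
  search <- match.arg(search)
  stopifnot(n_rep >= 1)
  point <- infer_tree(fam, model, seed = seed)
  dat <- as_phyDat(fam)
  set.seed(seed + 1L)
  if (search == "ml") {
    fit <- pml_of(point, fam, model)
    bs <- phangorn::bootstrap.pml(fit, bs = n_rep, optNni = TRUE,
                                  control = phangorn::pml.control(trace = 0))
  } else {
    bs <- phangorn::bootstrap.phyDat(dat, function(x) {
      dmm <- as.matrix(phangorn::dist.ml(x, model = "WAG"))
      if (any(!is.finite(dmm))) {
        mx <- max(dmm[is.finite(dmm)], 1)
        dmm[!is.finite(dmm)] <- 2 * mx
      }
      ape::nj(stats::as.dist(dmm))
    }, bs = n_rep)
  }
  # force per-tree tip labels (multiPhylo lists may share a TipLabel attr)
  bs <- lapply(seq_along(bs), function(i) bs[[i]])
  point_keys <- names(tree_biparts(point))
  counts <- stats::setNames(rep(0, length(point_keys)), point_keys)
  for (bt in bs) {
    hit <- intersect(names(tree_biparts(bt)), point_keys)
    counts[hit] <- counts[hit] + 1
  }
  supported_tree(point, bv = round(100 * counts / n_rep, 4))
}

#' Reference total log-likelihood by exhaustive state summation
#'
#' Independent validation routine: computes the alignment log-likelihood
#' on a small tree by brute-force summation over all joint internal-node
#' states, mixing the invariant spike and gamma categories explicitly.
#' Exponential-time in the number of internal nodes; intended for trees
#' with at most 5 leaves as a cross-check of the pruning-based engine.
#'
#' @param tree A rooted or unrooted `phylo` with branch lengths (<= 5
#'   leaves recommended).
#' @param fam A `gene_family` on the same leaves.
#' @param model An [substitution_model()].
#' @return Total log-likelihood (numeric scalar).
#' @export
loglik_enumeration <- function(tree, fam, model = substitution_model()) {
  phy <- as_phylo(tree)
  fit <- pml_of(phy, fam, model)          # source of WAG parameters only
  bf <- fit$bf
  Qv <- fit$Q
  M <- matrix(0, 20, 20)
  M[lower.tri(M)] <- Qv
  M <- M + t(M)
  R <- M %*% diag(bf)
  diag(R) <- -rowSums(R)
  R <- R / (-sum(bf * diag(R)))
  e <- eigen(R)
  V <- e$vectors
  Vi <- solve(V)
  Pt <- function(t) {
    P <- Re(V %*% diag(exp(e$values * t)) %*% Vi)
    P[P < 0] <- 0
    P
  }
  lev <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

  # state indicator per tip and site: 20-vector, ambiguous = all ones
  seqmat <- do.call(rbind, strsplit(fam$seqs, ""))
  rownames(seqmat) <- names(fam$seqs)
  tipvec <- function(ch) {
    if (ch %in% lev) {
      v <- numeric(20); v[match(ch, lev)] <- 1; v
    } else {
      rep(1, 20)
    }
  }

  rphy <- if (ape::is.rooted(phy)) phy else
    ape::root(phy, outgroup = phy$tip.label[1], resolve.root = TRUE)
  n <- length(rphy$tip.label)
  nint <- rphy$Nnode
  edges <- rphy$edge
  elen <- rphy$edge.length
  gam <- discretize_gamma(model$alpha, model$n_cat)
  pinv <- model$p_inv
  grates <- gam$rates / (1 - pinv)
  gw <- rep((1 - pinv) / model$n_cat, model$n_cat)

  int_nodes <- (n + 1):(n + nint)
  combos <- as.matrix(expand.grid(rep(list(1:20), nint)))
  int_col <- function(node) match(node, int_nodes)
  # transition matrices per category x edge (site-independent)
  Pcat <- lapply(grates, function(r) {
    lapply(seq_len(nrow(edges)), function(i) Pt(elen[i] * r))
  })
  sitesll <- numeric(fam$n_sites)
  for (s in seq_len(fam$n_sites)) {
    tv <- lapply(rphy$tip.label, function(lab) tipvec(seqmat[lab, s]))
    # invariant spike: a residue shared compatibly across all tips
    Ls <- pinv * sum(bf * Reduce(`*`, tv))
    for (kk in seq_along(grates)) {
      P <- Pcat[[kk]]
      pr <- bf[combos[, int_col(n + 1L)]]
      for (i in seq_len(nrow(edges))) {
        a_idx <- combos[, int_col(edges[i, 1])]
        chn <- edges[i, 2]
        if (chn <= n) {
          pr <- pr * as.numeric(P[[i]] %*% tv[[chn]])[a_idx]
        } else {
          pr <- pr * P[[i]][cbind(a_idx, combos[, int_col(chn)])]
        }
      }
      Ls <- Ls + gw[kk] * sum(pr)
    }
    sitesll[s] <- log(Ls)
  }
  sum(sitesll)
}
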