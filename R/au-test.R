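#' Multiscale RELL bootstrap of site log-likelihoods
#'
#' Resampling of estimated log-likelihoods (RELL): for each scale factor
#' `r`, alignment sites are resampled with replacement to a length of
#' `round(r * n_sites)`, `n_rep` times, and each candidate topology's
#' resampled total log-likelihood is formed from its per-site values
#' without re-optimizing anything. The bootstrap proportion `bp_r` of a
#' topology is the fraction of resamples in which it attains the maximum
#' total (ties broken uniformly at random). Resampling is realised
#' through multinomial site-count weights, which is equivalent to drawing
#' site indices and considerably faster.
#'
#' @param site_ll Numeric matrix, topologies x sites, of per-site
#'   log-likelihoods (rownames are topology ids).
#' @param scales Positive scale factors `r` (default the canonical ten,
#'   0.5 to 1.4).
#' @param n_rep Replicates per scale.
#' @param seed Integer seed.
#' @return Matrix of bootstrap proportions, topologies x scales, with
#'   attributes `scales` and `n_rep`.
#' @export
rell_bootstrap <- function(site_ll, scales = seq(0.5, 1.4, by = 0.1),
                           n_rep = 10000, seed = 1) {
  site_ll <- as.matrix(site_ll)
  k <- nrow(site_ll)
  n <- ncol(site_ll)
  if (k < 2) stop("at least two topologies are required")
  if (n < 2) stop("at least two sites are required")
  if (any(scales <= 0)) stop("scales must be positive")
  set.seed(seed)
  bp <- matrix(0, k, length(scales),
               dimnames = list(rownames(site_ll), paste0("r", scales)))
  for (j in seq_along(scales)) {
    m <- max(2L, as.integer(round(scales[j] * n)))
    # site-count weights, built in replicate chunks to bound memory
    chunk <- min(n_rep, max(256L, as.integer(4e6 / m)))
    wins <- integer(k)
    done <- 0L
    while (done < n_rep) {
      b <- min(chunk, n_rep - done)
      idx <- pmin(as.integer(stats::runif(m * b) * n) + 1L, n)
      lin <- idx + rep(seq_len(b) - 1L, each = m) * n
      counts <- matrix(tabulate(lin, nbins = n * b), n, b)
      totals <- site_ll %*% counts                   # k x b
      win <- max.col(t(totals), ties.method = "random")
      wins <- wins + tabulate(win, nbins = k)
      done <- done + b
    }
    bp[, j] <- wins / n_rep
  }
  attr(bp, "scales") <- scales
  attr(bp, "n_rep") <- n_rep
  bp
}

#' AU p-value from multiscale bootstrap proportions
#'
#' Fits the signed-distance/curvature model of the approximately unbiased
#' test: with `z_r = qnorm(1 - bp_r)`, the model `z_r = d * sqrt(r) +
#' c / sqrt(r)` is fit by weighted least squares, with delta-method
#' binomial weights `n_rep * dnorm(z_r)^2 / (bp_r (1 - bp_r))`, and the
#' p-value is `1 - pnorm(d - c)`. Proportions are clamped to
#' `[1/(2 n_rep), 1 - 1/(2 n_rep)]` before the probit transform; scales
#' whose pre-clamp proportion is exactly 0 or 1 are dropped from the fit
#' when at least four scales remain. If every scale is degenerate the
#' p-value is clamped to 0 or 1 and flagged.
#'
#' @param bp Numeric vector of bootstrap proportions, one per scale.
#' @param scales The scale factors the proportions were computed at.
#' @param n_rep Replicates per scale.
#' @return List with `p_au`, `d`, `c`, `degenerate`.
#' @export
au_pvalue <- function(bp, scales = seq(0.5, 1.4, by = 0.1), n_rep = 10000) {
  bp <- as.numeric(bp)
  if (length(bp) != length(scales)) stop("bp and scales differ in length")
  deg <- bp <= 0 | bp >= 1
  if (all(deg)) {
    p <- if (mean(bp) >= 0.5) 1 else 0
    return(list(p_au = p, d = NA_real_, c = NA_real_, degenerate = TRUE))
  }
  keep <- if (sum(!deg) >= 4) !deg else rep(TRUE, length(bp))
  r <- scales[keep]
  eps <- 1 / (2 * n_rep)
  b <- pmin(pmax(bp[keep], eps), 1 - eps)
  z <- stats::qnorm(1 - b)
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- n_rep * stats::dnorm(z)^2 / (b * (1 - b))
  fit <- stats::lm.wfit(X, z, w)
  d <- unname(fit$coefficients[1])
  cc <- unname(fit$coefficients[2])
  p <- 1 - stats::pnorm(d - cc)
  list(p_au = min(max(p, 0), 1), d = d, c = cc, degenerate = any(deg))
}

#' Approximately unbiased test over a pool of topologies
#'
#' Runs the multiscale RELL bootstrap on a site log-likelihood matrix and
#' computes each topology's AU p-value. A small p-value rejects the
#' topology as an explanation of the data; the maximum-likelihood
#' topology is expected to survive at conventional levels.
#'
#' @inheritParams rell_bootstrap
#' @return An `au_test` data.frame with columns `topology`, `log_lik`,
#'   `d`, `c`, `p_au`, `degenerate`, and the bootstrap-proportion matrix
#'   as attribute `bp`.
#' @export
au_test <- function(site_ll, scales = seq(0.5, 1.4, by = 0.1),
                    n_rep = 10000, seed = 1) {
  site_ll <- as.matrix(site_ll)
  if (is.null(rownames(site_ll))) {
    rownames(site_ll) <- paste0("topo", seq_len(nrow(site_ll)))
  }
  bp <- rell_bootstrap(site_ll, scales, n_rep, seed)
  res <- lapply(seq_len(nrow(site_ll)), function(i) {
    au_pvalue(bp[i, ], scales, n_rep)
  })
  out <- data.frame(
    topology = rownames(site_ll),
    log_lik = rowSums(site_ll),
    d = vapply(res, `[[`, numeric(1), "d"),
    c = vapply(res, `[[`, numeric(1), "c"),
    p_au = vapply(res, `[[`, numeric(1), "p_au"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  attr(out, "bp") <- bp
  class(out) <- c("au_test", "data.frame")
  out
}

#' Exhaustive re-grafting AU scan of the chlorarachniophyte branch
#'
#' The topology test at the heart of the screen: the chlorarachniophyte
#' branch is pruned and re-grafted onto every edge of the remaining tree
#' (whose topology stays fixed), each placement's branch lengths (and
#' optionally rate parameters) are re-optimized, per-site log-likelihoods
#' are collected, and the AU test is applied to the whole pool. Each
#' placement is labelled with the lineage composition of the backbone
#' clade it attaches to, so summaries such as "every placement inside the
#' Chloroplastida is rejected" can be read off directly.
#'
#' @param tree A `phylo` or `supported_tree` with branch lengths (the ML
#'   gene tree).
#' @param fam The `gene_family` alignment.
#' @param leafset The leaves of the branch to re-graft (the
#'   chlorarachniophyte OTUs); must be monophyletic in `tree`.
#' @param taxa A `taxon_table` (labels the attachment neighborhoods).
#' @param model An [substitution_model()]; the AU stage default is
#'   WAG+F+I+G4.
#' @param scales,n_rep,seed RELL bootstrap settings.
#' @param optimize_rates Re-estimate alpha / p_inv per placement
#'   (default) or freeze them at the model's values.
#' @return An `au_scan` data.frame with one row per placement:
#'   `placement`, `neighborhood`, `attachment_size`, `identity` (the
#'   input placement), `log_lik`, `d`, `c`, `p_au`, `degenerate`.
#'   Attributes: `bp`, `attachment` (tip sets), `trees`.
#' @export
regraft_au_scan <- function(tree, fam, leafset, taxa,
                            model = substitution_model(plus_F = TRUE,
                                                       p_inv = 0.05),
                            scales = seq(0.5, 1.4, by = 0.1),
                            n_rep = 10000, seed = 1,
                            optimize_rates = TRUE) {
  placements <- enumerate_regrafts(tree, leafset)
  att <- attr(placements, "attachment")
  ident <- attr(placements, "identity")
  k <- length(placements)
  sll <- NULL
  lls <- numeric(k)
  opt_trees <- vector("list", k)
  for (i in seq_len(k)) {
    opt <- optimize_branch_lengths(placements[[i]], fam, model,
                                   optimize_rates = optimize_rates)
    if (is.null(sll)) sll <- matrix(0, k, length(opt$site_log_lik))
    sll[i, ] <- opt$site_log_lik
    lls[i] <- opt$log_lik
    opt_trees[[i]] <- opt$tree
  }
  rownames(sll) <- sprintf("placement_%02d", seq_len(k))
  res <- au_test(sll, scales = scales, n_rep = n_rep, seed = seed)
  nb <- vapply(att, function(tips) {
    paste(sort(unique(lineage_of(taxa, tips))), collapse = "+")
  }, character(1))
  out <- data.frame(
    placement = rownames(sll),
    neighborhood = nb,
    attachment_size = lengths(att),
    identity = ident,
    log_lik = lls,
    d = res$d, c = res$c, p_au = res$p_au, degenerate = res$degenerate,
    stringsAsFactors = FALSE
  )
  attr(out, "bp") <- attr(res, "bp")
  attr(out, "attachment") <- att
  attr(out, "trees") <- opt_trees
  class(out) <- c("au_scan", "data.frame")
  out
}

#' @export
print.au_scan <- function(x, ...) {
  cat("Re-graft AU scan:", nrow(x), "placements\n")
  df <- as.data.frame(x)[, c("placement", "neighborhood", "identity",
                             "log_lik", "p_au")]
  df$log_lik <- round(df$log_lik, 2)
  df$p_au <- signif(df$p_au, 3)
  print(df[order(-df$log_lik), ], row.names = FALSE)
  invisible(x)
}

#' Write a site log-likelihood matrix in CONSEL-style layout
#'
#' Plain-text layout readable by CONSEL-compatible tools: a header line
#' with the number of topologies and sites, then one line per topology
#' with its id and the per-site log-likelihood values.
#'
#' @param site_ll Topologies x sites matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_ll <- function(site_ll, path) {
  site_ll <- as.matrix(site_ll)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(site_ll), ncol(site_ll)), con)
  ids <- rownames(site_ll)
  if (is.null(ids)) ids <- paste0("topo", seq_len(nrow(site_ll)))
  for (i in seq_len(nrow(site_ll))) {
    writeLines(paste(c(ids[i], format(site_ll[i, ], digits = 10)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a site log-likelihood matrix written by [write_site_ll()]
#'
#' @param path Input path.
#' @return Topologies x sites numeric matrix.
#' @export
read_site_ll <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  ids <- vapply(rows, `[`, character(1), 1)
  vals <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  if (nrow(vals) != hdr[1] || ncol(vals) != hdr[2]) {
    stop("site log-likelihood file is inconsistent with its header")
  }
  rownames(vals) <- ids
  vals
}
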