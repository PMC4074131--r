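test_that("discrete gamma categories are normalized and match quadrature", {
  expect_equal(discretize_gamma(0.7, 1)$rates, 1)
  # oracle: conditional means of the gamma(a, a) distribution over its
  # quartiles by high-resolution numerical integration
  a <- 1
  qs <- stats::qgamma(seq(0, 1, by = 0.25), shape = a, rate = a)
  oracle <- vapply(1:4, function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, a, a), qs[i], qs[i + 1],
                     rel.tol = 1e-12)$value * 4
  }, numeric(1))
  got <- discretize_gamma(1, 4)
  expect_equal(got$rates, oracle / mean(oracle), tolerance = 1e-8)
  expect_equal(got$weights, rep(0.25, 4))
  expect_error(discretize_gamma(-1, 4), "alpha")
})

test_that("per-site log-likelihoods sum to the total and hit the zero-distance limit", {
  tr <- random_tree(5, seed = 2)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 40, seed = 3)
  sll <- site_log_likelihoods(tr, fam, substitution_model(alpha = 0.8))
  expect_length(sll, 40)
  expect_true(all(is.finite(sll)))

  # near-zero total branch length with identical sequences: per-site lnL
  # approaches log of the stationary frequency of the site's residue
  star <- ape::read.tree(text = "(A:1e-9,B:1e-9,C:1e-9);")
  seqs <- stats::setNames(rep("ARND", 3), c("A", "B", "C"))
  fam0 <- gene_family("zero", seqs)
  m1 <- substitution_model(n_cat = 1)
  sll0 <- site_log_likelihoods(star, fam0, m1)
  fit <- egtscreen:::pml_of(star, fam0, m1)
  bf <- fit$bf
  lev <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  expect_equal(sll0, log(bf[match(c("A", "R", "N", "D"), lev)]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pruning likelihood matches exhaustive state summation", {
  for (seed in 1:3) {
    n_taxa <- 3 + seed %% 2           # 4- and 5-leaf trees
    tr <- random_tree(n_taxa + 1, seed = seed)
    fam <- simulate_alignment(tr, substitution_model(), n_sites = 20,
                              seed = seed + 10)
    model <- substitution_model(p_inv = 0.1, alpha = 0.7)
    pruning <- sum(site_log_likelihoods(tr, fam, model))
    brute <- loglik_enumeration(tr, fam, model)
    expect_equal(pruning, brute, tolerance = 1e-8)
  }
})

test_that("gamma and invariant machinery reduce to plain WAG in the limits", {
  tr <- random_tree(5, seed = 4)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 60, seed = 5)
  plain <- sum(site_log_likelihoods(tr, fam, substitution_model(n_cat = 1)))
  reduced <- sum(site_log_likelihoods(
    tr, fam, substitution_model(p_inv = 0, n_cat = 1)))
  expect_equal(reduced, plain, tolerance = 1e-12)
  # very large alpha concentrates all categories at rate 1
  big_alpha <- sum(site_log_likelihoods(
    tr, fam, substitution_model(alpha = 1e6, n_cat = 4)))
  expect_equal(big_alpha, plain, tolerance = 1e-6)
})

test_that("likelihood is invariant to rerooting (pulley principle)", {
  tr <- random_tree(6, seed = 6)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 50, seed = 7)
  model <- substitution_model(alpha = 0.9)
  ref <- sum(site_log_likelihoods(tr, fam, model))
  for (og in tr$tip.label[1:3]) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(sum(site_log_likelihoods(rr, fam, model)), ref,
                 tolerance = 1e-10)
  }
})

test_that("branch-length optimization improves monotonically and is a fixed point", {
  tr <- random_tree(6, seed = 8)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 300, seed = 9)
  start <- tr
  start$edge.length <- rep(0.3, nrow(start$edge))
  ll_start <- sum(site_log_likelihoods(start, fam, substitution_model()))
  opt <- optimize_branch_lengths(start, fam, substitution_model())
  expect_gte(opt$log_lik, ll_start)
  reopt <- optimize_branch_lengths(opt$tree, fam, substitution_model())
  expect_equal(reopt$log_lik, opt$log_lik, tolerance = 1e-4)
  expect_equal(sum(opt$site_log_lik), opt$log_lik, tolerance = 1e-8)
})

test_that("branch lengths are recovered from long simulated alignments", {
  tr <- random_tree(6, seed = 10)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 5000,
                            seed = 11)
  opt <- optimize_branch_lengths(tr, fam, substitution_model())
  # compare patristic distance matrices, robust to edge identity
  d_true <- ape::cophenetic.phylo(tr)
  d_est <- ape::cophenetic.phylo(opt$tree)
  d_est <- d_est[rownames(d_true), colnames(d_true)]
  rel <- abs(d_est - d_true) / pmax(d_true, 1e-9)
  expect_lt(stats::median(rel[upper.tri(rel)]), 0.15)
})

test_that("infer_tree recovers a strong-signal topology and the 4-taxon optimum", {
  set.seed(12)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- ifelse(tr$edge[, 2] <= 6, 0.15, 0.5)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 2000,
                            seed = 13)
  est <- infer_tree(fam, substitution_model(), seed = 1)
  expect_equal(phangorn::RF.dist(est, tr), 0)

  # 4 taxa: the inferred topology must be the best of the three possible
  tr4 <- ape::read.tree(text = "((A:0.2,B:0.2):0.3,(C:0.2,D:0.2):0.0);")
  fam4 <- simulate_alignment(ape::unroot(tr4), substitution_model(),
                             n_sites = 800, seed = 14)
  est4 <- infer_tree(fam4, substitution_model(), seed = 1)
  topos <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                  function(t) ape::unroot(ape::read.tree(text = t)))
  lls <- vapply(topos, function(t) {
    optimize_branch_lengths(t, fam4, substitution_model())$log_lik
  }, numeric(1))
  best <- topos[[which.max(lls)]]
  expect_equal(phangorn::RF.dist(est4, best), 0)
})

test_that("inferred topology does not depend on input sequence order", {
  tr <- random_tree(6, seed = 15)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 400,
                            seed = 16)
  est1 <- infer_tree(fam, substitution_model(), seed = 1)
  fam_perm <- gene_family(fam$family_id, rev(fam$seqs))
  est2 <- infer_tree(fam_perm, substitution_model(), seed = 1)
  expect_equal(phangorn::RF.dist(est1, est2), 0)
})

test_that("bootstrap values are percentages with expected degenerate behavior", {
  tr <- random_tree(6, seed = 17)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 300,
                            seed = 18)
  one <- bootstrap_support(fam, substitution_model(), n_rep = 1, seed = 1,
                           search = "nj")
  expect_true(all(one$bv %in% c(0, 100)))
  a <- bootstrap_support(fam, substitution_model(), n_rep = 20, seed = 5,
                         search = "nj")
  b <- bootstrap_support(fam, substitution_model(), n_rep = 20, seed = 5,
                         search = "nj")
  expect_identical(a$bv, b$bv)
})
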