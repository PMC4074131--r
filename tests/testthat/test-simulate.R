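test_that("simulated gene trees realize their declared histories", {
  for (h in c("GREEN_EGT", "RED_HGT_CASH", "RED_HGT_RHODOPHYTE",
              "SPLIT_HGT")) {
    for (seed in 1:10) {
      gt <- simulate_gene_tree(sim_scenario(h, seed = seed))
      taxa <- gt$taxa
      chl <- taxa$otu_id[taxa$lineage == "Chlorarachniophyta"]
      expect_true(cyano_basal_check(gt$tree, taxa))
      call <- classify_affiliation(gt$tree, taxa)
      expected <- switch(h, GREEN_EGT = "GREEN", RED_HGT_CASH = "CASH_TYPE",
                         RED_HGT_RHODOPHYTE = "RED_TYPE",
                         SPLIT_HGT = "SPLIT")
      expect_equal(call$class, expected,
                   info = sprintf("%s seed %d", h, seed))
      if (h == "SPLIT_HGT") {
        expect_false(length(chl) == 1 ||
                       classify_affiliation(gt$tree, taxa)$chlor_monophyletic)
      }
      expect_true(all(gt$tree$edge.length > 0))
    }
  }
})

test_that("scenario constraints are validated", {
  expect_error(sim_scenario("SPLIT_HGT", n_chlor = 1), "at least 2")
  expect_error(sim_scenario("RED_HGT_CASH", n_cash = 0), "n_cash")
})

test_that("simulation on a near-zero-length star yields identical sequences", {
  star <- ape::read.tree(text = "(A:1e-9,B:1e-9,C:1e-9,D:1e-9);")
  fam <- simulate_alignment(star, substitution_model(), n_sites = 100,
                            seed = 1)
  expect_length(unique(fam$seqs), 1)
})

test_that("simulated residue frequencies approach the model's frequencies", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  fam <- simulate_alignment(tr, substitution_model(n_cat = 1),
                            n_sites = 17000, seed = 2)
  obs <- table(strsplit(paste(fam$seqs, collapse = ""), "")[[1]])
  obs <- obs / sum(obs)
  fit <- egtscreen:::pml_of(tr, fam, substitution_model(n_cat = 1))
  lev <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  bf <- stats::setNames(fit$bf, lev)    # WAG stationary frequencies
  tv <- sum(abs(obs[lev] - bf)) / 2
  expect_lt(tv, 0.02)
})

test_that("observed divergence grows with path length on a caterpillar", {
  txt <- "(t1:0.05,(t2:0.05,(t3:0.05,(t4:0.05,t5:0.4):0.3):0.2):0.1);"
  tr <- ape::read.tree(text = txt)
  fam <- simulate_alignment(tr, substitution_model(), n_sites = 3000,
                            seed = 3)
  pdiff <- function(a, b) {
    x <- strsplit(fam$seqs[[a]], "")[[1]]
    y <- strsplit(fam$seqs[[b]], "")[[1]]
    mean(x != y)
  }
  d12 <- pdiff("t1", "t2")
  d13 <- pdiff("t1", "t3")
  d15 <- pdiff("t1", "t5")
  expect_lt(d12, d13)
  expect_lt(d13, d15)
})

test_that("corruption closes the loop with trimming and deduplication", {
  scn <- sim_scenario("RED_HGT_CASH", seed = 4)
  gt <- simulate_gene_tree(scn)
  fam <- simulate_alignment(gt$tree, scn$model, 500, seed = 5)

  cor <- corrupt_alignment(fam, gt$taxa, gap_rate = 0.2, seed = 6,
                           gap_targets = "GR01")
  gf <- gap_fraction(cor$family)
  expect_gte(gf[["GR01"]], 0.18)
  expect_lte(gf[["GR01"]], 0.22)
  tr <- trim_alignment(cor$family)
  expect_true("GR01" %in% tr$dropped)

  cor2 <- corrupt_alignment(fam, gt$taxa, n_redundant = 2, seed = 7)
  expect_length(cor2$family$seqs, length(fam$seqs) + 2)
  dd <- dedupe_species(cor2$family, cor2$taxa)
  expect_length(dd$seqs, length(fam$seqs))

  none <- corrupt_alignment(fam, gt$taxa, seed = 8)
  expect_equal(none$family$seqs, fam$seqs)
})

test_that("every history passes or fails the screen gates as it should", {
  # truth table on the *true* trees: all histories pass the cyano gates;
  # only SPLIT_HGT fails chlorarachniophyte monophyly
  for (h in c("GREEN_EGT", "RED_HGT_CASH", "SPLIT_HGT")) {
    for (seed in 1:5) {
      gt <- simulate_gene_tree(sim_scenario(h, seed = seed))
      taxa <- gt$taxa
      chl <- taxa$otu_id[taxa$lineage == "Chlorarachniophyta"]
      expect_gte(count_lineage(gt$tree, taxa, "Cyanobacteria"), 3)
      expect_true(cyano_basal_check(gt$tree, taxa))
      mono <- length(chl) == 1 ||
        bipartition_support(gt$tree, chl)$present
      expect_equal(mono, h != "SPLIT_HGT")
    }
  }
})

test_that("families are reproducible from their scenario seed", {
  a <- simulate_family(sim_scenario("RED_HGT_CASH", seed = 11,
                                    gap_rate = 0.2, n_redundant = 1))
  b <- simulate_family(sim_scenario("RED_HGT_CASH", seed = 11,
                                    gap_rate = 0.2, n_redundant = 1))
  expect_identical(a$family$seqs, b$family$seqs)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})
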