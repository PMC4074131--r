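test_that("parse_newick reads supports in both encodings", {
  st <- parse_newick("((A:1,B:1)95:0.5,C:1,D:1);")
  s <- bipartition_support(st, c("A", "B"))
  expect_true(s$present)
  expect_equal(s$bv, 95)
  expect_true(is.na(s$pp))

  st2 <- parse_newick("((A,B)95[&pp=0.99],C,D);")
  s2 <- bipartition_support(st2, c("A", "B"))
  expect_equal(s2$bv, 95)
  expect_equal(s2$pp, 0.99)

  st3 <- parse_newick("((A,B)0.98,C,D);", dialect = "pp")
  expect_equal(bipartition_support(st3, c("A", "B"))$pp, 0.98)
})

test_that("parse_newick rejects malformed input", {
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate leaf")
  expect_error(parse_newick("((A,B,(C,D));"), "unbalanced")
})

test_that("write_newick round-trips topology and supports", {
  st <- parse_newick("((A:1,B:2)95[&pp=0.99]:0.5,(C:1,D:1)80:0.3,E:1);")
  txt <- write_newick(st)
  st2 <- parse_newick(txt)
  expect_equal(phangorn::RF.dist(st$phy, st2$phy), 0)
  for (q in list(c("A", "B"), c("C", "D"))) {
    expect_equal(bipartition_support(st2, q), bipartition_support(st, q))
  }
})

test_that("bipartition_support distinguishes present and absent splits", {
  st <- parse_newick("((A,B)99,(C,D));")
  expect_true(bipartition_support(st, c("A", "B"))$present)
  expect_false(bipartition_support(st, c("A", "C"))$present)
  expect_true(bipartition_support(st, "A")$present)  # singleton, trivially
  expect_error(bipartition_support(st, c("A", "ZZ")), "not in the tree")
})

test_that("bipartition_support agrees with an exhaustive edge-scan oracle", {
  # oracle: independently enumerate clades via ape::prop.part on a rooted
  # copy, complementing where necessary
  oracle_present <- function(phy, leafset) {
    n <- length(phy$tip.label)
    pp <- ape::prop.part(phy)
    labs <- attr(pp, "labels")
    sets <- lapply(pp, function(i) labs[i])
    any(vapply(sets, function(s) {
      setequal(s, leafset) || setequal(setdiff(labs, s), leafset)
    }, logical(1)))
  }
  set.seed(7)
  for (rep in 1:40) {
    tr <- random_tree(10, seed = rep)
    k <- sample(2:8, 1)
    q <- sample(tr$tip.label, k)
    got <- bipartition_support(tr, q)$present
    expect_identical(got, oracle_present(tr, q),
                     info = sprintf("rep %d query %s", rep,
                                    paste(q, collapse = ",")))
  }
})

test_that("count_lineage matches direct leaf filtering", {
  taxa <- screen_taxa()
  st <- parse_newick("((CY01,CY02),(GR01,(CH01,CH02)));")
  expect_equal(count_lineage(st, taxa, "Cyanobacteria"), 2)
  expect_equal(count_lineage(st, taxa, "Rhodophyceae"), 0)
  expect_equal(count_lineage(st, taxa, "Chlorarachniophyta"), 2)
})

test_that("cyano_basal_check requires 3 cyanobacteria and basal placement", {
  taxa <- screen_taxa()
  ok <- parse_newick("((CY01,CY02,CY03),(GR01,(GR02,CH01)));")
  expect_true(cyano_basal_check(ok, taxa))
  few <- parse_newick("((CY01,CY02),(GR01,GR02,CH01));")
  expect_false(cyano_basal_check(few, taxa))
  interleaved <- parse_newick("((CY01,GR01),(CY02,(CY03,GR02)));")
  expect_false(cyano_basal_check(interleaved, taxa))
})

test_that("classify_affiliation types the canonical tree shapes", {
  taxa <- screen_taxa()
  # chlorarachniophyte clade sister to a stramenopile+haptophyte clade
  cash <- parse_newick(paste0(
    "((CY01,CY02,CY03),((GR01,GR02),((RH01,RH02),",
    "((CH01,CH02)97,(CA01,CA02)))));"))
  call <- classify_affiliation(cash, taxa)
  expect_equal(call$class, "CASH_TYPE")
  expect_true(call$chlor_monophyletic)
  expect_equal(call$chlor_clade_bv, 97)

  # chlorarachniophytes with the red algae, CASH elsewhere
  red <- parse_newick(paste0(
    "((CY01,CY02,CY03),((GR01,GR02),(((CH01,CH02),(RH01,RH02))88,",
    "(CA01,CA02))));"))
  call_red <- classify_affiliation(red, taxa)
  expect_equal(call_red$class, "RED_TYPE")
  expect_equal(call_red$red_affiliation_bv, 88)

  # two chlorarachniophytes attached in disjoint regions
  split <- parse_newick(paste0(
    "((CY01,CY02,CY03),((GR01,GR02),((CH01,(RH01,RH02)),",
    "(CH02,(CA01,CA02)))));"))
  expect_equal(classify_affiliation(split, taxa)$class, "SPLIT")

  # inside the Chloroplastida
  green <- parse_newick(paste0(
    "((CY01,CY02,CY03),(((CH01,CH02),(GR01,GR02)),((RH01,RH02),",
    "(CA01,CA02))));"))
  expect_equal(classify_affiliation(green, taxa)$class, "GREEN")

  # mixed red-lineage sister
  amb <- parse_newick(paste0(
    "((CY01,CY02,CY03),((GR01,GR02),((CH01,CH02),(RH01,CA01))));"))
  expect_equal(classify_affiliation(amb, taxa)$class, "AMBIGUOUS_RED")

  expect_error(
    classify_affiliation(parse_newick("((CY01,CY02),(GR01,GR02));"), taxa),
    "no chlorarachniophyte")
})

test_that("classification ignores nuisance OTUs and walks past them", {
  taxa <- make_taxa(
    c("CY01", "CY02", "CY03", "GR01", "GR02", "RH01", "RH02", "CH01",
      "CH02", "EU01", "OX01"),
    c(rep("Cyanobacteria", 3), rep("Chloroplastida", 2),
      rep("Rhodophyceae", 2), rep("Chlorarachniophyta", 2),
      "Euglenophyta", "OtherEukaryote"))
  # first sister is a plastid-lacking eukaryote, then a euglenophyte,
  # then the red algae: the walk must reach the red algae
  tr <- parse_newick(paste0(
    "((CY01,CY02,CY03),((GR01,GR02),((((CH01,CH02),OX01),EU01),",
    "(RH01,RH02))));"))
  call <- classify_affiliation(tr, taxa)
  expect_equal(call$class, "RED_TYPE")
})

test_that("classification is invariant to rotation and cyano-side rerooting", {
  taxa <- screen_taxa()
  base <- "((CY01,CY02,CY03),((GR01,GR02),((RH01,RH02),((CH01,CH02),(CA01,CA02)))));"
  ref <- classify_affiliation(parse_newick(base), taxa)$class
  phy <- parse_newick(base)$phy
  set.seed(1)
  for (i in 1:5) {
    rot <- ape::rotateConstr(phy, sample(phy$tip.label))
    expect_equal(classify_affiliation(supported_tree(rot), taxa)$class, ref)
  }
  for (og in c("CY01", "CY02", "CY03")) {
    rr <- ape::root(ape::unroot(phy), outgroup = og, resolve.root = TRUE)
    expect_equal(classify_affiliation(supported_tree(rr), taxa)$class, ref)
  }
})

test_that("enumerate_regrafts yields 2m-3 distinct placements", {
  for (m in 3:8) {
    # backbone of m leaves plus a 2-leaf group to re-graft
    back_labs <- sprintf("b%d", seq_len(m))
    txt <- sprintf("((X1,X2),%s);",
                   paste0("(", paste(back_labs, collapse = ","), ")"))
    phy <- ape::unroot(ape::multi2di(ape::read.tree(text = txt),
                                     random = FALSE))
    rg <- enumerate_regrafts(phy, c("X1", "X2"))
    expect_length(rg, 2 * m - 3)
    d <- as.matrix(phangorn::RF.dist(rg))
    expect_true(all(d[upper.tri(d)] > 0))
    expect_equal(sum(attr(rg, "identity")), 1)
  }
})

test_that("enumerate_regrafts refuses non-monophyletic groups", {
  phy <- ape::read.tree(text = "((A,C),(B,D),(E,F));")
  expect_error(enumerate_regrafts(phy, c("A", "B")), "not monophyletic")
})
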