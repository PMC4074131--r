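# egtscreen

Phylogenomic screening for "red" genes in a green secondary phototroph.

## The problem

The chlorarachniophytes (Rhizaria) acquired their plastid by secondary
endosymbiosis of a **green** alga, so their nuclear genes of cyanobacterial
(plastid) origin should branch with the Chloroplastida. Some do not: they
branch with the **red lineage** — the red algae (Rhodophyceae) plus the
CASH groups (Cryptophyta, Alveolata, Stramenopiles, Haptophyta) — pointing
to horizontal gene transfer from red-plastid-bearing eukaryotes. Deciding
which gene families genuinely carry that signal takes a chain of filters
over single-gene phylogenies, and the conclusion is only as credible as
the chain is reproducible.

`egtscreen` implements that chain for R users working on endosymbiotic /
horizontal gene transfer detection:

* **Alignment prep** — drop sequences with > 15% gaps, falling back to a
  < 70% threshold when fewer than four sequences survive; remove redundant
  OTUs of the same species (least-gapped representative kept).
* **Origin filters** — require > 10 OTUs, ≥ 3 cyanobacterial OTUs, and the
  plastid-EGT tree shape (eukaryotes monophyletic, cyanobacteria basal).
* **Affiliation typing** — root on the cyanobacteria and classify the
  chlorarachniophyte clade's first informative sister: `GREEN`,
  `CASH_TYPE`, `RED_TYPE`, `AMBIGUOUS_RED`, `SPLIT` or `UNCLASSIFIED`,
  with BV ≥ 75 / PP ≥ 0.95 reported as strong support.
* **Placement testing** — re-graft the chlorarachniophyte branch onto
  every edge of the remaining topology (2m − 3 placements) and test each
  with a from-scratch **approximately unbiased (AU) test**: multiscale
  RELL bootstrap of site log-likelihoods at scales r ∈ {0.5, …, 1.4},
  probit fit z_r = d·√r + c/√r, p_AU = 1 − Φ(d − c).
* **Simulator** — gene families with known histories (green EGT vs red
  HGT, plus split histories), gap corruption and redundant OTUs, for
  end-to-end validation with no downloads.

Maximum likelihood under WAG+F+I+Γ4 (Felsenstein pruning, branch-length
optimization, NJ + NNI search, bootstrap) is provided through `phangorn`.

## Worked example

Simulate a gene family whose true history is a red-lineage HGT (the
chlorarachniophyte branch sister to the CASH clade), screen it, and test
all alternative placements:

```r
library(egtscreen)

sf  <- simulate_family(sim_scenario("RED_HGT_CASH", seed = 7, n_sites = 2000))
cfg <- screen_config(bootstrap_reps = 100, bootstrap_search = "nj")
v   <- screen_family(sf$family, sf$taxa, cfg)
v
#> Family 'red_hgt_cash_s7': RED_LINEAGE_CANDIDATE
#>   OTUs in/after prep: 15 / 15  trim pass: primary
#>   affiliation: CASH_TYPE
```

The verdict says the family passed every gate (trimming, OTU count,
cyanobacterial count, basal-cyanobacteria shape) and the
chlorarachniophyte clade's informative sister is CASH-only — a red-lineage
candidate. Now the placement test:

```r
tr   <- infer_tree(sf$family, substitution_model(p_inv = 0.05), seed = 7)
chl  <- sf$taxa$otu_id[sf$taxa$lineage == "Chlorarachniophyta"]
scan <- regraft_au_scan(tr, sf$family, chl, sf$taxa, n_rep = 10000, seed = 7)
head(as.data.frame(scan)[order(-scan$log_lik),
                         c("neighborhood", "identity", "log_lik", "p_au")], 4)
#>                          neighborhood identity   log_lik  p_au
#> Cryptophyta+Haptophyta+Stramenopiles      TRUE -38834.85 0.938
#> Cryptophyta+Haptophyta+Stramenopiles     FALSE -38894.37 0.109
#>                        Stramenopiles     FALSE -38894.37 0.230
#>    Crypt...+Rhodophyceae+Stramenopiles   FALSE -38979.51 0.000
```

The maximum-likelihood placement (the true one, sister to the CASH clade)
has p_AU = 0.94; every placement inside the Chloroplastida is rejected at
p ≤ 0.05 — exactly the logic used to argue that a candidate gene cannot
be a green-EGT relic.

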