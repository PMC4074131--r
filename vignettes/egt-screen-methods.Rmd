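---
title: "Methods: screening for red-lineage genes in a green secondary phototroph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for red-lineage genes in a green secondary phototroph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Chlorarachniophytes are rhizarian amoeboflagellates whose plastid derives
from secondary endosymbiosis of a green alga. Genes of cyanobacterial
(plastid) origin in their nuclear genome are therefore expected to branch
with the Chloroplastida: the green endosymbiont delivered them by
endosymbiotic gene transfer (EGT). Yet some such genes instead branch with
the *red* lineage — the red algae (Rhodophyceae) and the CASH groups
(Cryptophyta, Alveolata, Stramenopiles, Haptophyta), i.e. the eukaryotes
carrying red-algal secondary or tertiary plastids. Finding and
authenticating these "red" genes requires a long chain of filters over
single-gene phylogenies, and every link of that chain is a potential
source of artifacts. `egtscreen` implements the chain as tested,
deterministic code:

1. **Alignment preparation** — per-sequence gap-fraction trimming with a
   fallback threshold, and removal of redundant OTUs of the same species.
2. **Origin filters** — a gene qualifies as plastid-derived only if its
   tree contains at least three cyanobacterial OTUs *and* shows the
   plastid-EGT shape: all eukaryotes monophyletic with the cyanobacteria
   basal.
3. **Affiliation typing** — on the rooted tree, the chlorarachniophyte
   clade's first informative sister decides between green (Chloroplastida)
   and red (CASH-type, red-type, or ambiguous-red) affiliation.
4. **Placement testing** — the chlorarachniophyte branch is re-grafted
   onto every edge of the remaining topology and each placement is tested
   with an approximately unbiased (AU) test built on a multiscale RELL
   bootstrap of site log-likelihoods.

A paired simulator generates gene families whose true history is known
(green EGT versus red HGT), so the whole pipeline can be validated end to
end without any sequence database.

## Alignment preparation

The gap fraction of a sequence is the proportion of alignment columns in
which it carries `-`. Ambiguity codes (`X`, `B`, `Z`, `?`, `*`) are *not*
gaps: the thresholds target coverage, not residue uncertainty; in the
likelihood they are fully ambiguous states. The primary pass drops
sequences with more than 15% gaps (the boundary value 0.15 is kept). If
fewer than four sequences survive, that result is discarded and the
fallback pass keeps sequences with *less than* 70% gaps — a concession to
homolog sets drawn from low-coverage EST-like sources whose alignments
carry stretched gap runs. A family that even then retains fewer than two
sequences is flagged untrimmable rather than raising an error, so a bulk
screen records the failure and continues. Trimming removes whole
sequences, never columns, and is provably idempotent.

Deduplication keeps one OTU per species name. The representative is the
least-gapped sequence, ties broken by ungapped length and then
lexicographically by label. The rule itself is a package choice — any
deterministic rule would do — but determinism is required so that screens
are exactly reproducible.

## Lineage model

Every OTU maps to exactly one lineage group. Three sets drive all logic:
Cyanobacteria (rooting and origin filters), Chloroplastida (green
affiliation), and the red lineage, defined as Rhodophyceae plus the four
CASH groups. Glaucophyta and Euglenophyta are deliberately *neutral*:
they are plastid-bearing context OTUs that neither trigger a green call
nor count as red. Plastid-lacking eukaryotes (`OtherEukaryote`,
`plastid_bearing = false`) are likewise neutral. Cryptophyte nucleomorph
sequences are mapped to Cryptophyta like any nuclear cryptophyte
sequence; the screen has no need to distinguish provenance below the
lineage level.

## Affiliation classification

The classifier is deterministic. The unrooted gene tree is rooted on the
cyanobacterial side (valid because the basal-cyanobacteria filter has
already established eukaryote monophyly). If the chlorarachniophyte
leaves are not monophyletic the family is a `SPLIT` — the screen treats
it separately because placement testing of a single branch is undefined.
Otherwise enclosing clades are walked outward from the chlorarachniophyte
clade; a sister group is *informative* once it contains at least one
Chloroplastida or red-lineage leaf. Neutral OTUs never stop the walk:
a sister consisting only of, say, a kinetoplastid or a euglenophyte is
recorded and skipped. The first informative sister is then scored by its
plastid-bearing members: all-green gives `GREEN`; a red-lineage strict
majority gives `RED_TYPE` (red algae, no CASH), `CASH_TYPE` (CASH, no
red algae) or `AMBIGUOUS_RED` (both); everything else is `UNCLASSIFIED`.
The strict-majority rule is the package's resolution of mixed sisters,
which the underlying screening logic leaves open; it keeps a minority of
stray green or neutral leaves from vetoing an otherwise clear red signal.

Support for the red affiliation is reported as the BV/PP of the smallest
clade uniting the chlorarachniophytes with red-lineage OTUs, compared
against the strong-support thresholds BV ≥ 75 and PP ≥ 0.95. Posterior
probabilities are never computed by this package — Bayesian runs are out
of scope — but are honored when present as input annotations
(`[&pp=...]` comments in Newick input); with no PP available the
classifier works from BV alone.

## Likelihood engine

Likelihood computations use the WAG amino-acid model with optional
empirical frequencies (+F), a proportion of invariant sites (+I), and
four discrete-gamma rate categories (Γ4, equal-probability categories at
their conditional mean rates, renormalized to mean rate exactly 1). The
engine — Felsenstein pruning, branch-length optimization, NJ starting
trees, NNI hill-climbing, bootstrap resampling, and sequence simulation —
is provided by `phangorn`/`ape`, the standard R phylogenetics stack; the
WAG matrix itself comes from `phangorn`'s distribution of it. The package
adds an independent brute-force validator, `loglik_enumeration()`, which
sums over all joint internal-node states on ≤ 5-leaf trees and is used in
the test suite to pin the pruning likelihood to 1e-8.

Three model presets mirror the screen's stages: WAG+Γ4 for the fast
first-round filter, WAG+I+Γ4 for final bootstrap-annotated trees, and
WAG+F+I+Γ4 for site log-likelihoods entering the AU test. Rate parameters
(α, p_inv) are re-estimated per fit; for re-grafted placements they are
re-estimated per placement by default, with a flag to freeze them.

Bootstrap support offers two replicate search modes: `"ml"` repeats the
full NNI search per replicate and is the default; `"nj"` uses WAG
ML-distance neighbor-joining per replicate and is intended for large
batch screens, where per-replicate NNI would dominate the runtime without
changing any gate decision (bootstrap values are reported on candidates,
not used to discard them).

## The AU test

The AU implementation is from scratch. For scale factors
r ∈ {0.5, 0.6, …, 1.4} and `n_rep` = 10,000 replicates per scale, sites
are resampled with replacement to round(r·n) columns; the resample is
realised as multinomial site-count weights and the per-topology totals
are formed by a single matrix product per scale (RELL: no re-optimization
inside the bootstrap). With bp_r a topology's winning proportion at scale
r, the probit transform z_r = Φ⁻¹(1 − bp_r) is fit by weighted least
squares to z_r = d·√r + c/√r, with delta-method binomial weights
n_rep·φ(z_r)²/(bp_r(1 − bp_r)), and p_AU = 1 − Φ(d − c). Proportions are
clamped to [1/(2·n_rep), 1 − 1/(2·n_rep)] before the transform; scales
degenerate at exactly 0 or 1 are dropped from the fit when at least four
scales remain, and a fully degenerate topology gets p clamped to 0 or 1
with a flag. Calibration is checked empirically: under an iid mean-zero
normal site-difference null (300 sites, 2,000 replicates per scale, 500
datasets) the rejection rate at level 0.05 falls within [0.02, 0.09].

Ties in resampled totals are broken uniformly at random, which matters
only for the exact-tie case of duplicated site-likelihood vectors (the
symmetric case then yields bp ≈ 0.5, as it should).

## The re-grafting scan

`enumerate_regrafts()` prunes the chlorarachniophyte branch and
re-attaches its stem to every edge of the remaining unrooted topology:
2m − 3 placements for an m-leaf binary backbone, pairwise distinct by
bipartition sets and including the original placement. Branch lengths of
the candidates are deliberately unset; `regraft_au_scan()` re-optimizes
them (backbone topology fixed) before collecting site log-likelihoods.
Each placement is labelled with the lineage composition of the backbone
clade it attaches onto, so statements like "every placement inside the
Chloroplastida is rejected at p ≤ 0.05" can be read off the scan table.
Neighboring placements can share a fitted likelihood when the optimal
attachment point slides to a node between their two edges; they remain
distinct topologies and are reported separately.

## The screen pipeline

`screen_family()` chains the stages in order: trim → dedupe → OTU-count
gate (> 10 OTUs) → fast WAG+Γ4 tree (no bootstrap) → cyanobacteria-count
gate (≥ 3) → basal-cyanobacteria (EGT shape) gate → automated long-branch
removal → final WAG+I+Γ4 tree with bootstrap → affiliation call. The
first failing gate short-circuits with `FAILED_FILTER_<stage>`; verdicts
and a funnel summary come from `run_screen()`.

Two design choices deserve note. First, long-branch exclusion — done by
eye in manual practice — is replaced by a reproducible rule: terminal
branches longer than 5× the median terminal length are dropped,
iterating at most three rounds, with the chlorarachniophyte OTUs
protected and a refusal to shrink below four leaves. Second, the
cyanobacteria-count gate is applied at its own stage (on the fast tree);
if the long-branch rule subsequently thins the cyanobacteria, the final
tree is only required to retain the rootable EGT shape — a count gate
re-applied after pruning would retroactively discard families whose
origin evidence had already been established.

Per-family seeds are derived from the base seed and the family
identifier, making verdicts independent of input order and byte-identical
across re-runs.

## The simulator, and what passing tests do and do not show

`sim_scenario()` fixes the study conditions: 3 cyanobacteria, 4
Chloroplastida, 2 red algae, 4 CASH and 2 chlorarachniophyte OTUs
(15 OTUs, clearing the > 10 gate with no slack hidden in the defaults);
internal and terminal branch lengths exponential with means 0.2 and 0.15
substitutions/site; 500-site alignments under WAG+Γ4. Histories place the
chlorarachniophyte branch inside the Chloroplastida (`GREEN_EGT`), sister
to the CASH clade (`RED_HGT_CASH`), sister to the red algae
(`RED_HGT_RHODOPHYTE`), or split across two red-lineage attachments
(`SPLIT_HGT`). Corruption adds contiguous gap blocks (emulating truncated
EST-derived sequences, the reason the fallback trimming threshold exists)
and lightly mutated redundant OTUs (1% of sites, so the least-gapped
dedup rule has a well-defined winner).

The simulator emulates the statistical structure the screen assumes —
topology signal, rate heterogeneity, gap contamination, redundancy. It
does **not** model indel processes, heterotachy, compositional
heterogeneity, incomplete taxon sampling of real databases, or
nucleomorph-specific evolution. Passing the recovery experiments
therefore demonstrates that the pipeline's logic and statistics are
correct under its own model, not that real 2012-era database screens are
reproduced; the headline counts of any particular empirical screen depend
on the underlying databases and are out of scope here.

## Problem sizes and numerical choices

The validation experiments run at desk scale by choice: the likelihood
oracle uses 4–5 taxa × 30 sites; AU calibration uses 500 datasets of 300
sites with 2,000 replicates per scale; the bootstrap-signal experiment
uses 8 taxa × 500 sites × 200 replicates × 10 seeds; the end-to-end
recovery experiment screens 20 simulated families at simulator defaults
with 100 bootstrap replicates (distance-searched) per family; the
re-graft scan demonstration uses one 2,000-site family and 10,000 RELL
replicates per scale. The screen's production default remains 1,000
ML-searched bootstrap replicates.

Numerical details: branch lengths are floored at tiny positive values
where optimizers or simulators require strict positivity; non-finite
ML distances (saturated pairs) are capped at twice the largest finite
distance before neighbor-joining; gamma rates are renormalized to mean 1
after discretization and rescaled by 1/(1 − p_inv) in the presence of an
invariant class, in both the likelihood and the simulator, so the two
sides of every closed-loop test share one branch-length currency.

## Known limitations

* Tree search is NNI-only from an NJ start; no ratchet or SPR search, so
  pathological likelihood surfaces may retain the start's basin. The
  screen's gates are robust to this in simulation, but hard real families
  may warrant an external ML tree, which can be supplied as annotated
  Newick input.
* PP values are accepted, never computed.
* The AU implementation follows the standard multiscale-bootstrap
  construction with one documented weighting variant; it is validated by
  calibration and self-consistency, not against any external binary.
* `SPLIT` families are detected and reported but excluded from placement
  testing, where a single prunable branch is undefined.
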