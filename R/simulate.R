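#' Simulation scenario for a gene family with known transfer history
#'
#' Defines the study conditions a synthetic gene family is generated
#' under. Four histories are available: `GREEN_EGT` (the chlorarachniophyte
#' branch sits inside the Chloroplastida, the expectation under secondary
#' endosymbiotic gene transfer from the green plastid donor),
#' `RED_HGT_CASH` (sister to the CASH clade), `RED_HGT_RHODOPHYTE` (sister
#' to the red algae), and `SPLIT_HGT` (the two chlorarachniophyte OTUs
#' attach in two disjoint regions of the red lineage, emulating
#' gene-duplication/replacement histories). Cyanobacteria are always basal
#' to the plastid-bearing eukaryotes, as expected for a gene of
#' cyanobacterial origin.
#'
#' @param history One of `"GREEN_EGT"`, `"RED_HGT_CASH"`,
#'   `"RED_HGT_RHODOPHYTE"`, `"SPLIT_HGT"`.
#' @param n_cyano,n_green,n_red,n_cash,n_chlor Leaf counts per lineage
#'   (defaults 3/4/2/4/2 — the smallest configuration that passes every
#'   screen gate: 15 OTUs > 10, 3 cyanobacteria).
#' @param internal_branch,terminal_branch Expected branch lengths
#'   (exponential means, substitutions/site).
#' @param n_sites Alignment length.
#' @param model An [substitution_model()] used to evolve sequences.
#' @param gap_rate,n_redundant Corruption controls passed to
#'   [corrupt_alignment()].
#' @param seed Integer seed; the whole family is deterministic given it.
#' @return A `sim_scenario`.
#' @export
sim_scenario <- function(history = c("GREEN_EGT", "RED_HGT_CASH",
                                     "RED_HGT_RHODOPHYTE", "SPLIT_HGT"),
                         n_cyano = 3, n_green = 4, n_red = 2, n_cash = 4,
                         n_chlor = 2, internal_branch = 0.2,
                         terminal_branch = 0.15, n_sites = 500,
                         model = substitution_model(),
                         gap_rate = 0, n_redundant = 0, seed = 1) {
  history <- match.arg(history)
  if (n_chlor < 1) stop("n_chlor must be >= 1")
  if (history == "SPLIT_HGT" && n_chlor < 2) {
    stop("SPLIT_HGT needs at least 2 chlorarachniophyte leaves")
  }
  if (history == "RED_HGT_CASH" && n_cash < 1) stop("n_cash must be >= 1")
  if (history == "RED_HGT_RHODOPHYTE" && n_red < 1) stop("n_red must be >= 1")
  if (history == "GREEN_EGT" && n_green < 1) stop("n_green must be >= 1")
  stopifnot(internal_branch > 0, terminal_branch > 0, n_sites >= 1)
  structure(list(history = history, n_cyano = n_cyano, n_green = n_green,
                 n_red = n_red, n_cash = n_cash, n_chlor = n_chlor,
                 internal_branch = internal_branch,
                 terminal_branch = terminal_branch, n_sites = n_sites,
                 model = model, gap_rate = gap_rate,
                 n_redundant = n_redundant, seed = as.integer(seed)),
            class = "sim_scenario")
}

sim_species_pool <- list(
  Cyanobacteria = c("Synechococcus", "Nostoc", "Anabaena", "Prochlorococcus",
                    "Gloeobacter", "Cyanothece"),
  Chloroplastida = c("Chlamydomonas", "Volvox", "Chlorella", "Ostreococcus",
                     "Micromonas", "Arabidopsis"),
  Rhodophyceae = c("Cyanidioschyzon", "Porphyridium", "Galdieria",
                   "Chondrus"),
  Stramenopiles = c("Thalassiosira", "Phaeodactylum", "Ectocarpus"),
  Haptophyta = c("Emiliania", "Pavlova"),
  Cryptophyta = c("Guillardia", "Rhodomonas"),
  Chlorarachniophyta = c("Bigelowiella", "Amorphochlora", "Lotharella",
                         "Chlorarachnion")
)

sim_labels <- function(scn) {
  mk <- function(prefix, k) sprintf("%s%02d", prefix, seq_len(k))
  list(cyano = mk("CY", scn$n_cyano), green = mk("GR", scn$n_green),
       red = mk("RH", scn$n_red), cash = mk("CA", scn$n_cash),
       chlor = mk("CH", scn$n_chlor))
}

sim_taxa <- function(scn) {
  lb <- sim_labels(scn)
  mk <- function(labels, lineages) {
    genera <- vapply(seq_along(labels), function(i) {
      pool <- sim_species_pool[[lineages[i]]]
      pool[(i - 1) %% length(pool) + 1]
    }, character(1))
    data.frame(otu_id = labels,
               species_name = sprintf("%s sp. %s", genera, labels),
               lineage = lineages, plastid_bearing = TRUE,
               stringsAsFactors = FALSE)
  }
  cash_lin <- rep(c("Stramenopiles", "Haptophyta", "Cryptophyta"),
                  length.out = scn$n_cash)
  taxon_table(rbind(
    mk(lb$cyano, rep("Cyanobacteria", scn$n_cyano)),
    mk(lb$green, rep("Chloroplastida", scn$n_green)),
    mk(lb$red, rep("Rhodophyceae", scn$n_red)),
    mk(lb$cash, cash_lin),
    mk(lb$chlor, rep("Chlorarachniophyta", scn$n_chlor))
  ))
}

# nested ladder newick for a label vector
ladder <- function(labels) {
  if (length(labels) == 1) return(labels)
  paste0("(", labels[1], ",", ladder(labels[-1]), ")")
}

#' Simulate a gene tree under a transfer history
#'
#' Builds the labelled topology dictated by the scenario's history, then
#' draws branch lengths independently from exponential distributions with
#' the scenario's internal/terminal means (floored at 0.005 for numerical
#' stability). Cyanobacteria are basal to all plastid-bearing eukaryotes.
#'
#' @param scn A [sim_scenario()].
#' @return List with `tree` (a rooted `phylo` with branch lengths),
#'   `taxa` (the matching `taxon_table`), and `truth` (history record:
#'   `history` and `attachment` lineage).
#' @export
simulate_gene_tree <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  set.seed(scn$seed)
  lb <- sim_labels(scn)
  chl <- ladder(lb$chlor)
  green <- ladder(lb$green)
  red <- ladder(lb$red)
  cash <- ladder(lb$cash)
  cyano <- ladder(lb$cyano)
  topo <- switch(
    scn$history,
    GREEN_EGT = {
      green_in <- if (scn$n_green == 1) {
        paste0("(", chl, ",", lb$green[1], ")")
      } else {
        paste0("((", chl, ",", lb$green[1], "),", ladder(lb$green[-1]), ")")
      }
      sprintf("(%s,(%s,(%s,%s)));", cyano, green_in, red, cash)
    },
    RED_HGT_CASH =
      sprintf("(%s,(%s,(%s,(%s,%s))));", cyano, green, red, chl, cash),
    RED_HGT_RHODOPHYTE =
      sprintf("(%s,(%s,((%s,%s),%s)));", cyano, green, chl, red, cash),
    SPLIT_HGT = {
      red_in <- paste0("(", lb$chlor[2], ",", red, ")")
      cash_in <- paste0("(", lb$chlor[1], ",", cash, ")")
      extra <- if (scn$n_chlor > 2) paste0(",", ladder(lb$chlor[-(1:2)])) else ""
      sprintf("(%s%s,(%s,(%s,%s)));", cyano, extra, green, red_in, cash_in)
    }
  )
  tree <- ape::read.tree(text = topo)
  nt <- length(tree$tip.label)
  is_term <- tree$edge[, 2] <= nt
  len <- numeric(nrow(tree$edge))
  len[is_term] <- stats::rexp(sum(is_term), rate = 1 / scn$terminal_branch)
  len[!is_term] <- stats::rexp(sum(!is_term), rate = 1 / scn$internal_branch)
  tree$edge.length <- pmax(len, 0.005)
  attachment <- switch(scn$history,
                       GREEN_EGT = "Chloroplastida",
                       RED_HGT_CASH = "CASH",
                       RED_HGT_RHODOPHYTE = "Rhodophyceae",
                       SPLIT_HGT = "split")
  list(tree = tree, taxa = sim_taxa(scn),
       truth = list(history = scn$history, attachment = attachment))
}

#' Evolve an alignment along a tree
#'
#' Standard Markov sequence evolution: root states are drawn from the
#' model's stationary frequencies and evolved edge by edge under the WAG
#' process, with each site assigned either to the invariant class (with
#' probability `p_inv`) or to one of the discrete-gamma rate categories.
#' Gamma rates are rescaled by `1/(1 - p_inv)` so the expected overall
#' rate stays 1 per unit branch length, matching the likelihood engine's
#' convention.
#'
#' @param tree A `phylo` with branch lengths.
#' @param model An [substitution_model()].
#' @param n_sites Number of alignment columns.
#' @param seed Integer seed.
#' @param family_id Identifier for the returned family.
#' @return A `gene_family`.
#' @export
simulate_alignment <- function(tree, model = substitution_model(),
                               n_sites = 500, seed = 1,
                               family_id = "sim") {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  set.seed(seed)
  gam <- discretize_gamma(model$alpha, model$n_cat)
  # site classes: 0 = invariant, 1..k = gamma categories
  cls <- ifelse(stats::runif(n_sites) < model$p_inv, 0L,
                sample.int(model$n_cat, n_sites, replace = TRUE))
  rates <- c(1e-9, gam$rates / (1 - model$p_inv))[cls + 1L]
  out <- matrix("", length(phy$tip.label), n_sites,
                dimnames = list(phy$tip.label, NULL))
  for (r in unique(rates)) {
    ix <- which(rates == r)
    sim <- phangorn::simSeq(phy, l = length(ix), type = "AA",
                            model = "WAG", rate = r)
    out[, ix] <- as.character(sim)[phy$tip.label, , drop = FALSE]
  }
  gene_family(family_id,
              apply(out, 1, paste, collapse = ""))
}

#' Corrupt an alignment with gap blocks and redundant OTUs
#'
#' Emulates the noise the trimming and deduplication stages exist for:
#' selected sequences receive one contiguous gap block covering
#' approximately `gap_rate` of the alignment (truncated EST-like
#' coverage), and `n_redundant` duplicate OTUs — same species, new OTU
#' id, sequence mutated at 1% of sites — are appended.
#'
#' @param fam A `gene_family`.
#' @param taxa The matching `taxon_table`.
#' @param gap_rate Fraction of sites gapped in each target sequence.
#' @param n_redundant Number of duplicate OTUs to append.
#' @param seed Integer seed.
#' @param gap_targets Labels to receive gap blocks; by default one
#'   non-chlorarachniophyte sequence chosen at random.
#' @return List with updated `family` and `taxa`.
#' @export
corrupt_alignment <- function(fam, taxa, gap_rate = 0, n_redundant = 0,
                              seed = 1, gap_targets = NULL) {
  stopifnot(inherits(fam, "gene_family"), gap_rate >= 0, gap_rate < 1)
  set.seed(seed)
  seqs <- fam$seqs
  n <- fam$n_sites
  lin <- lineage_of(taxa, names(seqs))
  if (gap_rate > 0) {
    if (is.null(gap_targets)) {
      pool <- names(seqs)[lin != "Chlorarachniophyta"]
      gap_targets <- sample(pool, 1)
    }
    len <- round(gap_rate * n)
    for (lab in gap_targets) {
      start <- sample.int(n - len + 1, 1)
      s <- strsplit(seqs[[lab]], "")[[1]]
      s[start:(start + len - 1)] <- "-"
      seqs[[lab]] <- paste(s, collapse = "")
    }
  }
  new_taxa <- as.data.frame(taxa)
  if (n_redundant > 0) {
    pool <- names(seqs)[lin != "Chlorarachniophyta"]
    src <- sample(pool, n_redundant)
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
    for (j in seq_along(src)) {
      lab <- src[j]
      new_lab <- paste0(lab, "_dup", j)
      s <- strsplit(seqs[[lab]], "")[[1]]
      mut <- which(s != "-")
      mut <- sample(mut, max(1, round(0.01 * length(mut))))
      s[mut] <- sample(aa, length(mut), replace = TRUE)
      seqs[new_lab] <- paste(s, collapse = "")
      row <- new_taxa[new_taxa$otu_id == lab, , drop = FALSE]
      row$otu_id <- new_lab
      new_taxa <- rbind(new_taxa, row)
    }
  }
  list(family = gene_family(fam$family_id, seqs),
       taxa = taxon_table(new_taxa))
}

#' Simulate a complete gene family
#'
#' Convenience wrapper: gene tree, evolved alignment, and corruption in
#' one call, all driven by the scenario's seed.
#'
#' @param scn A [sim_scenario()].
#' @param family_id Identifier (default derived from history and seed).
#' @return List with `family`, `taxa`, `tree`, `truth`.
#' @export
simulate_family <- function(scn, family_id = NULL) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (is.null(family_id)) {
    family_id <- sprintf("%s_s%d", tolower(scn$history), scn$seed)
  }
  gt <- simulate_gene_tree(scn)
  fam <- simulate_alignment(gt$tree, scn$model, scn$n_sites,
                            seed = scn$seed + 1L, family_id = family_id)
  cor <- corrupt_alignment(fam, gt$taxa, gap_rate = scn$gap_rate,
                           n_redundant = scn$n_redundant,
                           seed = scn$seed + 2L)
  list(family = cor$family, taxa = cor$taxa, tree = gt$tree,
       truth = gt$truth)
}
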