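#' Screen configuration
#'
#' Bundles every threshold of the two-round screen: the OTU-count gate
#' (more than 10 OTUs, i.e. `min_otus = 11`), the minimum cyanobacterial
#' OTU count for inferring cyanobacterial origin (3), the strong-support
#' thresholds (BV >= 75, PP >= 0.95), the trimming thresholds (15% / 70%
#' gaps), the number of final-round bootstrap replicates (1000), and the
#' automated replacement for manual long-branch exclusion (terminal
#' branches longer than `long_branch_factor` times the median).
#'
#' @param min_otus Minimum OTU count after trimming/deduplication.
#' @param min_cyano Minimum cyanobacterial OTU count.
#' @param bv_strong,pp_strong Strong-support thresholds.
#' @param trim A [trim_config()].
#' @param bootstrap_reps Final-round bootstrap replicates.
#' @param bootstrap_search Replicate search method, see
#'   [bootstrap_support()].
#' @param long_branch_factor Median multiple above which a terminal
#'   branch is considered long.
#' @param round1_model Fast-filter model (default WAG+G4).
#' @param final_model Final-round model (default WAG+I+G4).
#' @param seed Base seed; per-family seeds are derived from it and the
#'   family id, so results do not depend on input order.
#' @return A `screen_config`.
#' @export
screen_config <- function(min_otus = 11, min_cyano = 3, bv_strong = 75,
                          pp_strong = 0.95, trim = trim_config(),
                          bootstrap_reps = 1000,
                          bootstrap_search = c("ml", "nj"),
                          long_branch_factor = 5.0,
                          round1_model = substitution_model(),
                          final_model = substitution_model(p_inv = 0.1),
                          seed = 1) {
  bootstrap_search <- match.arg(bootstrap_search)
  stopifnot(min_otus >= 1, min_cyano >= 1, bootstrap_reps >= 1,
            long_branch_factor > 0)
  structure(list(min_otus = as.integer(min_otus),
                 min_cyano = as.integer(min_cyano),
                 bv_strong = bv_strong, pp_strong = pp_strong, trim = trim,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 bootstrap_search = bootstrap_search,
                 long_branch_factor = long_branch_factor,
                 round1_model = round1_model, final_model = final_model,
                 seed = as.integer(seed)),
            class = "screen_config")
}

# deterministic per-family seed from the base seed and the family id,
# independent of input order; kept below 2^31
family_seed <- function(base, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(base) + h) %% 2147483647)
}

#' Remove long-branched OTUs
#'
#' Automated, reproducible replacement for by-eye exclusion of
#' long-branched OTUs: leaves whose terminal branch exceeds `factor`
#' times the median terminal branch length are removed, iterating up to
#' `max_rounds` times since the median shifts after removals. Labels in
#' `protected` (the chlorarachniophyte OTUs, during a screen) are never
#' removed. If a removal would leave fewer than four leaves nothing is
#' removed and a warning is recorded.
#'
#' @param tree A `phylo` or `supported_tree` with branch lengths.
#' @param factor Positive median multiple.
#' @param protected Labels exempt from removal.
#' @param max_rounds Maximum removal rounds.
#' @return List with `tree` (pruned `phylo`), `removed` (labels), and
#'   `warnings` (character).
#' @export
long_branch_filter <- function(tree, factor = 5.0, protected = character(0),
                               max_rounds = 3) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  removed <- character(0)
  warnings <- character(0)
  for (round in seq_len(max_rounds)) {
    nt <- length(phy$tip.label)
    term <- phy$edge[, 2] <= nt
    tlen <- stats::setNames(phy$edge.length[term],
                            phy$tip.label[phy$edge[, 2][term]])
    med <- stats::median(tlen)
    long <- names(tlen)[tlen > factor * med]
    long <- setdiff(long, protected)
    if (length(long) == 0) break
    if (nt - length(long) < 4) {
      warnings <- c(warnings,
                    "long-branch removal skipped: fewer than 4 leaves would remain")
      break
    }
    phy <- ape::drop.tip(phy, long)
    removed <- c(removed, long)
  }
  list(tree = phy, removed = removed, warnings = warnings)
}

#' Screen one gene family
#'
#' Runs the full two-round screen on a single aligned family: gap
#' trimming, species deduplication, the OTU-count gate, a fast
#' first-round tree (no bootstrap) for the cyanobacterial-origin filters,
#' automated long-branch removal (chlorarachniophytes protected), a final
#' bootstrap-annotated tree, and the red/green affiliation call. The
#' first failing gate short-circuits the rest.
#'
#' @param fam A `gene_family`.
#' @param taxa A `taxon_table`.
#' @param cfg A [screen_config()].
#' @return A `screen_verdict`: list with the per-stage outcomes
#'   (`trim_pass_used`, `otu_count_pass`, `cyano_count_pass`,
#'   `egt_topology_pass`), the `affiliation` call (when reached), the
#'   final annotated `tree`, and `final_category` — one of
#'   `GREEN_AFFILIATION`, `RED_LINEAGE_CANDIDATE`, `SPLIT`, or
#'   `FAILED_FILTER_<stage>`.
#' @export
screen_family <- function(fam, taxa, cfg = screen_config()) {
  stopifnot(inherits(fam, "gene_family"))
  seed <- family_seed(cfg$seed, fam$family_id)
  v <- list(family_id = fam$family_id, n_otus_input = length(fam$seqs),
            trim_pass_used = NA_character_, n_otus = NA_integer_,
            otu_count_pass = NA, cyano_count_pass = NA,
            egt_topology_pass = NA, removed_long_branches = character(0),
            affiliation = NULL, tree = NULL,
            final_category = NA_character_)
  fail <- function(stage) {
    v$final_category <- paste0("FAILED_FILTER_", stage)
    structure(v, class = "screen_verdict")
  }

  tr <- trim_alignment(fam, cfg$trim)
  v$trim_pass_used <- tr$pass
  if (tr$untrimmable) return(fail("trim"))
  fam2 <- dedupe_species(tr$alignment, taxa)
  v$n_otus <- length(fam2$seqs)

  lin <- lineage_of(taxa, names(fam2$seqs))
  if (!any(lin == "Chlorarachniophyta")) return(fail("chlor_presence"))

  v$otu_count_pass <- v$n_otus >= cfg$min_otus
  if (!v$otu_count_pass) return(fail("otu_count"))

  fast <- infer_tree(fam2, cfg$round1_model, seed = seed)
  n_cyano <- count_lineage(fast, taxa, "Cyanobacteria")
  v$cyano_count_pass <- n_cyano >= cfg$min_cyano
  if (!v$cyano_count_pass) return(fail("cyano_count"))
  v$egt_topology_pass <- cyano_basal_check(fast, taxa,
                                           min_cyano = cfg$min_cyano)
  if (!v$egt_topology_pass) return(fail("egt_topology"))

  chl <- names(fam2$seqs)[lin == "Chlorarachniophyta"]
  lb <- long_branch_filter(fast, factor = cfg$long_branch_factor,
                           protected = chl)
  v$removed_long_branches <- lb$removed
  fam3 <- if (length(lb$removed) > 0) {
    gene_family(fam2$family_id,
                fam2$seqs[setdiff(names(fam2$seqs), lb$removed)])
  } else {
    fam2
  }

  final <- bootstrap_support(fam3, cfg$final_model,
                             n_rep = cfg$bootstrap_reps, seed = seed,
                             search = cfg$bootstrap_search)
  v$tree <- final
  # the cyano-count gate applied at its own stage (long-branch removal may
  # legitimately thin the cyanobacteria); here only the rootable EGT shape
  # (eukaryote monophyly) is re-checked on the final tree
  if (count_lineage(final, taxa, "Cyanobacteria") < 1 ||
      !cyano_basal_check(final, taxa, min_cyano = 1)) {
    v$egt_topology_pass <- FALSE
    return(fail("egt_topology"))
  }
  aff <- classify_affiliation(final, taxa, bv_strong = cfg$bv_strong,
                              pp_strong = cfg$pp_strong)
  v$affiliation <- aff
  v$final_category <- switch(aff$class,
                             GREEN = "GREEN_AFFILIATION",
                             RED_TYPE = "RED_LINEAGE_CANDIDATE",
                             CASH_TYPE = "RED_LINEAGE_CANDIDATE",
                             AMBIGUOUS_RED = "RED_LINEAGE_CANDIDATE",
                             SPLIT = "SPLIT",
                             "FAILED_FILTER_affiliation")
  structure(v, class = "screen_verdict")
}

#' @export
print.screen_verdict <- function(x, ...) {
  cat("Family '", x$family_id, "': ", x$final_category, "\n", sep = "")
  cat("  OTUs in/after prep:", x$n_otus_input, "/",
      ifelse(is.na(x$n_otus), "-", x$n_otus),
      " trim pass:", x$trim_pass_used, "\n")
  if (!is.null(x$affiliation)) {
    cat("  affiliation:", x$affiliation$class, "\n")
  }
  invisible(x)
}

#' Run the screen over a collection of families
#'
#' Applies [screen_family()] to every family and assembles the per-family
#' verdict table plus the stage-by-stage funnel summary. Per-family seeds
#' derive from the base seed and family id, so the verdicts are
#' deterministic and independent of input order; the verdict table is
#' sorted by family id.
#'
#' @param families A list of `gene_family` objects.
#' @param taxa A `taxon_table`.
#' @param cfg A [screen_config()].
#' @return An `egt_screen`: list with `verdicts` (data.frame), `funnel`
#'   (stage counts), `calls` (full `screen_verdict` objects), `config`.
#' @export
run_screen <- function(families, taxa, cfg = screen_config()) {
  stopifnot(length(families) >= 1)
  calls <- lapply(families, screen_family, taxa = taxa, cfg = cfg)
  ids <- vapply(calls, `[[`, character(1), "family_id")
  ord <- order(ids)
  calls <- calls[ord]
  verdicts <- do.call(rbind, lapply(calls, function(v) {
    data.frame(
      family_id = v$family_id,
      n_otus_input = v$n_otus_input,
      n_otus = v$n_otus,
      trim_pass_used = v$trim_pass_used,
      otu_count_pass = v$otu_count_pass,
      cyano_count_pass = v$cyano_count_pass,
      egt_topology_pass = v$egt_topology_pass,
      affiliation = if (is.null(v$affiliation)) NA_character_
                    else v$affiliation$class,
      red_affiliation_bv = if (is.null(v$affiliation)) NA_real_
                           else v$affiliation$red_affiliation_bv,
      final_category = v$final_category,
      stringsAsFactors = FALSE
    )
  }))
  rownames(verdicts) <- NULL
  fc <- verdicts$final_category
  funnel <- data.frame(
    stage = c("input", "trimmed", "otu_count", "cyano_count",
              "egt_topology", "classified"),
    n = c(nrow(verdicts),
          sum(verdicts$trim_pass_used != "none"),
          sum(verdicts$otu_count_pass, na.rm = TRUE),
          sum(verdicts$cyano_count_pass, na.rm = TRUE),
          sum(verdicts$egt_topology_pass, na.rm = TRUE),
          sum(fc %in% c("GREEN_AFFILIATION", "RED_LINEAGE_CANDIDATE",
                        "SPLIT"))),
    stringsAsFactors = FALSE
  )
  structure(list(verdicts = verdicts, funnel = funnel, calls = calls,
                 config = cfg),
            class = "egt_screen")
}

#' @export
print.egt_screen <- function(x, ...) {
  cat("EGT/HGT screen of", nrow(x$verdicts), "gene families\n\n")
  print(x$funnel, row.names = FALSE)
  cat("\nFinal categories:\n")
  print(table(x$verdicts$final_category))
  invisible(x)
}

#' @export
summary.egt_screen <- function(object, ...) {
  cat("Per-family verdicts:\n")
  print(object$verdicts, row.names = FALSE)
  cat("\n")
  print(object$funnel, row.names = FALSE)
  invisible(object)
}

#' Write screen outputs to a directory
#'
#' Emits `verdicts.tsv`, `funnel.tsv`, and per-family Newick trees (for
#' families that reached the final round).
#'
#' @param screen An `egt_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_output <- function(screen, dir) {
  stopifnot(inherits(screen, "egt_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(screen$verdicts, file.path(dir, "verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screen$funnel, file.path(dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (v in screen$calls) {
    if (!is.null(v$tree)) {
      write_newick(v$tree,
                   file.path(dir, paste0(v$family_id, ".nwk")))
    }
  }
  invisible(dir)
}
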