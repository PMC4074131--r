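#' Aligned amino-acid gene family
#'
#' A light container for one aligned gene family: a family identifier and a
#' named character vector of equal-length aligned amino-acid strings. Gaps
#' are `-`; the missing/ambiguous states `X`, `B`, `Z`, `?` and `*` are
#' allowed and are treated as fully ambiguous residues in likelihood
#' computations, but do not count as gaps when thresholding coverage.
#'
#' @param family_id Character scalar naming the family.
#' @param seqs Named character vector of aligned sequences.
#' @return A `gene_family` object.
#' @export
gene_family <- function(family_id, seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyDuplicated(names(seqs))) {
    stop("sequences must have unique non-empty names")
  }
  seqs <- toupper(vapply(seqs, as.character, character(1)))
  n_sites <- unique(nchar(seqs))
  if (length(n_sites) != 1 || n_sites == 0) {
    stop("all sequences must have the same positive aligned length")
  }
  ok <- "^[ACDEFGHIKLMNPQRSTVWYXBZ?*-]*$"
  bad <- names(seqs)[!grepl(ok, seqs)]
  if (length(bad) > 0) {
    stop("invalid characters in sequence(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(family_id = as.character(family_id), seqs = seqs,
         n_sites = as.integer(n_sites)),
    class = "gene_family"
  )
}

#' @export
print.gene_family <- function(x, ...) {
  cat("Gene family '", x$family_id, "': ", length(x$seqs),
      " sequences, ", x$n_sites, " aligned sites\n", sep = "")
  invisible(x)
}

#' Read an aligned gene family from FASTA
#'
#' @param path Path to an aligned FASTA file (gaps as `-`).
#' @param family_id Family identifier; defaults to the file name without
#'   extension.
#' @return A `gene_family`.
#' @export
read_family_fasta <- function(path, family_id = NULL) {
  if (is.null(family_id)) {
    family_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ss <- Biostrings::readBStringSet(path)
  gene_family(family_id, stats::setNames(as.character(ss), names(ss)))
}

#' Write a gene family to aligned FASTA
#'
#' @param fam A `gene_family`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(fam, path) {
  stopifnot(inherits(fam, "gene_family"))
  ss <- Biostrings::BStringSet(fam$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Gap fraction of aligned sequences
#'
#' The fraction of alignment columns in which a sequence has a gap (`-`).
#' Missing-state characters (`X`, `B`, `Z`, `?`, `*`) are residues of
#' unknown identity, not gaps, so they do not count: the threshold targets
#' alignment coverage, not residue ambiguity.
#'
#' @param x A `gene_family` or a character vector of aligned strings.
#' @return Numeric vector of gap fractions in `[0, 1]`.
#' @examples
#' gap_fraction("AC-DE")  # 0.2
#' @export
gap_fraction <- function(x) {
  seqs <- if (inherits(x, "gene_family")) x$seqs else as.character(x)
  if (length(seqs) == 0) stop("no sequences")
  n <- nchar(seqs)
  if (any(n == 0)) stop("empty sequence")
  gaps <- vapply(strsplit(seqs, ""), function(s) sum(s == "-"), numeric(1))
  gaps / n
}

#' Trimming configuration
#'
#' Controls the two-pass gap trimming. The primary pass excludes sequences
#' with more than `primary_gap_max` gaps (default 15%). If fewer than
#' `min_keep` sequences (default 4) survive, that result is discarded and a
#' fallback pass instead keeps sequences with less than `fallback_gap_max`
#' gaps (default 70%) — a concession to sparse gene families whose homologs
#' come from low-coverage EST-like sources with stretched alignment gaps.
#'
#' @param primary_gap_max Gap fraction above which the primary pass drops a
#'   sequence. Boundary is strict: exactly `primary_gap_max` is kept.
#' @param fallback_gap_max Gap fraction at or above which the fallback pass
#'   drops a sequence (strictly-less-than is kept).
#' @param min_keep Minimum number of survivors for the primary pass result
#'   to be accepted.
#' @return A `trim_config` list.
#' @export
trim_config <- function(primary_gap_max = 0.15, fallback_gap_max = 0.70,
                        min_keep = 4) {
  stopifnot(primary_gap_max > 0, primary_gap_max < fallback_gap_max,
            fallback_gap_max < 1, min_keep >= 2)
  structure(list(primary_gap_max = primary_gap_max,
                 fallback_gap_max = fallback_gap_max,
                 min_keep = as.integer(min_keep)),
            class = "trim_config")
}

#' Trim an alignment by per-sequence gap fraction
#'
#' First pass keeps sequences with gap fraction `<= primary_gap_max`; if
#' fewer than `min_keep` survive, the result is discarded and the fallback
#' pass keeps sequences with gap fraction `< fallback_gap_max`. Whole
#' sequences are removed; columns are never touched. If even the fallback
#' leaves fewer than two sequences the family is flagged untrimmable rather
#' than raising an error, so a screening run can record the failure and
#' move on.
#'
#' @param fam A `gene_family`.
#' @param cfg A [trim_config()].
#' @return A `trim_result`: list with `alignment` (a `gene_family`, or
#'   `NULL` if untrimmable), `pass` (`"primary"`, `"fallback"` or
#'   `"none"`), `dropped` (labels removed), `untrimmable` flag, and counts
#'   `n_in` / `n_kept`.
#' @export
trim_alignment <- function(fam, cfg = trim_config()) {
  stopifnot(inherits(fam, "gene_family"), inherits(cfg, "trim_config"))
  gf <- gap_fraction(fam)
  keep_primary <- gf <= cfg$primary_gap_max
  if (sum(keep_primary) >= cfg$min_keep) {
    keep <- keep_primary
    pass <- "primary"
  } else {
    keep <- gf < cfg$fallback_gap_max
    pass <- "fallback"
  }
  if (sum(keep) < 2) {
    return(structure(
      list(family_id = fam$family_id, alignment = NULL, pass = "none",
           dropped = names(fam$seqs)[!keep], untrimmable = TRUE,
           n_in = length(fam$seqs), n_kept = sum(keep)),
      class = "trim_result"
    ))
  }
  structure(
    list(family_id = fam$family_id,
         alignment = gene_family(fam$family_id, fam$seqs[keep]),
         pass = pass, dropped = names(fam$seqs)[!keep], untrimmable = FALSE,
         n_in = length(fam$seqs), n_kept = sum(keep)),
    class = "trim_result"
  )
}

#' @export
print.trim_result <- function(x, ...) {
  cat("Trim of '", x$family_id, "': ", x$n_kept, "/", x$n_in,
      " sequences kept (", x$pass, " pass)",
      if (x$untrimmable) " [UNTRIMMABLE]", "\n", sep = "")
  if (length(x$dropped) > 0) {
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a trim report for a set of families
#'
#' @param results A list of `trim_result` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(family_id = r$family_id, pass_used = r$pass, n_in = r$n_in,
               n_kept = r$n_kept,
               dropped_labels = paste(r$dropped, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove redundant OTUs of the same species
#'
#' Gene families assembled from overlapping databases often carry several
#' OTUs for one species; redundant OTUs with the same specific name are
#' excluded, keeping one representative per species. The representative is
#' the sequence with the lowest gap fraction, ties broken by the longest
#' ungapped length and then lexicographically by label, so the choice is
#' deterministic.
#'
#' @param fam A `gene_family`.
#' @param taxa A `taxon_table` resolving every leaf label.
#' @return A `gene_family` with one sequence per species.
#' @export
dedupe_species <- function(fam, taxa) {
  stopifnot(inherits(fam, "gene_family"))
  labels <- names(fam$seqs)
  i <- match(labels, taxa$otu_id)
  if (anyNA(i)) {
    stop("leaf label(s) not in taxonomy: ",
         paste(labels[is.na(i)], collapse = ", "))
  }
  sp <- taxa$species_name[i]
  gf <- gap_fraction(fam)
  ungapped <- nchar(gsub("-", "", fam$seqs))
  ord <- order(sp, gf, -ungapped, labels)
  keep_lab <- labels[ord][!duplicated(sp[ord])]
  keep <- labels %in% keep_lab
  gene_family(fam$family_id, fam$seqs[keep])
}
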