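#' Lineage groups recognised by the screen
#'
#' Every OTU in a screened gene tree is assigned to exactly one of these
#' groups. The classification logic treats three of them specially:
#' Cyanobacteria anchor the root of plastid gene trees, Chloroplastida is
#' the "green" (expected endosymbiotic) donor, and the red lineage —
#' Rhodophyceae plus the four CASH groups — is the alternative donor whose
#' signal the screen is designed to detect.
#'
#' @format Character vectors of lineage names.
#' @details
#' `CASH_GROUPS` is exactly Cryptophyta, Alveolata, Stramenopiles and
#' Haptophyta: the eukaryotes carrying red-algal secondary or tertiary
#' plastids. `RED_LINEAGE_GROUPS` is Rhodophyceae plus the CASH groups.
#' Glaucophyta and Euglenophyta are plastid-bearing context groups only;
#' they neither trigger a green call nor count as red lineage.
#' @export
LINEAGE_GROUPS <- c(
  "Cyanobacteria", "Glaucophyta", "Chloroplastida", "Rhodophyceae",
  "Cryptophyta", "Haptophyta", "Alveolata", "Stramenopiles",
  "Chlorarachniophyta", "Euglenophyta", "OtherEukaryote"
)

#' @rdname LINEAGE_GROUPS
#' @export
CASH_GROUPS <- c("Cryptophyta", "Alveolata", "Stramenopiles", "Haptophyta")

#' @rdname LINEAGE_GROUPS
#' @export
RED_LINEAGE_GROUPS <- c("Rhodophyceae", CASH_GROUPS)

#' Construct a validated taxonomy table
#'
#' A taxonomy table maps OTU identifiers (gene-tree leaf labels) to species
#' names, lineage groups, and a plastid-bearing flag. It drives every
#' lineage-aware topology query and the species-level deduplication of
#' alignments.
#'
#' @param df A data.frame with columns `otu_id`, `species_name`, `lineage`,
#'   `plastid_bearing`.
#' @return A `taxon_table` (a validated data.frame).
#' @examples
#' taxon_table(data.frame(
#'   otu_id = c("cy1", "gr1"),
#'   species_name = c("Synechococcus elongatus", "Chlamydomonas reinhardtii"),
#'   lineage = c("Cyanobacteria", "Chloroplastida"),
#'   plastid_bearing = c(TRUE, TRUE)
#' ))
#' @export
taxon_table <- function(df) {
  required <- c("otu_id", "species_name", "lineage", "plastid_bearing")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$otu_id <- as.character(df$otu_id)
  df$species_name <- as.character(df$species_name)
  df$lineage <- as.character(df$lineage)
  if (is.character(df$plastid_bearing)) {
    pb <- tolower(trimws(df$plastid_bearing))
    if (!all(pb %in% c("true", "false", "1", "0"))) {
      stop("plastid_bearing must be true/false")
    }
    df$plastid_bearing <- pb %in% c("true", "1")
  }
  df$plastid_bearing <- as.logical(df$plastid_bearing)
  bad <- which(!df$lineage %in% LINEAGE_GROUPS)
  if (length(bad) > 0) {
    stop(
      "unknown lineage label(s): ",
      paste(sprintf("row %d: '%s'", bad, df$lineage[bad]), collapse = "; ")
    )
  }
  dup <- df$otu_id[duplicated(df$otu_id)]
  if (length(dup) > 0) {
    stop("duplicate otu_id: ", paste(unique(dup), collapse = ", "))
  }
  if (anyNA(df$plastid_bearing)) stop("plastid_bearing must be true/false")
  class(df) <- c("taxon_table", "data.frame")
  df
}

#' Load a taxonomy table from a tab-separated file
#'
#' The file must be UTF-8, tab-separated, with a header row containing
#' exactly the columns `otu_id`, `species_name`, `lineage` and
#' `plastid_bearing` (values `true`/`false`). Lineage values must be valid
#' [LINEAGE_GROUPS] names; unknown labels and duplicated `otu_id`s are
#' errors that name the offending rows.
#'
#' @param path Path to the TSV file.
#' @return A `taxon_table`.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  taxon_table(df)
}

#' Write a taxonomy table to TSV
#'
#' @param taxa A `taxon_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxa, path) {
  stopifnot(inherits(taxa, "taxon_table"))
  out <- as.data.frame(taxa)
  out$plastid_bearing <- ifelse(out$plastid_bearing, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Red-lineage membership
#'
#' An OTU belongs to the red lineage iff its lineage is Rhodophyceae or one
#' of the CASH groups (Cryptophyta, Alveolata, Stramenopiles, Haptophyta).
#'
#' @param x A `taxon_table` (or subset of its rows), or a character vector
#'   of lineage names.
#' @return Logical vector, one element per record/lineage.
#' @export
in_red_lineage <- function(x) {
  lin <- if (inherits(x, "data.frame")) x$lineage else as.character(x)
  bad <- setdiff(unique(lin), LINEAGE_GROUPS)
  if (length(bad) > 0) stop("unknown lineage label(s): ", paste(bad, collapse = ", "))
  lin %in% RED_LINEAGE_GROUPS
}

#' Resolve leaf labels to lineage groups
#'
#' @param taxa A `taxon_table`.
#' @param labels Character vector of OTU identifiers.
#' @return Character vector of lineage names, same length as `labels`.
#' @export
lineage_of <- function(taxa, labels) {
  stopifnot(inherits(taxa, "taxon_table"))
  i <- match(labels, taxa$otu_id)
  if (anyNA(i)) {
    stop("leaf label(s) not in taxonomy: ",
         paste(labels[is.na(i)], collapse = ", "))
  }
  taxa$lineage[i]
}

#' @rdname lineage_of
#' @export
plastid_bearing_of <- function(taxa, labels) {
  stopifnot(inherits(taxa, "taxon_table"))
  i <- match(labels, taxa$otu_id)
  if (anyNA(i)) {
    stop("leaf label(s) not in taxonomy: ",
         paste(labels[is.na(i)], collapse = ", "))
  }
  taxa$plastid_bearing[i]
}
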