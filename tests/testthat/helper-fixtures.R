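# Shared fixture builders: tiny taxonomies, alignments and trees assembled
# in code so the suite carries no data files.

make_taxa <- function(otu_id, lineage, species_name = NULL,
                      plastid_bearing = NULL) {
  if (is.null(species_name)) {
    species_name <- paste("Species", otu_id)
  }
  if (is.null(plastid_bearing)) {
    plastid_bearing <- lineage != "OtherEukaryote"
  }
  taxon_table(data.frame(otu_id = otu_id, species_name = species_name,
                         lineage = lineage,
                         plastid_bearing = plastid_bearing,
                         stringsAsFactors = FALSE))
}

# taxonomy matching the simulator's label scheme (CYxx, GRxx, RHxx, CAxx,
# CHxx) for hand-written newick fixtures
screen_taxa <- function(n_cy = 3, n_gr = 4, n_rh = 2, n_ca = 4, n_ch = 2) {
  lab <- function(p, k) sprintf("%s%02d", p, seq_len(k))
  make_taxa(
    c(lab("CY", n_cy), lab("GR", n_gr), lab("RH", n_rh), lab("CA", n_ca),
      lab("CH", n_ch)),
    c(rep("Cyanobacteria", n_cy), rep("Chloroplastida", n_gr),
      rep("Rhodophyceae", n_rh),
      rep(c("Stramenopiles", "Haptophyta", "Cryptophyta"),
          length.out = n_ca),
      rep("Chlorarachniophyta", n_ch))
  )
}

# random aligned gene family with controlled gap fractions
random_family <- function(n_seq, n_sites, gap_fracs = rep(0, n_seq),
                          seed = 1, labels = sprintf("s%02d", seq_len(n_seq))) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- sample(aa, n_sites, replace = TRUE)
    ngap <- round(gap_fracs[i] * n_sites)
    if (ngap > 0) s[seq_len(ngap)] <- "-"
    paste(s, collapse = "")
  }, character(1))
  gene_family("test_fam", stats::setNames(seqs, labels))
}

# small random unrooted tree with branch lengths
random_tree <- function(n, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  ape::unroot(tr)
}
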