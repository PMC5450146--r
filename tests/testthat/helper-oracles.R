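# Shared fixtures and independent brute-force oracles for the suite.

# Brute-force pair counting: enumerate every pair of reads and tally
# same/different source against same/different cluster. Independent of
# the contingency-table formulas used by the package.
brute_pair_counts <- function(source, cluster) {
  n <- length(source)
  tm <- fs <- fm <- ts <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same_src <- source[i] == source[j]
        same_clu <- cluster[i] == cluster[j]
        if (same_src && same_clu) tm <- tm + 1
        else if (same_src && !same_clu) fs <- fs + 1
        else if (!same_src && same_clu) fm <- fm + 1
        else ts <- ts + 1
      }
    }
  }
  c(true_match = tm, false_split = fs, true_split = ts, false_match = fm)
}

# Brute-force weighted UniFrac: for every edge, find its descendant tip
# set via phangorn::Descendants (an independent route to the bipartition)
# and sum abundance mass explicitly.
brute_unifrac <- function(tree, a, b, normalized = FALSE) {
  tips <- tree$tip.label
  av <- setNames(numeric(length(tips)), tips); av[names(a)] <- a
  bv <- setNames(numeric(length(tips)), tips); bv[names(b)] <- b
  raw <- 0; denom <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    desc <- unlist(phangorn::Descendants(tree, child, type = "tips"))
    A <- sum(av[tips[desc]]); B <- sum(bv[tips[desc]])
    raw <- raw + tree$edge.length[e] * abs(A - B)
    denom <- denom + tree$edge.length[e] * (A + B)
  }
  if (normalized) { if (denom == 0) 0 else raw / denom } else raw
}

# A small fixture shared across files; built once per test run.
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture(4, 3, 1500, seed = 42)
    cache
  }
})

# A stool-like 6-genus spec over the small fixture's genera: Gaussian
# species counts, means summing to 1.
small_specs <- function() {
  do.call(rbind, Map(genus_spec,
    genus = sprintf("Genus%02d", 1:4),
    mean_frac = c(0.40, 0.30, 0.20, 0.10),
    sd_frac = c(0.10, 0.07, 0.05, 0.02),
    rule_type = "gaussian", p1 = 2, p2 = 1))
}

# OTU table rows built by hand from parallel vectors.
manual_otu <- function(seq, community, otu_id, taxonomy = "", weight = 1) {
  data.frame(seq = seq, community = community, otu_id = otu_id,
             ncbi_rank = "species", name = "", ncbi_tax_id = "",
             taxonomy_string = taxonomy, weight = weight,
             stringsAsFactors = FALSE)
}

# Mapping rows built by hand.
manual_mapping <- function(read_id, source, community,
                           taxonomy = "Bacteria;P;C;O;F;G;G s") {
  data.frame(read_id = read_id, source_accession = source,
             organism_name = source, taxonomy_string = taxonomy,
             community_id = community, stringsAsFactors = FALSE)
}
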