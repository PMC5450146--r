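#' Reference 16S sequence sets
#'
#' A reference set is a data frame with one row per reference sequence and
#' columns `accession`, `organism_name`, `taxonomy_string`, `sequence`.
#' Accessions are unique. These sets are the pool from which defined
#' communities draw their members, and the source templates for in-silico
#' PCR.
#'
#' `load_references()` joins a FASTA file (headers carry accessions; the
#' first whitespace-delimited token is used) with a taxonomy CSV mapping
#' `accession` to `organism_name` and `taxonomy_string`. FASTA entries with
#' no taxonomy row are excluded; their count is reported as a warning and
#' returned in the `n_unmatched` attribute.
#'
#' @param fasta_path Path to a FASTA file of reference sequences.
#' @param taxonomy_path Path to a CSV with columns `accession`,
#'   `organism_name`, `taxonomy_string`.
#' @return A reference-set data frame (see Details).
#' @export
load_references <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  acc <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(acc)) {
    stop("duplicate accession in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  tax <- utils::read.csv(taxonomy_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("accession", "organism_name", "taxonomy_string")
  if (!all(need %in% names(tax))) {
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tax$accession)) stop("duplicate accession in taxonomy")
  keep <- acc %in% tax$accession
  n_unmatched <- sum(!keep)
  if (n_unmatched > 0) {
    warning(n_unmatched, " FASTA entr",
            if (n_unmatched == 1) "y" else "ies",
            " without a taxonomy row; excluded")
  }
  idx <- match(acc[keep], tax$accession)
  refs <- data.frame(
    accession       = acc[keep],
    organism_name   = tax$organism_name[idx],
    taxonomy_string = tax$taxonomy_string[idx],
    sequence        = as.character(seqs[keep]),
    stringsAsFactors = FALSE
  )
  attr(refs, "n_unmatched") <- n_unmatched
  refs
}

#' Write a reference set to a directory
#'
#' Emits `refs.fasta` and `taxonomy.csv` (plus `tree.nwk` if a tree is
#' supplied), the on-disk layout read back by [load_references()].
#'
#' @param refs A reference-set data frame.
#' @param dir Output directory, created if needed.
#' @param tree Optional `phylo` tree over the accessions.
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(refs, dir, tree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(refs$sequence)
  names(seqs) <- refs$accession
  Biostrings::writeXStringSet(seqs, file.path(dir, "refs.fasta"))
  utils::write.csv(
    refs[, c("accession", "organism_name", "taxonomy_string")],
    file.path(dir, "taxonomy.csv"), row.names = FALSE, quote = TRUE)
  if (!is.null(tree)) ape::write.tree(tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

#' @rdname load_references
#' @param dir A directory written by [write_reference_set()].
#' @export
read_reference_set <- function(dir) {
  load_references(file.path(dir, "refs.fasta"), file.path(dir, "taxonomy.csv"))
}

#' Curate a reference set
#'
#' Retains only near-full-length, unambiguous sequences: length strictly
#' greater than `min_len` and alphabet restricted to A/C/G/T. Counts
#' removed per filter are attached as the `removed` attribute. Idempotent.
#'
#' @param refs A reference-set data frame.
#' @param min_len Minimum length (exclusive); default 1000 bp.
#' @return The filtered reference set.
#' @export
curate_references <- function(refs, min_len = 1000) {
  too_short <- nchar(refs$sequence) <= min_len
  ambiguous <- grepl("[^ACGT]", refs$sequence)
  keep <- !too_short & !ambiguous
  out <- refs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("curation removed every reference")
  attr(out, "removed") <- c(too_short = sum(too_short),
                            ambiguous = sum(ambiguous & !too_short))
  out
}

# 1 - cosine similarity between k-mer count profiles; alignment-free and
# deterministic.
kmer_cosine_dist <- function(sequences, k = 8) {
  prof <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = k)
  norms <- sqrt(rowSums(prof^2))
  sim <- (prof %*% t(prof)) / outer(norms, norms)
  d <- 1 - sim
  d[d < 0] <- 0  # guard rounding
  d
}

#' Drop per-species outlier sequences
#'
#' Within each species group of size >= 3, pairwise distances are computed
#' as 1 minus the cosine similarity of k-mer count profiles, the medoid
#' (minimum total distance) is taken as the group centroid, and records
#' whose distance to the medoid strictly exceeds the group's
#' `percentile` quantile of those distances are dropped. Groups smaller
#' than 3 pass through unchanged (a percentile over fewer than 3 distances
#' is degenerate).
#'
#' @param refs A reference-set data frame.
#' @param percentile Quantile threshold within each group, default 0.90.
#' @param k k-mer word length for the profile distance, default 8.
#' @return The reference set with outliers removed; dropped accessions in
#'   the `dropped` attribute.
#' @export
drop_species_outliers <- function(refs, percentile = 0.90, k = 8) {
  groups <- split(seq_len(nrow(refs)), refs$taxonomy_string)
  drop <- logical(nrow(refs))
  for (idx in groups) {
    if (length(idx) < 3L) next
    d <- kmer_cosine_dist(refs$sequence[idx], k = k)
    medoid <- which.min(rowSums(d))
    to_medoid <- d[, medoid]
    thr <- stats::quantile(to_medoid, percentile, names = FALSE)
    drop[idx[to_medoid > thr]] <- TRUE
  }
  out <- refs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- refs$accession[drop]
  out
}

# Fixed layout of a fixture 16S-like reference: two nested primer systems,
# V3-V5 style (357F..926R, ~554 bp) enclosing a V4 style (U515F..806R,
# ~289 bp), mimicking real 16S amplicon geometry.
fixture_layout <- function(seq_len) {
  f357 <- realize_primer("CCTACGGGAGGCAGCAG")
  f515 <- realize_primer("GTGYCAGCMGCCGCGGTAA")
  r806_rc <- revcomp_dna(realize_primer("GGACTACNVGGGTWTCTAAT"))
  r926_rc <- revcomp_dna(realize_primer("CCGTCAATTCMTTTRAGT"))
  fixed <- nchar(f357) + 150 + nchar(f515) + 250 + nchar(r806_rc) + 80 +
    nchar(r926_rc)
  if (seq_len < fixed + 120 + 100) {
    stop("seq_len too short: need at least ", fixed + 220,
         " bp for both primer systems plus flanks")
  }
  tail_len <- seq_len - fixed - 120
  list(
    segments = c(pad = 120, f357 = nchar(f357), sp1 = 150,
                 f515 = nchar(f515), insert = 250, r806 = nchar(r806_rc),
                 sp2 = 80, r926 = nchar(r926_rc), tail = tail_len),
    fixed_seqs = c(f357 = f357, f515 = f515, r806 = r806_rc, r926 = r926_rc)
  )
}

#' Generate a synthetic reference set with a known phylogeny
#'
#' Builds a fully in-silico reference pool so every downstream module can
#' be exercised without database downloads. Each genus gets an independent
#' random ancestor sequence with exact embedded binding sites for two
#' nested primer systems (V3--V5 and V4 style); species within a genus are
#' derived from the ancestor by point substitutions at non-primer
#' positions, so within-genus divergence is far below between-genus
#' divergence. Taxonomies follow the canonical seven-rank ladder, with
#' genera nested pairwise into families, orders, classes and phyla. An
#' ultrametric tree consistent with the mutation process (shallow
#' within-genus splits, deep between-genus splits) is returned alongside.
#'
#' @param n_genera Number of genera (>= 1).
#' @param species_per_genus Species per genus; one reference per species.
#' @param seq_len Reference length in bp, >= 1200.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param species_mut_rate Per-base substitution rate from the genus
#'   ancestor for each species; default 0.02.
#' @return A list with elements `refs` (reference-set data frame) and
#'   `tree` (ultrametric `phylo` whose tips are the accessions).
#' @export
make_fixture <- function(n_genera, species_per_genus, seq_len = 1500,
                         seed = 1, species_mut_rate = 0.02) {
  stopifnot(n_genera >= 1, species_per_genus >= 1, seq_len >= 1200)
  layout <- fixture_layout(seq_len)
  seg <- layout$segments
  fixed <- layout$fixed_seqs
  starts <- cumsum(c(1, seg[-length(seg)]))
  names(starts) <- names(seg)
  protected <- unlist(lapply(c("f357", "f515", "r806", "r926"), function(s) {
    seq(starts[[s]], length.out = seg[[s]])
  }))
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    rows <- vector("list", n_genera * species_per_genus)
    i <- 0L
    for (g in seq_len(n_genera)) {
      ancestor <- sample(bases, seq_len, replace = TRUE)
      for (s in names(fixed)) {
        ancestor[seq(starts[[s]], length.out = seg[[s]])] <-
          strsplit(fixed[[s]], "")[[1]]
      }
      fam <- ceiling(g / 2); ord <- ceiling(fam / 2)
      cls <- ceiling(ord / 2); phy <- ceiling(cls / 2)
      genus <- sprintf("Genus%02d", g)
      for (sp in seq_len(species_per_genus)) {
        child <- ancestor
        mutable <- setdiff(which(stats::runif(seq_len) < species_mut_rate),
                           protected)
        if (length(mutable)) {
          shift <- sample(1:3, length(mutable), replace = TRUE)
          child[mutable] <- bases[(match(child[mutable], bases) + shift - 1) %% 4 + 1]
        }
        i <- i + 1L
        organism <- sprintf("%s species%02d", genus, sp)
        rows[[i]] <- data.frame(
          accession = sprintf("SYN%02d_%02d", g, sp),
          organism_name = organism,
          taxonomy_string = paste(
            "Bacteria", sprintf("Phylum%02d", phy), sprintf("Class%02d", cls),
            sprintf("Order%02d", ord), sprintf("Family%02d", fam),
            genus, organism, sep = ";"),
          sequence = paste(child, collapse = ""),
          stringsAsFactors = FALSE
        )
      }
    }
    refs <- do.call(rbind, rows)
  })

  # Ultrametric tree: species split from the genus ancestor near the
  # leaves, genera split at the root. Leaf depth 1.0 throughout.
  inner <- species_mut_rate
  genus_clades <- vapply(seq_len(n_genera), function(g) {
    accs <- sprintf("SYN%02d_%02d", g, seq_len(species_per_genus))
    if (length(accs) == 1L) {
      sprintf("%s:1", accs)
    } else {
      sprintf("(%s):%g", paste(sprintf("%s:%g", accs, inner), collapse = ","),
              1 - inner)
    }
  }, character(1))
  newick <- if (n_genera == 1L) {
    sub(sprintf(":%g$", 1 - inner), ";", paste0(genus_clades, ";"))
  } else {
    paste0("(", paste(genus_clades, collapse = ","), ");")
  }
  tree <- ape::read.tree(text = newick)
  list(refs = refs, tree = tree)
}

# Genus of each reference, taken as the penultimate taxonomy field (the
# canonical ladder ends genus;species).
ref_genus <- function(refs) {
  vapply(refs$taxonomy_string, function(x) {
    lin <- parse_lineage(x)
    pos <- rank_position(lin, "genus")
    if (is.na(pos)) NA_character_ else unclass(lin)[pos]
  }, character(1), USE.NAMES = FALSE)
}
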