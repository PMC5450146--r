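# In-silico PCR: degenerate primer matching, amplicon slicing, read
# replication to depth, and a simple i.i.d. substitution/indel error model.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Does an IUPAC code match a concrete base?
#'
#' @param code A single IUPAC nucleotide symbol (possibly degenerate).
#' @param base A concrete base, one of A/C/G/T.
#' @return `TRUE` iff `base` is in the expansion of `code`.
#' @examples
#' iupac_match("Y", "C")  # TRUE
#' iupac_match("M", "G")  # FALSE
#' @export
iupac_match <- function(code, base) {
  set <- IUPAC_SETS[[code]]
  if (is.null(set)) stop("invalid IUPAC symbol: ", code)
  base %in% set
}

# Fixed, deterministic realization of a degenerate primer: each code is
# replaced by the first base of its expansion. Used to embed concrete
# binding sites in fixture references.
realize_primer <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("invalid IUPAC symbol: ", ch)
    set[1]
  }, character(1)), collapse = "")
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Primer pairs
#'
#' A primer pair holds the forward and reverse primers as written 5'->3'
#' at the bench (the reverse primer anneals to the plus strand as its
#' reverse complement). Degenerate IUPAC codes are allowed.
#'
#' `primers_hmp()` is the V3--V5 pair 357F/926R used with 454-style
#' simulation; `primers_emp()` is the V4 pair U515F/806R used with
#' MiSeq-style simulation.
#'
#' @param forward,reverse Primer sequences, 5'->3', IUPAC alphabet.
#' @param name Optional label.
#' @return A `primer_pair` list with elements `forward`, `reverse`, `name`.
#' @export
primer_pair <- function(forward, reverse, name = "custom") {
  forward <- toupper(forward); reverse <- toupper(reverse)
  ok <- function(x) !grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), x)
  if (!ok(forward) || !ok(reverse)) stop("primer contains non-IUPAC symbols")
  structure(list(forward = forward, reverse = reverse, name = name),
            class = "primer_pair")
}

#' @rdname primer_pair
#' @export
primers_hmp <- function() primer_pair("CCTACGGGAGGCAGCAG", "CCGTCAATTCMTTTRAGT",
                                      name = "357F/926R")

#' @rdname primer_pair
#' @export
primers_emp <- function() primer_pair("GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT",
                                      name = "U515F/806R")

#' Locate a primer binding site on a template
#'
#' Slides the primer ungapped along the plus strand and reports the
#' leftmost start where it aligns with at most `max_mismatch` IUPAC
#' mismatches AND no mismatch in the 3'-terminal `anchor_len` bases (the
#' annealing test: polymerase extension requires a matched 3' end).
#'
#' @param template Template DNA string over A/C/G/T.
#' @param primer Primer string, IUPAC alphabet, 5'->3'.
#' @param max_mismatch Maximum IUPAC mismatches outside the anchor
#'   requirement; default 2.
#' @param anchor_len Number of 3'-terminal bases that must match exactly
#'   (IUPAC-compatibly); default 3.
#' @param anchor_side Which end of the pattern string the anchor applies
#'   to: `"right"` (default; pattern written 5'->3' so its 3' end is
#'   rightmost) or `"left"` (for a reverse-complemented pattern whose 3'
#'   end is leftmost).
#' @return 1-based start position of the leftmost site, or `NA_integer_`
#'   if there is none (including when the primer is longer than the
#'   template).
#' @export
find_primer_site <- function(template, primer, max_mismatch = 2,
                             anchor_len = 3, anchor_side = c("right", "left")) {
  anchor_side <- match.arg(anchor_side)
  tch <- strsplit(template, "")[[1]]
  pch <- strsplit(toupper(primer), "")[[1]]
  m <- length(pch); n <- length(tch)
  if (m > n) return(NA_integer_)
  n_off <- n - m + 1L
  mismatch <- matrix(FALSE, nrow = n_off, ncol = m)
  for (j in seq_len(m)) {
    set <- IUPAC_SETS[[pch[j]]]
    if (is.null(set)) stop("invalid IUPAC symbol: ", pch[j])
    mismatch[, j] <- !(tch[seq_len(n_off) + j - 1L] %in% set)
  }
  anchor_cols <- if (anchor_side == "right") (m - anchor_len + 1L):m
                 else seq_len(anchor_len)
  ok <- rowSums(mismatch) <= max_mismatch &
    rowSums(mismatch[, anchor_cols, drop = FALSE]) == 0L
  if (!any(ok)) NA_integer_ else which(ok)[1]
}

#' Amplify a template with a primer pair
#'
#' Finds the forward primer on the plus strand and the reverse complement
#' of the reverse primer downstream of it, and returns the inclusive slice
#' from the start of the forward site through the end of the reverse site
#' (both primer-binding regions included unless `trim_primers`). Returns
#' `NULL` when either site is absent, the reverse site is not downstream
#' of the forward site, or the insert between the primers is empty --
#' absence of product is a legitimate outcome that callers tally.
#'
#' @param template Template DNA string over A/C/G/T.
#' @param primers A [primer_pair()].
#' @inheritParams find_primer_site
#' @param trim_primers If `TRUE`, the primer-binding regions are removed
#'   from the returned amplicon.
#' @return The amplicon string, or `NULL` for no product.
#' @export
amplify <- function(template, primers, max_mismatch = 2, anchor_len = 3,
                    trim_primers = FALSE) {
  stopifnot(inherits(primers, "primer_pair"))
  flen <- nchar(primers$forward)
  f <- find_primer_site(template, primers$forward, max_mismatch, anchor_len)
  if (is.na(f)) return(NULL)
  rc <- revcomp_dna(primers$reverse)
  rlen <- nchar(rc)
  downstream <- substring(template, f + flen)
  # the reverse primer's 3' end is the leftmost base of its reverse
  # complement on the plus strand
  r_rel <- find_primer_site(downstream, rc, max_mismatch, anchor_len,
                            anchor_side = "left")
  if (is.na(r_rel)) return(NULL)
  r <- f + flen + r_rel - 1L
  if (r - (f + flen) < 1L) return(NULL)  # empty insert
  if (trim_primers) substring(template, f + flen, r - 1L)
  else substring(template, f, r + rlen - 1L)
}

#' Generate amplicon reads and the gold-standard mapping
#'
#' For every member of every target community, the member's reference is
#' amplified once with `primers`; the read count is `round(frac * depth)`
#' (round-half-to-even). Members whose count rounds below one, or whose
#' reference yields no product, emit nothing and are recorded as designed
#' drop-outs so evaluators can distinguish simulation loss from pipeline
#' loss. Each emitted read receives a globally unique ID and exactly one
#' row in the mapping.
#'
#' @param targets A community-target data frame (see [sample_community()]).
#' @param refs The reference set the targets draw from.
#' @param primers A [primer_pair()].
#' @param depth Intended reads per community (e.g. 5000 for 454-style,
#'   50000 for MiSeq-style runs).
#' @inheritParams find_primer_site
#' @param trim_primers Passed to [amplify()].
#' @return A list with `amplicons` (data frame: `read_id`, `sequence`,
#'   `source_accession`, `community_id`), `mapping` (data frame:
#'   `read_id`, `source_accession`, `organism_name`, `taxonomy_string`,
#'   `community_id`) and `dropouts` (data frame: `community_id`,
#'   `accession`, `reason`).
#' @export
generate_reads <- function(targets, refs, primers, depth,
                           max_mismatch = 2, anchor_len = 3,
                           trim_primers = FALSE) {
  stopifnot(depth >= 1)
  missing_acc <- setdiff(targets$accession, refs$accession)
  if (length(missing_acc)) {
    stop("target accessions absent from reference set: ",
         paste(utils::head(missing_acc, 5), collapse = ", "))
  }
  # amplify each distinct accession once
  accs <- unique(targets$accession)
  seq_by_acc <- refs$sequence[match(accs, refs$accession)]
  amp_by_acc <- vapply(seq_by_acc, function(s) {
    a <- amplify(s, primers, max_mismatch, anchor_len, trim_primers)
    if (is.null(a)) NA_character_ else a
  }, character(1), USE.NAMES = FALSE)
  names(amp_by_acc) <- accs

  amp_rows <- list(); map_rows <- list(); drop_rows <- list()
  for (cid in unique(targets$community_id)) {
    mem <- targets[targets$community_id == cid, , drop = FALSE]
    counter <- 0L
    for (i in seq_len(nrow(mem))) {
      n_reads <- round(mem$frac[i] * depth)
      amp <- amp_by_acc[[mem$accession[i]]]
      if (is.na(amp) || n_reads < 1) {
        drop_rows[[length(drop_rows) + 1L]] <- data.frame(
          community_id = cid, accession = mem$accession[i],
          reason = if (is.na(amp)) "no_amplicon" else "rounded_to_zero",
          stringsAsFactors = FALSE)
        next
      }
      ids <- sprintf("%s_read_%06d", cid, counter + seq_len(n_reads))
      counter <- counter + n_reads
      amp_rows[[length(amp_rows) + 1L]] <- data.frame(
        read_id = ids, sequence = amp,
        source_accession = mem$accession[i], community_id = cid,
        stringsAsFactors = FALSE)
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        read_id = ids, source_accession = mem$accession[i],
        organism_name = mem$organism_name[i],
        taxonomy_string = mem$taxonomy_string[i],
        community_id = cid, stringsAsFactors = FALSE)
    }
  }
  empty <- function(cols) stats::setNames(
    data.frame(matrix(character(0), 0, length(cols)), stringsAsFactors = FALSE), cols)
  list(
    amplicons = if (length(amp_rows)) do.call(rbind, amp_rows)
                else empty(c("read_id", "sequence", "source_accession", "community_id")),
    mapping = if (length(map_rows)) do.call(rbind, map_rows)
              else empty(c("read_id", "source_accession", "organism_name",
                           "taxonomy_string", "community_id")),
    dropouts = if (length(drop_rows)) do.call(rbind, drop_rows)
               else empty(c("community_id", "accession", "reason"))
  )
}

#' Corrupt amplicons with an i.i.d. substitution/indel error model
#'
#' Each amplicon yields exactly one read with the same ID. Every base is
#' independently substituted with a uniformly random different base with
#' probability `sub_rate`; a deletion removes the base with probability
#' `indel_rate / 2`, and an insertion of a uniformly random base after the
#' position occurs with probability `indel_rate / 2`, so expected length
#' change is zero.
#'
#' @param amplicons Amplicon data frame from [generate_reads()] (columns
#'   `read_id`, `sequence` are used).
#' @param sub_rate Per-base substitution probability, in \[0, 0.2\].
#' @param indel_rate Total per-base indel probability, in \[0, 0.2\].
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `read_id`, `sequence`.
#' @export
apply_errors <- function(amplicons, sub_rate, indel_rate, seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.2, indel_rate >= 0, indel_rate <= 0.2)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- vapply(amplicons$sequence, function(s) {
      chars <- strsplit(s, "")[[1]]
      n <- length(chars)
      if (sub_rate > 0) {
        hit <- stats::runif(n) < sub_rate
        if (any(hit)) {
          shift <- sample(1:3, sum(hit), replace = TRUE)
          chars[hit] <- bases[(match(chars[hit], bases) + shift - 1) %% 4 + 1]
        }
      }
      if (indel_rate > 0) {
        del <- stats::runif(n) < indel_rate / 2
        ins <- stats::runif(n) < indel_rate / 2
        insbase <- ifelse(ins, sample(bases, n, replace = TRUE), "")
        chars[del] <- ""
        chars <- paste0(chars, insbase)
      }
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    data.frame(read_id = amplicons$read_id, sequence = out,
               stringsAsFactors = FALSE)
  })
}

#' Write amplicons as FASTA / reads as FASTQ / the mapping as CSV
#'
#' @param x Data frame with `read_id` and `sequence` columns (and for the
#'   mapping writer, the full mapping columns).
#' @param path Output file path.
#' @param quality_char Constant Phred+33 quality character for FASTQ,
#'   default `"I"` (Q40).
#' @return `path`, invisibly.
#' @export
write_amplicons_fasta <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$read_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_amplicons_fasta
#' @export
write_reads_fastq <- function(x, path, quality_char = "I") {
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$read_id
  qual <- Biostrings::PhredQuality(strrep(quality_char, nchar(x$sequence)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_amplicons_fasta
#' @export
write_mapping <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_amplicons_fasta
#' @export
read_mapping <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("read_id", "source_accession", "organism_name",
            "taxonomy_string", "community_id")
  if (!all(need %in% names(m))) {
    stop("mapping must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$read_id)) stop("duplicate read_id in mapping")
  m[, need]
}
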