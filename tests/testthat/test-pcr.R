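test_that("IUPAC codes match exactly their expansions", {
  expect_true(iupac_match("Y", "C"))
  expect_true(iupac_match("Y", "T"))
  expect_false(iupac_match("Y", "A"))
  expect_true(iupac_match("N", "G"))
  expect_true(iupac_match("M", "A"))
  expect_false(iupac_match("M", "G"))
  expect_true(iupac_match("V", "G"))
  expect_false(iupac_match("V", "T"))
  expect_error(iupac_match("Z", "A"), "invalid IUPAC")
})

test_that("find_primer_site honours the mismatch budget and 3' anchor", {
  set.seed(21)
  pad <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  # concrete realization of the V4 forward primer GTGYCAGCMGCCGCGGTAA
  site <- "GTGCCAGCAGCCGCGGTAA"
  template <- paste0(pad, site, pad)
  primer <- "GTGYCAGCMGCCGCGGTAA"
  # enumeration confirms the realization is an exact degenerate match
  pch <- strsplit(primer, "")[[1]]
  sch <- strsplit(site, "")[[1]]
  expect_true(all(mapply(iupac_match, pch, sch)))
  expect_equal(find_primer_site(template, primer), 201L)

  # one mismatch at the 3'-terminal base kills the site
  bad3 <- sub("TAA$", "TAC", site)
  expect_true(is.na(find_primer_site(paste0(pad, bad3, pad), primer)))
  # three internal mismatches exceed the budget of two
  bad_int <- site
  substr(bad_int, 2, 2) <- "A"; substr(bad_int, 5, 5) <- "G"
  substr(bad_int, 7, 7) <- "C"
  expect_true(is.na(find_primer_site(paste0(pad, bad_int, pad), primer,
                                     max_mismatch = 2)))
  # two internal mismatches pass
  ok2 <- site
  substr(ok2, 2, 2) <- "A"; substr(ok2, 5, 5) <- "G"
  expect_equal(find_primer_site(paste0(pad, ok2, pad), primer), 201L)
  # primer longer than template is no site, not an error
  expect_true(is.na(find_primer_site("ACGT", primer)))
  # leftmost of two sites wins
  expect_equal(find_primer_site(paste0(site, pad, site), primer), 1L)
})

test_that("amplify slices from forward start through reverse-site end", {
  set.seed(22)
  primers <- primer_pair("GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")
  fwd_site <- "GTGCCAGCAGCCGCGGTAA"
  rev_rc <- ampligold:::revcomp_dna("GGACTACAAGGGTATCTAAT")
  insert <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  pad <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  template <- paste0(pad, fwd_site, insert, rev_rc, pad)
  amp <- amplify(template, primers)
  expect_equal(nchar(amp), nchar(fwd_site) + 300 + nchar(rev_rc))
  expect_identical(amp, paste0(fwd_site, insert, rev_rc))
  # primer trimming removes both binding regions
  expect_identical(amplify(template, primers, trim_primers = TRUE), insert)

  # missing reverse site: no product
  expect_null(amplify(paste0(pad, fwd_site, insert), primers))
  # reverse site upstream of the forward site: no product
  expect_null(amplify(paste0(pad, rev_rc, insert, fwd_site, pad), primers))
  # empty insert: no product
  expect_null(amplify(paste0(pad, fwd_site, rev_rc, pad), primers))
})

test_that("both bench primer pairs amplify every fixture reference", {
  fx <- small_fixture()
  for (pp in list(primers_hmp(), primers_emp())) {
    amps <- vapply(fx$refs$sequence, function(s) {
      a <- amplify(s, pp)
      expect_false(is.null(a))
      nchar(a)
    }, numeric(1), USE.NAMES = FALSE)
    if (pp$name == "U515F/806R") v4 <- amps else v35 <- amps
  }
  # the V3-V5 amplicon is longer than the V4 amplicon on every reference
  expect_true(all(v35 > v4))
})

test_that("generate_reads replicates to depth with an exact mapping bijection", {
  fx <- small_fixture()
  targets <- data.frame(
    community_id = "c1",
    accession = fx$refs$accession[1:4],
    organism_name = fx$refs$organism_name[1:4],
    taxonomy_string = fx$refs$taxonomy_string[1:4],
    frac = c(0.5, 0.3, 0.19995, 0.00005),
    stringsAsFactors = FALSE)
  res <- generate_reads(targets, fx$refs, primers_emp(), depth = 5000)
  counts <- table(res$mapping$source_accession)
  expect_equal(unname(counts[targets$accession[1]]), round(0.5 * 5000))
  expect_equal(unname(counts[targets$accession[2]]), round(0.3 * 5000))
  # frac 0.00005 at depth 5000 rounds to 0: a designed drop-out
  expect_false(targets$accession[4] %in% names(counts))
  expect_equal(res$dropouts$accession, targets$accession[4])
  expect_equal(res$dropouts$reason, "rounded_to_zero")
  # bijection between amplicon reads and mapping rows
  expect_setequal(res$amplicons$read_id, res$mapping$read_id)
  expect_equal(anyDuplicated(res$mapping$read_id), 0)
  # total reads within |members|/2 of the nominal depth
  expect_lte(abs(nrow(res$mapping) - 5000), nrow(targets) / 2)
  # error-free amplicons are exact substrings of their source references
  src_seq <- fx$refs$sequence[match(res$amplicons$source_accession,
                                    fx$refs$accession)]
  uniq <- !duplicated(res$amplicons$source_accession)
  expect_true(all(mapply(grepl, res$amplicons$sequence[uniq], src_seq[uniq],
                         MoreArgs = list(fixed = TRUE))))
  expect_error(generate_reads(targets[0, ], fx$refs, primers_emp(), 0))
})

test_that("read totals stay within rounding error of depth across designs", {
  fx <- small_fixture()
  targets <- suppressWarnings(
    design_communities(small_specs(), fx$refs, n = 10, seed = 77))
  res <- generate_reads(targets, fx$refs, primers_emp(), depth = 5000)
  for (cid in unique(targets$community_id)) {
    members <- sum(targets$community_id == cid)
    n_reads <- sum(res$mapping$community_id == cid)
    expect_lte(abs(n_reads - 5000), members / 2)
  }
})

test_that("the error model is calibrated and the zero-rate case is identity", {
  fx <- small_fixture()
  amp <- data.frame(read_id = sprintf("r%03d", 1:400),
                    sequence = rep(substr(fx$refs$sequence[1], 1, 300), 400),
                    stringsAsFactors = FALSE)
  clean <- apply_errors(amp, 0, 0, seed = 1)
  expect_identical(clean$sequence, amp$sequence)

  # substitutions only: empirical rate within 3 binomial SE over 120k bases
  sub <- apply_errors(amp, 0.005, 0, seed = 2)
  n_bases <- sum(nchar(amp$sequence))
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, amp$sequence, sub$sequence))
  se <- sqrt(0.005 * 0.995 / n_bases)
  expect_lt(abs(mism / n_bases - 0.005), 3 * se)
  expect_identical(sub$read_id, amp$read_id)

  # indels only: mean length change about zero, variance positive
  ind <- apply_errors(amp, 0, 0.01, seed = 3)
  dlen <- nchar(ind$sequence) - nchar(amp$sequence)
  expect_lt(abs(mean(dlen)), 3 * sqrt(0.01 * 300) / sqrt(nrow(amp)))
  expect_gt(stats::var(dlen), 0)

  # determinism under seed
  expect_identical(apply_errors(amp, 0.01, 0.01, seed = 9)$sequence,
                   apply_errors(amp, 0.01, 0.01, seed = 9)$sequence)
  expect_error(apply_errors(amp, 0.5, 0), "sub_rate")
})

test_that("amplicons, reads and mappings round-trip through files", {
  fx <- small_fixture()
  targets <- design_communities(small_specs(), fx$refs, n = 2, seed = 5)
  res <- generate_reads(targets, fx$refs, primers_hmp(), depth = 200)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "amp.fasta")
  write_amplicons_fasta(res$amplicons, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(back), res$amplicons$read_id)
  expect_equal(as.character(back), res$amplicons$sequence,
               ignore_attr = TRUE)

  fq <- file.path(dir, "reads.fastq")
  reads <- apply_errors(res$amplicons, 0.005, 0.001, seed = 4)
  write_reads_fastq(reads, fq)
  lines <- readLines(fq)
  expect_equal(length(lines), 4 * nrow(reads))
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))

  mp <- file.path(dir, "mapping.csv")
  write_mapping(res$mapping, mp)
  expect_equal(read_mapping(mp), res$mapping, ignore_attr = TRUE)
})
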