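truth7 <- function(leaf = "Streptococcus intermedius") {
  parse_lineage(paste("Bacteria;Firmicutes;Bacilli;Lactobacillales",
                      "Streptococcaceae;Streptococcus", leaf, sep = ";"))
}

test_that("read outcomes land in the six categories with exact ranks off", {
  truth <- truth7()
  # wrong species, right genus: a sibling miscall at distance 1
  sib <- per_read_outcome(truth, truth7("Streptococcus mitis"), "species")
  expect_equal(sib$category, "miscalled_sibling")
  expect_equal(sib$ranks_off, 1)
  # called only to genus: undercalled by one rank
  genus_call <- truncate_lineage(truth, 6)
  und <- per_read_outcome(truth, genus_call, "species")
  expect_equal(und$category, "undercalled")
  expect_equal(und$ranks_off, 1)
  # called beyond species on the true path: overcalled
  strain <- parse_lineage(paste(serialize_lineage(truth), "strain X", sep = ";"))
  ov <- per_read_outcome(truth, strain, "species")
  expect_equal(ov$category, "overcalled")
  expect_equal(ov$ranks_off, 1)
  # placed in another phylum with a species-depth lineage: miscalled,
  # ranks_off = target depth 7 - lca depth 1 = 6
  wrong <- parse_lineage("Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides;Bacteroides fragilis")
  mis <- per_read_outcome(truth, wrong, "species")
  expect_equal(mis$category, "miscalled")
  expect_equal(mis$ranks_off, 6)
  # exact call and no call
  expect_equal(per_read_outcome(truth, truth, "species")$category, "correct")
  expect_equal(per_read_outcome(truth, NULL, "species")$category, "dropped")
  # genus target: a wrong-species call with the right genus is correct at
  # genus resolution, and the exact truth scores correct at either rank
  expect_equal(per_read_outcome(truth, truth7("Streptococcus mitis"),
                                "genus")$category, "correct")
  expect_equal(per_read_outcome(truth, truth, "genus")$category, "correct")
  # but a strain-depth call still overcalls relative to the truth's depth
  strain_g <- per_read_outcome(truth, strain, "genus")
  expect_equal(strain_g$category, "overcalled")
  expect_equal(strain_g$ranks_off, 1)
  expect_equal(per_read_outcome(truth, genus_call, "genus")$category, "correct")
  expect_error(per_read_outcome(parse_lineage("Bacteria"), truth, "genus"),
               "absent")
})

test_that("exact truth (possibly truncated) always scores correct/undercalled", {
  fx <- small_fixture()
  for (ts in fx$refs$taxonomy_string[c(1, 5, 9)]) {
    truth <- parse_lineage(ts)
    expect_equal(per_read_outcome(truth, truncate_lineage(truth, 7),
                                  "species")$category, "correct")
    # truncating a correct call above the target rank undercalls by the
    # truncation amount
    for (k in 1:4) {
      o <- per_read_outcome(truth, truncate_lineage(truth, 7 - k), "species")
      expect_equal(o$category, "undercalled")
      expect_equal(o$ranks_off, k)
    }
  }
})

test_that("per-source voting uses plurality with a severity tie-break", {
  expect_equal(per_source_outcome(rep("correct", 10), rep(0, 10))$category,
               "correct")
  o <- per_source_outcome(c(rep("undercalled", 6), rep("correct", 4)),
                          c(rep(1, 6), rep(0, 4)))
  expect_equal(o$category, "undercalled")
  expect_equal(o$ranks_off, 1)
  # 5 vs 5 tie: the more severe category wins
  tie <- per_source_outcome(c(rep("correct", 5), rep("miscalled", 5)),
                            c(rep(0, 5), rep(4, 5)))
  expect_equal(tie$category, "miscalled")
  expect_equal(tie$ranks_off, 4)
  # dropped reads only count when everything is dropped
  expect_equal(per_source_outcome(c("dropped", "dropped"), c(NA, NA))$category,
               "dropped")
  mixed <- per_source_outcome(c("dropped", "correct"), c(NA, 0))
  expect_equal(mixed$category, "correct")
  # worst-case strategy ignores counts
  wc <- per_source_outcome(c(rep("correct", 9), "miscalled"), c(rep(0, 9), 3),
                           strategy = "worst_case")
  expect_equal(wc$category, "miscalled")
})

test_that("summaries report category percents summing to 100 with ranks-off stats", {
  src <- data.frame(
    category = c("correct", "correct", "undercalled", "dropped"),
    ranks_off = c(0, 0, 1, NA))
  s <- summarize_outcomes(src)
  expect_equal(unname(s$percent["correct"]), 50)
  expect_equal(unname(s$percent["undercalled"]), 25)
  expect_equal(unname(s$percent["dropped"]), 25)
  expect_equal(sum(s$percent), 100, tolerance = 0.1)
  u <- s$ranks_off[s$ranks_off$category == "undercalled", ]
  expect_equal(c(u$median, u$min, u$max), c(1, 1, 1))

  # miscalled ranks_off {1, 4, 10} reports median 4, range 1-10
  src2 <- data.frame(category = rep("miscalled", 3), ranks_off = c(1, 4, 10))
  m <- summarize_outcomes(src2)$ranks_off
  m <- m[m$category == "miscalled", ]
  expect_equal(c(m$median, m$min, m$max), c(4, 1, 10))
  expect_error(summarize_outcomes(src[0, ]), "no source outcomes")
})

test_that("a six-way fixture scores one source per category at 1/6 each", {
  truth <- truth7()
  ts <- serialize_lineage(truth)
  mapping <- manual_mapping(sprintf("r%d", 1:6), sprintf("SRC%d", 1:6), "c1",
                            taxonomy = ts)
  calls <- c(
    ts,                                                    # correct
    serialize_lineage(truncate_lineage(truth, 6)),         # undercalled by 1
    paste(ts, "strain X", sep = ";"),                      # overcalled by 1
    sub("intermedius", "mitis", ts),                       # sibling miscall
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides;Bacteroides fragilis",
    "")                                                    # dropped
  otu <- manual_otu(sprintf("r%d", 1:6), "c1", sprintf("o%d", 1:6),
                    taxonomy = calls)
  src <- evaluate_classification(otu, mapping, "species")
  s <- summarize_outcomes(src)
  expect_equal(unname(s$percent), rep(100 / 6, 6), tolerance = 1e-9)
  expect_equal(sum(s$percent), 100, tolerance = 0.1)
  # the sibling miscall sits in its own category at exactly 1 rank off
  expect_equal(src$ranks_off[src$category == "miscalled_sibling"], 1)
})

test_that("read-fraction summaries bracket the per-source vote", {
  mapping <- manual_mapping(sprintf("r%d", 1:4), rep("S1", 4), "c1",
                            taxonomy = serialize_lineage(truth7()))
  ts <- serialize_lineage(truth7())
  otu <- manual_otu(sprintf("r%d", 1:4), "c1", "o1",
                    taxonomy = c(ts, ts, ts, sub("intermedius", "mitis", ts)))
  frac <- summarize_read_fractions(otu, mapping, "species")
  expect_equal(unname(frac["correct"]), 75)
  expect_equal(unname(frac["miscalled_sibling"]), 25)
  expect_equal(sum(frac), 100)
})

test_that("per-clade aggregation groups sources by the named rank", {
  fx <- make_fixture(6, 2, 1500, seed = 8)  # 6 genera over 2 orders
  mapping <- manual_mapping(fx$refs$accession, fx$refs$accession, "c1",
                            taxonomy = fx$refs$taxonomy_string)
  otu <- otu_table_from_mapping(mapping)
  src <- evaluate_classification(otu, mapping, "species")
  tab <- aggregate_by_clade(src, rank = "order")
  expect_setequal(tab$clade, c("Order01", "Order02"))
  expect_equal(tab$pct_correct, c(100, 100))

  # two orders with disjoint outcome mixes match per-order arithmetic
  src2 <- data.frame(
    taxonomy_string = c(rep("B;P;C;OrderA;F;G;G s", 2),
                        rep("B;P;C;OrderB;F;G;G s", 4)),
    category = c("correct", "miscalled", "correct", "correct", "undercalled",
                 "dropped"),
    ranks_off = c(0, 3, 0, 0, 2, NA))
  tab2 <- aggregate_by_clade(src2, rank = "order")
  a <- tab2[tab2$clade == "OrderA", ]
  expect_equal(c(a$pct_correct, a$pct_miscalled), c(50, 50))
  expect_equal(a$mean_ranks_off_miscalled, 3)
  b <- tab2[tab2$clade == "OrderB", ]
  expect_equal(c(b$pct_correct, b$pct_undercalled, b$pct_dropped),
               c(50, 25, 25))

  # lineages not reaching the rank group under "unresolved"
  src3 <- rbind(src2, data.frame(taxonomy_string = "B;P", category = "correct",
                                 ranks_off = 0))
  expect_true("unresolved" %in% aggregate_by_clade(src3, "order")$clade)
})
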