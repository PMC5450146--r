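# OTU-generation scoring: pair counting against the gold-standard mapping.

OTU_TABLE_HEADER <- c("seq", "community", "otu_id", "ncbi_rank", "name",
                      "ncbi_tax_id", "taxonomy_string", "weight")

#' Read and write the common OTU table
#'
#' The common pipeline-output format is a CSV with one row per read and
#' the exact header
#' `seq,community,otu_id,ncbi_rank,name,ncbi_tax_id,taxonomy_string,weight`.
#' Converters from specific pipelines are expected to produce this format;
#' all evaluators consume it.
#'
#' @param path CSV file path.
#' @return A data frame with the eight columns above; `weight` numeric.
#' @export
read_otu_table <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  header <- gsub('"', "", trimws(header))
  if (!identical(header, OTU_TABLE_HEADER)) {
    missing <- setdiff(OTU_TABLE_HEADER, header)
    extra <- setdiff(header, OTU_TABLE_HEADER)
    stop("bad OTU table header",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         if (!length(missing) && !length(extra)) "; columns out of order")
  }
  otu <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(weight = "numeric"))
  if (anyDuplicated(otu$seq)) {
    stop("duplicate seq id in OTU table: ",
         otu$seq[duplicated(otu$seq)][1])
  }
  if (any(otu$weight < 0)) stop("negative weight in OTU table")
  otu
}

#' @rdname read_otu_table
#' @param otu An OTU-table data frame.
#' @export
write_otu_table <- function(otu, path) {
  utils::write.csv(otu[, OTU_TABLE_HEADER], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Perfect-pipeline OTU table from a gold-standard mapping
#'
#' Builds the OTU table an error-free pipeline would emit: one OTU per
#' source accession, classification equal to the truth, unit weight per
#' read. Useful as an upper-bound baseline and for end-to-end self-tests.
#'
#' @param mapping A gold-standard mapping data frame.
#' @return An OTU-table data frame.
#' @export
otu_table_from_mapping <- function(mapping) {
  data.frame(
    seq = mapping$read_id,
    community = mapping$community_id,
    otu_id = mapping$source_accession,
    ncbi_rank = "species",
    name = mapping$organism_name,
    ncbi_tax_id = "",
    taxonomy_string = mapping$taxonomy_string,
    weight = 1,
    stringsAsFactors = FALSE
  )
}

#' Pair-counting metrics for one community
#'
#' Every pair of non-dropped reads is either truly from the same source or
#' not, and either co-clustered by the pipeline or not. With the
#' source-by-OTU contingency table `n_ij` over the N reads present in both
#' mapping and OTU table:
#' \itemize{
#'   \item true_match  = sum_ij C(n_ij, 2)
#'   \item false_split = sum_i C(n_i., 2) - true_match
#'   \item false_match = sum_j C(n_.j, 2) - true_match
#'   \item true_split  = C(N, 2) - true_match - false_split - false_match
#' }
#' Sensitivity = true_match / (true_match + false_split); specificity =
#' true_split / (true_split + false_match). Reads present in the mapping
#' but absent from the OTU table are dropped: excluded from pair counting
#' and reported as `dropped_reads` / `dropped_fraction`. The `weight`
#' column plays no role here (pairs are over reads, not abundances).
#'
#' @param otu An OTU-table data frame.
#' @param mapping A gold-standard mapping data frame.
#' @param community Community ID to score.
#' @return One-row data frame: community, the four pair counts,
#'   `dropped_reads`, `n_reads` (non-dropped), `sensitivity`,
#'   `specificity`, `dropped_fraction`. A zero denominator yields `NA`.
#' @export
pair_count_metrics <- function(otu, mapping, community) {
  map_c <- mapping[mapping$community_id == community, , drop = FALSE]
  otu_c <- otu[otu$community == community, , drop = FALSE]
  if (nrow(map_c) == 0L) stop("community '", community, "' not in mapping")
  unknown <- setdiff(otu_c$seq, map_c$read_id)
  if (length(unknown)) {
    stop("unknown read in OTU table for community '", community, "': ",
         unknown[1])
  }
  present <- map_c$read_id %in% otu_c$seq
  dropped <- sum(!present)
  kept <- map_c[present, , drop = FALSE]
  n <- nrow(kept)
  choose2 <- function(x) x * (x - 1) / 2
  if (n == 0L) {
    tm <- fs <- fm <- ts <- 0
  } else {
    src <- kept$source_accession
    clu <- otu_c$otu_id[match(kept$read_id, otu_c$seq)]
    tab <- table(src, clu)
    tm <- sum(choose2(tab))
    fs <- sum(choose2(rowSums(tab))) - tm
    fm <- sum(choose2(colSums(tab))) - tm
    ts <- choose2(n) - tm - fs - fm
  }
  ratio <- function(a, b) if (a + b > 0) a / (a + b) else NA_real_
  data.frame(
    community = community,
    true_match = tm, false_split = fs, true_split = ts, false_match = fm,
    dropped_reads = dropped, n_reads = n,
    sensitivity = ratio(tm, fs), specificity = ratio(ts, fm),
    dropped_fraction = dropped / nrow(map_c),
    stringsAsFactors = FALSE
  )
}

#' Pair-counting report over all communities
#'
#' Applies [pair_count_metrics()] per community of the mapping and
#' summarizes the distribution of sensitivity, specificity and dropped
#' fraction across communities (median and quartiles, box-plot style).
#'
#' @inheritParams pair_count_metrics
#' @return A list with `per_community` (one row per community) and
#'   `summary` (one row per metric: min, q1, median, q3, max).
#' @export
per_community_report <- function(otu, mapping) {
  stray <- setdiff(unique(otu$community), unique(mapping$community_id))
  if (length(stray)) {
    stop("community in OTU table but not in mapping: ", stray[1])
  }
  comms <- unique(mapping$community_id)
  per <- do.call(rbind, lapply(comms, function(cid) {
    pair_count_metrics(otu, mapping, cid)
  }))
  summarize_metric <- function(x) {
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE,
                         names = FALSE)
    data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }
  metrics <- c("sensitivity", "specificity", "dropped_fraction")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    cbind(data.frame(metric = m, stringsAsFactors = FALSE),
          summarize_metric(per[[m]]))
  }))
  list(per_community = per, summary = summ)
}
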