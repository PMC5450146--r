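# Community design: per-genus abundance specifications -> concrete
# gold-standard communities with per-member fractional abundances.

#' Per-genus community specifications
#'
#' A spec table has one row per genus with a targeted mean and standard
#' deviation of fractional abundance, plus a rule for how many species of
#' the genus to include: either `"gaussian"` (p1 = mean count, p2 = sd of
#' count) or `"log"` (p1 = a, p2 = b in n = a * log10(f) + b, where f is
#' the genus's drawn fractional abundance).
#'
#' @param genus Genus name.
#' @param mean_frac Target mean fractional abundance, in (0, 1].
#' @param sd_frac Standard deviation of fractional abundance, >= 0.
#' @param rule_type `"gaussian"` or `"log"`.
#' @param p1,p2 Rule parameters (see Details).
#' @return A one-row spec data frame; rbind rows to build a table.
#' @export
genus_spec <- function(genus, mean_frac, sd_frac, rule_type = c("gaussian", "log"),
                       p1, p2) {
  rule_type <- match.arg(rule_type)
  stopifnot(mean_frac > 0, mean_frac <= 1, sd_frac >= 0)
  data.frame(genus = genus, mean_frac = mean_frac, sd_frac = sd_frac,
             rule_type = rule_type, p1 = p1, p2 = p2,
             stringsAsFactors = FALSE)
}

#' Estimate genus specs from an abundance table
#'
#' Computes the per-genus mean and standard deviation (sample convention,
#' denominator n - 1) of relative abundance across samples (rows). Genera
#' absent everywhere are excluded. The species rule is left unset (`NA`):
#' how many species to draw per genus is a modelling choice the abundance
#' table cannot supply.
#'
#' @param abundance_table Numeric matrix or data frame, samples x genera;
#'   each row must sum to 1 within 1e-6.
#' @return A spec data frame with `rule_type`, `p1`, `p2` set to `NA`.
#' @export
estimate_genus_specs <- function(abundance_table) {
  m <- as.matrix(abundance_table)
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad)) {
    nm <- rownames(m)[bad[1]] %||% as.character(bad[1])
    stop("sample '", nm, "' is not normalized (row sum ", format(rs[bad[1]]), ")")
  }
  mu <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  sds[is.na(sds)] <- 0  # single-sample table
  keep <- mu > 0
  data.frame(genus = colnames(m)[keep], mean_frac = unname(mu[keep]),
             sd_frac = unname(sds[keep]),
             rule_type = NA_character_, p1 = NA_real_, p2 = NA_real_,
             stringsAsFactors = FALSE)
}

#' Number of species to draw for a genus
#'
#' Under the log rule, `n = round(a * log10(f) + b)`; under the gaussian
#' rule, `n = round(Normal(p1, p2) draw)`. Both are clamped to at least 1.
#' The logarithm base (10 by default) is exposed because fractional
#' abundances in microbiome practice are decade-scaled.
#'
#' @param spec A one-row spec data frame.
#' @param f The genus's drawn fractional abundance, in (0, 1].
#' @param log_base Base for the log rule, default 10.
#' @return Integer species count >= 1.
#' @export
species_count <- function(spec, f, log_base = 10) {
  stopifnot(f > 0, f <= 1)
  n <- switch(spec$rule_type,
    log = round(spec$p1 * log(f, base = log_base) + spec$p2),
    gaussian = round(stats::rnorm(1, spec$p1, spec$p2)),
    stop("spec has no species rule (rule_type is ", spec$rule_type, ")")
  )
  max(1L, as.integer(n))
}

#' Draw one defined community from genus specs
#'
#' For each genus: draw its fraction g from Normal(mean_frac, sd_frac);
#' draws <= 0 omit the genus from this community (genera come and go
#' between real stool samples). Compute the species count n from the
#' genus's rule, select min(n, available) distinct species uniformly
#' without replacement from the curated references of that genus, and
#' split g across the selected species by a symmetric Dirichlet(1) draw.
#' Finally all member fractions are renormalized to sum to exactly 1.
#'
#' @param specs Spec data frame ([genus_spec()] rows).
#' @param refs Curated reference set; genera are taken from the
#'   penultimate taxonomy field.
#' @param community_id Identifier for the community.
#' @param log_base Passed to [species_count()].
#' @return A community-target data frame with columns `community_id`,
#'   `accession`, `organism_name`, `taxonomy_string`, `frac`; the
#'   pre-renormalization per-genus draws are in the `genus_draws`
#'   attribute.
#' @export
sample_community <- function(specs, refs, community_id, log_base = 10) {
  genera <- ref_genus(refs)
  rows <- list()
  draws <- stats::setNames(numeric(nrow(specs)), specs$genus)
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, , drop = FALSE]
    g <- stats::rnorm(1, spec$mean_frac, spec$sd_frac)
    draws[i] <- g
    if (g <= 0) next
    pool <- refs[!is.na(genera) & genera == spec$genus, , drop = FALSE]
    if (nrow(pool) == 0L) {
      stop("no curated references available for genus '", spec$genus, "'")
    }
    species <- split(seq_len(nrow(pool)), pool$taxonomy_string)
    n <- species_count(spec, g, log_base = log_base)
    if (n > length(species)) {
      warning("genus '", spec$genus, "': requested ", n, " species, only ",
              length(species), " available; capped")
      n <- length(species)
    }
    chosen <- sample(species, n)
    idx <- vapply(chosen, function(ix) if (length(ix) == 1L) ix else sample(ix, 1),
                  integer(1))
    w <- stats::rgamma(n, shape = 1)  # Dirichlet(1,...,1) via normalized Exp(1)
    rows[[length(rows) + 1L]] <- data.frame(
      community_id = community_id,
      accession = pool$accession[idx],
      organism_name = pool$organism_name[idx],
      taxonomy_string = pool$taxonomy_string[idx],
      frac = g * w / sum(w),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("empty community: every genus draw was <= 0")
  out <- do.call(rbind, rows)
  out$frac <- out$frac / sum(out$frac)
  rownames(out) <- NULL
  attr(out, "genus_draws") <- draws
  out
}

#' Design a set of communities
#'
#' Draws `n` communities from one spec table under a single seed.
#'
#' @inheritParams sample_community
#' @param n Number of communities.
#' @param seed Integer seed; identical seeds give identical targets.
#' @param prefix Community ID prefix.
#' @return A community-target data frame covering all communities, with a
#'   `genus_draws` attribute (matrix: communities x genera,
#'   pre-renormalization Gaussian draws).
#' @export
design_communities <- function(specs, refs, n, seed = NULL,
                               prefix = "community", log_base = 10) {
  with_seed(seed, {
    out <- vector("list", n)
    draws <- matrix(NA_real_, n, nrow(specs),
                    dimnames = list(NULL, specs$genus))
    for (i in seq_len(n)) {
      cid <- sprintf("%s_%03d", prefix, i)
      out[[i]] <- sample_community(specs, refs, cid, log_base = log_base)
      draws[i, ] <- attr(out[[i]], "genus_draws")
    }
    targets <- do.call(rbind, out)
    attr(targets, "genus_draws") <- draws
    targets
  })
}

#' Read and write community-target tables
#'
#' Targets round-trip losslessly through CSV with columns `community_id`,
#' `accession`, `organism_name`, `taxonomy_string`, `frac`. On read, each
#' community's fractions must sum to 1 within 1e-6.
#'
#' @param targets A community-target data frame.
#' @param path CSV file path.
#' @export
write_targets <- function(targets, path) {
  cols <- c("community_id", "accession", "organism_name",
            "taxonomy_string", "frac")
  utils::write.csv(targets[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(frac = "numeric"))
  need <- c("community_id", "accession", "organism_name",
            "taxonomy_string", "frac")
  if (!all(need %in% names(t))) {
    stop("target file must have columns: ", paste(need, collapse = ", "))
  }
  sums <- tapply(t$frac, t$community_id, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-6]
  if (length(bad)) {
    stop("community '", bad[1], "' fractions sum to ",
         format(sums[bad[1]]), ", not 1")
  }
  dup <- tapply(t$accession, t$community_id, anyDuplicated)
  if (any(dup > 0)) stop("duplicate accession within a community")
  t[, need]
}

#' Per-community abundance vectors
#'
#' `abundances_from_targets()` returns the true relative abundances per
#' community, keyed by accession. `abundances_from_otu()` returns the
#' estimated relative abundances per community from an OTU table, summing
#' the `weight` column within each OTU and normalizing.
#'
#' @param targets A community-target data frame.
#' @return A named list of named numeric vectors, one per community, each
#'   summing to 1.
#' @export
abundances_from_targets <- function(targets) {
  lapply(split(targets, targets$community_id), function(d) {
    stats::setNames(d$frac / sum(d$frac), d$accession)
  })
}

#' @rdname abundances_from_targets
#' @param otu An OTU table (see [read_otu_table()]).
#' @export
abundances_from_otu <- function(otu) {
  lapply(split(otu, otu$community), function(d) {
    w <- tapply(d$weight, d$otu_id, sum)
    stats::setNames(as.vector(w / sum(w)), names(w))
  })
}
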