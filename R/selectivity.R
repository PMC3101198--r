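# Randomization tests for taxonomic selectivity of extinction risk:
# is threat distributed unevenly across higher taxa (families, orders)?

#' Build a taxon partition from a species table
#'
#' Groups species into higher taxa at the requested level and attaches
#' the binary threat classification. Every species belongs to exactly
#' one taxon; empty taxon labels are an error.
#'
#' @param species_table Species table (see [read_species_table()]).
#' @param level Grouping column: `"family"`, `"order"`, or `"genus"`.
#' @return A list with `taxon` (factor), `threatened` (logical), and
#'   `level`, one entry per species.
#' @export
taxon_partition <- function(species_table,
                            level = c("family", "order", "genus")) {
  level <- match.arg(level)
  df <- read_species_table(species_table)
  taxa <- df[[level]]
  if (any(!nzchar(taxa)) || anyNA(taxa)) {
    stop("empty ", level, " labels in species table")
  }
  structure(
    list(taxon = factor(taxa), threatened = is_threatened(df$category),
         species = df$species, level = level),
    class = "taxon_partition"
  )
}

#' Proportion of threatened species per taxon
#'
#' @param partition A [taxon_partition()].
#' @return List with `proportion` (named vector per taxon), `n` (taxon
#'   sizes), and `global_mean` (the species-level proportion threatened,
#'   the reference line for selectivity plots).
#' @export
threat_proportion_by_taxon <- function(partition) {
  stopifnot(inherits(partition, "taxon_partition"))
  n <- tabulate(partition$taxon, nbins = nlevels(partition$taxon))
  names(n) <- levels(partition$taxon)
  k <- tapply(partition$threatened, partition$taxon, sum)
  prop <- as.numeric(k) / n
  names(prop) <- names(n)
  list(proportion = prop, n = n,
       global_mean = mean(partition$threatened))
}

# Variance across taxa of the threatened proportion for one label vector.
# `sizes` are the fixed per-taxon sizes; randomization only permutes which
# species carry the threat labels, never the taxon memberships.
.prop_variance <- function(threatened, taxon_int, sizes, weighted = FALSE) {
  k <- rowsum(as.numeric(threatened), taxon_int, reorder = TRUE)[, 1]
  p <- k / sizes
  if (weighted) {
    w <- sizes / sum(sizes)
    sum(w * (p - sum(w * p))^2)
  } else {
    stats::var(p)
  }
}

#' Randomization test for taxonomic selectivity of threat
#'
#' The observed statistic is the variance across taxa of the proportion
#' of threatened species. Significance comes from randomizing species
#' membership among taxa (equivalently, permuting threat labels across
#' species) while keeping the number of species per taxon constant, and
#' recomputing the variance; `p = (count + 1) / (n_rand + 1)` where
#' `count` is the number of randomizations with variance at least the
#' observed value.
#'
#' @param partition A [taxon_partition()].
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Integer seed (required: the test is stochastic).
#' @param weighted Use a taxon-size-weighted variance instead of the
#'   default unweighted variance across taxa.
#' @return List with `statistic`, `p`, `n_rand`, `null` (the randomized
#'   statistics).
#' @export
selectivity_test <- function(partition, n_rand = 1000, seed,
                             weighted = FALSE) {
  stopifnot(inherits(partition, "taxon_partition"))
  if (nlevels(partition$taxon) < 2L) {
    stop("need at least 2 taxa for a selectivity test")
  }
  n_t <- sum(partition$threatened)
  if (n_t == 0L || n_t == length(partition$threatened)) {
    stop("degenerate input: all species threatened or none threatened")
  }
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  taxon_int <- as.integer(partition$taxon)
  sizes <- tabulate(taxon_int, nbins = nlevels(partition$taxon))
  obs <- .prop_variance(partition$threatened, taxon_int, sizes, weighted)
  null <- vapply(seq_len(n_rand), function(i) {
    .prop_variance(sample(partition$threatened), taxon_int, sizes, weighted)
  }, numeric(1))
  list(statistic = obs,
       p = (sum(null >= obs) + 1) / (n_rand + 1),
       n_rand = n_rand, null = null)
}

#' Flag taxa with significantly more or fewer threatened species
#'
#' Compares each taxon's observed proportion of threatened species with
#' its distribution over the same randomizations used by
#' [selectivity_test()] (species shuffled among taxa, taxon sizes fixed).
#' `p_high` is the randomization probability of a proportion at least as
#' large as observed, `p_low` of one at least as small; both use the
#' `(count + 1)/(n_rand + 1)` convention. A taxon is flagged `enriched`
#' if `p_high <= alpha` and `depleted` if `p_low <= alpha`; no
#' multiple-testing correction is applied.
#'
#' @inheritParams selectivity_test
#' @param alpha Flagging level (default 0.05).
#' @return Data frame: taxon, n, proportion, p_high, p_low, flag.
#' @export
flag_extreme_taxa <- function(partition, n_rand = 1000, seed, alpha = 0.05) {
  stopifnot(inherits(partition, "taxon_partition"))
  if (nlevels(partition$taxon) < 2L) {
    stop("need at least 2 taxa")
  }
  n_t <- sum(partition$threatened)
  if (n_t == 0L || n_t == length(partition$threatened)) {
    stop("degenerate input: all species threatened or none threatened")
  }
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  taxon_int <- as.integer(partition$taxon)
  n_taxa <- nlevels(partition$taxon)
  sizes <- tabulate(taxon_int, nbins = n_taxa)
  obs <- rowsum(as.numeric(partition$threatened), taxon_int)[, 1] / sizes
  ge <- le <- rep(0L, n_taxa)
  for (i in seq_len(n_rand)) {
    p_r <- rowsum(as.numeric(sample(partition$threatened)),
                  taxon_int)[, 1] / sizes
    ge <- ge + (p_r >= obs)
    le <- le + (p_r <= obs)
  }
  p_high <- (ge + 1) / (n_rand + 1)
  p_low <- (le + 1) / (n_rand + 1)
  flag <- rep("none", n_taxa)
  flag[p_high <= alpha] <- "enriched"
  flag[p_low <= alpha] <- "depleted"
  data.frame(
    taxon = levels(partition$taxon),
    n = sizes,
    proportion = obs,
    p_high = p_high,
    p_low = p_low,
    flag = flag,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
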