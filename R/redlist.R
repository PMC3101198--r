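# IUCN Red List category semantics: ordered categories, binary threat
# classification, the 0-5 ordinal threat score, genus-level status-change
# indices between two Red List snapshots, and the tertile transition G-test.

#' Ordered IUCN Red List categories
#'
#' The seven assessed Red List categories in order of increasing extinction
#' risk. Data-deficient (DD) and not-evaluated (NE) codes are deliberately
#' absent: analyses here assume assessed-only species lists, and unknown
#' codes are rejected at parse time.
#'
#' @format Character vector of category codes, lowest risk first.
#' @export
IUCN_CATEGORIES <- c("LC", "NT", "VU", "EN", "CR", "EW", "EX")

#' Parse Red List category codes
#'
#' Converts character codes to an ordered factor over
#' `LC < NT < VU < EN < CR < EW < EX`. Unknown codes (including DD/NE)
#' are an error, not an NA: silently dropping unassessed species would
#' bias every downstream proportion.
#'
#' @param x Character vector of category codes (case-insensitive).
#' @return Ordered factor with levels `IUCN_CATEGORIES`.
#' @export
#' @examples
#' parse_category(c("LC", "cr"))
parse_category <- function(x) {
  x <- toupper(trimws(as.character(x)))
  bad <- unique(x[!x %in% IUCN_CATEGORIES])
  if (length(bad) > 0L) {
    stop("unknown Red List category code(s): ", paste(bad, collapse = ", "),
         " (DD/NE and other unassessed codes are not accepted; ",
         "filter to assessed species first)")
  }
  factor(x, levels = IUCN_CATEGORIES, ordered = TRUE)
}

category_rank <- function(category) {
  as.integer(parse_category(category))
}

#' Binary threat classification
#'
#' A species is "threatened" if its category is vulnerable or worse
#' (VU, EN, CR, EW, EX) and "non-threatened" if least-concern or
#' near-threatened (LC, NT).
#'
#' @param category Character vector or ordered factor of category codes.
#' @return Logical vector, `TRUE` for threatened.
#' @export
#' @examples
#' is_threatened(c("LC", "NT", "VU", "EX"))
is_threatened <- function(category) {
  category_rank(category) >= match("VU", IUCN_CATEGORIES)
}

#' Ordinal threat score on the 0-5 scale
#'
#' Maps the six extant-assessable categories onto a linear scale:
#' LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, EW = 5. Extinct (EX) species
#' have no defined position on this scale and are an error; callers must
#' exclude them from trait-style analyses (they still count as threatened
#' in proportions via [is_threatened()]).
#'
#' @param category Character vector or ordered factor of category codes.
#' @return Integer vector of scores in 0..5.
#' @export
#' @examples
#' threat_score(c("LC", "VU", "EW"))
threat_score <- function(category) {
  r <- category_rank(category)
  if (any(r == match("EX", IUCN_CATEGORIES))) {
    stop("EX (extinct) is not scorable on the 0-5 scale; ",
         "exclude extinct species before scoring")
  }
  r - 1L
}

#' Read and validate a species threat table
#'
#' Reads a UTF-8 comma-separated table with required header columns
#' `species`, `genus`, `family`, `order`, `category` and optional
#' `qds_count` (occupied quarter-degree squares, a range-size proxy).
#' Category codes are validated, species names must be unique and
#' nonempty, and `qds_count` (when present) must be a non-negative
#' integer.
#'
#' @param path Path to a CSV file, or a data frame already in memory.
#' @return A `data.frame` with validated columns; `category` is an
#'   ordered factor.
#' @export
read_species_table <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("species", "genus", "family", "order", "category")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("species table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!nzchar(df$species)) || anyNA(df$species)) {
    stop("species names must be nonempty")
  }
  if (anyDuplicated(df$species)) {
    stop("duplicate species names: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  }
  df$category <- parse_category(df$category)
  if ("qds_count" %in% names(df)) {
    q <- df$qds_count
    if (any(!is.na(q) & (q < 0 | q != floor(q)))) {
      stop("qds_count must be a non-negative integer where present")
    }
  }
  df
}

#' Write a species threat table
#'
#' @param df Species table as returned by [read_species_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(df, path) {
  out <- df
  out$category <- as.character(out$category)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-species status transitions between two Red List snapshots
#'
#' Matches species present in both lists and scores each as +1 if threat
#' increased, -1 if it decreased, and 0 if unchanged (the sign of the
#' category rank difference). Species present in only one list are
#' excluded and reported.
#'
#' @param old_list,new_list Species tables (see [read_species_table()]).
#' @return A list with `transitions` (data.frame: species, category_old,
#'   category_new, delta), `only_old`, `only_new` (excluded species names).
#' @export
status_transitions <- function(old_list, new_list) {
  old_list <- read_species_table(old_list)
  new_list <- read_species_table(new_list)
  shared <- intersect(old_list$species, new_list$species)
  if (length(shared) == 0L) stop("no shared species between the two lists")
  io <- match(shared, old_list$species)
  im <- match(shared, new_list$species)
  delta <- sign(category_rank(new_list$category[im]) -
                category_rank(old_list$category[io]))
  list(
    transitions = data.frame(
      species = shared,
      genus = old_list$genus[io],
      category_old = as.character(old_list$category[io]),
      category_new = as.character(new_list$category[im]),
      delta = as.integer(delta),
      stringsAsFactors = FALSE
    ),
    only_old = setdiff(old_list$species, shared),
    only_new = setdiff(new_list$species, shared)
  )
}

#' Genus-level index of change in threat status
#'
#' Sums the per-species transition values (+1 increased, -1 decreased,
#' 0 unchanged) within each genus, for species shared between the two
#' snapshots.
#'
#' @inheritParams status_transitions
#' @return A list with `index` (named integer vector, one entry per genus),
#'   `transitions`, and the exclusion report (`only_old`, `only_new`).
#' @export
status_change_index <- function(old_list, new_list) {
  tr <- status_transitions(old_list, new_list)
  idx <- tapply(tr$transitions$delta, tr$transitions$genus, sum)
  tr$index <- stats::setNames(as.integer(idx), names(idx))
  tr
}

#' Likelihood-ratio goodness-of-fit statistic (G)
#'
#' \eqn{G = 2 \sum_i O_i \ln(O_i / E_i)}; terms with zero observed count
#' contribute zero. Observed and expected totals must agree (the expected
#' vector describes a distribution of the same total count).
#'
#' @param observed Non-negative count vector.
#' @param expected Positive expected-count vector of the same length.
#' @param tol Relative tolerance for the total-count check.
#' @return The G statistic (non-negative scalar).
#' @export
#' @examples
#' g_statistic(c(43, 44), c(27.0667, 59.9333))
g_statistic <- function(observed, expected, tol = 1e-6) {
  if (length(observed) != length(expected) || length(observed) < 2L) {
    stop("observed and expected must have equal length >= 2")
  }
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (any(expected <= 0)) stop("expected counts must be positive")
  if (abs(sum(observed) - sum(expected)) >
      tol * max(1, abs(sum(observed)))) {
    stop("observed and expected totals differ (", sum(observed), " vs ",
         sum(expected), ")")
  }
  terms <- ifelse(observed == 0, 0, observed * log(observed / expected))
  2 * sum(terms)
}

#' G-test on the independence framing of a 2 x k table
#'
#' @param table_counts Matrix of counts.
#' @return G statistic against expected counts from the margins.
#' @keywords internal
g_independence <- function(table_counts) {
  expected <- outer(rowSums(table_counts), colSums(table_counts)) /
    sum(table_counts)
  terms <- ifelse(table_counts == 0, 0,
                  table_counts * log(table_counts / expected))
  2 * sum(terms)
}

#' Tertile transition G-test
#'
#' Tests whether species in the most-threatened genera (by the older
#' snapshot) deteriorate faster than species in the least-threatened
#' genera. Genera are ranked by the mean 0-5 threat score of their listed
#' species in the old list (EX species excluded from scoring); species
#' are pooled within the top and bottom tertiles of that ranking; each
#' species shared between snapshots is classified as "increased" versus
#' "unchanged or decreased". The default `framing = "goodness_of_fit"`
#' computes G for the top-tertile counts against expected proportions
#' taken from the bottom-tertile ratio, referred to chi-square with 1
#' degree of freedom; `framing = "independence"` instead tests the 2 x 2
#' table of tertile by outcome.
#'
#' @inheritParams status_transitions
#' @param framing `"goodness_of_fit"` (default) or `"independence"`.
#' @return List with `G`, `p`, `df`, `top_counts` and `bottom_counts`
#'   (increase : non-increase), `ranking` (per-genus mean old scores),
#'   and `singleton_genera` (genera entering the ranking with a single
#'   assessed species, flagged for inspection).
#' @export
tertile_transition_gtest <- function(old_list, new_list,
                                     framing = c("goodness_of_fit",
                                                 "independence")) {
  framing <- match.arg(framing)
  old_list <- read_species_table(old_list)
  tr <- status_transitions(old_list, new_list)$transitions

  scorable <- old_list[as.character(old_list$category) != "EX", , drop = FALSE]
  mean_score <- tapply(threat_score(scorable$category), scorable$genus, mean)
  genera <- names(sort(mean_score))            # ascending threat
  # ties in mean score: sort() on the named vector keeps name order within
  # ties only incidentally, so enforce lexicographic tie-break explicitly
  ord <- order(mean_score[genera], genera)
  genera <- genera[ord]
  n_gen <- length(genera)
  if (n_gen < 3L) stop("need at least 3 ranked genera to form tertiles")
  k <- floor(n_gen / 3)
  bottom_gen <- genera[seq_len(k)]
  top_gen <- genera[seq.int(n_gen - k + 1L, n_gen)]

  count_pair <- function(gens) {
    d <- tr$delta[tr$genus %in% gens]
    c(increase = sum(d > 0), other = sum(d <= 0))
  }
  top_counts <- count_pair(top_gen)
  bottom_counts <- count_pair(bottom_gen)
  if (sum(top_counts) == 0L || sum(bottom_counts) == 0L) {
    stop("a tertile contains zero species shared between the snapshots")
  }

  res <- transition_gtest_counts(top_counts, bottom_counts, framing)
  tab <- table(factor(old_list$genus, levels = unique(old_list$genus)))
  res$ranking <- mean_score[genera]
  res$singleton_genera <- names(tab)[tab == 1L & names(tab) %in% genera]
  res
}

#' Transition G-test from pooled tertile counts
#'
#' The count-level core of [tertile_transition_gtest()]: given
#' (increase : non-increase) counts for the top and bottom tertiles,
#' computes G and its 1-df chi-square p-value. The default framing tests
#' the top-tertile counts as a goodness-of-fit against the proportions
#' observed in the bottom tertile; `"independence"` tests the 2 x 2
#' table instead.
#'
#' @param top_counts,bottom_counts Length-2 count vectors
#'   (increase, non-increase).
#' @param framing `"goodness_of_fit"` (default) or `"independence"`.
#' @return List with `G`, `p`, `df`, `framing`, `top_counts`,
#'   `bottom_counts`.
#' @export
#' @examples
#' transition_gtest_counts(c(43, 44), c(28, 62))
transition_gtest_counts <- function(top_counts, bottom_counts,
                                    framing = c("goodness_of_fit",
                                                "independence")) {
  framing <- match.arg(framing)
  stopifnot(length(top_counts) == 2L, length(bottom_counts) == 2L,
            all(top_counts >= 0), all(bottom_counts >= 0))
  if (framing == "goodness_of_fit") {
    if (any(bottom_counts == 0)) {
      stop("bottom tertile gives a zero expected count")
    }
    expected <- sum(top_counts) * bottom_counts / sum(bottom_counts)
    G <- g_statistic(top_counts, expected)
  } else {
    G <- g_independence(rbind(top_counts, bottom_counts))
  }
  list(
    G = G,
    p = stats::pchisq(G, df = 1, lower.tail = FALSE),
    df = 1L,
    framing = framing,
    top_counts = top_counts,
    bottom_counts = bottom_counts
  )
}
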