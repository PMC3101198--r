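# Quarter-degree-square (QDS) spatial analyses: per-cell aggregation of
# genus attributes, lattice spatial weights, Moran's I with a
# richness-correction step, and Pearson correlation with the
# Clifford-Richardson-Hemon effective-sample-size adjustment for
# spatially autocorrelated fields.

#' Aggregate genus occurrences into a quarter-degree grid
#'
#' Collapses genus-by-cell occurrence records into one row per cell
#' holding the unweighted mean over genera present of the proportion of
#' threatened species and the diversification rate, plus the genus
#' count. Duplicate (cell, genus) records are collapsed first. A genus
#' occurring in several cells contributes to each.
#'
#' @param records Data frame with columns `cell_row`, `cell_col`,
#'   `genus`, `prop_threatened`, `div_rate`, and optionally
#'   `habitat_index` (a per-cell covariate, constant within cell).
#' @return Data frame (one row per cell): `cell_row`, `cell_col`,
#'   `mean_threat`, `mean_div_rate`, `genus_count`, and `habitat_index`
#'   when supplied.
#' @export
aggregate_cells <- function(records) {
  required <- c("cell_row", "cell_col", "genus", "prop_threatened",
                "div_rate")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("occurrence records are missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("no occurrence records")
  key <- paste(records$cell_row, records$cell_col, records$genus,
               sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  cell <- paste(records$cell_row, records$cell_col, sep = "\r")
  parts <- split(records, cell)
  out <- do.call(rbind, lapply(parts, function(g) {
    row <- data.frame(
      cell_row = g$cell_row[1],
      cell_col = g$cell_col[1],
      mean_threat = mean(g$prop_threatened),
      mean_div_rate = mean(g$div_rate),
      genus_count = nrow(g)
    )
    if ("habitat_index" %in% names(g)) {
      row$habitat_index <- mean(g$habitat_index)
    }
    row
  }))
  out <- out[order(out$cell_row, out$cell_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lattice spatial weights for grid cells
#'
#' Binary contiguity weights on an integer lattice: `"queen"` links the
#' 8 surrounding cells (Chebyshev distance 1, the default for lattice
#' floristic data), `"rook"` the 4 orthogonal neighbours.
#'
#' @param cell_row,cell_col Integer cell indices.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @param row_standardize Divide each row by its sum (default FALSE:
#'   binary weights).
#' @return Square weight matrix with zero diagonal.
#' @export
lattice_weights <- function(cell_row, cell_col,
                            scheme = c("queen", "rook"),
                            row_standardize = FALSE) {
  scheme <- match.arg(scheme)
  if (anyDuplicated(paste(cell_row, cell_col))) {
    stop("duplicate cell indices")
  }
  dr <- abs(outer(cell_row, cell_row, "-"))
  dc <- abs(outer(cell_col, cell_col, "-"))
  w <- if (scheme == "queen") {
    (pmax(dr, dc) == 1) * 1
  } else {
    ((dr + dc) == 1) * 1
  }
  diag(w) <- 0
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  w
}

#' Moran's I spatial autocorrelation
#'
#' \eqn{I = (n/W)\,\sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2} with
#' \eqn{z} the deviations from the mean and \eqn{W} the total weight.
#' The null expectation is \eqn{-1/(n-1)}; the z-score and p-value use
#' the variance under the randomization null, with a permutation
#' p-value available as a cross-check.
#'
#' @param values Numeric vector over cells (non-constant, length >= 4).
#' @param weights Weight matrix (e.g. [lattice_weights()]); zero
#'   diagonal, at least one nonzero entry.
#' @param alternative `"greater"` (clumping, default), `"less"`, or
#'   `"two.sided"`.
#' @param n_perm If > 0, also compute a permutation p-value with this
#'   many permutations (requires `seed`).
#' @param seed Integer seed for the permutation p-value.
#' @return List with `I`, `expected`, `sd`, `z`, `p`, and `p_perm`
#'   (NA unless requested).
#' @export
morans_i <- function(values, weights,
                     alternative = c("greater", "less", "two.sided"),
                     n_perm = 0, seed = NULL) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 4L) stop("need at least 4 cells")
  if (!is.matrix(weights) || nrow(weights) != n || ncol(weights) != n) {
    stop("weights must be an n x n matrix")
  }
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  S0 <- sum(weights)
  if (S0 <= 0) stop("weights are all zero")
  if (stats::var(values) == 0) stop("constant values")

  I_of <- function(v) {
    z <- v - mean(v)
    (n / S0) * sum(weights * outer(z, z)) / sum(z^2)
  }
  I <- I_of(values)
  EI <- -1 / (n - 1)

  z <- values - mean(values)
  S1 <- 0.5 * sum((weights + t(weights))^2)
  S2 <- sum((rowSums(weights) + colSums(weights))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(varI)
  p <- switch(alternative,
              greater = stats::pnorm(zscore, lower.tail = FALSE),
              less = stats::pnorm(zscore),
              two.sided = 2 * stats::pnorm(abs(zscore),
                                           lower.tail = FALSE))
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed is required for the permutation p-value")
    set.seed(as.integer(seed))
    I_null <- vapply(seq_len(n_perm), function(i) I_of(sample(values)),
                     numeric(1))
    count <- switch(alternative,
                    greater = sum(I_null >= I),
                    less = sum(I_null <= I),
                    two.sided = sum(abs(I_null - EI) >= abs(I - EI)))
    p_perm <- (count + 1) / (n_perm + 1)
  }
  list(I = I, expected = EI, sd = sqrt(varI), z = zscore, p = p,
       p_perm = p_perm, alternative = alternative)
}

#' Richness-corrected per-cell threat
#'
#' Residuals of an ordinary least squares regression of per-cell mean
#' threat on log genus count. These residuals are the input to
#' [morans_i()] when testing for geographic clumping of threat beyond
#' what cell richness explains.
#'
#' @param grid Grid data frame (see [aggregate_cells()]) with
#'   `mean_threat` and `genus_count`.
#' @return Numeric vector of residuals (sum to zero).
#' @export
richness_corrected_threat <- function(grid) {
  stopifnot(all(c("mean_threat", "genus_count") %in% names(grid)))
  if (nrow(grid) < 3L) stop("need at least 3 cells")
  lgc <- log(grid$genus_count)
  if (stats::var(lgc) == 0) {
    warning("constant genus_count: falling back to centred mean_threat")
    return(grid$mean_threat - mean(grid$mean_threat))
  }
  stats::residuals(stats::lm(grid$mean_threat ~ lgc))
}

#' Pearson correlation with Clifford-Richardson-Hemon correction
#'
#' Tests the correlation between two spatially autocorrelated fields by
#' adjusting the degrees of freedom rather than the correlation itself.
#' Pair covariances are pooled within distance classes (integer
#' Chebyshev cell separations up to `max_class`); the variance of the
#' sample correlation is estimated from the normalized sum of products
#' of the two fields' autocovariances over classes, the effective sample
#' size is \eqn{\hat n_{eff} = 1 + 1/\widehat{var}(r)}, and
#' \eqn{F = r^2 (\hat n_{eff} - 2)/(1 - r^2)} is referred to
#' \eqn{F(1, \hat n_{eff} - 2)}. `r` itself is the ordinary Pearson
#' correlation — the correction only changes the significance.
#'
#' @param x,y Numeric vectors over cells (complete pairs, length >= 10).
#' @param cell_row,cell_col Integer cell indices giving the geometry.
#' @param max_class Largest Chebyshev separation pooled into classes
#'   (default 10); pairs further apart are ignored.
#' @return List with `r`, `n_eff`, `F`, `p`, `n`. When
#'   `n_eff <= 3` the test is unavailable: `F` and `p` are NA.
#' @export
clifford_corrected_correlation <- function(x, y, cell_row, cell_col,
                                           max_class = 10) {
  n <- length(x)
  if (length(y) != n || length(cell_row) != n || length(cell_col) != n) {
    stop("x, y and cell indices must have equal length")
  }
  if (n < 10L) stop("need at least 10 cells")
  if (anyNA(x) || anyNA(y)) stop("complete pairs required")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant field")

  xc <- x - mean(x)
  yc <- y - mean(y)
  sx2 <- sum(xc^2) / n
  sy2 <- sum(yc^2) / n

  d <- pmax(abs(outer(cell_row, cell_row, "-")),
            abs(outer(cell_col, cell_col, "-")))
  # class 0 holds the n self-pairs (the field variances); classes 1..cap
  # hold ordered pairs at each Chebyshev separation
  num <- n * sx2 * sy2                       # class-0 contribution
  for (k in seq_len(max_class)) {
    sel <- d == k
    Nk <- sum(sel)
    if (Nk == 0) next
    cxk <- sum(outer(xc, xc)[sel]) / Nk
    cyk <- sum(outer(yc, yc)[sel]) / Nk
    num <- num + Nk * cxk * cyk
  }
  var_r <- num / (n^2 * sx2 * sy2)
  n_eff <- 1 + 1 / var_r
  r <- stats::cor(x, y)
  if (n_eff <= 3) {
    return(list(r = r, n_eff = n_eff, F = NA_real_, p = NA_real_, n = n))
  }
  Fstat <- r^2 * (n_eff - 2) / (1 - r^2)
  p <- stats::pf(Fstat, 1, n_eff - 2, lower.tail = FALSE)
  list(r = r, n_eff = n_eff, F = Fstat, p = p, n = n)
}
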