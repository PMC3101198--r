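# Genus-level diversification analyses: net diversification rates,
# binomial GLMs of the proportion of threatened species against
# richness, clade age and rate (with the two sensitivity weightings),
# marginal deviance contributions, Spearman checks, and partial Mantel
# tests against phylogenetic distance.

#' Net diversification rate
#'
#' \eqn{\ln(n) / \mathrm{age}}: the net rate (speciation minus
#' extinction) implied by present richness `n` after `age_my` million
#' years, assuming exponential growth from a single lineage.
#'
#' @param n Species richness (integer >= 1).
#' @param age_my Clade age in millions of years (> 0).
#' @return Rate in lineages per lineage per million years.
#' @export
#' @examples
#' diversification_rate(10, 4)    # ~0.576
diversification_rate <- function(n, age_my) {
  if (any(n < 1)) stop("richness must be at least 1")
  if (any(age_my <= 0)) stop("age must be positive")
  log(n) / age_my
}

#' Read and validate a genus summary table
#'
#' CSV columns: `genus`, `richness`, `age_my`, `n_threatened`,
#' `n_listed`, `endemic` (logical). A `div_rate` column is computed
#' as `log(richness)/age_my`.
#'
#' @param path CSV path or data frame.
#' @return Validated data frame with `div_rate` added.
#' @export
read_genus_summaries <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("genus", "richness", "age_my", "n_threatened", "n_listed",
                "endemic")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("genus summary table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(df$richness < 1)) stop("richness must be >= 1")
  if (any(df$age_my <= 0)) stop("age_my must be positive")
  if (any(df$n_threatened < 0) || any(df$n_threatened > df$n_listed)) {
    stop("need 0 <= n_threatened <= n_listed")
  }
  if (any(df$n_listed > df$richness)) {
    stop("n_listed cannot exceed richness")
  }
  df$endemic <- as.logical(df$endemic)
  df$div_rate <- diversification_rate(df$richness, df$age_my)
  df
}

#' Write a genus summary table
#'
#' @param df Genus summary data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genus_summaries <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Transformed design columns for the threat GLMs. Richness and rate are
# log transformed, age square-root transformed.
glm_design <- function(df, predictors) {
  cols <- list(
    richness = log(df$richness),
    age = sqrt(df$age_my),
    rate = log(df$div_rate)
  )
  out <- as.data.frame(cols[predictors])
  names(out) <- predictors
  out
}

#' Binomial GLM of threat against diversification predictors
#'
#' Fits a logit-link binomial GLM with the per-genus proportion of
#' threatened species as the response (successes `n_threatened`,
#' failures `n_listed - n_threatened`). Predictors are drawn from
#' `richness` (log transformed), `age` (square-root transformed) and
#' `rate` (log of `log(richness)/age`). Genera with no listed species
#' are dropped; when `rate` is a predictor, monotypic genera (rate 0,
#' log undefined) are dropped too, with counts reported. Optional
#' weighting mirrors the two sensitivity schemes: `"log_records"`
#' weights each genus by `log(n_listed + 1)` and `"listed_ratio"` by
#' `n_listed / richness`.
#'
#' @param summaries Genus summary table (see [read_genus_summaries()]).
#' @param predictors Character subset of `c("richness", "age", "rate")`;
#'   empty `character(0)` fits the intercept-only model.
#' @param weighting `"none"` (default), `"log_records"`, or
#'   `"listed_ratio"`.
#' @param endemic_only Restrict to genera flagged endemic (default TRUE:
#'   ages of non-endemics are overestimated when sister lineages are
#'   missing from the tree).
#' @return Object of class `threat_glm`: list with `coefficients`
#'   (estimate, z, p per term), `aic`, `null_deviance`,
#'   `residual_deviance`, `n_genera`, `dropped`, and the underlying
#'   `glm` fit.
#' @export
fit_threat_glm <- function(summaries,
                           predictors = c("richness", "age", "rate"),
                           weighting = c("none", "log_records",
                                         "listed_ratio"),
                           endemic_only = TRUE) {
  weighting <- match.arg(weighting)
  df <- read_genus_summaries(summaries)
  if (!all(predictors %in% c("richness", "age", "rate"))) {
    stop("predictors must be among richness, age, rate")
  }
  dropped <- list()
  if (endemic_only) {
    dropped$non_endemic <- sum(!df$endemic)
    df <- df[df$endemic, , drop = FALSE]
  }
  dropped$unlisted <- sum(df$n_listed < 1)
  df <- df[df$n_listed >= 1, , drop = FALSE]
  if ("rate" %in% predictors) {
    dropped$zero_rate <- sum(df$div_rate <= 0)
    df <- df[df$div_rate > 0, , drop = FALSE]
  }
  if (nrow(df) < 2L) stop("need at least 2 usable genera")

  dat <- data.frame(.succ = df$n_threatened,
                    .fail = df$n_listed - df$n_threatened)
  if (length(predictors) > 0L) {
    dat <- cbind(dat, glm_design(df, predictors))
  }
  w <- switch(weighting,
              none = rep(1, nrow(df)),
              log_records = log(df$n_listed + 1),
              listed_ratio = df$n_listed / df$richness)
  rhs <- if (length(predictors) == 0L) "1" else
    paste(predictors, collapse = " + ")
  form <- stats::as.formula(paste("cbind(.succ, .fail) ~", rhs))
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    weights = w)
  if (!fit$converged) {
    stop("GLM did not converge in ", fit$iter, " IRLS iterations")
  }
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    warning("fitted probabilities numerically 0 or 1: possible complete ",
            "separation; coefficients and p-values are unreliable")
  }
  cf <- summary(fit)$coefficients
  structure(
    list(
      coefficients = data.frame(
        term = rownames(cf),
        estimate = cf[, "Estimate"],
        se = cf[, "Std. Error"],
        z = cf[, "z value"],
        p = cf[, "Pr(>|z|)"],
        row.names = NULL
      ),
      aic = stats::AIC(fit),
      null_deviance = fit$null.deviance,
      residual_deviance = fit$deviance,
      n_genera = nrow(df),
      weighting = weighting,
      predictors = predictors,
      dropped = dropped,
      glm = fit
    ),
    class = "threat_glm"
  )
}

#' @export
print.threat_glm <- function(x, ...) {
  cat("Binomial GLM of threatened proportion (", x$n_genera, " genera, ",
      "weighting: ", x$weighting, ")\n", sep = "")
  print(x$coefficients, digits = 4)
  cat("AIC:", format(x$aic, digits = 6),
      " null deviance:", format(x$null_deviance, digits = 6),
      " residual deviance:", format(x$residual_deviance, digits = 6), "\n")
  invisible(x)
}

#' Marginal deviance explained by one predictor
#'
#' The additional proportion of the null deviance explained when
#' `variable` is added to the model containing the remaining predictors:
#' `(deviance(reduced) - deviance(full)) / null_deviance`.
#'
#' @inheritParams fit_threat_glm
#' @param full_predictors Predictors of the full model.
#' @param variable One member of `full_predictors`.
#' @return Proportion of null deviance (scalar in \[0, 1\]).
#' @export
marginal_deviance <- function(summaries, full_predictors, variable,
                              weighting = "none", endemic_only = TRUE) {
  if (!variable %in% full_predictors) {
    stop("variable must be one of the full model's predictors")
  }
  full <- fit_threat_glm(summaries, full_predictors, weighting,
                         endemic_only)
  reduced <- fit_threat_glm(summaries, setdiff(full_predictors, variable),
                            weighting, endemic_only)
  (reduced$residual_deviance - full$residual_deviance) / full$null_deviance
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (a thin, validating
#' wrapper over [stats::cor()]).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant vector: rank correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}

#' Distance matrix from per-object scalar values
#'
#' Absolute pairwise differences, the convention used when feeding a
#' scalar genus attribute (threat proportion, diversification rate)
#' into a Mantel test.
#'
#' @param x Named numeric vector.
#' @return Symmetric matrix of `|x_i - x_j|`.
#' @export
trait_distance_matrix <- function(x) {
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(names(x), names(x))
  d
}

check_dist_matrix <- function(d, name) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop(name, " must be a square matrix")
  }
  if (max(abs(d - t(d))) > 1e-8) stop(name, " must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop(name, " must have a zero diagonal")
  d
}

# residuals of the upper-triangle entries of d regressed on those of z
mantel_residuals <- function(dv, zv) {
  stats::lm.fit(cbind(1, zv), dv)$residuals
}

#' Partial Mantel test
#'
#' Correlation between two distance matrices controlling for a third:
#' `r` is the Pearson correlation of the residuals of the off-diagonal
#' (upper-triangle) entries of `dX` and `dY` after each is regressed on
#' the corresponding entries of `dZ`. Significance comes from permuting
#' the object labels (rows and columns together) of `dX`,
#' `p = (count + 1)/(n_perm + 1)`, one-tailed on `r >= observed` by
#' default.
#'
#' @param dX,dY,dZ Square symmetric distance matrices in matching order
#'   with zero diagonals.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (required).
#' @param tail `"greater"` (default) or `"two_sided"`.
#' @return List with `r`, `p`, `n_perm`, `tail`.
#' @export
partial_mantel <- function(dX, dY, dZ, n_perm = 999, seed,
                           tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  dX <- check_dist_matrix(dX, "dX")
  dY <- check_dist_matrix(dY, "dY")
  dZ <- check_dist_matrix(dZ, "dZ")
  n <- nrow(dX)
  if (nrow(dY) != n || nrow(dZ) != n) stop("matrix sizes differ")
  if (missing(seed)) stop("seed is required")
  ut <- upper.tri(dX)
  zv <- dZ[ut]
  yv <- dY[ut]
  if (stats::var(dX[ut]) == 0 || stats::var(yv) == 0) {
    stop("constant off-diagonal distances")
  }
  ry <- mantel_residuals(yv, zv)
  rx_obs <- mantel_residuals(dX[ut], zv)
  if (stats::var(rx_obs) < 1e-12 * stats::var(dX[ut])) {
    stop("conditioning matrix explains X entirely; partial correlation ",
         "undefined")
  }
  r_obs <- stats::cor(rx_obs, ry)
  set.seed(as.integer(seed))
  r_null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample(n)
    stats::cor(mantel_residuals(dX[idx, idx][ut], zv), ry)
  }, numeric(1))
  count <- if (tail == "greater") sum(r_null >= r_obs)
           else sum(abs(r_null) >= abs(r_obs))
  list(r = r_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm,
       tail = tail)
}
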