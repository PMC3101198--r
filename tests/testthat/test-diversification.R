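test_that("diversification rate is log richness over age", {
  expect_equal(diversification_rate(1, 5), 0)
  expect_equal(diversification_rate(2, 1), log(2))
  expect_equal(diversification_rate(10, 4), log(10) / 4)
  expect_error(diversification_rate(10, 0), "age")
  expect_error(diversification_rate(0, 5), "richness")
  # scale consistency: multiplying ages by c divides rates by c
  n <- c(5, 50, 120); a <- c(2, 11, 27)
  expect_equal(diversification_rate(n, 3 * a),
               diversification_rate(n, a) / 3)
})

test_that("genus summary IO validates invariants and computes rates", {
  df <- data.frame(genus = c("g1", "g2"), richness = c(10L, 3L),
                   age_my = c(5, 2), n_threatened = c(2L, 0L),
                   n_listed = c(8L, 3L), endemic = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_genus_summaries(read_genus_summaries(df), path)
  back <- read_genus_summaries(path)
  expect_equal(back$div_rate, log(c(10, 3)) / c(5, 2))
  bad <- df; bad$n_threatened[1] <- 9L
  expect_error(read_genus_summaries(bad), "n_threatened")
  bad2 <- df; bad2$n_listed[1] <- 11L
  expect_error(read_genus_summaries(bad2), "exceed richness")
})

test_that("intercept-only fit recovers the pooled log-odds in closed form", {
  df <- data.frame(genus = paste0("g", 1:4), richness = 50L, age_my = 10,
                   n_threatened = c(5L, 10L, 4L, 6L), n_listed = 25L,
                   endemic = TRUE)
  f <- fit_threat_glm(df, character(0))
  expect_equal(f$coefficients$estimate, log(25 / 75), tolerance = 1e-8)
})

test_that("coefficients match the hand-coded IRLS oracle, all weightings", {
  set.seed(21)
  df <- planted_age_summaries(n = 60)
  X <- cbind(1, log(df$richness), sqrt(df$age_my))
  for (wt in c("none", "log_records", "listed_ratio")) {
    f <- fit_threat_glm(df, c("richness", "age"), weighting = wt)
    w <- switch(wt, none = rep(1, nrow(df)),
                log_records = log(df$n_listed + 1),
                listed_ratio = df$n_listed / df$richness)
    b <- irls_oracle(X, df$n_threatened, df$n_listed - df$n_threatened, w)
    expect_equal(f$coefficients$estimate, b, tolerance = 1e-6)
  }
  # constant weights equal the unweighted fit
  f0 <- fit_threat_glm(df, "age")
  b0 <- irls_oracle(cbind(1, sqrt(df$age_my)), df$n_threatened,
                    df$n_listed - df$n_threatened, rep(7, nrow(df)))
  expect_equal(f0$coefficients$estimate, b0, tolerance = 1e-6)
})

test_that("monotypic genera are dropped from rate models with a count", {
  set.seed(22)
  df <- planted_age_summaries(n = 40)
  df$richness[1:3] <- 1L
  df$n_listed[1:3] <- 1L
  df$n_threatened[1:3] <- pmin(df$n_threatened[1:3], 1L)
  f <- fit_threat_glm(df, "rate")
  expect_identical(f$dropped$zero_rate, 3L)
  expect_identical(f$n_genera, 37L)
})

test_that("a planted negative age effect is recovered", {
  set.seed(23)
  hits <- replicate(40, {
    f <- fit_threat_glm(planted_age_summaries(), "age")
    f$coefficients$estimate[2] < 0 && f$coefficients$p[2] < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("marginal deviance: nesting, null effects, effect-size ordering", {
  set.seed(24)
  n <- 300
  age <- stats::runif(n, 1, 30)
  rich <- round(exp(stats::runif(n, log(5), log(200))))
  nl <- pmax(1L, round(rich * 0.8))
  p <- stats::plogis(1 - 0.5 * sqrt(age))   # age matters, richness does not
  df <- data.frame(genus = paste0("g", 1:n), richness = rich, age_my = age,
                   n_threatened = stats::rbinom(n, nl, p), n_listed = nl,
                   endemic = TRUE)
  md_age <- marginal_deviance(df, c("richness", "age"), "age")
  md_rich <- marginal_deviance(df, c("richness", "age"), "richness")
  expect_gt(md_age, md_rich)          # ordering follows planted strength
  expect_lt(md_rich, 0.01)            # null predictor explains ~nothing
  # nesting: reduced deviance >= full deviance, so margins are >= 0
  expect_gte(md_age, 0)
  expect_gte(md_rich, 0)
  expect_error(marginal_deviance(df, c("richness", "age"), "rate"),
               "full model")
})

test_that("two-predictor AIC wins when both effects are planted", {
  set.seed(25)
  wins <- replicate(30, {
    n <- 200
    age <- stats::runif(n, 1, 30)
    rich <- round(exp(stats::runif(n, log(5), log(200))))
    nl <- pmax(1L, round(rich * 0.8))
    p <- stats::plogis(1 - 0.4 * sqrt(age) + 0.4 * log(rich))
    df <- data.frame(genus = paste0("g", 1:n), richness = rich,
                     age_my = age, n_threatened = stats::rbinom(n, nl, p),
                     n_listed = nl, endemic = TRUE)
    both <- fit_threat_glm(df, c("richness", "age"))$aic
    both < fit_threat_glm(df, "age")$aic &&
      both < fit_threat_glm(df, "richness")$aic
  })
  expect_gte(mean(wins), 0.9)
})

test_that("spearman rho behaves and exposes the shared-age artefact", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_error(spearman_rho(x, rep(1, 8)), "constant")
  # richness independent of age still yields strongly negative
  # rho(age, ln n / age): the rate shares the 1/age factor
  set.seed(26)
  age <- stats::runif(200, 1, 30)
  n <- round(exp(stats::runif(200, log(5), log(200))))
  expect_lte(spearman_rho(age, diversification_rate(n, age)), -0.7)
})

test_that("partial Mantel: exact cases, degenerate conditioning, calibration", {
  set.seed(27)
  n <- 15
  x <- stats::setNames(stats::rnorm(n), paste0("g", 1:n))
  dX <- trait_distance_matrix(x)
  dZ <- trait_distance_matrix(stats::setNames(stats::rnorm(n), names(x)))
  res <- partial_mantel(dX, dX, dZ, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_error(partial_mantel(dX, dZ, dX, n_perm = 99, seed = 1),
               "explains X entirely")
  # statistic agrees with an independent implementation on random inputs
  dY <- trait_distance_matrix(stats::setNames(
    0.5 * x + stats::rnorm(n), names(x)))
  mine <- partial_mantel(dX, dY, dZ, n_perm = 99, seed = 2)$r
  ut <- upper.tri(dX)
  rx <- stats::residuals(stats::lm(dX[ut] ~ dZ[ut]))
  ry <- stats::residuals(stats::lm(dY[ut] ~ dZ[ut]))
  expect_equal(mine, stats::cor(rx, ry), tolerance = 1e-12)
  vg <- vegan::mantel.partial(stats::as.dist(dX), stats::as.dist(dY),
                              stats::as.dist(dZ), permutations = 49)
  expect_equal(mine, unname(vg$statistic), tolerance = 1e-10)
  # null calibration: p roughly uniform for unrelated matrices
  set.seed(28)
  ps <- replicate(100, {
    a <- trait_distance_matrix(stats::setNames(stats::rnorm(12), 1:12))
    b <- trait_distance_matrix(stats::setNames(stats::rnorm(12), 1:12))
    cz <- trait_distance_matrix(stats::setNames(stats::rnorm(12), 1:12))
    partial_mantel(a, b, cz, n_perm = 99, seed = sample.int(2^30, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
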