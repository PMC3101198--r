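test_that("category parsing enforces the ordered scale and rejects unknowns", {
  f <- parse_category(c("lc", "EX"))
  expect_s3_class(f, "ordered")
  expect_true(f[1] < f[2])
  expect_error(parse_category("DD"), "DD")
  expect_error(parse_category("XX"), "unknown")
  # total order over all seven categories
  ranks <- as.integer(parse_category(IUCN_CATEGORIES))
  expect_identical(ranks, 1:7)
})

test_that("binary threat classification splits at VU", {
  expect_identical(is_threatened(c("LC", "NT")), c(FALSE, FALSE))
  expect_identical(is_threatened(c("VU", "EN", "CR", "EW", "EX")),
                   rep(TRUE, 5))
})

test_that("threat score is the 0-5 linear scale, strictly monotone, EX barred", {
  expect_identical(threat_score(c("LC", "VU", "EW")), c(0L, 2L, 5L))
  scores <- threat_score(IUCN_CATEGORIES[1:6])
  expect_identical(scores, 0:5)
  expect_true(all(diff(scores) > 0))
  expect_error(threat_score("EX"), "not scorable")
})

test_that("species table IO validates and round-trips", {
  df <- make_species(4, c("LC", "VU", "EN", "CR"))
  df$qds_count <- c(50L, 8L, 2L, 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_species_table(read_species_table(df), path)
  back <- read_species_table(path)
  expect_identical(back$species, df$species)
  expect_identical(as.character(back$category), df$category)
  expect_identical(back$qds_count, df$qds_count)

  expect_error(read_species_table(df[, -5]), "missing required column")
  dup <- rbind(df, df[1, ])
  expect_error(read_species_table(dup), "duplicate species")
  bad <- df; bad$qds_count[1] <- -1
  expect_error(read_species_table(bad), "non-negative")
})

test_that("status change index sums per-species deltas within genera", {
  old <- make_species(3, c("LC", "VU", "EN"))
  new <- old
  new$category <- c("EN", "LC", "EN")   # +1, -1, 0
  res <- status_change_index(old, new)
  expect_identical(unname(res$index["Genus1"]), 0L)

  new2 <- old
  new2$category <- c("VU", "EN", "EN")  # +1, +1, 0
  expect_identical(unname(status_change_index(old, new2)$index["Genus1"]),
                   2L)
  # identity case: identical lists give 0 everywhere
  expect_true(all(status_change_index(old, old)$index == 0L))
  # antisymmetry: swapping the snapshots flips every genus index
  fwd <- status_change_index(old, new)$index
  rev <- status_change_index(new, old)$index
  expect_identical(fwd, -rev[names(fwd)])
})

test_that("species present in only one list are excluded and reported", {
  old <- make_species(3, "LC")
  new <- make_species(4, "VU")
  res <- status_transitions(old, new)
  expect_identical(nrow(res$transitions), 3L)
  expect_identical(res$only_new, "sp4")
  only_a <- make_species(2, "LC", prefix = "a")
  only_b <- make_species(2, "LC", prefix = "b")
  expect_error(status_transitions(only_a, only_b), "no shared species")
})

test_that("G statistic matches hand and log-likelihood oracles", {
  expect_equal(g_statistic(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(g_statistic(c(43, 44), c(27.0667, 59.9333)),
               12.62, tolerance = 0.001)
  expect_error(g_statistic(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(g_statistic(c(5, 5), c(2, 3)), "totals differ")
  # independent oracle: G = 2 * log(multinomial LR) for arbitrary tables
  set.seed(1)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    obs <- stats::rmultinom(1, 200, prob = stats::runif(k, 0.5, 2))[, 1]
    p0 <- stats::runif(k, 0.5, 2); p0 <- p0 / sum(p0)
    exp_counts <- 200 * p0
    phat <- obs / 200
    ll <- function(p) sum(ifelse(obs == 0, 0, obs * log(p)))
    expect_equal(g_statistic(obs, exp_counts), 2 * (ll(phat) - ll(p0)),
                 tolerance = 1e-10)
    expect_gte(g_statistic(obs, exp_counts), 0)
  }
})

test_that("G approaches Pearson chi-square when expected counts are large", {
  set.seed(2)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    p0 <- stats::runif(k, 0.8, 1.2); p0 <- p0 / sum(p0)
    n <- 2000
    obs <- stats::rmultinom(1, n, p0)[, 1]
    e <- n * p0
    if (any(e < 20) || any(obs == 0)) next
    G <- g_statistic(obs, e)
    X2 <- sum((obs - e)^2 / e)
    if (X2 < 0.5) next  # both near zero; relative comparison meaningless
    expect_lt(abs(G - X2) / X2, 0.05)
  }
})

test_that("transition G-test reproduces the printed tertile framing", {
  res <- transition_gtest_counts(c(43, 44), c(28, 62))
  expect_equal(res$G, 12.61, tolerance = 0.01)
  expect_lt(res$p, 0.001)
  expect_identical(res$df, 1L)
  # the independence framing is available but clearly different
  alt <- transition_gtest_counts(c(43, 44), c(28, 62), "independence")
  expect_equal(alt$G, 6.21, tolerance = 0.01)
  # identical ratios give G = 0
  expect_equal(transition_gtest_counts(c(20, 40), c(10, 20))$G, 0)
})

test_that("tertile test ranks genera by old-list mean score and pools species", {
  # 6 genera, 2 species each; top tertile (2 most threatened genera)
  # all increase, bottom tertile none do
  cats <- list(g1 = c("LC", "LC"), g2 = c("LC", "NT"),
               g3 = c("NT", "VU"), g4 = c("VU", "VU"),
               g5 = c("EN", "EN"), g6 = c("CR", "CR"))
  old <- do.call(rbind, lapply(names(cats), function(g) {
    make_species(2, cats[[g]], genus = g, prefix = paste0(g, "_sp"))
  }))
  old$species <- paste0("s", seq_len(nrow(old)))
  new <- old
  up <- old$genus %in% c("g5", "g6")
  new$category <- as.character(old$category)
  new$category[up] <- c("CR", "CR", "EW", "EW")
  new$category[1] <- "NT"   # one increase in the bottom tertile
  res <- tertile_transition_gtest(old, new)
  expect_identical(unname(res$top_counts), c(4L, 0L))
  expect_identical(unname(res$bottom_counts), c(1L, 3L))
  expect_gt(res$G, 0)
  # invariant to genus relabeling (ranks preserved)
  relabel <- c(g1 = "m1", g2 = "m2", g3 = "m3", g4 = "m4", g5 = "m5",
               g6 = "m6")
  old2 <- old; old2$genus <- unname(relabel[old$genus])
  new2 <- new; new2$genus <- unname(relabel[new$genus])
  res2 <- tertile_transition_gtest(old2, new2)
  expect_equal(res2$G, res$G)
  expect_error(tertile_transition_gtest(old[1:4, ], new[1:4, ]),
               "at least 3")
})
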