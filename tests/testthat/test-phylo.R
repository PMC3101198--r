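test_that("newick IO round-trips and rejects malformed trees", {
  t4 <- balanced4()
  expect_identical(length(t4$tip.label), 4L)
  expect_equal(crown_age(t4), 2)
  # round-trip preserves topology and branch lengths
  set.seed(1)
  for (i in 1:20) {
    tr <- simulate_birth_death_tree(0.6, 0.1, n_tips = sample(4:20, 1),
                                    seed = sample.int(2^30, 1))
    back <- read_newick(write_newick(tr))
    expect_identical(back$tip.label, tr$tip.label)
    expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-9)
    expect_identical(back$edge, tr$edge)
  }
  expect_error(read_newick("(A:1,A:1);"), "duplicate tip")
  expect_error(read_newick("(A,B);"), "branch length")
})

test_that("ultrametricity is enforced where required", {
  expect_error(crown_age(read_newick("(A:1,B:2);")), "not ultrametric")
  expect_equal(crown_age(read_newick("(A:3,B:3);")), 3)
  t4 <- balanced4()
  scaled <- t4; scaled$edge.length <- scaled$edge.length * 10
  expect_equal(crown_age(scaled), 20)
})

test_that("patristic distances behave as a metric, with sqrt transform", {
  cherry <- read_newick("(A:3,B:3);")
  expect_equal(phylo_distance_matrix(cherry)["A", "B"], 6)
  expect_equal(phylo_distance_matrix(cherry, "sqrt")["A", "B"], sqrt(6))
  set.seed(2)
  for (i in 1:5) {
    tr <- simulate_birth_death_tree(0.5, 0, n_tips = 8,
                                    seed = sample.int(2^30, 1))
    d <- phylo_distance_matrix(tr)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    n <- nrow(d)
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
    }
  }
})

test_that("independent contrasts match the direct formula and ape", {
  cherry <- read_newick("(A:1,B:1);")
  pic <- independent_contrasts(cherry, c(A = 0, B = 2))
  expect_equal(abs(as.numeric(pic)), sqrt(2))
  t4 <- balanced4()
  expect_true(all(independent_contrasts(t4, c(A = 1, B = 1, C = 1,
                                              D = 1)) == 0))
  # cross-check against ape::pic on random trees/traits
  set.seed(3)
  for (i in 1:10) {
    tr <- simulate_birth_death_tree(0.5, 0.1, n_tips = 10,
                                    seed = sample.int(2^30, 1))
    x <- sim_brownian_trait(tr)
    mine <- sort(abs(as.numeric(independent_contrasts(tr, x))))
    theirs <- sort(abs(as.numeric(ape::pic(x[tr$tip.label], tr))))
    expect_equal(mine, theirs, tolerance = 1e-10)
  }
})

test_that("contrasts and K agree with the dense GLS oracle", {
  set.seed(4)
  for (tr in fixture_trees()) {
    x <- sim_brownian_trait(tr)
    expect_equal(sum(independent_contrasts(tr, x)^2),
                 gls_contrast_ss_oracle(tr, x), tolerance = 1e-10)
    expect_equal(blomberg_k(tr, x), gls_k_oracle(tr, x),
                 tolerance = 1e-8)
    expect_equal(blomberg_k(tr, x),
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("K is invariant to affine trait maps and branch rescaling", {
  tr <- simulate_birth_death_tree(0.5, 0.1, n_tips = 24, seed = 41)
  set.seed(5)
  for (i in 1:5) {
    x <- sim_brownian_trait(tr)
    k0 <- blomberg_k(tr, x)
    expect_equal(blomberg_k(tr, 3.7 * x - 11), k0, tolerance = 1e-10)
    tr2 <- tr; tr2$edge.length <- tr$edge.length * 42
    expect_equal(blomberg_k(tr2, x), k0, tolerance = 1e-10)
  }
})

test_that("K rejects invalid inputs", {
  tr <- simulate_birth_death_tree(0.5, 0, n_tips = 8, seed = 43)
  expect_error(blomberg_k(tr, stats::setNames(rep(1, 8), tr$tip.label)),
               "constant trait")
  x <- sim_brownian_trait(tr)
  names(x)[1] <- "nonexistent"
  expect_error(blomberg_k(tr, x), "tip labels")
  expect_error(blomberg_k(read_newick("(A:1,B:2);"),
                          c(A = 1, B = 2)), "at least 4 tips")
})

test_that("tip-shuffled traits give low K and significant trait-on-tree p", {
  tr <- simulate_birth_death_tree(0.5, 0, n_tips = 128, seed = 47)
  set.seed(6)
  k_bm <- replicate(100, blomberg_k(tr, sim_brownian_trait(tr)))
  k_shuf <- replicate(50, {
    x <- sim_brownian_trait(tr)
    blomberg_k(tr, stats::setNames(sample(x), names(x)))
  })
  # shuffling destroys signal: K below the Brownian 5th percentile
  expect_gte(mean(k_shuf < stats::quantile(k_bm, 0.05)), 0.95)
})

test_that("randomization p has power under Brownian signal and null calibration", {
  tr <- simulate_birth_death_tree(0.5, 0, n_tips = 32, seed = 53)
  set.seed(7)
  p_bm <- replicate(60, {
    k_randomization_p(tr, sim_brownian_trait(tr), n_rand = 99,
                      seed = sample.int(2^30, 1))$p
  })
  expect_gte(mean(p_bm <= 0.05), 0.8)
  p_null <- replicate(100, {
    x <- stats::setNames(stats::rnorm(32), tr$tip.label)
    k_randomization_p(tr, x, n_rand = 99,
                      seed = sample.int(2^30, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(p_null, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(k_randomization_p(tr, sim_brownian_trait(tr), n_rand = 0,
                                 seed = 1), "n_rand")
})

test_that("polytomies are resolved with a warning and contrasts then work", {
  poly <- read_newick("(A:2,B:2,C:2,D:2);")
  expect_warning(res <- resolve_polytomies(poly), "zero-length")
  expect_true(ape::is.binary.phylo(res))
  x <- c(A = 1, B = 2, C = 3, D = 4)
  expect_silent(independent_contrasts(res, x))
  # a genuine zero-length sister pair is rejected with guidance
  zero_cherry <- read_newick("((A:0,B:0):1,(C:1,D:1):0);")
  expect_error(independent_contrasts(zero_cherry, x),
               "resolve_polytomies")
})
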