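# Shared fixtures and independent oracles, built in code at test time.

# Small species table builder
make_species <- function(n, categories, genus = "Genus1",
                         family = "Family1", order = "Order1",
                         prefix = "sp") {
  data.frame(
    species = paste0(prefix, seq_len(n)),
    genus = rep_len(genus, n),
    family = rep_len(family, n),
    order = rep_len(order, n),
    category = rep_len(categories, n),
    stringsAsFactors = FALSE
  )
}

# The worked 4-tip balanced tree and trait
balanced4 <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")
trait4 <- function() c(A = 0, B = 10, C = 5, D = 5)

# A deterministic set of small ultrametric trees (6..12 tips) for
# oracle-equivalence checks
fixture_trees <- function() {
  lapply(seq(6, 12), function(n) {
    simulate_birth_death_tree(0.6, 0.1, n_tips = n, seed = 100 + n)
  })
}

# Dense GLS oracle for Blomberg's K: builds the full covariance matrix
# and evaluates the defining ratio by matrix algebra, independent of
# the pruning implementation.
gls_k_oracle <- function(tree, x) {
  V <- ape::vcv.phylo(tree)
  x <- x[rownames(V)]
  n <- length(x)
  Vi <- solve(V)
  one <- rep(1, n)
  ahat <- as.numeric(t(one) %*% Vi %*% x / (t(one) %*% Vi %*% one))
  mse0 <- sum((x - ahat)^2) / (n - 1)
  mse <- as.numeric(t(x - ahat) %*% Vi %*% (x - ahat)) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  (mse0 / mse) / expected
}

# GLS-based contrasts oracle: the standardized contrasts satisfy
# sum(pic^2) = (x - ahat)' V^-1 (x - ahat); checked as a set via the
# quadratic form rather than node-by-node pairing.
gls_contrast_ss_oracle <- function(tree, x) {
  V <- ape::vcv.phylo(tree)
  x <- x[rownames(V)]
  Vi <- solve(V)
  one <- rep(1, length(x))
  ahat <- as.numeric(t(one) %*% Vi %*% x / (t(one) %*% Vi %*% one))
  as.numeric(t(x - ahat) %*% Vi %*% (x - ahat))
}

# Hand-coded IRLS for the binomial logit GLM, independent of stats::glm
irls_oracle <- function(X, succ, fail, w = rep(1, length(succ)),
                        n_iter = 60) {
  beta <- rep(0, ncol(X))
  m <- succ + fail
  for (i in seq_len(n_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    W <- w * m * mu * (1 - mu)
    z <- eta + (succ / m - mu) / (mu * (1 - mu))
    beta <- solve(t(X) %*% (X * W), t(X) %*% (W * z))
  }
  as.vector(beta)
}

# Genus summary generator with a planted age effect on the logit scale
planted_age_summaries <- function(n = 200, slope = -0.5) {
  age <- stats::runif(n, 1, 30)
  rich <- round(exp(stats::runif(n, log(5), log(200))))
  nl <- pmax(1L, round(rich * 0.8))
  p <- stats::plogis(1 + slope * sqrt(age))
  data.frame(
    genus = paste0("g", seq_len(n)),
    richness = rich, age_my = age,
    n_threatened = stats::rbinom(n, nl, p),
    n_listed = nl, endemic = TRUE,
    stringsAsFactors = FALSE
  )
}
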