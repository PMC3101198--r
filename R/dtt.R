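# Disparity-through-time (DTT) profiles and their two null models:
# Brownian motion, and a punctuated model in which trait values are
# apportioned asymmetrically between daughter lineages at speciation
# (an approximation of range-size evolution under peripatric speciation).

#' Trait disparity of a set of values
#'
#' Average pairwise distance between values: the mean over unordered
#' pairs of squared differences (`"avg_sq"`, default) or absolute
#' differences (`"avg_abs"`). A single value has zero disparity.
#'
#' @param values Numeric vector.
#' @param metric `"avg_sq"` or `"avg_abs"`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' disparity(c(0, 10, 5, 5))       # 200/6
disparity <- function(values, metric = c("avg_sq", "avg_abs")) {
  metric <- match.arg(metric)
  m <- length(values)
  if (m < 1L) stop("disparity needs at least one value")
  if (m == 1L) return(0)
  if (metric == "avg_sq") {
    (m * sum(values^2) - sum(values)^2) / (m * (m - 1) / 2)
  } else {
    mean(stats::dist(values, method = "manhattan"))
  }
}

# Tip sets below every node (tips and internals), as index vectors into
# the tip ordering 1..n.
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; v <- edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  sets
}

#' Disparity-through-time profile
#'
#' For each divergence time (internal node height, measured from the
#' root) the profile records the mean relative disparity of the lineages
#' present immediately before that time: each lineage crossing the time
#' slice defines a subtree, whose tip disparity is divided by the
#' disparity of all tips; single-tip subtrees contribute zero to the
#' mean. The first entry (the root, relative time 0) is exactly 1 — one
#' lineage holding the whole clade — and a terminal entry at relative
#' time 1 records the slice just before the present. Values near 1 mean
#' trait variation lies within subclades; values near 0 mean it lies
#' between them. Simultaneous divergences are collapsed into one slice.
#'
#' @param tree Ultrametric `phylo` object.
#' @param trait Named numeric vector over tips, non-constant.
#' @param metric Disparity metric, see [disparity()].
#' @param tol Ultrametricity tolerance.
#' @return Object of class `dtt_profile`: list with `relative_times`,
#'   `relative_disparity`, `n_tips`, `metric`.
#' @export
dtt_profile <- function(tree, trait, metric = c("avg_sq", "avg_abs"),
                        tol = 1e-6) {
  metric <- match.arg(metric)
  tree <- validate_tree(tree)
  assert_ultrametric(tree, tol)
  x <- match_trait(tree, trait)
  total <- disparity(x, metric)
  if (total == 0) stop("constant trait: total disparity is zero")
  n_tip <- length(x)
  h <- node_heights(tree)
  T_crown <- max(h[seq_len(n_tip)])
  sets <- descendant_tips(tree)

  internal_h <- h[(n_tip + 1L):(n_tip + tree$Nnode)]
  times <- c(sort(unique(internal_h)), T_crown)
  times <- times[!duplicated(signif(times / T_crown, 12))]
  edge <- tree$edge
  h_parent <- h[edge[, 1]]
  h_child <- h[edge[, 2]]

  rel_disp <- vapply(times, function(t) {
    if (t <= 0) return(1)
    # small slack so tips remain "alive" at the terminal slice even with
    # rounding-level deviations from exact ultrametricity
    alive <- which(h_parent < t & h_child >= t - 1e-9 * T_crown)
    vals <- vapply(alive, function(e) {
      disparity(x[sets[[edge[e, 2]]]], metric)
    }, numeric(1))
    mean(vals) / total
  }, numeric(1))

  structure(
    list(relative_times = times / T_crown,
         relative_disparity = rel_disp,
         n_tips = n_tip, metric = metric),
    class = "dtt_profile"
  )
}

#' @export
print.dtt_profile <- function(x, ...) {
  cat("DTT profile:", x$n_tips, "tips,", length(x$relative_times),
      "time slices, metric", x$metric, "\n")
  cat("  relative disparity:",
      paste(signif(x$relative_disparity, 3), collapse = " "), "\n")
  invisible(x)
}

# Shared machinery for the two null models: simulate n_sim tip vectors
# with `simulate_fun()`, run each through dtt_profile on the fixed tree,
# and summarize pointwise. Degenerate (constant) replicates are dropped
# and counted.
null_dtt <- function(tree, simulate_fun, n_sim, metric, level = 0.95) {
  profiles <- vector("list", n_sim)
  dropped <- 0L
  for (i in seq_len(n_sim)) {
    xi <- simulate_fun()
    if (stats::var(xi) == 0) {
      dropped <- dropped + 1L
      next
    }
    profiles[[i]] <- dtt_profile(tree, xi, metric)
  }
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  if (dropped > 0L) {
    warning(dropped, " degenerate replicate(s) with constant tip values ",
            "dropped")
  }
  if (length(profiles) == 0L) {
    stop("all replicates degenerate (constant tip values)")
  }
  mat <- do.call(rbind, lapply(profiles, `[[`, "relative_disparity"))
  a <- (1 - level) / 2
  list(
    relative_times = profiles[[1]]$relative_times,
    mean = colMeans(mat),
    lo = apply(mat, 2, stats::quantile, probs = a),
    hi = apply(mat, 2, stats::quantile, probs = 1 - a),
    n_sim = length(profiles),
    n_dropped = dropped,
    metric = metric
  )
}

#' Brownian-motion null for disparity through time
#'
#' Simulates traits under Brownian motion on the tree (`n_sim`
#' replicates), computes each replicate's DTT profile, and returns the
#' pointwise mean curve and quantile envelope on the tree's slice grid.
#' Because DTT is a ratio of disparities, the curve does not depend on
#' the Brownian rate.
#'
#' @param tree Ultrametric `phylo` object.
#' @param n_sim Number of replicates (default 1000, minimum 2).
#' @param metric Disparity metric, see [disparity()].
#' @param seed Integer seed (required).
#' @param sigma2 Brownian rate (immaterial for the curve; kept for
#'   diagnostics).
#' @param level Envelope coverage (default 0.95).
#' @return List with `relative_times`, `mean`, `lo`, `hi`, `n_sim`.
#' @export
brownian_null_dtt <- function(tree, n_sim = 1000,
                              metric = c("avg_sq", "avg_abs"), seed,
                              sigma2 = 1, level = 0.95) {
  metric <- match.arg(metric)
  if (n_sim < 2) stop("n_sim must be at least 2")
  if (missing(seed)) stop("seed is required")
  tree <- validate_tree(tree)
  assert_ultrametric(tree)
  set.seed(as.integer(seed))
  null_dtt(tree, function() sim_brownian_trait(tree, sigma2), n_sim,
           metric, level)
}

#' Parameters of the punctuated trait-evolution model
#'
#' @param asymmetry_factor Factor (>= 1) by which the peripheral-isolate
#'   daughter's value is reduced at speciation (value divided by the
#'   factor).
#' @param drift_sd Standard deviation of the evolutionary drift added
#'   along branches (per square-root unit time under the default
#'   scaling).
#' @param trend Deterministic expansion per unit time applied to the
#'   reduced daughter on the branch immediately following its origin.
#' @param root_value Trait value (> 0) at the root; on the range-size
#'   reading, the ancestral number of occupied quarter-degree squares.
#' @param floor_eps Positive floor applied after every branch so that
#'   range-like traits stay positive.
#' @param drift_scaling `"sqrt_time"` (drift sd scales with the square
#'   root of branch length; Brownian-consistent in the no-asymmetry
#'   limit) or `"per_branch"` (one unscaled draw per branch).
#' @param seed Optional integer seed stored with the parameters.
#' @return List of class `punctuated_params`.
#' @export
punctuated_params <- function(asymmetry_factor = 2, drift_sd = 2,
                              trend = 0.3, root_value = 50,
                              floor_eps = 1e-6,
                              drift_scaling = c("sqrt_time", "per_branch"),
                              seed = NULL) {
  drift_scaling <- match.arg(drift_scaling)
  if (asymmetry_factor < 1) {
    stop("asymmetry_factor must be >= 1 (the reduced daughter divides ",
         "by the factor; use the factor itself, not its reciprocal)")
  }
  if (drift_sd < 0) stop("drift_sd must be non-negative")
  if (root_value <= 0) stop("root_value must be positive")
  if (floor_eps <= 0) stop("floor_eps must be positive")
  structure(
    list(asymmetry_factor = asymmetry_factor, drift_sd = drift_sd,
         trend = trend, root_value = root_value, floor_eps = floor_eps,
         drift_scaling = drift_scaling, seed = seed),
    class = "punctuated_params"
  )
}

#' Simulate punctuated (peripatric) trait evolution on a tree
#'
#' At each divergence one daughter lineage — chosen with probability 1/2
#' — takes the parental value divided by `asymmetry_factor` (the small
#' peripheral isolate) and the other inherits the parental value
#' unchanged. Along every branch the value then drifts by a normal
#' deviate with mean zero (standard deviation `drift_sd` times the
#' square root of branch length under the default scaling), and the
#' reduced daughter additionally gains `trend` per unit time on the
#' branch immediately following the split, modelling the isolate's range
#' expansion prior to its next divergence. Values are floored at
#' `floor_eps` after each branch.
#'
#' @param tree Ultrametric, fully bifurcating `phylo` object.
#' @param params A [punctuated_params()] object.
#' @param seed Integer seed; defaults to `params$seed`; one of the two
#'   must be supplied.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_punctuated <- function(tree, params = punctuated_params(),
                                seed = params$seed) {
  stopifnot(inherits(params, "punctuated_params"))
  tree <- validate_tree(tree)
  if (!ape::is.binary.phylo(tree)) {
    stop("punctuated simulation requires a fully bifurcating tree")
  }
  assert_ultrametric(tree)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_tip <- length(tree$tip.label)
  tree_co <- ape::reorder.phylo(tree, "cladewise")
  edge <- tree_co$edge
  elen <- tree_co$edge.length
  x <- rep(NA_real_, n_tip + tree$Nnode)
  x[n_tip + 1L] <- params$root_value

  # decide, per internal node, which outgoing edge carries the isolate
  first_child_edge <- !duplicated(edge[, 1])
  reduced_first <- stats::runif(n_tip + tree$Nnode) < 0.5

  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]; t_br <- elen[e]
    is_reduced <- if (first_child_edge[e]) reduced_first[parent]
                  else !reduced_first[parent]
    start <- if (is_reduced) x[parent] / params$asymmetry_factor
             else x[parent]
    sd_br <- if (params$drift_scaling == "sqrt_time") {
      params$drift_sd * sqrt(t_br)
    } else {
      params$drift_sd
    }
    val <- start + stats::rnorm(1, 0, sd_br) +
      if (is_reduced) params$trend * t_br else 0
    x[child] <- max(val, params$floor_eps)
  }
  stats::setNames(x[seq_len(n_tip)], tree_co$tip.label)
}

#' Punctuated-evolution null for disparity through time
#'
#' Replicates of [simulate_punctuated()] piped through [dtt_profile()];
#' same return contract as [brownian_null_dtt()]. Replicates whose tip
#' values come out constant (possible under degenerate parameter
#' settings) are dropped with a warning and counted in `n_dropped`.
#'
#' @inheritParams brownian_null_dtt
#' @param params A [punctuated_params()] object.
#' @export
punctuated_null_dtt <- function(tree, params = punctuated_params(),
                                n_sim = 1000,
                                metric = c("avg_sq", "avg_abs"), seed,
                                level = 0.95) {
  metric <- match.arg(metric)
  if (n_sim < 2) stop("n_sim must be at least 2")
  if (missing(seed)) seed <- params$seed
  if (is.null(seed)) stop("seed is required")
  tree <- validate_tree(tree)
  set.seed(as.integer(seed))
  null_dtt(tree, function() simulate_punctuated(tree, params, seed = NULL),
           n_sim, metric, level)
}
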