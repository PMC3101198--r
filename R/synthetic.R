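# Synthetic data with the statistical structure the analyses assume:
# birth-death phylogenies, range evolution with speciational asymmetry,
# Red List categories assigned from range size, threat clustered within
# higher taxa, spatially autocorrelated cell fields, and paired Red List
# snapshots. Everything is deterministic under its seed and round-trips
# through the package's own readers.

#' Simulate a birth-death tree of extant species
#'
#' Forward (in time) simulation from a single root lineage with
#' per-lineage speciation rate `birth` and extinction rate `death`;
#' extinct lineages are pruned and unary nodes collapsed, leaving an
#' ultrametric tree of extant tips. Stopping is either at `n_tips`
#' extant lineages (the tree is cut at the moment the count is reached)
#' or after `duration` time units. Clades that die out before the
#' stopping condition are retried up to `max_retry` times.
#'
#' @param birth Speciation rate (> 0).
#' @param death Extinction rate (>= 0).
#' @param n_tips Stop at this many extant tips (exclusive with
#'   `duration`).
#' @param duration Stop at this elapsed time.
#' @param seed Integer seed (required).
#' @param max_retry Retries after whole-clade extinction (default 100).
#' @return Ultrametric `phylo` object.
#' @export
simulate_birth_death_tree <- function(birth, death = 0, n_tips = NULL,
                                      duration = NULL, seed,
                                      max_retry = 100) {
  if (birth <= 0) stop("birth rate must be positive")
  if (death < 0) stop("death rate must be non-negative")
  if (is.null(n_tips) == is.null(duration)) {
    stop("supply exactly one of n_tips or duration")
  }
  if (!is.null(n_tips) && n_tips < 2) stop("n_tips must be at least 2")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_retry)) {
    res <- .bd_forward_once(birth, death, n_tips, duration)
    if (!is.null(res)) return(res)
  }
  stop("whole clade went extinct in all ", max_retry,
       " attempts; raise birth or lower death")
}

# One forward pass; NULL when the clade dies (or < 2 survivors).
.bd_forward_once <- function(birth, death, n_tips, duration) {
  # per-lineage records; children = 0 means extant-or-extinct leaf
  parent <- c(NA_integer_)
  t_start <- c(0)
  t_end <- c(NA_real_)
  alive <- c(1L)
  now <- 0
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    if (!is.null(n_tips) && k >= n_tips) {
      # run the clock to a uniform point before the next event so the
      # youngest pair does not end on zero-length terminal branches
      now <- now + stats::rexp(1, k * (birth + death)) * stats::runif(1)
      break
    }
    wait <- stats::rexp(1, k * (birth + death))
    if (!is.null(duration) && now + wait > duration) {
      now <- duration
      break
    }
    now <- now + wait
    lin <- alive[sample.int(k, 1)]
    if (stats::runif(1) < birth / (birth + death)) {
      t_end[lin] <- now
      for (d in 1:2) {
        parent <- c(parent, lin)
        t_start <- c(t_start, now)
        t_end <- c(t_end, NA_real_)
      }
      alive <- c(setdiff(alive, lin),
                 length(parent) - 1L, length(parent))
    } else {
      t_end[lin] <- now
      alive <- setdiff(alive, lin)
    }
  }
  if (length(alive) < 2L) return(NULL)
  t_end[alive] <- now
  extant <- rep(FALSE, length(parent))
  extant[alive] <- TRUE
  .lineages_to_phylo(parent, t_start, t_end, extant)
}

# Build a newick string from the lineage table, pruning lineages without
# extant descendants and collapsing unary pass-through nodes.
.lineages_to_phylo <- function(parent, t_start, t_end, extant) {
  kids <- split(seq_along(parent), factor(parent, seq_along(parent)))
  tip_id <- 0L
  build <- function(i, extra_len) {
    len <- t_end[i] - t_start[i] + extra_len
    ch <- kids[[i]]
    if (length(ch) == 0L) {
      if (!extant[i]) return(NULL)
      tip_id <<- tip_id + 1L
      return(sprintf("t%d:%.12g", tip_id, len))
    }
    sub <- Filter(Negate(is.null), lapply(ch, build, extra_len = 0))
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L) {
      # unary after pruning: absorb this lineage's length into the child
      return(build_absorb(sub[[1]], len))
    }
    sprintf("(%s):%.12g", paste(unlist(sub), collapse = ","), len)
  }
  build_absorb <- function(newick_part, add) {
    # child strings end in ":<len>"; add this lineage's length to it
    pos <- regexpr(":[0-9.eE+-]+$", newick_part)
    len <- as.numeric(substring(newick_part, pos + 1L))
    sprintf("%s:%.12g", substring(newick_part, 1L, pos - 1L), len + add)
  }
  root_str <- build(1L, 0)
  if (is.null(root_str)) return(NULL)
  # strip the root's subtending branch: crown trees start at the first
  # divergence with extant descendants on both sides
  pos <- regexpr(":[0-9.eE+-]+$", root_str)
  tr <- ape::read.tree(text = paste0(substring(root_str, 1L, pos - 1L), ";"))
  if (is.null(tr) || length(tr$tip.label) < 2L) return(NULL)
  tr
}

#' Assign Red List categories from range size
#'
#' Threshold rule on occupied quarter-degree squares: `count <= t_CR`
#' gives CR, `<= t_EN` EN, `<= t_VU` VU, optionally `<= t_NT` NT, and
#' LC otherwise. Mirrors the use of small range size as a key listing
#' criterion, so lineages of small-ranged species come out with high
#' threat proportions.
#'
#' @param qds_counts Positive integer vector of occupied cells.
#' @param thresholds Named increasing vector `c(t_CR, t_EN, t_VU)`.
#' @param t_NT Optional NT upper threshold (> `t_VU`).
#' @return Ordered factor of categories.
#' @export
#' @examples
#' assign_categories_from_range(c(1, 2, 5, 40))
assign_categories_from_range <- function(qds_counts,
                                         thresholds = c(t_CR = 1, t_EN = 3,
                                                        t_VU = 10),
                                         t_NT = NULL) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be three strictly increasing values ",
         "(t_CR < t_EN < t_VU)")
  }
  if (any(qds_counts < 0)) stop("qds_counts must be non-negative")
  out <- rep("LC", length(qds_counts))
  if (!is.null(t_NT)) {
    if (t_NT <= thresholds[3]) stop("t_NT must exceed t_VU")
    out[qds_counts <= t_NT] <- "NT"
  }
  out[qds_counts <= thresholds[3]] <- "VU"
  out[qds_counts <= thresholds[2]] <- "EN"
  out[qds_counts <= thresholds[1]] <- "CR"
  parse_category(out)
}

#' Spatially autocorrelated random field on a grid
#'
#' Moving-average smoothing of unit white noise: each cell averages the
#' noise within Chebyshev radius `range`, then the field is rescaled to
#' unit variance. `range = 0` returns white noise.
#'
#' @param n_row,n_col Grid dimensions.
#' @param range Smoothing radius in cells (autocorrelation range).
#' @param seed Optional integer seed.
#' @return Matrix of field values.
#' @export
autocorrelated_field <- function(n_row, n_col, range = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(n_row * n_col), n_row, n_col)
  if (range == 0) return(noise)
  out <- matrix(0, n_row, n_col)
  for (i in seq_len(n_row)) {
    for (j in seq_len(n_col)) {
      ri <- max(1, i - range):min(n_row, i + range)
      rj <- max(1, j - range):min(n_col, j + range)
      out[i, j] <- mean(noise[ri, rj])
    }
  }
  (out - mean(out)) / stats::sd(out)
}

#' Configuration for the synthetic Cape-like dataset
#'
#' Defaults describe the emulation scale used throughout: 200 genera of
#' 5-200 species on a 40 x 40 quarter-degree-style lattice, with threat
#' assigned from simulated range sizes, clustered within families, and
#' coupled to diversification rate.
#'
#' @param n_genera Number of genera.
#' @param richness_range Inclusive range of per-genus species richness
#'   (drawn log-uniformly).
#' @param age_range Clade age range in my (uniform).
#' @param n_families Number of families genera are assigned to.
#' @param family_sd Standard deviation of the shared family effect on
#'   log range size (threat clustering strength).
#' @param rate_coupling Effect of standardized log diversification rate
#'   on log median range size (negative couples fast diversification to
#'   small ranges, hence high threat).
#' @param range_log_mu,range_log_sd Baseline log-normal parameters for
#'   species range sizes (occupied cells).
#' @param grid_dim Lattice dimensions `c(rows, cols)`.
#' @param habitat_range Autocorrelation range (cells) of the
#'   habitat-impact field, generated independently of threat.
#' @param n_clade_trees Number of exemplar species-level clade trees.
#' @param clade_tree_tips Tip count of each exemplar tree.
#' @param trait Punctuated-model parameters for range evolution on the
#'   exemplar trees ([punctuated_params()]).
#' @param snapshot_base_up,snapshot_score_up Baseline and per-unit-score
#'   log-odds of a species moving up one threat category between
#'   snapshots (higher-scored genera deteriorate faster).
#' @param snapshot_down Probability of moving down one category.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_genera = 200,
                         richness_range = c(5, 200),
                         age_range = c(1, 30),
                         n_families = 20,
                         family_sd = 0.8,
                         rate_coupling = -0.8,
                         range_log_mu = log(15),
                         range_log_sd = 1.0,
                         grid_dim = c(40, 40),
                         habitat_range = 3,
                         n_clade_trees = 3,
                         clade_tree_tips = 64,
                         trait = punctuated_params(),
                         snapshot_base_up = -2.2,
                         snapshot_score_up = 0.5,
                         snapshot_down = 0.08) {
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a complete synthetic Cape-like dataset
#'
#' Builds every input the analysis pipeline consumes: a species threat
#' table (with range sizes and categories assigned from them), genus
#' summaries (richness, age, net diversification rate, threat counts),
#' exemplar species-level clade trees with punctuated range evolution,
#' genus-by-cell occurrence records plus the aggregated grid with an
#' independently generated habitat-impact field, and a pair of Red List
#' snapshots in which genera scored as more threatened in the first
#' snapshot deteriorate faster.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (required; the dataset is a pure function of
#'   config and seed).
#' @return List with `species`, `genus_summaries`, `clade_trees`,
#'   `clade_ranges`, `occurrences`, `grid`, `snapshot_old`,
#'   `snapshot_new`, `config`.
#' @export
synth_cape_like_dataset <- function(config = synth_config(), seed) {
  stopifnot(inherits(config, "synth_config"))
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  cfg <- config

  # ---- genus-level skeleton -------------------------------------------
  genus <- sprintf("Genus%03d", seq_len(cfg$n_genera))
  family <- sprintf("Family%02d",
                    sample.int(cfg$n_families, cfg$n_genera, replace = TRUE))
  ord <- sprintf("Order%02d",
                 (match(family, sort(unique(family))) - 1L) %/% 4L + 1L)
  richness <- round(exp(stats::runif(cfg$n_genera,
                                     log(cfg$richness_range[1]),
                                     log(cfg$richness_range[2]))))
  age <- stats::runif(cfg$n_genera, cfg$age_range[1], cfg$age_range[2])
  rate <- diversification_rate(richness, age)
  fam_eff <- stats::setNames(stats::rnorm(cfg$n_families, 0, cfg$family_sd),
                             sprintf("Family%02d", seq_len(cfg$n_families)))

  # ---- species table with ranges and categories -----------------------
  z_rate <- as.numeric(scale(log(rate)))
  sp_genus <- rep(seq_len(cfg$n_genera), richness)
  mu_sp <- cfg$range_log_mu + cfg$rate_coupling * z_rate[sp_genus] +
    fam_eff[family[sp_genus]]
  qds <- pmax(1, round(exp(stats::rnorm(length(sp_genus), mu_sp,
                                        cfg$range_log_sd))))
  species <- data.frame(
    species = sprintf("%s_sp%03d", genus[sp_genus],
                      unlist(lapply(richness, seq_len))),
    genus = genus[sp_genus],
    family = family[sp_genus],
    order = ord[sp_genus],
    category = as.character(assign_categories_from_range(qds)),
    qds_count = qds,
    stringsAsFactors = FALSE
  )
  species <- read_species_table(species)

  thr <- tapply(is_threatened(species$category), species$genus, sum)
  genus_summaries <- data.frame(
    genus = genus,
    richness = richness,
    age_my = age,
    n_threatened = as.integer(thr[genus]),
    n_listed = richness,
    endemic = TRUE,
    stringsAsFactors = FALSE
  )
  genus_summaries <- read_genus_summaries(genus_summaries)

  # ---- exemplar clade trees with punctuated range evolution -----------
  clade_trees <- list()
  clade_ranges <- list()
  for (i in seq_len(cfg$n_clade_trees)) {
    tr <- simulate_birth_death_tree(birth = 0.5, death = 0.1,
                                    n_tips = cfg$clade_tree_tips,
                                    seed = sample.int(2^30, 1))
    x <- simulate_punctuated(tr, cfg$trait, seed = sample.int(2^30, 1))
    clade_trees[[sprintf("clade%02d", i)]] <- tr
    clade_ranges[[sprintf("clade%02d", i)]] <- x
  }

  # ---- geography: genus occurrence blocks + independent habitat field -
  nr <- cfg$grid_dim[1]; nc <- cfg$grid_dim[2]
  prop_thr <- genus_summaries$n_threatened / genus_summaries$n_listed
  centre_r <- sample.int(nr, cfg$n_genera, replace = TRUE)
  centre_c <- sample.int(nc, cfg$n_genera, replace = TRUE)
  radius <- pmin(6L, pmax(1L, round(log(richness))))
  occ <- do.call(rbind, lapply(seq_len(cfg$n_genera), function(g) {
    rows <- max(1, centre_r[g] - radius[g]):min(nr, centre_r[g] + radius[g])
    cols <- max(1, centre_c[g] - radius[g]):min(nc, centre_c[g] + radius[g])
    cells <- expand.grid(cell_row = rows, cell_col = cols)
    keep <- stats::runif(nrow(cells)) < 0.7
    if (!any(keep)) keep[1] <- TRUE
    data.frame(cells[keep, , drop = FALSE],
               genus = genus[g],
               prop_threatened = prop_thr[g],
               div_rate = genus_summaries$div_rate[g])
  }))
  habitat <- autocorrelated_field(nr, nc, cfg$habitat_range)
  occ$habitat_index <- habitat[cbind(occ$cell_row, occ$cell_col)]
  grid <- aggregate_cells(occ)

  # ---- paired Red List snapshots --------------------------------------
  old_cat <- species$category
  score_ok <- as.character(old_cat) != "EX"
  genus_score <- tapply(threat_score(old_cat[score_ok]),
                        species$genus[score_ok], mean)
  gs <- genus_score[species$genus]
  gs[is.na(gs)] <- 0
  p_up <- stats::plogis(cfg$snapshot_base_up + cfg$snapshot_score_up * gs)
  rank_old <- as.integer(old_cat)
  u <- stats::runif(nrow(species))
  rank_new <- rank_old +
    (u < p_up) * 1L -
    (u >= p_up & u < p_up + cfg$snapshot_down) * 1L
  rank_new <- pmin(pmax(rank_new, 1L), length(IUCN_CATEGORIES))
  snapshot_new <- species
  snapshot_new$category <- parse_category(IUCN_CATEGORIES[rank_new])

  list(species = species,
       genus_summaries = genus_summaries,
       clade_trees = clade_trees,
       clade_ranges = clade_ranges,
       occurrences = occ,
       grid = grid,
       snapshot_old = species,
       snapshot_new = snapshot_new,
       config = cfg)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the plain-text formats the package's readers consume: species
#' and snapshot CSVs, the genus summary CSV, one newick file per clade
#' tree with a matching range CSV, the occurrence CSV and aggregated
#' grid CSV.
#'
#' @param dataset Result of [synth_cape_like_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_species_table(dataset$species, file.path(dir, "species.csv"))
  write_species_table(dataset$snapshot_new,
                      file.path(dir, "snapshot_new.csv"))
  write_genus_summaries(dataset$genus_summaries,
                        file.path(dir, "genus_summaries.csv"))
  utils::write.csv(dataset$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$grid, file.path(dir, "grid.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(dataset$clade_trees)) {
    write_newick(dataset$clade_trees[[nm]],
                 file.path(dir, paste0(nm, ".nwk")))
    utils::write.csv(
      data.frame(tip = names(dataset$clade_ranges[[nm]]),
                 value = as.numeric(dataset$clade_ranges[[nm]])),
      file.path(dir, paste0(nm, "_ranges.csv")),
      row.names = FALSE, quote = FALSE
    )
  }
  invisible(dir)
}
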