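# Synthetic-data generator. Produces inputs with the statistical structure
# the analyses assume — a clock-free fossil tree with stratigraphic tip
# ranges, an Mk-style discrete character matrix evolved along it, and tip
# traits drawn from the exact multivariate normal each evolutionary model
# defines — so that every pipeline stage can be tested end to end without
# external data files.

#' Simulation configuration
#'
#' Defaults emulate a Lower Jurassic plesiosaur-style dataset: 32 taxa by
#' 207 characters with states 0-2 and 40% missing cells, a ~25 Myr window
#' (205-180 Ma) spanning three stratigraphic bins, and trunk-length traits
#' in millimetres (directional Brownian motion: step mean 16.1 mm/Myr, step
#' variance 20 mm^2/Myr, measurement sd 55 mm, root state 680 mm).
#'
#' @param seed master seed; component generators use fixed offsets from it
#' @param n_taxa,n_characters,n_states matrix dimensions and state count
#' @param missing_fraction i.i.d. probability a cell is missing
#' @param char_rate per-character state-change rate (changes/Myr)
#' @param birth_rate lineage splitting rate (1/Myr) shaping node spacing
#' @param window c(older, younger) age window in Ma
#' @param range_duration_mean mean observed range length (Myr)
#' @param trait_model `"trend"`, `"bm"` or `"stasis"`
#' @param root_state,step_variance,step_mean,measurement_sd trait parameters
#'   (mm, mm^2/Myr, mm/Myr, mm)
#' @param trait_mean,trait_variance stasis parameters (mm, mm^2)
#' @param bins time-bin tibble
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1, n_taxa = 32, n_characters = 207,
                       n_states = 3, missing_fraction = 0.4,
                       char_rate = 0.01, birth_rate = 0.25,
                       window = c(205, 180), range_duration_mean = 2,
                       trait_model = "trend", root_state = 680,
                       step_variance = 20, step_mean = 16.1,
                       measurement_sd = 55,
                       trait_mean = 1381, trait_variance = 100,
                       bins = default_bins()) {
  stopifnot(n_taxa >= 4, missing_fraction >= 0, missing_fraction <= 1,
            char_rate >= 0, birth_rate > 0, window[1] > window[2])
  structure(as.list(environment()), class = "sim_config")
}

#' Default Lower Jurassic time bins
#'
#' Three narrow intervals: earliest Hettangian (201.6-199.3 Ma), Sinemurian
#' (199.3-190.8 Ma), lower Toarcian (183-180 Ma).
#' @return a bin tibble
#' @export
default_bins <- function() {
  time_bins(c("Hettangian", "Sinemurian", "Toarcian"),
            c(201.6, 199.3, 183.0), c(199.3, 190.8, 180.0))
}

#' Simulate a fossil tree with stratigraphic tip ranges
#'
#' Grows a random binary topology and assigns node ages top-down inside the
#' age window: the root sits at the older bound and each node is younger
#' than its parent by an exponential wait (rate `birth_rate`), truncated at
#' the younger bound. Each tip's first appearance (FAD) is its branch end;
#' its last appearance is an exponential range later, truncated at the
#' window.
#'
#' @param config a [sim_config]
#' @return list with `tree` (an `ape::phylo` with branch durations in Myr),
#'   `records` (taxon tibble with `fad`, `lad`), `node_age`
#' @export
simulate_tree_with_ranges <- function(config) {
  set.seed(config$seed)
  n <- config$n_taxa
  older <- config$window[1]; younger <- config$window[2]
  phy <- ape::rtree(n, rooted = TRUE, br = NULL)
  phy$tip.label <- sprintf("t%02d", seq_len(n))
  ntip <- n
  ages <- numeric(ntip + phy$Nnode)
  root <- ntip + 1L
  ages[root] <- older
  pre <- ape::reorder.phylo(phy, "cladewise")$edge
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; c <- pre[i, 2]
    wait <- stats::rexp(1, config$birth_rate)
    ages[c] <- max(younger, ages[p] - wait)
  }
  fad <- ages[seq_len(ntip)]
  lad <- pmax(younger, fad - stats::rexp(ntip, 1 / config$range_duration_mean))
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  phy$root.time <- older
  records <- tibble::tibble(name = phy$tip.label, fad = fad, lad = lad,
                            trunk_length = NA_real_, neck_length = NA_real_,
                            bin_label = NA_character_)
  list(tree = phy, records = records,
       node_age = ages)
}

#' Simulate an Mk-style character matrix along a tree
#'
#' Each character evolves independently under a symmetric k-state Markov
#' process along the tree's branch durations (uniform root state), after
#' which cells are masked missing i.i.d. at `missing_fraction`. `block_mask`
#' (a named list: taxon label -> character indices) additionally blanks
#' whole anatomical blocks per taxon, emulating e.g. a taxon with 100%
#' postcranial missing data.
#'
#' @param tree an `ape::phylo` with branch durations (Myr)
#' @param config a [sim_config]
#' @param block_mask optional named list of per-taxon character indices to
#'   set missing
#' @return a [char_matrix]
#' @export
simulate_matrix <- function(tree, config, block_mask = NULL) {
  set.seed(config$seed + 1000L)
  k <- config$n_states
  nc <- config$n_characters
  ntip <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(NA_integer_, ntip + tree$Nnode, nc)
  root <- ntip + 1L
  states[root, ] <- sample.int(k, nc, replace = TRUE) - 1L
  elen <- pre$edge.length
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1]; c <- pre$edge[i, 2]
    t <- if (is.null(elen)) 1 else elen[i]
    # symmetric k-state process: P(state unchanged) over duration t
    p_same <- 1 / k + (k - 1) / k * exp(-k / (k - 1) * config$char_rate * t)
    changed <- stats::runif(nc) > p_same
    s <- states[p, ]
    shift <- sample.int(k - 1, nc, replace = TRUE)
    s[changed] <- (s[changed] + shift[changed]) %% k
    states[c, ] <- s
  }
  tip_states <- states[seq_len(ntip), , drop = FALSE]
  miss <- matrix(stats::runif(ntip * nc) < config$missing_fraction, ntip, nc)
  masks <- matrix(bitwShiftL(1L, tip_states), ntip, nc)
  masks[miss] <- NA_integer_
  rownames(masks) <- tree$tip.label
  if (!is.null(block_mask)) {
    for (tx in names(block_mask)) {
      masks[tx, block_mask[[tx]]] <- NA_integer_
    }
  }
  new_char_matrix(masks, tree$tip.label)
}

#' Simulate tip traits under stasis, BM, or BM+trend
#'
#' Draws tip values from the exact multivariate normal each model defines on
#' the calibrated tree — the same covariance construction the fitting
#' routines use (`step_variance * C + measurement_sd^2 * I`, mean
#' `root_state [+ step_mean * depth]`; stasis is i.i.d. normal plus noise) —
#' so generator and fitter close the loop.
#'
#' @param timetree a `time_tree` (ignored by stasis except for tip labels)
#' @param config a [sim_config]; `trait_model` selects the process
#' @return tibble with `taxon` and `value`
#' @export
simulate_traits <- function(timetree, config) {
  set.seed(config$seed + 2000L)
  tips <- timetree$phy$tip.label
  n <- length(tips)
  model <- config$trait_model
  if (model == "stasis") {
    v <- config$trait_variance + config$measurement_sd^2
    vals <- stats::rnorm(n, config$trait_mean, sqrt(v))
  } else if (model %in% c("bm", "trend")) {
    C <- phylo_vcv(timetree)
    tips <- rownames(C)
    depth <- diag(C)
    mu <- rep(config$root_state, n)
    if (model == "trend") mu <- mu + config$step_mean * depth
    Sigma <- config$step_variance * C
    diag(Sigma) <- diag(Sigma) + config$measurement_sd^2
    vals <- drop(MASS::mvrnorm(1, mu, Sigma))
  } else stop("unknown trait model: ", model)
  tibble::tibble(taxon = tips, value = unname(vals))
}
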