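# Character-based (cladistic) disparity: pairwise dissimilarity between taxa
# as the proportion of comparable characters that differ, principal
# coordinates of that matrix with the Cailliez negative-eigenvalue
# correction, per-interval disparity metrics (mean pairwise dissimilarity and
# sum of variances of ordination scores), and rarefaction confidence
# intervals.

#' Pairwise character dissimilarity
#'
#' For each pair of taxa, the proportion of comparable cells (cells scored in
#' both taxa) whose state sets are disjoint. A shared state in a polymorphic
#' overlap counts as not-different. Pairs with no comparable cells are
#' undefined (`NA`).
#'
#' @param matrix a [char_matrix]
#' @param taxa optional subset of taxon labels
#' @return a `dissim_matrix`: list with `d` (symmetric proportion matrix,
#'   zero diagonal), `n_comparable` (cell counts), `taxa`
#' @export
pairwise_dissimilarity <- function(matrix, taxa = NULL) {
  if (!is.null(taxa)) matrix <- matrix[normalise_label(taxa), ]
  M <- matrix$masks
  n <- nrow(M)
  if (n < 2) stop("need at least 2 taxa")
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  ncmp <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    mi <- M[i, ]
    for (j in (i + 1):n) {
      mj <- M[j, ]
      comp <- !is.na(mi) & !is.na(mj)
      k <- sum(comp)
      ncmp[i, j] <- ncmp[j, i] <- k
      d[i, j] <- d[j, i] <- if (k == 0) NA_real_ else
        sum(bitwAnd(mi[comp], mj[comp]) == 0L) / k
    }
  }
  diag(ncmp) <- colSums(!is.na(t(M)))
  structure(list(d = d, n_comparable = ncmp, taxa = rownames(M)),
            class = "dissim_matrix")
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat("<dissim_matrix> ", length(x$taxa), " taxa; ",
      sum(is.na(x$d[upper.tri(x$d)])), " undefined pair(s)\n", sep = "")
  invisible(x)
}

#' Remove taxa causing undefined dissimilarities
#'
#' Greedily deletes the taxon participating in the most undefined (no
#' comparable cells) pairs until none remain — e.g. a taxon scored only for
#' postcrania can never be compared with a cranium-only taxon. The removal
#' order is recorded in the `"removed"` attribute.
#'
#' @param dissim a `dissim_matrix`
#' @return a `dissim_matrix` with no undefined pairs
#' @export
drop_undefined_taxa <- function(dissim) {
  d <- dissim$d
  ncmp <- dissim$n_comparable
  removed <- character(0)
  repeat {
    undef <- is.na(d)
    diag(undef) <- FALSE
    if (!any(undef)) break
    counts <- rowSums(undef)
    worst <- which.max(counts)
    removed <- c(removed, rownames(d)[worst])
    d <- d[-worst, -worst, drop = FALSE]
    ncmp <- ncmp[-worst, -worst, drop = FALSE]
  }
  structure(list(d = d, n_comparable = ncmp, taxa = rownames(d)),
            class = "dissim_matrix", removed = removed)
}

#' Principal coordinates with Cailliez correction
#'
#' Gower-transforms the dissimilarity matrix (double centering of -d^2/2) and
#' eigendecomposes it. With `correction = "cailliez"`, the smallest constant
#' c making the configuration Euclidean (all eigenvalues non-negative) is
#' found from the standard 2n x 2n companion eigenproblem, added to all
#' off-diagonal dissimilarities, and the corrected matrix re-embedded. Scores
#' are eigenvectors scaled by the square root of their eigenvalue; axes with
#' eigenvalue at or below `tolerance` are dropped.
#'
#' @param dissim a `dissim_matrix` with no undefined pairs
#' @param correction `"cailliez"` (default) or `"none"`
#' @param tolerance eigenvalue cutoff for retaining axes
#' @return an `ordination`: list with `scores` (taxa x axes), `eigenvalues`,
#'   `cailliez_constant`, `percent_per_axis`, `taxa`
#' @export
principal_coordinates <- function(dissim, correction = c("cailliez", "none"),
                                  tolerance = 1e-10) {
  correction <- match.arg(correction)
  D <- dissim$d
  if (any(is.na(D)))
    stop("dissimilarity matrix has undefined pairs; drop_undefined_taxa() first")
  if (!isSymmetric(unname(D), tol = 1e-12)) stop("dissimilarity not symmetric")
  n <- nrow(D)
  cc <- 0
  if (correction == "cailliez") {
    G <- gower_center(D)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tolerance) {
      cc <- cailliez_constant(D)
      D <- D + cc
      diag(D) <- 0
    }
  }
  G <- gower_center(D)
  eig <- eigen(G, symmetric = TRUE)
  keep <- eig$values > tolerance
  vals <- eig$values[keep]
  scores <- eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(vals), sum(keep))
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  structure(list(scores = scores, eigenvalues = vals,
                 cailliez_constant = cc,
                 percent_per_axis = 100 * vals / sum(vals),
                 taxa = rownames(D)),
            class = "ordination")
}

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(D)
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

# smallest additive constant making D Euclidean (largest real eigenvalue of
# the 2n x 2n companion matrix)
cailliez_constant <- function(D) {
  n <- nrow(D)
  d1 <- gower_center(D)
  d2 <- {
    A <- -0.5 * D
    C <- diag(n) - matrix(1 / n, n, n)
    C %*% A %*% C
  }
  comp <- rbind(cbind(matrix(0, n, n), 2 * d1),
                cbind(-diag(n), -4 * d2))
  ev <- eigen(comp, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> ", length(x$taxa), " taxa, ", ncol(x$scores),
      " axes; Cailliez constant ", format(x$cailliez_constant, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Cumulative percentage of dissimilarity on the first k axes
#'
#' @param ordination an `ordination`
#' @param k number of leading axes
#' @return cumulative percentage (0 for `k = 0`)
#' @export
axis_percentages <- function(ordination, k) {
  if (k == 0) return(0)
  if (k > length(ordination$eigenvalues)) stop("k exceeds retained axes")
  100 * sum(ordination$eigenvalues[seq_len(k)]) / sum(ordination$eigenvalues)
}

#' Mean pairwise dissimilarity within a taxon subset
#'
#' @param dissim a `dissim_matrix`
#' @param taxa taxon labels (default: all)
#' @return arithmetic mean of d over unordered pairs; `NA` for a singleton
#' @export
mean_pairwise_dissimilarity <- function(dissim, taxa = NULL) {
  if (is.null(taxa)) taxa <- dissim$taxa
  taxa <- normalise_label(taxa)
  miss <- setdiff(taxa, dissim$taxa)
  if (length(miss)) stop("taxa not in dissimilarity matrix: ",
                         paste(miss, collapse = ", "))
  if (length(taxa) < 2) return(NA_real_)
  d <- dissim$d[taxa, taxa]
  vals <- d[upper.tri(d)]
  if (anyNA(vals)) stop("subset contains undefined pairs")
  mean(vals)
}

#' Sum of variances of ordination scores within a taxon subset
#'
#' The sum over axes of the sample variance (n-1 denominator) of the subset's
#' scores — the sample-size-robust disparity metric.
#'
#' @param ordination an `ordination`
#' @param taxa taxon labels (default: all)
#' @return scalar; `NA` for a singleton
#' @export
sum_of_variances <- function(ordination, taxa = NULL) {
  if (is.null(taxa)) taxa <- ordination$taxa
  taxa <- normalise_label(taxa)
  miss <- setdiff(taxa, ordination$taxa)
  if (length(miss)) stop("taxa not in ordination: ",
                         paste(miss, collapse = ", "))
  if (length(taxa) < 2) return(NA_real_)
  s <- ordination$scores[taxa, , drop = FALSE]
  sum(apply(s, 2, stats::var))
}

#' Rarefaction confidence interval for a disparity metric
#'
#' Resamples `sample_size` taxa without replacement `n_resamples` times,
#' recomputes the metric each time, and reports the 2.5th/97.5th percentile
#' bounds alongside the full-pool point estimate. Bit-reproducible for a
#' fixed seed.
#'
#' @param x a `dissim_matrix` (for `metric = "mpd"`) or an `ordination`
#'   (for `metric = "sov"`)
#' @param taxa the taxon pool (default: all taxa of `x`)
#' @param sample_size taxa drawn per resample (at least 2)
#' @param n_resamples number of resamples
#' @param seed RNG seed
#' @param metric `"mpd"` or `"sov"`
#' @return one-row tibble: `point`, `lower`, `upper`
#' @export
rarefaction_ci <- function(x, taxa = NULL, sample_size,
                           n_resamples = 1000, seed = 1,
                           metric = c("mpd", "sov")) {
  metric <- match.arg(metric)
  f <- if (metric == "mpd") {
    stopifnot(inherits(x, "dissim_matrix"))
    function(t) mean_pairwise_dissimilarity(x, t)
  } else {
    stopifnot(inherits(x, "ordination"))
    function(t) sum_of_variances(x, t)
  }
  if (is.null(taxa)) taxa <- x$taxa
  if (sample_size < 2) stop("sample_size must be at least 2")
  if (sample_size > length(taxa)) stop("sample_size exceeds pool size")
  point <- f(taxa)
  set.seed(seed)
  vals <- vapply(seq_len(n_resamples), function(i)
    f(sample(taxa, sample_size)), 0)
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  tibble::tibble(point = point, lower = q[1], upper = q[2])
}

#' Per-interval disparity with rarefaction confidence intervals
#'
#' Computes the pairwise dissimilarity matrix over the assigned taxa, removes
#' taxa causing undefined pairs, runs the Cailliez-corrected principal
#' coordinates, and reports mean pairwise dissimilarity and sum of variances
#' per time bin with rarefaction CIs at a common sample size (default: the
#' smallest bin's taxon count, which equalises sampling across bins).
#'
#' @param matrix a [char_matrix]
#' @param assignments tibble with `name` and `bin_label` columns (taxa with
#'   `NA` bins are excluded — supply the interval whitelist here)
#' @param n_resamples rarefaction resamples per bin
#' @param seed RNG seed, recorded in the result's attributes
#' @param sample_size common rarefied sample size (default: smallest bin)
#' @param correction passed to [principal_coordinates()]
#' @return a `disparity_result` tibble: per bin `n_taxa`, `mpd` with CI
#'   bounds, `sov` with CI bounds. Attributes: `ordination`, `dissim`,
#'   `removed`, `sample_size`, `seed`.
#' @export
disparity_by_bin <- function(matrix, assignments, n_resamples = 1000,
                             seed = 1, sample_size = NULL,
                             correction = "cailliez") {
  asg <- assignments[!is.na(assignments$bin_label), ]
  asg$name <- normalise_label(asg$name)
  keep <- intersect(cm_taxa(matrix), asg$name)
  dis <- drop_undefined_taxa(pairwise_dissimilarity(matrix, keep))
  ord <- principal_coordinates(dis, correction = correction)
  asg <- asg[asg$name %in% dis$taxa, ]
  bins <- unique(asg$bin_label)
  n_by_bin <- vapply(bins, function(b) sum(asg$bin_label == b), 0L)
  if (is.null(sample_size)) sample_size <- max(2L, min(n_by_bin))
  rows <- purrr::map_dfr(seq_along(bins), function(i) {
    b <- bins[i]
    taxa <- asg$name[asg$bin_label == b]
    if (length(taxa) < 2)
      return(tibble::tibble(bin = b, n_taxa = length(taxa),
                            mpd = NA_real_, mpd_lower = NA_real_,
                            mpd_upper = NA_real_, sov = NA_real_,
                            sov_lower = NA_real_, sov_upper = NA_real_))
    ss <- min(sample_size, length(taxa))
    ci_m <- rarefaction_ci(dis, taxa, ss, n_resamples, seed + i, "mpd")
    ci_s <- rarefaction_ci(ord, taxa, ss, n_resamples, seed + i, "sov")
    tibble::tibble(bin = b, n_taxa = length(taxa),
                   mpd = ci_m$point, mpd_lower = ci_m$lower,
                   mpd_upper = ci_m$upper,
                   sov = ci_s$point, sov_lower = ci_s$lower,
                   sov_upper = ci_s$upper)
  })
  attr(rows, "ordination") <- ord
  attr(rows, "dissim") <- dis
  attr(rows, "removed") <- attr(dis, "removed")
  attr(rows, "sample_size") <- sample_size
  attr(rows, "seed") <- seed
  class(rows) <- c("disparity_result", class(rows))
  rows
}
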