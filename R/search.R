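# Heuristic tree search: random-addition-sequence stepwise addition followed
# by TBR (tree bisection and reconnection) branch swapping, retaining all
# distinct trees at the best length found. Bremer decay indices come from a
# reverse-constraint search: the shortest tree NOT containing the clade.

#' Heuristic parsimony search
#'
#' Runs `n_replicates` random-addition replicates. Each replicate builds a
#' starting tree by greedy stepwise addition under a seeded random taxon
#' order (replicate r uses `seed + r`), then applies TBR branch swapping to a
#' local optimum, keeping every distinct tree at the current best length.
#' The union of trees at the global best length is returned, deduplicated by
#' bipartition set.
#'
#' @param matrix a [char_matrix] with at least 4 taxa
#' @param n_replicates number of random-addition replicates
#' @param seed master seed; replicate r draws its addition order from
#'   `seed + r`
#' @param outgroup optional taxon label used to root the returned trees
#'   (rooting never affects scores)
#' @param max_trees_held cap on the equal-length tree pool per replicate
#'   (default unlimited)
#' @return an object of class `parsimony_search`: list with `trees` (list of
#'   `ape::phylo`), `length` (best steps), `n_replicates`, `seed`
#' @export
heuristic_search <- function(matrix, n_replicates = 10, seed = 1,
                             outgroup = NULL, max_trees_held = Inf) {
  ctx <- cm_score_ctx(matrix)
  n <- length(ctx$taxa)
  if (n < 4) stop("heuristic search needs at least 4 taxa")
  res <- search_core(ctx, n_replicates, seed, max_trees_held,
                     objective = function(ut) score_ut(ut, ctx))
  trees <- lapply(res$pool, ut_to_phylo)
  if (!is.null(outgroup)) trees <- lapply(trees, root_safely, outgroup)
  structure(list(trees = trees, length = res$best,
                 n_replicates = n_replicates, seed = seed),
            class = "parsimony_search")
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("<parsimony_search> ", length(x$trees), " tree(s) of length ",
      x$length, " (", x$n_replicates, " replicates, seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

root_safely <- function(phy, outgroup) {
  outgroup <- normalise_label(outgroup)
  if (!outgroup %in% phy$tip.label) return(phy)
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}

search_core <- function(ctx, n_replicates, seed, max_trees_held, objective) {
  n <- length(ctx$taxa)
  best <- Inf
  pool <- list()
  hashes <- character(0)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    ord <- sample.int(n)
    ut <- stepwise_addition(ctx, ord, objective)
    opt <- tbr_optimize(ut, objective, max_trees_held)
    if (opt$best < best) {
      best <- opt$best
      pool <- list(); hashes <- character(0)
    }
    if (opt$best == best) {
      for (k in seq_along(opt$pool)) {
        h <- opt$hashes[k]
        if (!(h %in% hashes)) {
          pool <- c(pool, opt$pool[k])
          hashes <- c(hashes, h)
        }
      }
    }
  }
  list(pool = pool, best = best, hashes = hashes)
}

stepwise_addition <- function(ctx, ord, objective) {
  n <- length(ctx$taxa)
  ut <- ut_start(ord[1:3], n, ctx$taxa, n + 1L)
  next_int <- n + 2L
  for (k in 4:n) {
    tip <- ord[k]
    cands <- lapply(seq_len(nrow(ut$edge)), function(i)
      ut_insert_tip(ut, i, tip, next_int))
    lens <- vapply(cands, objective, 0)
    ut <- cands[[which.min(lens)]]
    next_int <- next_int + 1L
  }
  ut
}

tbr_optimize <- function(ut0, objective, max_trees_held) {
  best <- objective(ut0)
  pool <- list(ut0)
  hashes <- ut_hash(ut0)
  swapped <- FALSE
  repeat {
    todo <- which(!swapped)
    if (!length(todo)) break
    i <- todo[1]
    swapped[i] <- TRUE
    nbs <- ut_tbr_neighbors(pool[[i]])
    lens <- vapply(nbs, objective, 0)
    mn <- min(lens)
    if (mn < best) {
      best <- mn
      keep <- nbs[lens == mn]
      pool <- list(); hashes <- character(0); swapped <- logical(0)
      for (t in keep) {
        h <- ut_hash(t)
        if (!(h %in% hashes) && length(pool) < max_trees_held) {
          pool <- c(pool, list(t)); hashes <- c(hashes, h)
          swapped <- c(swapped, FALSE)
        }
      }
    } else {
      for (t in nbs[lens == best]) {
        h <- ut_hash(t)
        if (!(h %in% hashes) && length(pool) < max_trees_held) {
          pool <- c(pool, list(t)); hashes <- c(hashes, h)
          swapped <- c(swapped, FALSE)
        }
      }
    }
  }
  list(pool = pool, best = best, hashes = hashes)
}

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted binary topology (3, 15, 105, 945, ... for 4, 5,
#' 6, 7, ... taxa), scores each, and returns all optimal trees. Intended for
#' small problems (at most 9 taxa) and as the ground truth against which the
#' heuristic search is validated.
#'
#' @param matrix a [char_matrix] with 4..9 taxa
#' @return an object of class `parsimony_search`
#' @export
exhaustive_search <- function(matrix) {
  ctx <- cm_score_ctx(matrix)
  n <- length(ctx$taxa)
  if (n < 4 || n > 9) stop("exhaustive search supports 4..9 taxa")
  tops <- all_topologies_ut(n, ctx$taxa)
  lens <- vapply(tops, function(u) score_ut(u, ctx), 0)
  best <- min(lens)
  structure(list(trees = lapply(tops[lens == best], ut_to_phylo),
                 length = best, n_replicates = NA_integer_, seed = NA_integer_),
            class = "parsimony_search")
}

# all unrooted binary topologies on tips 1..n, by recursive tip insertion
all_topologies_ut <- function(n, labels) {
  tops <- list(ut_start(1:3, n, labels, n + 1L))
  if (n == 3) return(tops)
  for (k in 4:n) {
    new_int <- n + (k - 2L)
    tops <- unlist(lapply(tops, function(u)
      lapply(seq_len(nrow(u$edge)), function(i)
        ut_insert_tip(u, i, k, new_int))), recursive = FALSE)
  }
  tops
}

#' Bremer decay index of a clade
#'
#' The number of extra steps needed before the clade disappears from the
#' optimal tree set, computed by a reverse-constraint search: the same
#' heuristic search run with trees containing the clade excluded from the
#' optimum, giving the shortest tree NOT containing it. A trivial
#' bipartition (fewer than 2 members, or fewer than 2 non-members) can never
#' be broken and is reported as `Inf`.
#'
#' @param matrix a [char_matrix]
#' @param clade character vector of taxon labels forming the clade
#' @param n_replicates,seed,max_trees_held as in [heuristic_search()]
#' @param best_length optional known best length (saves repeating the
#'   unconstrained search)
#' @return integer decay index (or `Inf`)
#' @export
decay_index <- function(matrix, clade, n_replicates = 10, seed = 1,
                        max_trees_held = Inf, best_length = NULL) {
  ctx <- cm_score_ctx(matrix)
  n <- length(ctx$taxa)
  ids <- match(normalise_label(clade), ctx$taxa)
  if (anyNA(ids)) stop("unknown taxon in clade: ",
                       paste(clade[is.na(ids)], collapse = ", "))
  if (length(ids) < 2 || length(ids) > n - 2) return(Inf)
  if (is.null(best_length))
    best_length <- heuristic_search(matrix, n_replicates, seed)$length
  penalty <- 1e7
  obj <- function(ut) {
    score_ut(ut, ctx) + if (ut_contains_split(ut, ids)) penalty else 0
  }
  res <- search_core(ctx, n_replicates, seed, max_trees_held = 1, obj)
  if (res$best >= penalty) return(Inf)
  as.integer(round(res$best - best_length))
}
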