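# Parsimony scoring and tree statistics. Tree length is computed by a
# minimum-change dynamic programme over states (see src/sankoff.cpp): unit
# step costs for unordered characters, |i-j| costs for additive ones, exact on
# polytomies. Missing cells carry the full state universe and never add steps;
# polymorphic cells carry their state set.

# scoring context: everything the kernel needs, computed once per matrix
cm_score_ctx <- function(x) {
  list(masks = x$masks, n_states = cm_n_states(x), ordered = x$ordered,
       taxa = cm_taxa(x))
}

score_ut <- function(ut, ctx) {
  sum(sankoff_score_cpp(ut$edge, nrow(ctx$masks), ctx$masks,
                        ctx$n_states, ctx$ordered))
}

#' Parsimony tree length
#'
#' Minimum number of character-state changes implied by a tree, summed over
#' characters. The score is that of the unrooted tree, so it is invariant
#' under re-rooting.
#'
#' @param tree an `ape::phylo`; tips must be a subset of the matrix taxa
#' @param matrix a [char_matrix]
#' @param per_character if `TRUE`, return the per-character step vector
#' @return total steps (or per-character steps)
#' @export
fitch_length <- function(tree, matrix, per_character = FALSE) {
  ctx <- cm_score_ctx(matrix)
  ut <- ut_from_phylo(phy_norm(tree), labels = ctx$taxa)
  steps <- sankoff_score_cpp(ut$edge, nrow(ctx$masks), ctx$masks,
                             ctx$n_states, ctx$ordered)
  if (per_character) steps else sum(steps)
}

phy_norm <- function(tree) {
  tree$tip.label <- normalise_label(tree$tip.label)
  tree
}

#' Minimum conceivable steps for one character
#'
#' The smallest number of changes the character can require on any tree:
#' (number of states needed) - 1, where polymorphic cells are assigned the
#' state minimising the count (a minimum hitting set over the cells' state
#' sets). For additive characters it is the smallest achievable state range.
#' An all-missing character scores 0.
#'
#' @param matrix a [char_matrix]
#' @param j character index
#' @return integer step count
#' @export
char_min_steps <- function(matrix, j) {
  masks <- matrix$masks[, j]
  masks <- masks[!is.na(masks)]
  if (!length(masks)) return(0L)
  sets <- lapply(masks, mask_to_states)
  if (matrix$ordered[j]) {
    lo <- max(vapply(sets, min, 0L))   # smallest achievable maximum state
    hi <- min(vapply(sets, max, 0L))   # largest achievable minimum state
    return(max(0L, lo - hi))
  }
  states <- sort(unique(unlist(sets)))
  for (k in seq_along(states)) {
    for (S in utils::combn(states, k, simplify = FALSE)) {
      smask <- states_to_mask(S)
      if (all(bitwAnd(masks, smask) > 0L)) return(k - 1L)
    }
  }
  length(states) - 1L
}

#' Maximum conceivable steps for one character
#'
#' The worst-tree (star tree) step count: scored cells minus the frequency of
#' the most common state, with polymorphic cells assigned to whichever of
#' their states is most frequent. An all-missing character scores 0.
#'
#' @inheritParams char_min_steps
#' @return integer step count
#' @export
char_max_steps <- function(matrix, j) {
  masks <- matrix$masks[, j]
  masks <- masks[!is.na(masks)]
  if (!length(masks)) return(0L)
  states <- sort(unique(unlist(lapply(masks, mask_to_states))))
  freq <- vapply(states, function(s)
    sum(bitwAnd(masks, bitwShiftL(1L, s)) > 0L), 0L)
  length(masks) - max(freq)
}

#' Ensemble consistency, retention and rescaled consistency indices
#'
#' PAUP-style ensemble indices over all included characters:
#' CI = sum(min_i) / length, RI = (sum(max_i) - length) /
#' (sum(max_i) - sum(min_i)), RC = CI * RI. RI is `NA` when the matrix has no
#' parsimony-informative variation (sum(max) == sum(min)).
#'
#' @inheritParams fitch_length
#' @return a one-row tibble: `length`, `ci`, `ri`, `rc`
#' @export
ensemble_indices <- function(tree, matrix) {
  len <- fitch_length(tree, matrix)
  mins <- sum(vapply(seq_len(cm_n_characters(matrix)),
                     function(j) char_min_steps(matrix, j), 0L))
  maxs <- sum(vapply(seq_len(cm_n_characters(matrix)),
                     function(j) char_max_steps(matrix, j), 0L))
  ci <- if (len > 0) mins / len else NA_real_
  ri <- if (maxs > mins) (maxs - len) / (maxs - mins) else NA_real_
  tibble::tibble(length = len, ci = ci, ri = ri, rc = ci * ri)
}

#' Strict consensus of a set of trees
#'
#' The tree containing exactly the bipartitions present in every input tree.
#'
#' @param trees a list of `ape::phylo` (or a `multiPhylo`) sharing one tip set
#' @return an `ape::phylo`
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  if (length(trees) == 0) stop("empty tree set")
  if (length(trees) == 1) return(trees[[1]])
  ape::consensus(trees, p = 1, rooted = FALSE)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  lapply(trees, phy_norm)
}

#' Prune a taxon from a set of trees
#'
#' Removes the taxon from every tree, suppresses the resulting degree-2
#' nodes, and merges trees that become topologically identical.
#'
#' @param trees a list of `ape::phylo` (or a single tree)
#' @param taxon taxon label to remove
#' @return a list of distinct pruned trees
#' @export
prune_taxon <- function(trees, taxon) {
  trees <- as_tree_list(trees)
  taxon <- normalise_label(taxon)
  if (!all(vapply(trees, function(t) taxon %in% t$tip.label, TRUE)))
    stop("taxon '", taxon, "' not present in all trees")
  pruned <- lapply(trees, ape::drop.tip, tip = taxon)
  dedup_trees(pruned)
}

dedup_trees <- function(trees) {
  labels <- sort(trees[[1]]$tip.label)
  hashes <- vapply(trees, function(t) ut_hash(ut_from_phylo(t, labels)), "")
  trees[!duplicated(hashes)]
}
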