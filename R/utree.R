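# Internal light-weight unrooted tree representation used by the parsimony
# search. A "ut" is a list(edge = m x 2 integer matrix of undirected edges,
# n_tip, labels). Tips are 1..n_tip (row order of the character matrix in
# play); internal node ids are arbitrary integers > n_tip.

ut_new <- function(edge, n_tip, labels) {
  storage.mode(edge) <- "integer"
  list(edge = edge, n_tip = as.integer(n_tip), labels = labels)
}

ut_from_phylo <- function(phy, labels = NULL) {
  if (is.null(labels)) labels <- phy$tip.label
  idx <- match(phy$tip.label, labels)
  if (anyNA(idx)) stop("tree tips not found among taxon labels: ",
                       paste(phy$tip.label[is.na(idx)], collapse = ", "))
  n <- length(labels)
  ntip_phy <- length(phy$tip.label)
  # renumber: phylo tip i -> idx[i]; phylo internal j -> n + (j - ntip_phy)
  map <- c(idx, n + seq_len(phy$Nnode))
  edge <- cbind(map[phy$edge[, 1]], map[phy$edge[, 2]])
  # suppress a degree-2 root (rooted binary input) to get the unrooted tree
  root <- map[ntip_phy + 1L]
  deg <- tabulate(edge, nbins = max(edge))
  if (deg[root] == 2L) {
    rows <- which(edge[, 1] == root | edge[, 2] == root)
    nb <- setdiff(as.vector(edge[rows, ]), root)
    edge <- edge[-rows, , drop = FALSE]
    edge <- rbind(edge, nb)
  }
  ut_new(edge, n, labels)
}

# Convert back to an ape phylo (basal trifurcation, i.e. unrooted shape).
ut_to_phylo <- function(ut) {
  E <- ut$edge
  n <- ut$n_tip
  present_tips <- sort(unique(as.vector(E)[as.vector(E) <= n]))
  ntip <- length(present_tips)
  if (ntip == 2L && nrow(E) == 1L) {
    # degenerate two-tip tree
    phy <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2),
                tip.label = ut$labels[present_tips], Nnode = 1L)
    class(phy) <- "phylo"
    return(phy)
  }
  adj <- ut_adjacency(E)
  root <- ut_pick_root(E, n)
  # DFS assigning ape ids: tips 1..ntip (in label order of appearance),
  # internals ntip+1..
  tip_id <- integer(max(c(E))); tip_id[present_tips] <- seq_len(ntip)
  new_id <- integer(length(adj))
  next_int <- ntip + 1L
  parent <- integer(length(adj))
  stack <- root; parent[root] <- -1L
  order <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    if (v <= n) new_id[v] <- tip_id[v] else { new_id[v] <- next_int; next_int <- next_int + 1L }
    for (w in adj[[v]]) if (w != parent[v]) { parent[w] <- v; stack <- c(stack, w) }
  }
  rows <- order[order != root]
  edge <- cbind(new_id[parent[rows]], new_id[rows])
  phy <- list(edge = edge, tip.label = ut$labels[present_tips],
              Nnode = next_int - ntip - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

ut_adjacency <- function(E) {
  mx <- max(E)
  adj <- vector("list", mx)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1]; b <- E[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

ut_pick_root <- function(E, n_tip) {
  internals <- unique(as.vector(E)[as.vector(E) > n_tip])
  if (length(internals)) internals[1] else E[1, 1]
}

# unrooted star/triple on the given tip ids
ut_start <- function(tips, n_tip, labels, internal_id) {
  stopifnot(length(tips) == 3)
  ut_new(cbind(rep(internal_id, 3L), tips), n_tip, labels)
}

# insert tip `tip` on edge row `i`, using `new_int` as the new internal node
ut_insert_tip <- function(ut, i, tip, new_int) {
  E <- ut$edge
  u <- E[i, 1]; v <- E[i, 2]
  E[i, ] <- c(u, new_int)
  E <- rbind(E, c(new_int, v), c(new_int, tip))
  ut_new(E, ut$n_tip, ut$labels)
}

# --- splits ------------------------------------------------------------
# Split (bipartition) sets come from src/splits.cpp as sorted double-encoded
# tip bitmasks, canonicalised to the side not containing the smallest tip.

ut_splits <- function(ut) ut_splits_cpp(ut$edge, ut$n_tip)

ut_hash <- function(ut) paste(ut_splits(ut), collapse = ";")

ut_contains_split <- function(ut, tip_ids) {
  E <- ut$edge
  present <- unique(as.vector(E)[as.vector(E) <= ut$n_tip])
  ref <- min(present)
  mask <- sum(2^(tip_ids - 1))
  if (ref %in% tip_ids) mask <- sum(2^(present - 1)) - mask
  mask %in% ut_splits(ut)
}

# --- TBR ---------------------------------------------------------------

# connected component containing `start` in edge set E
ut_component <- function(E, start) {
  if (nrow(E) == 0) return(start)
  adj <- ut_adjacency(E)
  seen <- integer(0)
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    if (v <= length(adj) && !is.null(adj[[v]])) stack <- c(stack, adj[[v]])
  }
  seen
}

# After deleting an edge, suppress the now degree-2 endpoint `v` inside its
# component. Returns list(edge, attach_node, freed).
ut_suppress <- function(E, v) {
  rows <- which(E[, 1] == v | E[, 2] == v)
  if (length(rows) == 0) {
    return(list(edge = E, attach_node = v, freed = integer(0), single = TRUE))
  }
  if (length(rows) == 2) {
    nb <- setdiff(as.vector(E[rows, ]), v)
    if (length(nb) == 1) nb <- rep(nb, 2)  # parallel edges cannot occur in a tree
    E <- E[-rows, , drop = FALSE]
    E <- rbind(E, nb)
    return(list(edge = E, attach_node = NA_integer_, freed = v, single = FALSE))
  }
  list(edge = E, attach_node = NA_integer_, freed = integer(0), single = FALSE)
}

# All TBR reconnections of `ut` (bisect every edge; reattach every edge/edge
# pair). Returns list of ut; includes trees identical to the input (callers
# deduplicate by hash).
ut_tbr_neighbors <- function(ut) {
  E <- ut$edge
  n <- ut$n_tip
  res <- list()
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1]; v <- E[i, 2]
    rem <- E[-i, , drop = FALSE]
    compU <- ut_component(rem, u)
    inU <- rem[, 1] %in% compU  # edges of u-side (trees: both endpoints same side)
    EU <- rem[inU, , drop = FALSE]
    EV <- rem[!inU, , drop = FALSE]
    su <- ut_suppress(EU, u)
    sv <- ut_suppress(EV, v)
    freed <- c(su$freed, sv$freed)
    attA <- if (su$single) 0L else seq_len(nrow(su$edge))
    attB <- if (sv$single) 0L else seq_len(nrow(sv$edge))
    for (a in attA) {
      for (b in attB) {
        EA <- su$edge; EB <- sv$edge
        free_pool <- freed
        if (a == 0L) {
          pa <- su$attach_node
        } else {
          pa <- free_pool[1]; free_pool <- free_pool[-1]
          a2 <- EA[a, 2]
          EA[a, 2] <- pa
          EA <- rbind(EA, c(pa, a2))
        }
        if (b == 0L) {
          pb <- sv$attach_node
        } else {
          pb <- free_pool[1]; free_pool <- free_pool[-1]
          b2 <- EB[b, 2]
          EB[b, 2] <- pb
          EB <- rbind(EB, c(pb, b2))
        }
        newE <- rbind(EA, EB, c(pa, pb))
        res[[length(res) + 1L]] <- ut_new(newE, n, ut$labels)
      }
    }
  }
  res
}
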