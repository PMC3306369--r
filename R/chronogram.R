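# Time-calibration of a cladogram against stratigraphic tip ranges. Ages are
# in Ma before present (larger = older) everywhere; branch durations are in
# Myr. Node ages start at the oldest first appearance among descendants and
# zero-duration branches are then smoothed, either by forcing a minimum
# branch duration ("mbl") or by sharing time equally with the closest
# ancestral positive branch ("equal").

#' Calibrate a cladogram against stratigraphic ages
#'
#' Tips are placed at their first appearance datum (FAD; or range midpoint),
#' every internal node at the oldest age among its descendants, and
#' zero-duration branches are smoothed. Under `"mbl"` every branch is forced
#' to at least `min_duration` by pushing ancestral nodes older; under
#' `"equal"` each run of zero branches shares the duration of the closest
#' ancestral positive branch equally. The root is finally extended to at
#' least `root_extension` Myr above the oldest tip.
#'
#' @param tree an `ape::phylo` (polytomies allowed; calibrated as hard)
#' @param records taxon table (tibble with `name`, `fad`, `lad`) covering
#'   every tip
#' @param method `"mbl"` (default) or `"equal"`
#' @param min_duration minimum branch duration in Myr (used by `"mbl"`)
#' @param root_extension minimum root age above the oldest tip, Myr
#' @param tip_age place tips at `"fad"` (default) or range `"midpoint"`
#' @return a `time_tree`: list with `phy` (branch lengths in Myr,
#'   `$root.time` set), `node_age` (ages, Ma, indexed by ape node id),
#'   `ranges` (tip ranges tibble)
#' @export
calibrate <- function(tree, records, method = c("mbl", "equal"),
                      min_duration = 1, root_extension = 1,
                      tip_age = c("fad", "midpoint")) {
  method <- match.arg(method)
  tip_age <- match.arg(tip_age)
  phy <- phy_norm(tree)
  recs <- records
  recs$name <- normalise_label(recs$name)
  idx <- match(phy$tip.label, recs$name)
  if (anyNA(idx))
    stop("tip(s) without a stratigraphic range: ",
         paste(phy$tip.label[is.na(idx)], collapse = ", "))
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  fad <- recs$fad[idx]
  lad <- recs$lad[idx]
  ages <- numeric(ntip + nnode)
  ages[seq_len(ntip)] <- if (tip_age == "fad") fad else (fad + lad) / 2

  post <- ape::reorder.phylo(phy, "postorder")$edge
  root <- ntip + 1L
  parent_of <- integer(ntip + nnode)
  # oldest-descendant initial ages
  ages[(ntip + 1):(ntip + nnode)] <- -Inf
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1]; c <- post[i, 2]
    parent_of[c] <- p
    ages[p] <- max(ages[p], ages[c])
  }
  oldest_tip <- max(ages[seq_len(ntip)])

  if (method == "mbl") {
    if (min_duration < 0) stop("min_duration must be >= 0")
    ages2 <- ages
    ages2[(ntip + 1):(ntip + nnode)] <- -Inf
    for (i in seq_len(nrow(post))) {
      p <- post[i, 1]; c <- post[i, 2]
      ages2[p] <- max(ages2[p], ages2[c] + min_duration, ages[p])
    }
    ages <- ages2
    ages[root] <- max(ages[root], oldest_tip + root_extension)
  } else {
    ages[root] <- max(ages[root], oldest_tip + root_extension)
    # preorder scan sharing zero branches with the closest positive ancestor
    pre <- ape::reorder.phylo(phy, "cladewise")$edge
    for (i in seq_len(nrow(pre))) {
      p <- pre[i, 1]; c <- pre[i, 2]
      if (ages[p] - ages[c] > 0) next
      # walk up past zero branches to the first positive one
      a <- p
      chain <- c(c, p)
      while (a != root && ages[parent_of[a]] - ages[a] <= 0) {
        a <- parent_of[a]
        chain <- c(chain, a)
      }
      if (a == root) next  # no positive duration above; leave as zero
      top <- parent_of[a]
      m <- length(chain)           # number of edges from `top` down to `c`
      span <- ages[top] - ages[c]
      if (span <= 0) next
      # chain is c, p, ..., a (youngest to oldest); respace equally
      for (k in seq_len(m - 1)) {
        node <- chain[k + 1]
        ages[node] <- ages[c] + span * k / m
      }
    }
  }

  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(phy$edge.length < -1e-9))
    stop("calibration produced a negative branch duration")
  phy$edge.length[phy$edge.length < 0] <- 0
  phy$root.time <- ages[root]
  structure(list(phy = phy,
                 node_age = ages,
                 ranges = tibble::tibble(name = phy$tip.label,
                                         fad = fad, lad = lad,
                                         tip_age = ages[seq_len(ntip)])),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat("<time_tree> ", length(x$phy$tip.label), " tips; root age ",
      format(x$phy$root.time, digits = 6), " Ma\n", sep = "")
  invisible(x)
}

#' Node ages of a calibrated tree
#' @param timetree a `time_tree`
#' @return tibble with `node` (ape id), `label` (tips only), `age` (Ma)
#' @export
node_ages <- function(timetree) {
  ntip <- length(timetree$phy$tip.label)
  tibble::tibble(node = seq_along(timetree$node_age),
                 label = c(timetree$phy$tip.label,
                           rep(NA_character_,
                               length(timetree$node_age) - ntip)),
                 age = timetree$node_age)
}

#' Per-branch temporal spans, including observed tip ranges
#'
#' One interval per branch, running from the parent node's age to the child
#' node's age; terminal branches extend to the tip's last appearance (LAD),
#' so each tip's observed range is part of its lineage's span. These spans
#' are what the ghost-lineage diversity count overlaps against time bins.
#'
#' @param timetree a `time_tree`
#' @return tibble: `node`, `label` (tips only), `start` (older bound, Ma),
#'   `end` (younger bound, Ma), `is_tip`
#' @export
lineage_intervals <- function(timetree) {
  phy <- timetree$phy
  ntip <- length(phy$tip.label)
  ages <- timetree$node_age
  child <- phy$edge[, 2]
  start <- ages[phy$edge[, 1]]
  end <- ages[child]
  is_tip <- child <= ntip
  tip_rows <- match(child[is_tip], seq_len(ntip))
  end[is_tip] <- pmin(end[is_tip], timetree$ranges$lad[tip_rows])
  start[is_tip] <- pmax(start[is_tip], timetree$ranges$fad[tip_rows])
  tibble::tibble(node = child,
                 label = ifelse(is_tip, phy$tip.label[child], NA_character_),
                 start = start, end = end, is_tip = is_tip)
}
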