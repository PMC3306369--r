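# Phylogenetic diversity estimates: per-bin lineage counts combining observed
# taxon occurrences with the ghost lineages implied by the calibrated tree.
# Bins are half-open in time — closed at the older bound, open at the younger
# — so a lineage hitting a shared boundary is counted once.

# overlap of span [end, start] (ages, start >= end) with bin (younger, older]
span_overlaps_bin <- function(start, end, older, younger) {
  start > younger & end <= older
}

#' Phylogenetic diversity curve
#'
#' Counts, for each time bin, every lineage (branch) of the calibrated tree
#' whose temporal span overlaps the bin — a branch crossing a bin with no tip
#' in it is exactly the ghost-lineage contribution. The count is split into
#' taxa observed in the bin (observed range overlapping) and ghost-only
#' lineages. Taxa absent from the tree (`extra_taxa`) add one observed
#' lineage to every bin their range overlaps. At
#' `level = "species_expansion"`, an OTU's terminal interval is replaced by
#' its listed member species' ranges (for multispecific genera).
#'
#' @param timetree a `time_tree`
#' @param bins tibble of time bins (see [time_bins()])
#' @param extra_taxa optional taxon table of range-only additions
#' @param level `"otu"` (default) or `"species_expansion"`
#' @param expansions named list: OTU label -> tibble with `name`, `fad`,
#'   `lad` of member species (used by `"species_expansion"`)
#' @return a `diversity_curve` tibble: `bin`, `observed`, `ghost`, `total`
#' @export
phylogenetic_diversity <- function(timetree, bins, extra_taxa = NULL,
                                   level = c("otu", "species_expansion"),
                                   expansions = NULL) {
  level <- match.arg(level)
  iv <- lineage_intervals(timetree)
  if (level == "species_expansion" && length(expansions)) {
    names(expansions) <- normalise_label(names(expansions))
    keep <- !(iv$is_tip & iv$label %in% names(expansions))
    expanded <- purrr::map_dfr(intersect(names(expansions),
                                         iv$label[iv$is_tip]), function(otu) {
      sp <- expansions[[otu]]
      tibble::tibble(node = NA_integer_, label = normalise_label(sp$name),
                     start = sp$fad, end = sp$lad, is_tip = TRUE)
    })
    iv <- dplyr::bind_rows(iv[keep, ], expanded)
  }
  ranges <- timetree$ranges
  if (level == "species_expansion" && length(expansions)) {
    keep_r <- !(ranges$name %in% names(expansions))
    exp_r <- purrr::map_dfr(expansions, function(sp)
      tibble::tibble(name = normalise_label(sp$name), fad = sp$fad,
                     lad = sp$lad, tip_age = sp$fad))
    ranges <- dplyr::bind_rows(ranges[keep_r, ], exp_r)
  }
  tree_span <- c(max(iv$start), min(iv$end))
  rows <- purrr::pmap_dfr(bins, function(label, older_bound, younger_bound) {
    if (older_bound < tree_span[2] || younger_bound > tree_span[1])
      warning("bin '", label, "' lies outside the tree's temporal span")
    total <- sum(span_overlaps_bin(iv$start, iv$end,
                                   older_bound, younger_bound))
    observed <- sum(span_overlaps_bin(ranges$fad, ranges$lad,
                                      older_bound, younger_bound))
    if (!is.null(extra_taxa) && nrow(extra_taxa)) {
      add <- sum(span_overlaps_bin(extra_taxa$fad, extra_taxa$lad,
                                   older_bound, younger_bound))
      total <- total + add
      observed <- observed + add
    }
    tibble::tibble(bin = label, observed = observed,
                   ghost = total - observed, total = total)
  })
  class(rows) <- c("diversity_curve", class(rows))
  rows
}
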