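# Simple morphometric summaries: neck:trunk length ratios as a body-plan
# proxy, per-bin size ranges, and isometric mass-scaling factors.

#' Neck:trunk proportion table
#'
#' Computes the neck:trunk length ratio for every taxon with both
#' measurements; records missing either length are skipped (reported in the
#' `"skipped"` attribute). An optional logical `underestimate` column is
#' carried through as a flag (e.g. a neck missing some anterior cervicals),
#' propagating to plots but never altering the numbers.
#'
#' @param records taxon table with `trunk_length` and `neck_length` (mm)
#' @return tibble: `taxon`, `trunk_length`, `neck_length`, `ratio`,
#'   `bin_label`, `underestimate`
#' @export
proportion_table <- function(records) {
  has <- !is.na(records$trunk_length) & !is.na(records$neck_length)
  kept <- records[has, ]
  if (any(kept$trunk_length <= 0 | kept$neck_length <= 0))
    stop("lengths must be positive")
  out <- tibble::tibble(
    taxon = kept$name,
    trunk_length = kept$trunk_length,
    neck_length = kept$neck_length,
    ratio = kept$neck_length / kept$trunk_length,
    bin_label = if ("bin_label" %in% names(kept)) kept$bin_label
                else NA_character_,
    underestimate = if ("underestimate" %in% names(kept))
      isTRUE_vec(kept$underestimate) else FALSE)
  attr(out, "skipped") <- records$name[!has]
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Per-bin minimum and maximum of a measurement
#'
#' @param values tibble with a `value` column and a `bin_label` column (e.g.
#'   trunk lengths labelled by interval)
#' @param bins optional bin table fixing the output order
#' @return tibble: `bin`, `n`, `min`, `max` (bins with no values omitted)
#' @export
range_by_bin <- function(values, bins = NULL) {
  v <- values[!is.na(values$value) & !is.na(values$bin_label), ]
  labels <- if (!is.null(bins)) bins$label else unique(v$bin_label)
  rows <- purrr::map_dfr(labels, function(b) {
    x <- v$value[v$bin_label == b]
    if (!length(x)) return(NULL)
    tibble::tibble(bin = b, n = length(x), min = min(x), max = max(x))
  })
  rows
}

#' Isometric mass-scaling factor
#'
#' Under isometry, mass scales with the cube of linear size: a body twice as
#' long implies an eight-fold mass increase. The factor is `(b / a)^3`.
#'
#' @param length_a,length_b linear measurements (same units, positive)
#' @return dimensionless mass factor
#' @export
isometric_mass_factor <- function(length_a, length_b) {
  if (any(c(length_a, length_b) <= 0)) stop("lengths must be positive")
  (length_b / length_a)^3
}
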