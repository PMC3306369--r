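# Reading and writing the standard formats the pipeline touches: NEXUS
# character matrices, newick trees, delimited taxon tables, JSON time bins.
# Parsing of the NEXUS data block and of newick is delegated to ape; this
# module adds the state-set semantics (missing vs inapplicable vs polymorphic)
# and validation.

#' Normalise a taxon label
#'
#' Labels are matched across files after trimming outer whitespace and
#' collapsing internal runs of spaces/underscores to a single underscore
#' (NEXUS and newick dialects differ on space encoding).
#' @param x character vector of labels
#' @return normalised labels
#' @export
normalise_label <- function(x) {
  x <- gsub("^[ \t]+|[ \t]+$", "", x)
  gsub("[ _]+", "_", x)
}

as_input_file <- function(text_or_path) {
  if (length(text_or_path) > 1 || grepl("\n", text_or_path)) {
    f <- tempfile()
    writeLines(paste(text_or_path, collapse = "\n"), f)
    f
  } else text_or_path
}

#' Read a NEXUS character matrix
#'
#' Parses a DATA/CHARACTERS block into a [char_matrix]. `?` maps to missing;
#' the gap symbol `-` (inapplicable) is treated as missing by default, or as
#' an extra distinct state; polymorphisms `{01}`/`(01)` become multi-element
#' state sets.
#'
#' @param file path to a NEXUS file, or the document text itself
#' @param inapplicable `"missing"` (default) or `"state"`: how to treat `-`
#' @param ordered optional logical vector of per-character additive flags
#' @return a [char_matrix]
#' @export
read_character_matrix <- function(file, inapplicable = c("missing", "state"),
                                  ordered = NULL) {
  inapplicable <- match.arg(inapplicable)
  path <- as_input_file(file)
  dat <- ape::read.nexus.data(path)
  lens <- lengths(dat)
  if (length(unique(lens)) > 1) {
    bad <- names(dat)[which(lens != stats::median(lens))[1]]
    stop("row length mismatch for taxon '", bad, "' (", lens[[bad]],
         " cells, expected ", stats::median(lens), ")")
  }
  taxa <- normalise_label(names(dat))
  toks <- do.call(rbind, lapply(dat, function(r) unlist(r)))
  gap_state <- NULL
  if (inapplicable == "state" && any(toks == "-")) {
    all_states <- suppressWarnings(as.integer(unlist(
      strsplit(toks[!toks %in% c("?", "-")], "/"))))
    gap_state <- max(all_states, 0L, na.rm = TRUE) + 1L
  }
  masks <- matrix(NA_integer_, nrow(toks), ncol(toks))
  for (i in seq_len(nrow(toks))) for (j in seq_len(ncol(toks))) {
    tok <- toks[i, j]
    masks[i, j] <- if (tok == "-") {
      if (is.null(gap_state)) NA_integer_ else states_to_mask(gap_state)
    } else token_to_mask(tok)
  }
  new_char_matrix(masks, taxa, ordered)
}

#' Write a character matrix as NEXUS
#'
#' Emits a DATA block readable by [read_character_matrix()]; missing cells as
#' `?`, polymorphic cells as `{..}`. Output is deterministic, so a
#' read-then-write round trip is byte stable.
#'
#' @param x a [char_matrix]
#' @param file optional path; if `NULL` the document is returned as a string
#' @return the NEXUS text, invisibly when written to a file
#' @export
write_character_matrix <- function(x, file = NULL) {
  ntax <- nrow(x$masks)
  nchar_ <- ncol(x$masks)
  symbols <- paste(seq_len(max(cm_n_states(x), 1L)) - 1L, collapse = "")
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", ntax, nchar_),
             sprintf("FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"%s\";",
                     symbols),
             "MATRIX")
  if (ntax > 0) {
    labs <- gsub(" ", "_", cm_taxa(x))
    width <- max(nchar(labs))
    for (i in seq_len(ntax)) {
      row <- paste(vapply(x$masks[i, ], mask_to_token, ""), collapse = "")
      lines <- c(lines, sprintf("%-*s %s", width, labs[i], row))
    }
  }
  lines <- c(lines, ";", "END;", "")
  text <- paste(lines, collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(text, file, sep = "")
  invisible(text)
}

#' Read a taxon table
#'
#' A delimited table of stratigraphic ranges and body measurements: columns
#' `name`, `fad`, `lad` (ages in Ma, larger = older), and optionally
#' `trunk_length`, `neck_length` (mm) and `bin_label`. Absent measurements
#' stay `NA`, never zero.
#'
#' @param file path to a CSV file, or its text
#' @return a tibble with one row per taxon
#' @export
read_taxon_table <- function(file) {
  path <- as_input_file(file)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "fad", "lad")
  if (!all(req %in% names(df)))
    stop("taxon table must have columns: ", paste(req, collapse = ", "))
  for (col in c("fad", "lad", "trunk_length", "neck_length")) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    if (is.character(v)) {
      v[v == ""] <- NA
      suppressWarnings(num <- as.numeric(v))
      if (any(!is.na(v) & is.na(num)))
        stop("non-numeric value in column '", col, "': ",
             v[!is.na(v) & is.na(num)][1])
      df[[col]] <- num
    }
  }
  if (!"trunk_length" %in% names(df)) df$trunk_length <- rep(NA_real_, nrow(df))
  if (!"neck_length" %in% names(df)) df$neck_length <- rep(NA_real_, nrow(df))
  if (!"bin_label" %in% names(df)) df$bin_label <- rep(NA_character_, nrow(df))
  df$bin_label[!is.na(df$bin_label) & df$bin_label == ""] <- NA_character_
  bad <- which(!is.na(df$fad) & !is.na(df$lad) & df$fad < df$lad)
  if (length(bad))
    stop("fad < lad (ages must decrease toward the present) for taxon '",
         df$name[bad[1]], "'")
  for (col in c("trunk_length", "neck_length")) {
    neg <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(neg))
      stop("non-positive ", col, " for taxon '", df$name[neg[1]], "'")
  }
  df$name <- normalise_label(df$name)
  tibble::as_tibble(df[, c("name", "fad", "lad", "trunk_length",
                           "neck_length", "bin_label")])
}

#' Write a taxon table
#' @param records a tibble as returned by [read_taxon_table()]
#' @param file output CSV path
#' @export
write_taxon_table <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Define time bins
#'
#' @param label bin labels
#' @param older_bound,younger_bound bin limits in Ma (older > younger)
#' @return a tibble of bins, validated to be non-overlapping
#' @export
time_bins <- function(label, older_bound, younger_bound) {
  bins <- tibble::tibble(label = as.character(label),
                         older_bound = as.numeric(older_bound),
                         younger_bound = as.numeric(younger_bound))
  if (any(bins$older_bound <= bins$younger_bound))
    stop("each bin must have older_bound > younger_bound")
  o <- order(bins$older_bound, decreasing = TRUE)
  b <- bins[o, ]
  if (nrow(b) > 1 && any(b$older_bound[-1] > b$younger_bound[-nrow(b)] &
                         b$older_bound[-1] < b$older_bound[-nrow(b)]))
    stop("time bins overlap")
  bins
}

#' Read a JSON time-bin definition
#' @param file path to a JSON array of objects with fields `label`,
#'   `older_bound`, `younger_bound`, or the JSON text
#' @return a tibble of bins
#' @export
read_time_bins <- function(file) {
  df <- jsonlite::fromJSON(file)
  time_bins(df$label, df$older_bound, df$younger_bound)
}

#' Write time bins as JSON
#' @param bins a tibble of bins
#' @param file output path
#' @export
write_time_bins <- function(bins, file) {
  jsonlite::write_json(bins, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a newick tree
#' @param file path to a newick file or the newick string
#' @return an `ape::phylo` tree, tip labels normalised
#' @export
read_tree <- function(file) {
  text <- if (grepl("\\(", file)) file else paste(readLines(file), collapse = "")
  if (lengths(regmatches(text, gregexpr("\\(", text))) !=
      lengths(regmatches(text, gregexpr("\\)", text))))
    stop("unbalanced parentheses in newick input")
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse newick input")
  phy$tip.label <- normalise_label(phy$tip.label)
  phy
}

#' Write a tree as newick
#' @param tree an `ape::phylo`
#' @param file optional output path; if `NULL` the newick string is returned
#' @return the newick string, invisibly when written to a file
#' @export
write_tree <- function(tree, file = NULL) {
  text <- ape::write.tree(tree)
  if (is.null(file)) return(text)
  writeLines(text, file)
  invisible(text)
}
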