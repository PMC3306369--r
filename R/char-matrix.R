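#' Discrete character matrix
#'
#' A `char_matrix` holds a taxa-by-characters matrix of discrete states, the
#' substrate for parsimony and disparity analyses. Each cell is a *set* of
#' non-negative integer state codes: a singleton for an ordinary scoring, a
#' multi-element set for a polymorphic cell, and missing ("?") is stored as
#' `NA` and kept distinguishable from every observed state. Internally cells
#' are bit masks (bit *s* set means state *s* present), which keeps parsimony
#' scoring fast.
#'
#' @param cells a character matrix (taxa in rows) of tokens such as `"0"`,
#'   `"?"`, `"01"`/`"0/1"` (polymorphism), or a list-matrix of integer
#'   vectors; row names are taxon labels.
#' @param taxa taxon labels; defaults to `rownames(cells)`.
#' @param ordered logical vector, one per character: treat as additive
#'   (ordered) with linear step costs. Default all unordered.
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(cells, taxa = rownames(cells), ordered = NULL) {
  if (is.null(taxa)) stop("taxon labels required (rownames or `taxa`)")
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  if (is.list(cells)) {
    masks <- matrix(NA_integer_, nrow(cells), ncol(cells))
    for (i in seq_len(nrow(cells))) for (j in seq_len(ncol(cells)))
      masks[i, j] <- states_to_mask(cells[[i, j]])
  } else {
    masks <- apply(unname(cells), c(1, 2), token_to_mask)
  }
  new_char_matrix(masks, taxa, ordered)
}

new_char_matrix <- function(masks, taxa, ordered = NULL) {
  storage.mode(masks) <- "integer"
  rownames(masks) <- taxa
  nchar_ <- ncol(masks)
  if (is.null(ordered)) ordered <- rep(FALSE, nchar_)
  stopifnot(length(ordered) == nchar_)
  structure(list(masks = masks, ordered = as.logical(ordered)),
            class = "char_matrix")
}

states_to_mask <- function(states) {
  if (length(states) == 0 || all(is.na(states))) return(NA_integer_)
  as.integer(sum(bitwShiftL(1L, unique(as.integer(states)))))
}

token_to_mask <- function(tok) {
  tok <- gsub("[{}() ]", "", as.character(tok))
  if (is.na(tok) || tok %in% c("?", "")) return(NA_integer_)
  states <- if (grepl("/", tok)) strsplit(tok, "/")[[1]] else strsplit(tok, "")[[1]]
  suppressWarnings(st <- as.integer(states))
  if (anyNA(st)) stop("unrecognised state token: '", tok, "'")
  states_to_mask(st)
}

mask_to_states <- function(mask) {
  if (is.na(mask)) return(integer(0))
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) > 0L) - 1L
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", nrow(x$masks), " taxa x ", ncol(x$masks),
      " characters; ", cm_missing_count(x), " missing cells\n", sep = "")
  invisible(x)
}

#' Taxa of a character matrix
#' @param x a `char_matrix`
#' @return character vector of taxon labels
#' @export
cm_taxa <- function(x) rownames(x$masks)

#' Number of characters
#' @param x a `char_matrix`
#' @return integer count
#' @export
cm_n_characters <- function(x) ncol(x$masks)

#' Count of missing ("?") cells
#' @param x a `char_matrix`
#' @return integer count
#' @export
cm_missing_count <- function(x) sum(is.na(x$masks))

#' Subset a character matrix by taxa and/or characters
#' @param x a `char_matrix`
#' @param i taxon labels or indices
#' @param j character indices
#' @param ... ignored
#' @export
`[.char_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$masks))
  if (missing(j)) j <- seq_len(ncol(x$masks))
  new_char_matrix(x$masks[i, j, drop = FALSE], rownames(x$masks[i, , drop = FALSE]),
                  x$ordered[j])
}

#' States observed in one character
#'
#' The state universe of a character: every state code occurring in a scored
#' cell (polymorphic states included). Missing cells contribute nothing.
#' @param x a `char_matrix`
#' @param j character index
#' @return sorted integer vector of state codes
#' @export
cm_observed_states <- function(x, j) {
  m <- x$masks[, j]
  m <- m[!is.na(m)]
  if (!length(m)) return(integer(0))
  sort(unique(unlist(lapply(m, mask_to_states))))
}

# global state universe size (states 0 .. n-1)
cm_n_states <- function(x) {
  m <- x$masks[!is.na(x$masks)]
  if (!length(m)) return(1L)
  mx <- max(unlist(lapply(m, function(z) max(mask_to_states(z)))))
  mx + 1L
}

# cell as a string token for writing ("?" / "0" / "{01}")
mask_to_token <- function(mask) {
  if (is.na(mask)) return("?")
  st <- mask_to_states(mask)
  if (length(st) == 1) as.character(st) else paste0("{", paste(st, collapse = ""), "}")
}
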