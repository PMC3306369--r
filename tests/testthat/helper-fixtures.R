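# Fixture builders shared across the suite. All data are generated in code.

# char_matrix from row strings like "01?{01}2"
cm_from_strings <- function(rows) {
  taxa <- names(rows)
  toks <- lapply(rows, function(r) {
    m <- gregexpr("\\{[0-9]+\\}|\\([0-9]+\\)|[0-9?\\-]", r)[[1]]
    regmatches(r, list(m))[[1]]
  })
  stopifnot(length(unique(lengths(toks))) == 1)
  cells <- do.call(rbind, toks)
  rownames(cells) <- taxa
  char_matrix(cells)
}

# a matrix with one perfectly hierarchical (pectinate) signal and no conflict
perfect_matrix <- function(n_taxa = 7) {
  taxa <- paste0("t", seq_len(n_taxa))
  nchar_ <- n_taxa - 3
  cells <- matrix("0", n_taxa, nchar_, dimnames = list(taxa, NULL))
  for (j in seq_len(nchar_)) cells[(j + 2):n_taxa, j] <- "1"
  char_matrix(cells)
}

sim_bundle <- function(seed, n_taxa = 7, n_characters = 10,
                       missing_fraction = 0.2, char_rate = 0.03, ...) {
  cfg <- sim_config(seed = seed, n_taxa = n_taxa,
                    n_characters = n_characters,
                    missing_fraction = missing_fraction,
                    char_rate = char_rate, ...)
  sim <- simulate_tree_with_ranges(cfg)
  list(cfg = cfg, tree = sim$tree, records = sim$records,
       matrix = simulate_matrix(sim$tree, cfg))
}

# independent per-cell loop oracle for pairwise dissimilarity
dissim_cell_oracle <- function(mat, a, b) {
  ncmp <- 0L; ndiff <- 0L
  for (j in seq_len(cm_n_characters(mat))) {
    sa <- paleomacro:::mask_to_states(mat$masks[a, j])
    sb <- paleomacro:::mask_to_states(mat$masks[b, j])
    if (!length(sa) || !length(sb)) next
    ncmp <- ncmp + 1L
    if (!length(intersect(sa, sb))) ndiff <- ndiff + 1L
  }
  if (ncmp == 0) NA_real_ else ndiff / ncmp
}

# direct multivariate-normal log-density (independent of the GLS machinery)
mvn_logdens <- function(y, mu, V) {
  n <- length(y)
  -0.5 * (n * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            drop(t(y - mu) %*% solve(V) %*% (y - mu)))
}
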