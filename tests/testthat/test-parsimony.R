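test_that("tree length handles invariant, clean, missing and polymorphic characters", {
  m <- cm_from_strings(c(A = "00", B = "00", C = "01", D = "01"))
  tr <- read_tree("((A,B),(C,D));")
  expect_equal(fitch_length(tr, m, per_character = TRUE), c(0, 1))

  # missing never adds steps on its own; polymorphism uses the state set
  m2 <- cm_from_strings(c(A = "0?", B = "0{01}", C = "11", D = "10"))
  expect_equal(fitch_length(tr, m2, per_character = TRUE), c(1, 1))
})

test_that("tree length agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  b <- sim_bundle(seed = 17, n_taxa = 10, n_characters = 40,
                  missing_fraction = 0.25)
  chars <- matrix("?", 10, 40)
  for (i in 1:10) for (j in 1:40) {
    s <- paleomacro:::mask_to_states(b$matrix$masks[i, j])
    if (length(s) == 1) chars[i, j] <- as.character(s)
  }
  rownames(chars) <- cm_taxa(b$matrix)
  pd <- phangorn::phyDat(chars, type = "USER", levels = c("0", "1", "2"),
                         ambiguity = "?")
  for (s in 1:5) {
    set.seed(s)
    rt <- ape::rtree(10)
    rt$tip.label <- sample(cm_taxa(b$matrix))
    expect_equal(fitch_length(rt, b$matrix),
                 as.numeric(phangorn::parsimony(rt, pd, method = "sankoff")))
  }
})

test_that("tree length is invariant under re-rooting", {
  b <- sim_bundle(seed = 3, n_taxa = 9, n_characters = 30)
  set.seed(11)
  tr <- ape::rtree(9)
  tr$tip.label <- cm_taxa(b$matrix)
  len <- fitch_length(tr, b$matrix)
  for (tip in tr$tip.label[1:4]) {
    rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_length(rerooted, b$matrix), len)
  }
})

test_that("character step bounds follow state frequencies", {
  m <- cm_from_strings(c(A = "0", B = "0", C = "1", D = "1", E = "1"))
  expect_equal(char_min_steps(m, 1), 1L)
  expect_equal(char_max_steps(m, 1), 2L)

  inv <- cm_from_strings(c(A = "1", B = "1", C = "1"))
  expect_equal(char_min_steps(inv, 1), 0L)
  expect_equal(char_max_steps(inv, 1), 0L)

  allmiss <- cm_from_strings(c(A = "?", B = "?", C = "?"))
  expect_equal(char_min_steps(allmiss, 1), 0L)
  expect_equal(char_max_steps(allmiss, 1), 0L)
})

test_that("max steps equals the star-tree length for random characters", {
  # the star tree is the worst binary-resolvable case for a single character
  for (s in 1:10) {
    set.seed(400 + s)
    states <- sample(c("0", "1", "2", "?"), 10, replace = TRUE,
                     prob = c(.3, .3, .2, .2))
    if (length(unique(states[states != "?"])) < 2) next
    names(states) <- paste0("t", 1:10)
    m <- cm_from_strings(states)
    star <- ape::read.tree(text = paste0(
      "(", paste(names(states), collapse = ","), ");"))
    expect_equal(char_max_steps(m, 1), as.integer(fitch_length(star, m)))
  }
})

test_that("ensemble indices are exact on a homoplasy-free matrix and hand-worked toys", {
  m <- perfect_matrix(6)
  tr <- read_tree("(t1,(t2,(t3,(t4,(t5,t6)))));")
  st <- ensemble_indices(tr, m)
  expect_equal(st$ci, 1)
  expect_equal(st$ri, 1)

  # one convergent character: t3 and t6 share state 1 but are not sisters,
  # so it needs 2 steps on ((t1,(t2,t3)),(t4,(t5,t6))) (min 1, max 2); the
  # clean second character ((t4,t5,t6) = 1) needs 1 step (min 1, max 3).
  toy <- cm_from_strings(c(t1 = "00", t2 = "00", t3 = "10",
                           t4 = "01", t5 = "01", t6 = "11"))
  tr2 <- read_tree("((t1,(t2,t3)),(t4,(t5,t6)));")
  st2 <- ensemble_indices(tr2, toy)
  expect_equal(st2$length, 3)
  expect_equal(st2$ci, 2 / 3)
  expect_equal(st2$ri, (5 - 3) / (5 - 2))
  expect_equal(st2$rc, st2$ci * st2$ri)
})

test_that("RC = CI x RI and RI is absent without informative variation", {
  b <- sim_bundle(seed = 21, n_taxa = 8, n_characters = 30)
  set.seed(2)
  tr <- ape::rtree(8)
  tr$tip.label <- cm_taxa(b$matrix)
  st <- ensemble_indices(tr, b$matrix)
  expect_equal(st$rc, st$ci * st$ri, tolerance = 1e-12)

  inv <- cm_from_strings(c(A = "00", B = "00", C = "00", D = "00"))
  st0 <- ensemble_indices(read_tree("((A,B),(C,D));"), inv)
  expect_true(is.na(st0$ri))
})

test_that("heuristic search recovers a perfect hierarchical signal exactly", {
  m <- perfect_matrix(8)
  hs <- heuristic_search(m, n_replicates = 3, seed = 1)
  expect_equal(hs$length, cm_n_characters(m))  # one step per clean character
  expect_equal(length(hs$trees), 1L)
  true_tree <- read_tree("(t1,(t2,(t3,(t4,(t5,(t6,(t7,t8)))))));")
  labels <- sort(cm_taxa(m))
  expect_identical(
    paleomacro:::ut_hash(paleomacro:::ut_from_phylo(hs$trees[[1]], labels)),
    paleomacro:::ut_hash(paleomacro:::ut_from_phylo(true_tree, labels)))
})

test_that("heuristic search with a fixed seed is reproducible", {
  b <- sim_bundle(seed = 12)
  h1 <- heuristic_search(b$matrix, n_replicates = 3, seed = 4)
  h2 <- heuristic_search(b$matrix, n_replicates = 3, seed = 4)
  expect_identical(h1$length, h2$length)
  expect_identical(lapply(h1$trees, write_tree), lapply(h2$trees, write_tree))
})

test_that("strict consensus keeps shared clades and collapses conflicts", {
  t1 <- read_tree("((A,B),(C,(D,E)));")
  expect_identical(write_tree(strict_consensus(list(t1))), write_tree(t1))

  t2 <- read_tree("((A,B),(D,(C,E)));")
  cons <- strict_consensus(list(t1, t2))
  labels <- sort(t1$tip.label)
  sp <- paleomacro:::ut_splits(paleomacro:::ut_from_phylo(cons, labels))
  # only the AB | CDE split survives
  expect_equal(length(sp), 1L)
  expect_error(strict_consensus(list()), "empty")
})

test_that("consensus of all topologies is the star tree", {
  tops <- paleomacro:::all_topologies_ut(6, paste0("t", 1:6))
  expect_equal(length(tops), 105L)
  trees <- lapply(tops, paleomacro:::ut_to_phylo)
  cons <- strict_consensus(trees)
  expect_equal(cons$Nnode, 1L)
})

test_that("pruning a taxon reattaches its sibling and merges duplicates", {
  t1 <- read_tree("((A,B),(C,(D,E)));")
  p <- prune_taxon(list(t1), "E")
  expect_identical(
    paleomacro:::ut_hash(paleomacro:::ut_from_phylo(p[[1]], c("A", "B", "C", "D"))),
    paleomacro:::ut_hash(paleomacro:::ut_from_phylo(
      read_tree("((A,B),(C,D));"), c("A", "B", "C", "D"))))

  # trees differing only in E's position merge after pruning
  t2 <- read_tree("((A,B),((C,E),D));")
  expect_equal(length(prune_taxon(list(t1, t2), "E")), 1L)
  expect_error(prune_taxon(list(t1), "Z"), "not present")
})

test_that("pruned-set consensus is at least as resolved as consensus-then-prune", {
  for (s in 1:5) {
    set.seed(500 + s)
    trees <- lapply(1:4, function(i) ape::rtree(8))
    for (i in seq_along(trees)) trees[[i]]$tip.label <- paste0("t", 1:8)
    tax <- "t3"
    a <- strict_consensus(prune_taxon(trees, tax))
    b <- prune_taxon(list(strict_consensus(trees)), tax)[[1]]
    labels <- sort(a$tip.label)
    sa <- paleomacro:::ut_splits(paleomacro:::ut_from_phylo(a, labels))
    sb <- paleomacro:::ut_splits(paleomacro:::ut_from_phylo(b, labels))
    expect_true(all(sb %in% sa))
  }
})

test_that("decay index is forced by uncontradicted characters", {
  # 3 identical characters support (C,D) and nothing else varies
  m <- cm_from_strings(c(A = "000", B = "000", C = "111",
                         D = "111", E = "000", F = "000"))
  expect_equal(decay_index(m, c("C", "D"), n_replicates = 3, seed = 1), 3L)
  expect_equal(decay_index(m, c("A", "B", "C", "D", "E")), Inf)
})

test_that("decay index matches exhaustive enumeration on 6-taxon matrices", {
  decay_oracle <- function(mat, ids) {
    ctx <- paleomacro:::cm_score_ctx(mat)
    tops <- paleomacro:::all_topologies_ut(length(ctx$taxa), ctx$taxa)
    lens <- vapply(tops, function(u) paleomacro:::score_ut(u, ctx), 0)
    has <- vapply(tops, function(u)
      paleomacro:::ut_contains_split(u, ids), TRUE)
    min(lens[!has]) - min(lens)
  }
  for (s in 1:5) {
    b <- sim_bundle(seed = 200 + s, n_taxa = 6, n_characters = 15,
                    missing_fraction = 0.1)
    hs <- heuristic_search(b$matrix, n_replicates = 3, seed = s)
    cons <- strict_consensus(hs$trees)
    if (cons$Nnode < 2) next
    clade <- ape::extract.clade(cons, length(cons$tip.label) + 2)$tip.label
    if (length(clade) < 2 || length(clade) > 4) next
    ids <- match(clade, cm_taxa(b$matrix))
    expect_equal(decay_index(b$matrix, clade, n_replicates = 4, seed = s,
                             best_length = hs$length),
                 decay_oracle(b$matrix, ids))
  }
})
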