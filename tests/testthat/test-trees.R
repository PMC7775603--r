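test_that("UPGMA handles the textbook cases exactly", {
  d2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))

  d3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(ape::write.tree(t3), "((A:0.1,B:0.1):0.2,C:0.3);")

  expect_error(upgma(matrix(0, 1, 1, dimnames = list("A", "A"))), "2 taxa")
  dna <- d3; dna["A", "C"] <- dna["C", "A"] <- NA
  expect_error(upgma(dna), "undefined")
})

test_that("UPGMA matches an exhaustive average-linkage oracle", {
  for (seed in 1:10) {
    n <- sample(4:7, 1)
    v <- random_distance_matrix(n, seed = 1000 + seed)
    tree <- upgma(v)
    oracle <- oracle_average_linkage(v)
    expect_setequal(tree_clades(tree), oracle$clades)
    expect_equal(sort(tree_heights(tree)), sort(oracle$heights),
                 tolerance = 1e-9)
    expect_true(ape::is.ultrametric(tree, tol = 1e-9))
  }
})

test_that("UPGMA exactly recovers random ultrametric trees from path metrics", {
  for (seed in 1:10) {
    set.seed(seed)
    true <- ape::rcoal(8)
    D <- cophenetic(true)
    rebuilt <- upgma(D)
    rf <- robinson_foulds(rebuilt, true)
    expect_equal(rf$count, 0)
    # heights of the rebuilt tree match the coalescent node times
    expect_equal(sort(tree_heights(rebuilt)),
                 sort(tree_heights(true)), tolerance = 1e-9)
  }
})

test_that("UPGMA is invariant to taxon input order and ties break by label", {
  v <- random_distance_matrix(6, seed = 77)
  t1 <- upgma(v)
  set.seed(3)
  perm <- sample(6)
  t2 <- upgma(v[perm, perm])
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  # perfect tie: four equidistant pairs; lexicographically smallest merges first
  tie <- matrix(0.5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(tie) <- 0
  expect_equal(ape::write.tree(upgma(tie)),
               ape::write.tree(upgma(tie[4:1, 4:1])))
})

test_that("clade recovery is exact-membership", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(clade_recovered(tr, c("A", "B")))
  expect_false(clade_recovered(tr, c("B", "C")))
  tr2 <- ape::read.tree(text = "((A,(B,C)),D);")
  expect_true(clade_recovered(tr2, c("A", "B", "C")))
  expect_true(clade_recovered(tr2, "D"))
  expect_error(clade_recovered(tr, c("A", "Z")), "not in tree")
})

test_that("gold-standard scoring counts exact clades and excludes on request", {
  tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
  groups <- list(ab = c("A", "B"), abc = c("A", "B", "C"),
                 de = c("D", "E"), bc = c("B", "C"))
  sc <- gold_standard_score(tr, groups)
  expect_equal(sc$recovered, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(sc, "fraction"), 0.75)
  sc2 <- gold_standard_score(tr, groups, exclude = "bc")
  expect_equal(attr(sc2, "fraction"), 1)
  empty <- gold_standard_score(tr, list())
  expect_equal(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "fraction")))
})

test_that("bootstrap support: perfect signal, determinism, enumeration", {
  # every column splits {A,B} vs {C,D}: both clades certain
  x <- matrix(rep(c("+", "+", "-", "-"), 6), 4, 6,
              dimnames = list(LETTERS[1:4], paste0("p", 1:6)))
  m <- parameter_matrix(x)
  bt <- bootstrap_upgma(m, "hamming", n_reps = 25, seed = 1)
  expect_true(all(bt$support == 100))
  expect_equal(bt$n_discarded, 0L)

  m2 <- random_binary_matrix(5, 8, seed = 12)
  b1 <- bootstrap_upgma(m2, "hamming", n_reps = 50, seed = 9)
  b2 <- bootstrap_upgma(m2, "hamming", n_reps = 50, seed = 9)
  expect_identical(b1$support, b2$support)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))

  # exact enumeration oracle at P = 3: all 27 ordered column resamples
  m3 <- random_binary_matrix(5, 3, seed = 31)
  x3 <- unclass(m3)
  tree3 <- upgma(pcm_dist(m3, "hamming"))
  keys <- sapply(tree_clades(tree3), paste, collapse = "\r")
  exact <- setNames(numeric(length(keys)), keys)
  total <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    xb <- x3[, c(i, j, k)]
    colnames(xb) <- paste0("c", 1:3)
    Db <- pcm_dist(parameter_matrix(xb), "hamming", undefined = "flag")
    if (anyNA(Db$values)) next
    tb <- upgma(Db)
    total <- total + 1
    kb <- sapply(tree_clades(tb), paste, collapse = "\r")
    exact[keys %in% kb] <- exact[keys %in% kb] + 1
  }
  exact_pct <- 100 * exact / total
  bt3 <- bootstrap_upgma(m3, "hamming", n_reps = 2000, seed = 4)
  expect_true(all(abs(bt3$support - exact_pct) <= 5))
})

test_that("Robinson-Foulds counts bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(robinson_foulds(t1, t1)$count, 0)
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  rf <- robinson_foulds(t1, t2)
  expect_equal(rf$count, 2)
  expect_equal(rf$normalized, 1)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinson_foulds(t1, t3), "leaf sets")
})

test_that("Newick write/read round-trips lengths and support labels", {
  set.seed(5)
  for (i in 1:5) {
    tr <- ape::rcoal(7)
    tr$node.label <- sprintf("%d", sample(0:100, tr$Nnode))
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    back <- read_newick(path)
    expect_equal(robinson_foulds(back, tr)$count, 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
    expect_setequal(back$node.label, tr$node.label)
  }
})
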