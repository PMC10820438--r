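make_aln <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = names(seqs), sequence = unname(seqs))
}

test_that("pairwise distances implement p and Poisson models with pairwise deletion", {
  aln <- make_aln(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "AACCAAAAAA")
  D <- pairwise_distances(aln)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.2)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))

  Dp <- pairwise_distances(aln, model = "poisson")
  expect_equal(Dp["a", "c"], -log(0.8), tolerance = 1e-12)

  # gapped columns are deleted pairwise, not globally
  aln2 <- make_aln(a = "AA-AA", b = "AAC-A", c = "AACCA")
  D2 <- pairwise_distances(aln2)
  expect_equal(D2["a", "b"], 0)      # 3 comparable columns, all equal
  expect_equal(D2["b", "c"], 0)      # 4 comparable columns, all equal
  expect_equal(D2["a", "c"], 0.25)   # 4 comparable, 1 mismatch

  gappy <- make_aln(a = "A--", b = "-A-", c = "AAA")
  expect_error(pairwise_distances(gappy), "no ungapped columns")
})

test_that("nj_tree solves the 3-taxon three-point formulas", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (5 + 9 - 10) / 2, tolerance = 1e-9)
  expect_equal(bl[["B"]], (5 + 10 - 9) / 2, tolerance = 1e-9)
  expect_equal(bl[["C"]], (9 + 10 - 5) / 2, tolerance = 1e-9)
})

test_that("nj_tree recovers additive quartets and validates input", {
  true <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  D <- ape::cophenetic.phylo(true)
  tr <- nj_tree(D)
  expect_equal(tree_splits(tr), "C|D")
  # path lengths reproduce the additive matrix exactly
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)] - D)), 0,
               tolerance = 1e-9)

  Z <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  star <- nj_tree(Z)
  expect_equal(length(tree_splits(star)), 0)   # star tree: no internal edges
  expect_true(all(star$edge.length == 0))

  Dn <- D; Dn[1, 2] <- NaN; Dn[2, 1] <- NaN
  expect_error(nj_tree(Dn), "NA/NaN")
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  Da <- D; Da[1, 2] <- Da[1, 2] + 1
  expect_error(nj_tree(Da), "symmetric")
})

test_that("NJ recovers random additive trees and matches the ape cross-check", {
  withr::local_seed(12)
  for (i in 1:20) {
    k <- sample(4:10, 1)
    true <- ape::rtree(k)
    true$edge.length <- stats::runif(nrow(true$edge), 0.1, 1)
    D <- ape::cophenetic.phylo(true)
    mine <- nj_tree(D)
    expect_setequal(tree_splits(mine), oracle_splits(true))
    expect_setequal(tree_splits(mine), tree_splits(ape::nj(D)))
  }
})

test_that("bootstrap supports are 100 on conflict-free alignments and binary at n=1", {
  m <- generate_msa(n_taxa = 6, n_columns = 200, rate = 0, seed = 2)
  # rate 0: all rows identical
  expect_equal(length(unique(m$alignment$sequence)), 1)

  m2 <- generate_msa(n_taxa = 6, n_columns = 400, rate = 0.25, seed = 5)
  bt <- bootstrap_support(m2$alignment, n = 30, seed = 9)
  sup <- suppressWarnings(as.integer(bt$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))

  bt1 <- bootstrap_support(m2$alignment, n = 1, seed = 4)
  sup1 <- suppressWarnings(as.integer(bt1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0L, 100L)))
})

test_that("bootstrap supports match an independent re-implementation", {
  m <- generate_msa(n_taxa = 8, n_columns = 500, rate = 0.3, seed = 7)
  n_boot <- 40
  seed <- 13
  bt <- bootstrap_support(m$alignment, n = n_boot, seed = seed)

  # independent route: same resampling scheme, ape's NJ, oracle split keys
  mat <- do.call(rbind, strsplit(m$alignment$sequence, ""))
  rownames(mat) <- m$alignment$id
  pdist <- function(mm) {
    n <- nrow(mm)
    D <- matrix(0, n, n, dimnames = list(rownames(mm), rownames(mm)))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- mean(mm[i, ] != mm[j, ])
    }
    D
  }
  orig_keys <- oracle_splits(ape::nj(pdist(mat)))
  counts <- setNames(rep(0, length(orig_keys)), orig_keys)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      keys <- oracle_splits(ape::nj(pdist(mat[, idx])))
      counts[orig_keys %in% keys] <- counts[orig_keys %in% keys] + 1
    }
  })
  oracle_sup <- sort(round(100 * counts / n_boot))
  mine_sup <- sort(as.integer(bt$node.label[bt$node.label != ""]))
  expect_equal(length(mine_sup), length(oracle_sup))
  expect_true(all(abs(mine_sup - oracle_sup) <= 5))
})

test_that("bootstrap supports are invariant to taxon order permutation", {
  m <- generate_msa(n_taxa = 6, n_columns = 400, rate = 0.3, seed = 21)
  bt1 <- bootstrap_support(m$alignment, n = 25, seed = 3)
  perm <- m$alignment[c(4, 1, 6, 2, 5, 3), ]
  bt2 <- bootstrap_support(perm, n = 25, seed = 3)
  lab_sup <- function(bt) {
    keys <- hfbscan::tree_splits(bt)
    sup <- sort(as.integer(bt$node.label[bt$node.label != ""]))
    list(splits = sort(keys), support = sup)
  }
  expect_equal(lab_sup(bt1)$splits, lab_sup(bt2)$splits)
  expect_equal(lab_sup(bt1)$support, lab_sup(bt2)$support)
})

test_that("Newick output round-trips with branch lengths and integer supports", {
  m <- generate_msa(n_taxa = 6, n_columns = 300, rate = 0.3, seed = 7)
  bt <- bootstrap_support(m$alignment, n = 20, seed = 3)
  nwk <- write_newick(bt)
  expect_match(nwk, ";$")
  back <- ape::read.tree(text = nwk)
  expect_setequal(tree_splits(back), tree_splits(bt))
  sup <- back$node.label[back$node.label != ""]
  expect_true(all(grepl("^[0-9]+$", sup)))
  expect_true(all(as.integer(sup) >= 0 & as.integer(sup) <= 100))

  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bt, path)
  expect_setequal(tree_splits(ape::read.tree(path)), tree_splits(bt))
})
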