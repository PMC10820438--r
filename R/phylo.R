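#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but rows may contain the gap symbol `-` and must all
#' have equal length.
#'
#' @param path path to an aligned FASTA file.
#' @return a tibble with columns `id` and `sequence`.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) abort(sprintf("Alignment file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) abort(sprintf("Duplicate alignment id(s): %s", paste(dup, collapse = ", ")))
  aln <- tibble(id = ids, sequence = toupper(unname(as.character(set))))
  validate_alignment(aln)
  aln
}

validate_alignment <- function(aln) {
  stopifnot(all(c("id", "sequence") %in% names(aln)))
  if (nrow(aln) < 3) abort("An alignment needs at least 3 taxa.")
  lens <- nchar(aln$sequence)
  if (length(unique(lens)) != 1) abort("All aligned rows must have equal length.")
  invisible(aln)
}

aln_matrix <- function(aln) {
  validate_alignment(aln)
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  rownames(m) <- aln$id
  m
}

dist_from_matrix <- function(mat, model = c("p", "poisson")) {
  model <- match.arg(model)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        abort(sprintf(
          "Taxa '%s' and '%s' share no ungapped columns.",
          rownames(mat)[i], rownames(mat)[j]
        ))
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      d <- if (model == "poisson") {
        if (p >= 1) abort("Poisson correction undefined at p = 1.") else -log(1 - p)
      } else {
        p
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Pairwise distances from a protein alignment
#'
#' p-distance (mismatches over compared columns) or its Poisson correction
#' -ln(1 - p), with pairwise deletion of gapped columns: each pair is
#' compared over the columns where neither row has a gap.
#'
#' @param aln alignment tibble with columns `id` and `sequence`.
#' @param model `"p"` (default) or `"poisson"`.
#' @return a symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pairwise_distances <- function(aln, model = c("p", "poisson")) {
  dist_from_matrix(aln_matrix(aln), match.arg(model))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion. Q-matrix ties are broken by
#' the lowest (row, column) index pair so trees are deterministic; negative
#' branch-length estimates are clamped to zero; internal edges of exactly
#' zero length are collapsed (an all-zero matrix therefore yields a star
#' tree). For an additive matrix, path lengths through the tree reproduce
#' the input distances exactly.
#'
#' @param D symmetric non-negative distance matrix with at least 3 taxa;
#'   dimnames are used as tip labels.
#' @return an unrooted `phylo` tree (see \pkg{ape}).
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("`D` must be a square matrix.")
  if (anyNA(D) || any(!is.finite(D))) abort("`D` contains NA/NaN/Inf values.")
  if (any(abs(D - t(D)) > 1e-12)) abort("`D` must be symmetric.")
  if (any(D < 0)) abort("`D` must be non-negative.")
  n <- nrow(D)
  if (n < 3) abort("Neighbor-joining needs at least 3 taxa.")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  # Each active node carries a growing Newick fragment.
  frag <- labels
  d <- D
  bl <- function(x) format(max(x, 0), digits = 12, scientific = FALSE)

  while (length(frag) > 3) {
    m <- length(frag)
    r <- rowSums(d)
    q_best <- Inf
    pair <- c(1L, 2L)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        if (q < q_best - 1e-12) {
          q_best <- q
          pair <- c(i, j)
        }
      }
    }
    i <- pair[1]; j <- pair[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(vi), frag[j], bl(vj))
    d_new <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), pair)
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], d_new[keep]),
                c(d_new[keep], 0))
    frag <- c(frag[keep], new_frag)
    d <- d2
  }
  # Three-point formulas close the final trifurcation.
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf(
    "(%s:%s,%s:%s,%s:%s);",
    frag[1], bl(v1), frag[2], bl(v2), frag[3], bl(v3)
  )
  tree <- ape::read.tree(text = nwk)
  ape::di2multi(tree, tol = 1e-12)
}

#' Internal bipartitions of an unrooted tree
#'
#' Canonical keys for the non-trivial splits; each split is represented by
#' the sorted tip labels on the side not containing the alphabetically first
#' taxon, joined with `|`.
#'
#' @param tree a `phylo` object.
#' @return character vector of split keys (may be empty for a star tree).
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  ref <- sort(labs)[1]
  keys <- character(0)
  for (part in pp) {
    side <- labs[part]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `n` times, rebuilds the NJ
#' tree for each replicate, and scores every internal edge of the original
#' tree by the percentage of replicates containing the same bipartition.
#' Supports are stored as integer node labels (the basal trifurcation gets
#' an empty label). Column index draws come from a single seeded generator,
#' one `sample.int(n_col, n_col, replace = TRUE)` call per replicate, so runs
#' are reproducible for a fixed seed.
#'
#' @param aln alignment tibble with columns `id` and `sequence`.
#' @param n number of bootstrap replicates.
#' @param seed RNG seed.
#' @param model distance model passed to [pairwise_distances()].
#' @return an unrooted `phylo` tree with bootstrap supports in `node.label`.
#' @export
bootstrap_support <- function(aln, n = 1000, seed = 1, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (n < 1) abort("`n` must be at least 1.")
  mat <- aln_matrix(aln)
  tree <- nj_tree(dist_from_matrix(mat, model))

  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ntip <- length(labs)
  ref <- sort(labs)[1]
  node_keys <- vapply(pp, function(part) {
    side <- labs[part]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= ntip - 2) {
      paste(sort(side), collapse = "|")
    } else {
      NA_character_
    }
  }, character(1))

  counts <- setNames(rep(0L, sum(!is.na(node_keys))), node_keys[!is.na(node_keys)])
  n_col <- ncol(mat)
  withr::local_seed(seed)
  for (b in seq_len(n)) {
    idx <- sample.int(n_col, n_col, replace = TRUE)
    rep_keys <- tree_splits(nj_tree(dist_from_matrix(mat[, idx, drop = FALSE], model)))
    hit <- names(counts) %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }
  support <- setNames(as.integer(round(100 * counts / n)), names(counts))
  node_label <- character(length(node_keys))
  node_label[!is.na(node_keys)] <- as.character(support[node_keys[!is.na(node_keys)]])
  tree$node.label <- node_label
  tree
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written and bootstrap supports (if present) appear as
#' internal node labels; the string round-trips through [ape::read.tree()].
#'
#' @param tree a `phylo` object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nwk <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
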