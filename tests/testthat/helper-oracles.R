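# Independent oracles used to cross-check the implementation. These are
# deliberately written from scratch against the definitions, not by calling
# the package's internals.

# Brute-force spacing-grammar matcher: slide every 8-subset of cysteine
# positions and check every range and forbidden-letter constraint.
brute_force_match <- function(seq, grammar) {
  chars <- strsplit(seq, "")[[1]]
  cys <- which(chars == "C")
  if (length(cys) < 8) return(FALSE)
  subs <- utils::combn(cys, 8)
  rng <- function(x, r) x >= r[1] && x <= r[2]
  for (j in seq_len(ncol(subs))) {
    p <- subs[, j]
    if (!rng(p[1] - 1, grammar$leader)) next
    if (!rng(length(chars) - p[8], grammar$tail)) next
    ok <- TRUE
    for (i in 1:7) {
      gap <- p[i + 1] - p[i] - 1
      if (!rng(gap, grammar$gaps[[i]])) { ok <- FALSE; break }
      if (gap > 0 && any(chars[(p[i] + 1):(p[i + 1] - 1)] %in% grammar$forbid_in_gaps)) {
        ok <- FALSE; break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Random amino-acid sequence with a controllable cysteine frequency.
random_protein <- function(len, c_weight = 0.05) {
  letters20 <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  w <- rep((1 - c_weight) / 19, 20)
  w[letters20 == "C"] <- c_weight
  paste(sample(letters20, len, replace = TRUE, prob = w), collapse = "")
}

# Direct pH grid scan for the isoelectric point: net charge evaluated on a
# fine grid with the Henderson-Hasselbalch sums written out longhand.
grid_scan_pi <- function(seq, step = 1e-4) {
  chars <- strsplit(seq, "")[[1]]
  nterm_pka <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
                 E = 7.7, G = 7.5)
  nt <- nterm_pka[chars[1]]
  if (is.na(nt)) nt <- 7.5
  side_pos <- c(H = 5.98, K = 10.0, R = 12.0)
  side_neg <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  ph <- seq(0, 14, by = step)
  q <- 1 / (1 + 10^(ph - nt)) - 1 / (1 + 10^(3.55 - ph))
  for (res in names(side_pos)) {
    q <- q + sum(chars == res) / (1 + 10^(ph - side_pos[[res]]))
  }
  for (res in names(side_neg)) {
    q <- q - sum(chars == res) / (1 + 10^(side_neg[[res]] - ph))
  }
  ph[which.min(abs(q))]
}

# Build a sequence from an explicit skeleton layout with a filler letter.
skeleton_seq <- function(leader, gaps, tail, filler = "A") {
  stopifnot(length(gaps) == 7)
  out <- strrep(filler, leader)
  for (g in gaps) out <- paste0(out, "C", strrep(filler, g))
  paste0(out, "C", strrep(filler, tail))
}

# Sorted canonical split keys of a phylo tree, written independently of
# tree_splits(): enumerate each internal edge's tip partition by deleting
# the edge from the (unrooted) graph.
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next  # pendant edge
    tips <- ape::extract.clade(tree, child)$tip.label
    side <- sort(tips)
    other <- sort(setdiff(tree$tip.label, tips))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (sort(tree$tip.label)[1] %in% side) {
      paste(other, collapse = "|")
    } else {
      paste(side, collapse = "|")
    }
    keys <- c(keys, key)
  }
  sort(unique(keys))
}
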