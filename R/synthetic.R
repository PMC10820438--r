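# Hydrophobic-biased residue alphabet for planted hydrophobin gaps/leaders
# (no C, no W: extra cysteines would break the planted skeleton, and the
# strict pattern variant also bans tryptophan). Weights target a mildly
# hydrophobic GRAVY once the 8 skeleton cysteines (KD 2.5) are added.
HFB_ALPHABET <- c(
  A = 0.12, I = 0.07, L = 0.08, V = 0.07, F = 0.05, G = 0.12, S = 0.12,
  T = 0.10, M = 0.03, P = 0.05, Y = 0.03, N = 0.04, Q = 0.04, D = 0.03,
  E = 0.03, K = 0.03, H = 0.01, R = 0.01
)

# Decoy alphabet: all canonical letters except cysteine (cysteines are
# placed explicitly so their count is controlled).
DECOY_ALPHABET <- setNames(rep(1 / 19, 19), setdiff(AA_CANONICAL, "C"))

draw_letters <- function(n, alphabet = HFB_ALPHABET) {
  if (n == 0) return("")
  paste(sample(names(alphabet), n, replace = TRUE, prob = alphabet), collapse = "")
}

#' Census simulation plan
#'
#' Parameters of the synthetic proteome emulating a hydrophobin census:
#' 19 planted typical class I proteins, 3 atypical variants (two 7-cysteine,
#' one 6-cysteine), and 80 decoys of which 20% are near-miss mutants (a
#' grammar-conforming construction with one gap pushed out of range by one
#' residue). Planted sequences are rejection-sampled to land inside the
#' published physicochemical envelope (GRAVY 0.27-0.951, pI 3.57-8.50).
#' Random decoys are rejection-sampled so that no grammar matches and the
#' cysteine count avoids 6, 7 and 9 (counts that would legitimately make a
#' sequence an atypical candidate).
#'
#' @param n_typical number of planted typical class I proteins.
#' @param atypical_cys cysteine counts of the planted atypical variants.
#' @param n_decoys number of decoys.
#' @param near_miss_fraction fraction of decoys that are near-miss mutants.
#' @param length_range decoy length window in residues.
#' @param gravy_range accepted GRAVY window for planted sequences.
#' @param pi_range accepted theoretical-pI window for planted sequences.
#' @param seed RNG seed; the same seed yields byte-identical output.
#' @param max_retries rejection-sampling cap per sequence.
#' @return a list of class `census_plan`.
#' @export
census_plan <- function(n_typical = 19,
                        atypical_cys = c(7, 7, 6),
                        n_decoys = 80,
                        near_miss_fraction = 0.2,
                        length_range = c(80, 400),
                        gravy_range = c(0.27, 0.951),
                        pi_range = c(3.57, 8.50),
                        seed = 42,
                        max_retries = 10000) {
  structure(
    list(
      n_typical = n_typical, atypical_cys = atypical_cys, n_decoys = n_decoys,
      near_miss_fraction = near_miss_fraction, length_range = length_range,
      gravy_range = gravy_range, pi_range = pi_range, seed = seed,
      max_retries = max_retries
    ),
    class = "census_plan"
  )
}

retry_cap <- function(tries, cap, what) {
  if (tries > cap) abort(sprintf("Rejection sampling exceeded %d retries for %s.", cap, what))
}

# Assemble a sequence from a drawn skeleton layout.
assemble_skeleton <- function(leader_len, gaps, tail_len) {
  pieces <- character(0)
  pieces <- c(pieces, draw_letters(leader_len))
  for (i in 1:7) {
    pieces <- c(pieces, "C", draw_letters(gaps[i]))
  }
  c_seq <- paste(pieces, collapse = "")
  paste0(c_seq, "C", draw_letters(tail_len))
}

draw_typical_layout <- function(min_len = 80) {
  leader <- sample(2:38, 1)
  gaps <- c(
    sample(5:9, 1), 0L, sample(11:44, 1), sample(8:23, 1),
    sample(5:9, 1), 0L, sample(6:18, 1)
  )
  tail <- sample(2:14, 1)
  total <- leader + 8 + sum(gaps) + tail
  if (total < min_len) leader <- min(38L, leader + (min_len - total))
  list(leader = leader, gaps = gaps, tail = tail)
}

sample_typical <- function(plan, grammars) {
  tries <- 0
  repeat {
    tries <- tries + 1
    retry_cap(tries, plan$max_retries, "a typical class I sequence")
    lay <- draw_typical_layout(plan$length_range[1])
    seq <- assemble_skeleton(lay$leader, lay$gaps, lay$tail)
    if (match_grammar(seq, grammars$class_II)$matched) next
    g <- gravy(seq)
    if (g < plan$gravy_range[1] || g > plan$gravy_range[2]) next
    pi <- theoretical_pi(seq)
    if (pi < plan$pi_range[1] || pi > plan$pi_range[2]) next
    return(list(sequence = seq, gap_vector = lay$gaps))
  }
}

sample_atypical <- function(plan, grammars, n_cys) {
  stopifnot(n_cys %in% c(6, 7))
  base <- sample_typical(plan, grammars)
  skel <- cys_skeleton(base$sequence)
  # Drop singleton skeleton cysteines (positions 4 then 1) so 7- and 6-Cys
  # variants keep most of the hydrophobin-like architecture.
  drop <- if (n_cys == 7) skel[4] else skel[c(4, 1)]
  chars <- seq_chars(base$sequence)
  chars[drop] <- "A"
  seq <- paste(chars, collapse = "")
  stopifnot(length(cys_skeleton(seq)) == n_cys)
  seq
}

sample_near_miss <- function(plan, grammars) {
  tries <- 0
  bounds <- list(
    `1` = c(5, 9), `3` = c(11, 44), `4` = c(8, 23), `5` = c(5, 9), `7` = c(6, 18)
  )
  repeat {
    tries <- tries + 1
    retry_cap(tries, plan$max_retries, "a near-miss decoy")
    lay <- draw_typical_layout(plan$length_range[1])
    which_gap <- as.integer(sample(names(bounds), 1))
    b <- bounds[[as.character(which_gap)]]
    # Push the chosen gap out of range by exactly one residue.
    lay$gaps[which_gap] <- if (stats::runif(1) < 0.5 && b[1] > 0) b[1] - 1L else b[2] + 1L
    seq <- assemble_skeleton(lay$leader, lay$gaps, lay$tail)
    if (nchar(seq) < plan$length_range[1]) next
    if (any(vapply(grammars, function(g) match_grammar(seq, g)$matched, logical(1)))) next
    return(seq)
  }
}

sample_random_decoy <- function(plan, grammars) {
  tries <- 0
  cys_choices <- c(0:5, 8, 10, 11, 12)
  repeat {
    tries <- tries + 1
    retry_cap(tries, plan$max_retries, "a random decoy")
    len <- sample(plan$length_range[1]:plan$length_range[2], 1)
    n_cys <- sample(cys_choices, 1)
    body <- seq_chars(draw_letters(len, DECOY_ALPHABET))
    if (n_cys > 0) {
      body[sample(len, n_cys)] <- "C"
    }
    seq <- paste(body, collapse = "")
    if (length(cys_skeleton(seq)) != n_cys) next
    if (any(vapply(grammars, function(g) match_grammar(seq, g)$matched, logical(1)))) next
    return(seq)
  }
}

#' Generate a synthetic proteome with known ground truth
#'
#' Plants grammar-conforming typical class I hydrophobins, atypical 6/7-Cys
#' variants and decoys according to a [census_plan()], recording the intended
#' verdict of every record. Deterministic for a fixed plan seed.
#'
#' @param plan a [census_plan()].
#' @param fasta,truth_tsv optional output paths for the FASTA and the truth
#'   table.
#' @return a list with `proteins` (tibble: `id`, `sequence`, `source`) and
#'   `truth` (tibble: `id`, `planted` class, `verdict` expected from
#'   screening, `n_cys`, `length`, `gap_vector`).
#' @examples
#' census <- generate_proteome(census_plan(n_typical = 2, n_decoys = 5))
#' census$truth
#' @export
generate_proteome <- function(plan = census_plan(), fasta = NULL, truth_tsv = NULL) {
  stopifnot(inherits(plan, "census_plan"))
  grammars <- hfb_grammars()
  withr::local_seed(plan$seed)

  rows <- list()
  add <- function(id, seq, planted, verdict, gap_vector = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble(
      id = id, sequence = seq, planted = planted, verdict = verdict,
      n_cys = length(cys_skeleton(seq)), length = nchar(seq),
      gap_vector = gap_vector
    )
  }
  for (i in seq_len(plan$n_typical)) {
    s <- sample_typical(plan, grammars)
    add(sprintf("syn_hyd_typ%02d", i), s$sequence, "typical_class_I",
        "typical_class_I", paste(s$gap_vector, collapse = "-"))
  }
  for (i in seq_along(plan$atypical_cys)) {
    s <- sample_atypical(plan, grammars, plan$atypical_cys[i])
    add(sprintf("syn_hyd_atyp%02d", i), s, "atypical", "atypical")
  }
  n_near <- round(plan$n_decoys * plan$near_miss_fraction)
  for (i in seq_len(n_near)) {
    add(sprintf("syn_decoy_nm%02d", i), sample_near_miss(plan, grammars),
        "decoy_near_miss", "rejected")
  }
  for (i in seq_len(plan$n_decoys - n_near)) {
    add(sprintf("syn_decoy_rd%02d", i), sample_random_decoy(plan, grammars),
        "decoy_random", "rejected")
  }
  all_rows <- list_rbind(rows)
  proteins <- all_rows |>
    select("id", "sequence") |>
    mutate(source = "provided")
  truth <- all_rows |> select(-"sequence") |> select("id", dplyr::everything())

  if (!is.null(fasta)) write_fasta(proteins, fasta)
  if (!is.null(truth_tsv)) {
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(proteins = proteins, truth = truth)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a 4-stage x 3-replicate qRT-PCR design with a housekeeping
#' reference gene. The reference Ct is constant in expectation across stages;
#' each target's Ct at a stage is `base_ct - log2_effect + noise`, so
#' [fold_change_ddct()] recovers the planted fold change (exactly when
#' `noise_sd = 0`).
#'
#' @param effects a data frame with columns `gene`, `stage`, `log2_effect`
#'   (log2 fold change relative to the calibrator stage; stages absent for a
#'   gene default to effect 0).
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param seed RNG seed.
#' @param ref_gene reference gene id.
#' @param base_ct,ref_ct expected target/reference Ct at zero effect.
#' @param stages stage set.
#' @param n_reps replicates per (gene, stage).
#' @return a Ct tibble (`gene`, `stage`, `replicate`, `ct`).
#' @export
generate_ct_table <- function(effects, noise_sd = 0.2, seed = 1,
                              ref_gene = "gapdh", base_ct = 25, ref_ct = 18,
                              stages = CT_STAGES, n_reps = 3) {
  stopifnot(all(c("gene", "stage", "log2_effect") %in% names(effects)))
  withr::local_seed(seed)
  genes <- unique(effects$gene)
  grid <- tidyr::expand_grid(
    gene = c(ref_gene, genes), stage = stages, replicate = seq_len(n_reps)
  ) |>
    left_join(as_tibble(effects), by = c("gene", "stage")) |>
    mutate(
      log2_effect = dplyr::coalesce(.data$log2_effect, 0),
      ct = ifelse(.data$gene == ref_gene, ref_ct,
                  base_ct - .data$log2_effect) +
        stats::rnorm(dplyr::n(), mean = 0, sd = noise_sd)
    ) |>
    select("gene", "stage", "replicate", "ct")
  validate_ct_table(grid)
}

#' Simulate a protein alignment along a tree
#'
#' Evolves a root sequence along a (given or random) tree with symmetric
#' Jukes-Cantor-style substitutions over the 20 amino-acid alphabet: on an
#' edge of length t, each site changes with probability 1 - exp(-rate * t)
#' to a uniformly drawn different letter. The generating tree is returned so
#' recovery can be scored.
#'
#' @param tree a `phylo` tree with edge lengths, or NULL to draw a random
#'   one with `n_taxa` tips and edge lengths uniform on (0.05, 0.25).
#' @param n_taxa number of tips when `tree` is NULL.
#' @param n_columns alignment length.
#' @param rate substitution rate per unit branch length.
#' @param seed RNG seed.
#' @return a list with `alignment` (tibble: `id`, `sequence`) and `tree`.
#' @export
generate_msa <- function(tree = NULL, n_taxa = 12, n_columns = 500,
                         rate = 0.3, seed = 1) {
  withr::local_seed(seed)
  if (is.null(tree)) {
    tree <- ape::rtree(n_taxa)
    tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 0.25)
  }
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(AA_CANONICAL, n_columns, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    s <- seqs[[parent]]
    p_change <- 1 - exp(-rate * tree$edge.length[e])
    hit <- which(stats::runif(n_columns) < p_change)
    if (length(hit) > 0) {
      s[hit] <- vapply(s[hit], function(old) {
        sample(setdiff(AA_CANONICAL, old), 1)
      }, character(1))
    }
    seqs[[child]] <- s
  }
  alignment <- tibble(
    id = tree$tip.label,
    sequence = vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), character(1))
  )
  list(alignment = alignment, tree = tree)
}
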