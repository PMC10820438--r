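test_that("cys_skeleton returns increasing 1-based cysteine positions", {
  expect_equal(cys_skeleton("ACCA"), c(2L, 3L))
  expect_equal(cys_skeleton("AAAA"), integer(0))
  s <- skeleton_seq(3, c(6, 0, 35, 20, 5, 0, 13), 4)
  expect_equal(length(cys_skeleton(s)), 8)
  expect_true(all(diff(cys_skeleton(s)) > 0))
})

test_that("match_grammar reads the gap vector between skeleton cysteines", {
  g <- hfb_grammars()
  class_ii_seq <- skeleton_seq(0, c(9, 0, 11, 16, 8, 0, 10), 0)
  hit <- match_grammar(class_ii_seq, g$class_II)
  expect_true(hit$matched)
  expect_equal(hit$gap_vector, c(9L, 0L, 11L, 16L, 8L, 0L, 10L))
  expect_equal(hit$leader_len, 0L)
  expect_equal(hit$tail_len, 0L)
  # the same spacing fails class I: gap 3 is 11, outside 33-41
  expect_false(match_grammar(class_ii_seq, g$class_I)$matched)
})

test_that("sequences with 7 cysteines cannot match an 8-cysteine grammar", {
  g <- hfb_grammars()
  s <- skeleton_seq(0, c(9, 0, 11, 16, 8, 0, 10), 0)
  chars <- strsplit(s, "")[[1]]
  chars[which(chars == "C")[4]] <- "A"
  s7 <- paste(chars, collapse = "")
  for (gr in g) expect_false(match_grammar(s7, gr)$matched)
})

test_that("forbidden letters inside a gap block a match", {
  g_strict <- hfb_grammars(mode = "paper_strict")
  s <- skeleton_seq(2, c(6, 0, 35, 20, 5, 0, 13), 4, filler = "A")
  expect_true(match_grammar(s, g_strict$typical)$matched)
  chars <- strsplit(s, "")[[1]]
  skel <- which(chars == "C")
  chars[skel[3] + 2] <- "W"  # tryptophan inside gap 3
  s_w <- paste(chars, collapse = "")
  expect_false(match_grammar(s_w, g_strict$typical)$matched)
  # default mode only bans cysteine, so the W sequence still matches
  expect_true(match_grammar(s_w, hfb_grammars()$typical)$matched)
})

test_that("extra cysteines are handled by 8-subset enumeration with a cap", {
  g <- hfb_grammars()
  # 9th cysteine in the leader: skeleton must be chosen among 9 positions
  s9 <- paste0("AC", skeleton_seq(3, c(6, 0, 35, 20, 5, 0, 13), 4))
  hit <- match_grammar(s9, g$class_I)
  expect_true(hit$matched)
  expect_equal(hit$gap_vector, c(6L, 0L, 35L, 20L, 5L, 0L, 13L))
  capped <- match_grammar(s9, g$class_I, max_combinations = 3)
  expect_false(capped$matched)
  expect_true(capped$cap_exceeded)
})

test_that("match_grammar agrees with the brute-force 8-subset oracle", {
  withr::local_seed(101)
  grammars <- hfb_grammars(include_strain = TRUE)
  for (i in 1:200) {
    repeat {
      s <- random_protein(sample(30:300, 1), c_weight = 0.05)
      if (length(cys_skeleton(s)) <= 12) break
    }
    for (gr in grammars) {
      expect_equal(
        match_grammar(s, gr)$matched, brute_force_match(s, gr),
        info = sprintf("seq %d vs %s", i, gr$name)
      )
    }
  }
})

test_that("classify_hfb applies the length window strictly", {
  g <- hfb_grammars()
  # perfect typical class I spacing but 79 aa total
  s79 <- skeleton_seq(34, c(5, 0, 11, 8, 5, 0, 6), 2)
  expect_equal(nchar(s79), 79)
  call <- classify_hfb(s79, g)
  expect_equal(call$verdict, "rejected")
  expect_equal(call$reject_reason, "length")
  # pad to 80 within leader bounds and it becomes a candidate
  s80 <- paste0("A", s79)
  expect_equal(classify_hfb(s80, g)$verdict, "typical_class_I")
})

test_that("classify_hfb separates typical class I, class II and atypical", {
  g <- hfb_grammars()
  typ <- skeleton_seq(10, c(7, 0, 30, 15, 6, 0, 12), 5)
  expect_equal(classify_hfb(typ, g)$verdict, "typical_class_I")

  class_ii <- skeleton_seq(20, c(9, 0, 11, 16, 8, 0, 10), 15)
  expect_equal(classify_hfb(class_ii, g)$verdict, "class_II")

  chars <- strsplit(typ, "")[[1]]
  skel <- which(chars == "C")
  chars[skel[c(1, 4)]] <- "A"
  six <- paste(chars, collapse = "")
  call <- classify_hfb(six, g)
  expect_equal(call$n_cys, 6L)
  expect_equal(call$verdict, "atypical")
})

test_that("classification is invariant within the tail range and flips beyond it", {
  g <- hfb_grammars()
  base <- skeleton_seq(10, c(7, 0, 30, 15, 6, 0, 12), 2)
  expect_equal(classify_hfb(base, g)$verdict, "typical_class_I")
  for (extra in 1:12) {  # tail grows from 2 up to the 14-residue bound
    expect_equal(
      classify_hfb(paste0(base, strrep("A", extra)), g)$verdict,
      "typical_class_I"
    )
  }
  beyond <- paste0(base, strrep("A", 13))  # tail 15 exceeds the X2-14 range
  expect_equal(classify_hfb(beyond, g)$verdict, "rejected")
  expect_equal(classify_hfb(beyond, g)$reject_reason, "no_grammar_match")
})

test_that("screen_proteome partitions verdicts and handles decoy-only input", {
  withr::local_seed(77)
  decoys <- tibble::tibble(
    id = sprintf("d%02d", 1:10),
    sequence = replicate(10, {
      repeat {
        s <- random_protein(sample(80:200, 1), c_weight = 0.02)
        n <- length(cys_skeleton(s))
        if (!n %in% c(6, 7, 9) &&
            !any(vapply(hfb_grammars(), function(g) match_grammar(s, g)$matched, logical(1)))) {
          break
        }
      }
      s
    })
  )
  scr <- screen_proteome(decoys)
  expect_s3_class(scr, "hfb_screen")
  expect_equal(scr$n_candidates, 0)
  expect_equal(sum(scr$counts$n), 10)
  expect_equal(nrow(tidy(scr)), 10)
  expect_equal(glance(scr)$n_rejected, 10)
})

test_that("external annotations are consumed, never computed", {
  proteins <- tibble::tibble(
    id = c("a", "b"),
    sequence = c(
      skeleton_seq(10, c(7, 0, 30, 15, 6, 0, 12), 5),
      skeleton_seq(12, c(8, 0, 25, 12, 7, 0, 10), 6)
    )
  )
  ann <- tibble::tibble(id = "a", signal_peptide = "Yes", sub_location = "extr")
  scr <- screen_proteome(proteins, annotations = ann)
  calls <- tidy(scr)
  expect_equal(calls$signal_peptide[calls$protein_id == "a"], "Yes")
  expect_equal(calls$signal_peptide[calls$protein_id == "b"], "unknown")
})

test_that("grammar YAML round trip preserves ranges", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "my_class_II:",
    "  leader: [0, .inf]",
    "  gaps:",
    "    - [9, 10]",
    "    - [0, 0]",
    "    - [11, 11]",
    "    - [16, 16]",
    "    - [8, 9]",
    "    - [0, 0]",
    "    - [10, 10]",
    "  tail: [0, .inf]",
    "  forbid_in_gaps: [C]"
  ), path)
  g <- read_grammars(path)
  s <- skeleton_seq(0, c(9, 0, 11, 16, 8, 0, 10), 0)
  expect_true(match_grammar(s, g$my_class_II)$matched)
  expect_equal(g$my_class_II$gaps[[4]], c(16, 16))
})
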