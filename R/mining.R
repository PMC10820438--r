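#' Cysteine skeleton of a protein sequence
#'
#' @param seq amino-acid string.
#' @return integer vector of 1-based positions of every cysteine, strictly
#'   increasing; empty when the sequence has none.
#' @examples
#' cys_skeleton("ACCA")  # 2 3
#' @export
cys_skeleton <- function(seq) {
  check_aa_sequence(seq)
  which(seq_chars(seq) == "C")
}

#' Match a sequence against a cysteine-spacing grammar
#'
#' With exactly 8 cysteines the gap vector is checked directly. With more,
#' 8-subsets of the cysteine positions are enumerated (lexicographically, so
#' the first hit minimizes the leader length) up to `max_combinations`; a
#' sequence whose subset count exceeds the cap is returned as a no-match with
#' `cap_exceeded = TRUE`. Gap lengths count residues strictly between
#' consecutive skeleton cysteines, and a gap containing any letter in the
#' grammar's `forbid_in_gaps` set fails.
#'
#' @param seq amino-acid string.
#' @param grammar a [cys_grammar()].
#' @param max_combinations enumeration cap for >8-cysteine sequences.
#' @return a list: `matched` (logical), `gap_vector` (integer(7) or NULL),
#'   `leader_len`, `tail_len`, `skeleton` (positions used), `cap_exceeded`.
#' @export
match_grammar <- function(seq, grammar, max_combinations = 5000) {
  stopifnot(inherits(grammar, "cys_grammar"))
  check_aa_sequence(seq)
  cys <- which(seq_chars(seq) == "C")
  no_match <- list(
    matched = FALSE, gap_vector = NULL, leader_len = NA_integer_,
    tail_len = NA_integer_, skeleton = NULL, cap_exceeded = FALSE
  )
  n_cys <- length(cys)
  if (n_cys < 8) return(no_match)
  if (n_cys == 8) {
    return(check_skeleton(seq, cys, grammar) %||% no_match)
  }
  n_comb <- choose(n_cys, 8)
  if (n_comb > max_combinations) {
    no_match$cap_exceeded <- TRUE
    return(no_match)
  }
  subsets <- utils::combn(cys, 8)
  for (j in seq_len(ncol(subsets))) {
    hit <- check_skeleton(seq, subsets[, j], grammar)
    if (!is.null(hit)) return(hit)
  }
  no_match
}

# Checks one candidate 8-Cys skeleton against a grammar; NULL on failure.
check_skeleton <- function(seq, skel, grammar) {
  len <- nchar(seq)
  leader <- skel[1] - 1L
  tail <- len - skel[8]
  in_range <- function(x, r) x >= r[1] && x <= r[2]
  if (!in_range(leader, grammar$leader) || !in_range(tail, grammar$tail)) {
    return(NULL)
  }
  gaps <- diff(skel) - 1L
  for (i in 1:7) {
    if (!in_range(gaps[i], grammar$gaps[[i]])) return(NULL)
  }
  if (length(grammar$forbid_in_gaps) > 0) {
    for (i in 1:7) {
      if (gaps[i] == 0L) next
      gap_str <- substr(seq, skel[i] + 1L, skel[i + 1L] - 1L)
      if (any(vapply(grammar$forbid_in_gaps, grepl, logical(1),
                     x = gap_str, fixed = TRUE))) {
        return(NULL)
      }
    }
  }
  list(
    matched = TRUE, gap_vector = as.integer(gaps),
    leader_len = as.integer(leader), tail_len = as.integer(tail),
    skeleton = as.integer(skel), cap_exceeded = FALSE
  )
}

#' Classify one protein as typical class I, class II, atypical, or rejected
#'
#' Applies the census rules: proteins outside the length window are rejected;
#' the narrower class II consensus is tested before the broad typical
#' pattern, so a typical match that is not class II is called
#' `typical_class_I`; sequences with 6, 7 or 9 cysteines that satisfy no
#' grammar are `atypical` hydrophobin-like candidates; everything else is
#' rejected with a reason.
#'
#' @param sequence amino-acid string.
#' @param grammars grammar set from [hfb_grammars()] (must contain `typical`
#'   and `class_II`).
#' @param id optional protein identifier for the output row.
#' @param length_range allowed protein length window in residues.
#' @return a one-row tibble: `protein_id`, `length`, `n_cys`, `verdict`,
#'   `matched_grammar`, `gap_vector` (dash-separated string or NA),
#'   `leader_len`, `tail_len`, `reject_reason`.
#' @examples
#' g <- hfb_grammars()
#' seq <- paste0(
#'   "MA", "C", "AVAVA", "CC", "AVAVAVAVAVA", "C", "AVAVAVAV",
#'   "C", "AVAVA", "CC", "AVAVAV", "C", "AV"
#' )
#' classify_hfb(strrep("A", 80 - nchar(seq)) |> paste0(seq), g)
#' @export
classify_hfb <- function(sequence, grammars = hfb_grammars(), id = NA_character_,
                         length_range = c(80, 400)) {
  if (!all(c("typical", "class_II") %in% names(grammars))) {
    abort("`grammars` must include at least 'typical' and 'class_II'.")
  }
  check_aa_sequence(sequence)
  len <- nchar(sequence)
  n_cys <- length(cys_skeleton(sequence))
  call_row <- function(verdict, hit = NULL, grammar = NA_character_,
                       reason = NA_character_) {
    tibble(
      protein_id = id,
      length = len,
      n_cys = n_cys,
      verdict = verdict,
      matched_grammar = grammar,
      gap_vector = if (is.null(hit)) NA_character_ else paste(hit$gap_vector, collapse = "-"),
      leader_len = if (is.null(hit)) NA_integer_ else hit$leader_len,
      tail_len = if (is.null(hit)) NA_integer_ else hit$tail_len,
      reject_reason = reason
    )
  }
  if (len < length_range[1] || len > length_range[2]) {
    return(call_row("rejected", reason = "length"))
  }
  if (n_cys < 6) {
    return(call_row("rejected", reason = "cys_count"))
  }
  if (n_cys >= 8) {
    hit_ii <- match_grammar(sequence, grammars$class_II)
    if (hit_ii$matched) return(call_row("class_II", hit_ii, "class_II"))
    hit_typ <- match_grammar(sequence, grammars$typical)
    if (hit_typ$matched) return(call_row("typical_class_I", hit_typ, "typical"))
  }
  if (n_cys %in% c(6L, 7L, 9L)) {
    return(call_row("atypical"))
  }
  call_row("rejected", reason = "no_grammar_match")
}

#' Screen a proteome for hydrophobin candidates
#'
#' Classifies every record and tallies verdicts. "Candidates" are proteins
#' called `typical_class_I`, `class_II` or `atypical`.
#'
#' @param proteins a data frame with columns `id` and `sequence` (as from
#'   [read_fasta()] or [generate_proteome()]).
#' @param grammars grammar set from [hfb_grammars()].
#' @param annotations optional data frame with columns `id`, `signal_peptide`,
#'   `sub_location` from an external pre-computed annotation run; absent
#'   entries are reported as `"unknown"` (these predictions are never computed
#'   in-package).
#' @param length_range allowed protein length window.
#' @return an object of class `hfb_screen`: use [tidy()] for per-protein
#'   calls, [glance()] for the verdict tally, [autoplot()] for a summary plot.
#' @export
screen_proteome <- function(proteins, grammars = hfb_grammars(),
                            annotations = NULL, length_range = c(80, 400)) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0) abort("`proteins` must contain at least one record.")
  calls <- purrr::map2(
    proteins$sequence, proteins$id,
    ~ classify_hfb(.x, grammars, id = .y, length_range = length_range)
  ) |>
    list_rbind() |>
    arrange(.data$protein_id)

  ann <- if (is.null(annotations)) {
    tibble(protein_id = calls$protein_id,
           signal_peptide = "unknown", sub_location = "unknown")
  } else {
    stopifnot("id" %in% names(annotations))
    annotations |>
      rename(protein_id = "id") |>
      select(dplyr::any_of(c("protein_id", "signal_peptide", "sub_location")))
  }
  calls <- left_join(calls, ann, by = "protein_id") |>
    mutate(
      signal_peptide = dplyr::coalesce(.data$signal_peptide, "unknown"),
      sub_location = dplyr::coalesce(.data$sub_location, "unknown")
    )

  counts <- calls |>
    count(.data$verdict, name = "n") |>
    tidyr::complete(
      verdict = c("typical_class_I", "class_II", "atypical", "rejected"),
      fill = list(n = 0L)
    )
  structure(
    list(
      calls = calls,
      counts = counts,
      n_candidates = sum(counts$n[counts$verdict != "rejected"])
    ),
    class = "hfb_screen"
  )
}

#' @export
print.hfb_screen <- function(x, ...) {
  cat(sprintf(
    "<hfb_screen> %d proteins: %d candidates (%d typical class I, %d class II, %d atypical), %d rejected\n",
    nrow(x$calls), x$n_candidates,
    x$counts$n[x$counts$verdict == "typical_class_I"],
    x$counts$n[x$counts$verdict == "class_II"],
    x$counts$n[x$counts$verdict == "atypical"],
    x$counts$n[x$counts$verdict == "rejected"]
  ))
  invisible(x)
}

#' @rdname screen_proteome
#' @param x an `hfb_screen` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.hfb_screen <- function(x, ...) x$calls

#' @rdname screen_proteome
#' @exportS3Method generics::glance
glance.hfb_screen <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$calls),
    n_typical_class_I = x$counts$n[x$counts$verdict == "typical_class_I"],
    n_class_II = x$counts$n[x$counts$verdict == "class_II"],
    n_atypical = x$counts$n[x$counts$verdict == "atypical"],
    n_rejected = x$counts$n[x$counts$verdict == "rejected"],
    n_candidates = x$n_candidates
  )
}

#' @rdname screen_proteome
#' @param object an `hfb_screen` object.
#' @exportS3Method ggplot2::autoplot
autoplot.hfb_screen <- function(object, ...) {
  ggplot2::ggplot(object$counts, ggplot2::aes(x = .data$verdict, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(
      x = NULL, y = "proteins",
      title = "Hydrophobin census verdicts"
    ) +
    ggplot2::theme_minimal()
}

#' Write a mining report to TSV and/or JSON
#'
#' @param screen an `hfb_screen` object.
#' @param tsv,json optional output paths.
#' @return the screen object, invisibly.
#' @export
write_mining_report <- function(screen, tsv = NULL, json = NULL) {
  stopifnot(inherits(screen, "hfb_screen"))
  if (!is.null(tsv)) {
    utils::write.table(screen$calls, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("JSON output requires the 'jsonlite' package.")
    }
    jsonlite::write_json(
      list(calls = screen$calls, counts = screen$counts),
      json, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(screen)
}
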