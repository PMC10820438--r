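#' Construct a cysteine-spacing grammar
#'
#' A grammar describes an 8-cysteine skeleton as ordered residue-count
#' constraints: a leader range (residues before the first Cys), seven gap
#' ranges (residues strictly between consecutive skeleton cysteines; an
#' adjacent "CC" is the fixed range c(0, 0)), and a tail range (residues
#' after the last Cys). Letters listed in `forbid_in_gaps` may not occur
#' inside any gap.
#'
#' @param name grammar name.
#' @param leader length-2 integer range for the leader.
#' @param gaps list of seven length-2 integer ranges.
#' @param tail length-2 integer range for the tail.
#' @param forbid_in_gaps character vector of residue letters banned from gaps.
#' @return an object of class `cys_grammar`.
#' @examples
#' cys_grammar(
#'   "class_II", c(0, Inf),
#'   list(c(9, 10), c(0, 0), c(11, 11), c(16, 16), c(8, 9), c(0, 0), c(10, 10)),
#'   c(0, Inf)
#' )
#' @export
cys_grammar <- function(name, leader, gaps, tail, forbid_in_gaps = "C") {
  if (length(gaps) != 7) abort("`gaps` must list exactly 7 ranges (8 skeleton cysteines).")
  check_range <- function(r, what) {
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2] || r[1] < 0) {
      abort(sprintf("%s must be a valid non-negative range (min <= max).", what))
    }
    as.numeric(r)
  }
  g <- list(
    name = name,
    leader = check_range(leader, "`leader`"),
    gaps = lapply(seq_along(gaps), function(i) check_range(gaps[[i]], sprintf("gap %d", i))),
    tail = check_range(tail, "`tail`"),
    forbid_in_gaps = as.character(forbid_in_gaps %||% character())
  )
  structure(g, class = "cys_grammar")
}

#' @export
print.cys_grammar <- function(x, ...) {
  fmt <- function(r) {
    if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "-", ifelse(is.finite(r[2]), r[2], "*"))
  }
  gaps <- vapply(x$gaps, fmt, character(1))
  cat(sprintf(
    "<cys_grammar %s> X%s-%s-X%s  [forbid in gaps: %s]\n",
    x$name, fmt(x$leader),
    paste0("C", ifelse(gaps == "0", "", paste0("-X", gaps, "-")), collapse = ""),
    fmt(x$tail),
    paste(x$forbid_in_gaps, collapse = "")
  ))
  invisible(x)
}

#' Built-in hydrophobin spacing grammars
#'
#' Returns the grammar set used by [classify_hfb()]:
#' \describe{
#'   \item{typical}{the broad typical class I pattern
#'     X2-38 C X5-9 CC X11-44 C X8-23 C X5-9 CC X6-18 C X2-14 — the primary
#'     census filter.}
#'   \item{class_I}{the narrower class I consensus
#'     C X6-7 CC X33-41 C X19-25 C X5 CC X12-17 C (leader/tail free).}
#'   \item{class_II}{the class II consensus
#'     C X9-10 CC X11 C X16 C X8-9 CC X10 C (leader/tail free).}
#'   \item{gf_strain}{optional strain-specific pattern
#'     C X7-8 CC X13-32 C X12-13 C X5-6 CC X11-12 C; its fourth gap range is
#'     interpreted as X12-13 (the published pattern's "C12/13" is taken as a
#'     typographical slip for X).}
#' }
#'
#' In `"default"` mode gaps may not contain cysteine; `"paper_strict"`
#' additionally bans tryptophan from gaps.
#'
#' @param mode `"default"` (gaps forbid C) or `"paper_strict"` (forbid C and W).
#' @param include_strain include the optional strain-specific grammar?
#' @return a named list of [cys_grammar()] objects.
#' @export
hfb_grammars <- function(mode = c("default", "paper_strict"), include_strain = FALSE) {
  mode <- match.arg(mode)
  forbid <- if (mode == "paper_strict") c("C", "W") else "C"
  free <- c(0, Inf)
  g <- list(
    typical = cys_grammar(
      "typical",
      leader = c(2, 38),
      gaps = list(c(5, 9), c(0, 0), c(11, 44), c(8, 23), c(5, 9), c(0, 0), c(6, 18)),
      tail = c(2, 14),
      forbid_in_gaps = forbid
    ),
    class_I = cys_grammar(
      "class_I",
      leader = free,
      gaps = list(c(6, 7), c(0, 0), c(33, 41), c(19, 25), c(5, 5), c(0, 0), c(12, 17)),
      tail = free,
      forbid_in_gaps = forbid
    ),
    class_II = cys_grammar(
      "class_II",
      leader = free,
      gaps = list(c(9, 10), c(0, 0), c(11, 11), c(16, 16), c(8, 9), c(0, 0), c(10, 10)),
      tail = free,
      forbid_in_gaps = forbid
    )
  )
  if (include_strain) {
    g$gf_strain <- cys_grammar(
      "gf_strain",
      leader = free,
      gaps = list(c(7, 8), c(0, 0), c(13, 32), c(12, 13), c(5, 6), c(0, 0), c(11, 12)),
      tail = free,
      forbid_in_gaps = forbid
    )
  }
  g
}

#' Read spacing grammars from a YAML file
#'
#' Each top-level entry maps a grammar name to `leader`, `gaps` (list of 7
#' two-element ranges), `tail` and optional `forbid_in_gaps`. `.inf` (YAML)
#' or a missing bound is treated as unbounded.
#'
#' @param path YAML file path.
#' @return a named list of [cys_grammar()] objects.
#' @export
read_grammars <- function(path) {
  if (!file.exists(path)) abort(sprintf("Grammar file not found: %s", path))
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    spec <- raw[[nm]]
    rng <- function(r) {
      r <- unlist(r)
      if (length(r) == 1) r <- c(r, r)
      r[is.na(r)] <- Inf
      as.numeric(r)
    }
    cys_grammar(
      name = nm,
      leader = rng(spec$leader %||% c(0, Inf)),
      gaps = lapply(spec$gaps, rng),
      tail = rng(spec$tail %||% c(0, Inf)),
      forbid_in_gaps = spec$forbid_in_gaps %||% "C"
    )
  })
  setNames(out, names(raw))
}
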