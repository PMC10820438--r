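# Internal validation helpers shared across modules.

AA_CANONICAL <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Round half away from zero
#'
#' Base [round()] rounds half to even; percentage reports here follow the
#' half-up convention so printed two-decimal values match hand arithmetic.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Checks a single amino-acid sequence string; X allowed only when allow_x.
check_aa_sequence <- function(seq, allow_x = TRUE, arg = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq)) {
    abort(sprintf("`%s` must be a single non-NA string.", arg))
  }
  if (nchar(seq) == 0) {
    abort(sprintf("`%s` must be non-empty.", arg))
  }
  allowed <- if (allow_x) c(AA_CANONICAL, "X") else AA_CANONICAL
  letters_seen <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(letters_seen, allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` contains disallowed letters: %s", arg,
      paste(bad, collapse = ", ")
    ))
  }
  invisible(seq)
}

seq_chars <- function(seq) strsplit(seq, "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
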