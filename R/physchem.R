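# Kyte-Doolittle hydropathy values for the 20 canonical residues.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Average residue (monomer minus water) masses in Da.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Bjellqvist pKa table for theoretical pI
#'
#' Side-chain and terminal pKa values as used by the ProtParam service;
#' the N-terminal pKa is residue-specific with a 7.5 default. All values are
#' overridable, e.g. to compare pKa conventions.
#'
#' @param cterm C-terminal carboxyl pKa.
#' @param nterm_default N-terminal pKa for residues without a specific value.
#' @param nterm named numeric vector of residue-specific N-terminal pKa.
#' @param side named numeric vector of ionizable side-chain pKa
#'   (negative groups D, E, C, Y; positive groups H, K, R).
#' @return a list of class `pka_table`.
#' @export
bjellqvist_pka <- function(cterm = 3.55,
                           nterm_default = 7.5,
                           nterm = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36,
                                     T = 6.82, V = 7.44, E = 7.7, G = 7.5),
                           side = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
                                    H = 5.98, K = 10.0, R = 12.0)) {
  vals <- c(cterm, nterm_default, nterm, side)
  if (any(vals <= 0 | vals >= 14)) abort("All pKa values must lie in (0, 14).")
  structure(
    list(cterm = cterm, nterm_default = nterm_default, nterm = nterm, side = side),
    class = "pka_table"
  )
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water; matches 2-decimal Da values
#' from standard protein-parameter services.
#'
#' @param seq amino-acid string (canonical residues only; `X` has no mass and
#'   errors).
#' @return molecular weight in Da (unrounded; round to 2 decimals to report).
#' @examples
#' molecular_weight("G")  # 75.07 Da
#' @export
molecular_weight <- function(seq) {
  check_aa_sequence(seq, allow_x = FALSE)
  sum(AA_AVG_MASS[seq_chars(seq)]) + WATER_MASS
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle value over all residues; positive values indicate a
#' hydrophobic protein.
#'
#' @param seq amino-acid string (canonical residues only).
#' @return GRAVY index in \[-4.5, 4.5\].
#' @examples
#' gravy("IR")  # 0
#' @export
gravy <- function(seq) {
  check_aa_sequence(seq, allow_x = FALSE)
  mean(KD_SCALE[seq_chars(seq)])
}

# Net protein charge at a given pH under the Henderson-Hasselbalch model.
net_charge <- function(seq, pH, pka = bjellqvist_pka()) {
  chars <- seq_chars(seq)
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - pH))
  nt <- pka$nterm[chars[1]]
  if (is.na(nt)) nt <- pka$nterm_default
  charge <- pos_frac(nt) + neg_frac(pka$cterm)
  for (res in c("H", "K", "R")) {
    n <- sum(chars == res)
    if (n > 0) charge <- charge + n * pos_frac(pka$side[[res]])
  }
  for (res in c("D", "E", "C", "Y")) {
    n <- sum(chars == res)
    if (n > 0) charge <- charge + n * neg_frac(pka$side[[res]])
  }
  charge
}

#' Theoretical isoelectric point
#'
#' pH at which the modeled net charge crosses zero, found by bisection on
#' (0, 14) to |charge| < `tol`. The charge function is strictly decreasing in
#' pH, so the root is unique; the termini are always ionizable, so a root
#' always exists in the open interval.
#'
#' @param seq amino-acid string (canonical residues only).
#' @param pka a [bjellqvist_pka()] table.
#' @param tol bisection stopping tolerance on |net charge|.
#' @return pI in pH units (unrounded; report to 2 decimals).
#' @examples
#' theoretical_pi(strrep("K", 10)) > 7  # basic protein
#' @export
theoretical_pi <- function(seq, pka = bjellqvist_pka(), tol = 1e-4) {
  check_aa_sequence(seq, allow_x = FALSE)
  lo <- 0
  hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Counts of charged residues
#'
#' Negatives are D + E, positives K + R; histidine is excluded by the usual
#' protein-parameter convention.
#'
#' @param seq amino-acid string.
#' @return a one-row tibble with `n_negative` and `n_positive`.
#' @examples
#' charged_counts("DEKR")  # 2 and 2
#' @export
charged_counts <- function(seq) {
  check_aa_sequence(seq)
  chars <- seq_chars(seq)
  tibble(
    n_negative = sum(chars %in% c("D", "E")),
    n_positive = sum(chars %in% c("K", "R"))
  )
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Unweighted mean of the scale over a centered window; the profile has
#' `length - window + 1` points.
#'
#' @param seq amino-acid string (canonical residues only).
#' @param window odd window width, at most the sequence length.
#' @return a tibble with `center` (1-based residue position of the window
#'   center) and `score`.
#' @export
hydropathy_profile <- function(seq, window = 9) {
  check_aa_sequence(seq, allow_x = FALSE)
  len <- nchar(seq)
  if (window %% 2 == 0) abort("`window` must be odd.")
  if (window > len) abort("`window` exceeds the sequence length.")
  vals <- KD_SCALE[seq_chars(seq)]
  half <- (window - 1) / 2
  scores <- as.numeric(stats::filter(vals, rep(1 / window, window), sides = 2))
  keep <- (half + 1):(len - half)
  tibble(center = keep, score = scores[keep])
}

#' Physicochemical profile table for a set of proteins
#'
#' Computes, per protein, the descriptor columns of a census
#' characterization table: length, molecular weight, theoretical pI, GRAVY
#' and charged-residue counts.
#'
#' @param proteins a data frame with columns `id` and `sequence`.
#' @param pka a [bjellqvist_pka()] table.
#' @return a tibble with one row per protein: `protein_id`, `length`, `mw`
#'   (Da, 2 decimals), `pi` (2 decimals), `gravy` (3 decimals),
#'   `n_negative`, `n_positive`.
#' @export
physchem_profile <- function(proteins, pka = bjellqvist_pka()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  purrr::map2(proteins$id, proteins$sequence, function(id, s) {
    cc <- charged_counts(s)
    tibble(
      protein_id = id,
      length = nchar(s),
      mw = round_half_up(molecular_weight(s), 2),
      pi = round_half_up(theoretical_pi(s, pka), 2),
      gravy = round_half_up(gravy(s), 3),
      n_negative = cc$n_negative,
      n_positive = cc$n_positive
    )
  }) |>
    list_rbind()
}

#' Plot hydropathy profiles
#'
#' @param proteins a data frame with columns `id` and `sequence`.
#' @param window odd window width passed to [hydropathy_profile()].
#' @return a ggplot object, one panel per protein, with the zero line marked
#'   (scores above zero are hydrophobic stretches).
#' @export
plot_hydropathy <- function(proteins, window = 9) {
  prof <- purrr::map2(proteins$id, proteins$sequence, function(id, s) {
    mutate(hydropathy_profile(s, window), protein_id = id)
  }) |>
    list_rbind()
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$center, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~protein_id, scales = "free_x") +
    ggplot2::labs(
      x = "residue position (window center)",
      y = sprintf("Kyte-Doolittle score (window %d)", window)
    ) +
    ggplot2::theme_minimal()
}
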