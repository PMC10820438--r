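#' Packaged water-contact-angle measurement table
#'
#' Mean WCA readings (degrees, mean over three drop regions with SD) for
#' blank and hydrophobin-coated Teflon film and mica slices, before and
#' after a hot 2% SDS rinse, for the recombinant hydrophobin rGf.hyd9954 and
#' the HGFII-his comparator. These published instrument means are the inputs
#' to [wca_report()].
#'
#' @return a tibble with columns `surface` (`teflon`/`mica`), `condition`
#'   (`blank`/`coated`/`coated_rinsed`), `protein` (id or NA for blanks),
#'   `mean_deg`, `sd_deg`, `n`.
#' @export
gf_wca_measurements <- function() {
  tibble(
    surface = c(
      "teflon", "mica",
      "teflon", "teflon", "mica", "mica",
      "teflon", "teflon", "mica", "mica"
    ),
    condition = c(
      "blank", "blank",
      rep(c("coated", "coated_rinsed"), 4)
    ),
    protein = c(
      NA, NA,
      rep("rGf.hyd9954", 4), rep("HGFII-his", 4)
    ),
    mean_deg = c(
      86.32, 8.86,
      59.48, 62.17, 20.73, 17.43,
      58.40, 71.79, 17.38, 7.22
    ),
    sd_deg = c(
      3.26, 0.63,
      2.47, 4.15, 0.98, 2.19,
      2.71, 2.56, 0.57, 0.45
    ),
    n = 3L
  )
}

check_wca <- function(x, arg) {
  if (any(!is.finite(x)) || any(x < 0 | x > 180)) {
    abort(sprintf("`%s` must be contact angles in [0, 180] degrees.", arg))
  }
  invisible(x)
}

#' Coating-induced wettability alteration
#'
#' Percent change of the water contact angle of a coated surface relative to
#' the blank surface: 100 * |coated - blank| / blank, reported with a
#' direction ("reduced" when the coating lowers the angle, i.e. makes a
#' hydrophobic surface wettable; "increase" when it raises it). Values are
#' rounded half-up to two decimals.
#'
#' @param blank blank-surface WCA in degrees (> 0).
#' @param coated coated-surface WCA in degrees.
#' @return a tibble with `percent` and `direction` (vectorized over inputs).
#' @examples
#' wettability_alteration(86.32, 59.48)  # 31.09% reduced
#' @export
wettability_alteration <- function(blank, coated) {
  check_wca(blank, "blank")
  check_wca(coated, "coated")
  if (any(blank <= 0)) abort("`blank` WCA must be > 0 to form a relative change.")
  tibble(
    percent = round_half_up(100 * abs(coated - blank) / blank, 2),
    direction = dplyr::case_when(
      coated < blank ~ "reduced",
      coated > blank ~ "increase",
      TRUE ~ "unchanged"
    )
  )
}

#' Post-rinse resilience of a coating
#'
#' Percent change magnitude of the coated-surface WCA after an SDS rinse,
#' relative to the pre-rinse coated surface: 100 * |rinsed - coated| /
#' coated, rounded half-up to two decimals, with the direction of change
#' retained. Small values mean the self-assembled film resisted the rinse.
#'
#' @param coated pre-rinse coated-surface WCA in degrees (> 0).
#' @param rinsed post-rinse WCA in degrees.
#' @return a tibble with `percent` and `direction`.
#' @examples
#' rinse_resilience(59.48, 62.17)  # 4.52% increase
#' @export
rinse_resilience <- function(coated, rinsed) {
  check_wca(coated, "coated")
  check_wca(rinsed, "rinsed")
  if (any(coated <= 0)) abort("`coated` WCA must be > 0 to form a relative change.")
  tibble(
    percent = round_half_up(100 * abs(rinsed - coated) / coated, 2),
    direction = dplyr::case_when(
      rinsed < coated ~ "decrease",
      rinsed > coated ~ "increase",
      TRUE ~ "unchanged"
    )
  )
}

#' Wettability and resilience report from a WCA measurement table
#'
#' For each protein and surface, computes the coating-induced wettability
#' alteration relative to the blank surface, and the post-SDS-rinse change
#' relative to the pre-rinse coated surface (denominator conventions carried
#' in the `relative_to` column).
#'
#' @param measurements a tibble shaped like [gf_wca_measurements()].
#' @return a tibble: `protein`, `surface`, `quantity`
#'   (`wettability_alteration`/`rinse_resilience`), `percent`, `direction`,
#'   `relative_to`.
#' @examples
#' wca_report(gf_wca_measurements())
#' @export
wca_report <- function(measurements) {
  need <- c("surface", "condition", "protein", "mean_deg")
  stopifnot(all(need %in% names(measurements)))
  blanks <- measurements |>
    filter(.data$condition == "blank") |>
    select("surface", blank_deg = "mean_deg")
  coated <- measurements |>
    filter(.data$condition == "coated") |>
    left_join(blanks, by = "surface")
  rinsed <- measurements |>
    filter(.data$condition == "coated_rinsed") |>
    select("surface", "protein", rinsed_deg = "mean_deg")

  alt <- coated |>
    mutate(wettability_alteration(.data$blank_deg, .data$mean_deg)) |>
    mutate(quantity = "wettability_alteration", relative_to = "blank") |>
    select("protein", "surface", "quantity", "percent", "direction", "relative_to")

  res <- coated |>
    dplyr::inner_join(rinsed, by = c("surface", "protein")) |>
    mutate(rinse_resilience(.data$mean_deg, .data$rinsed_deg)) |>
    mutate(quantity = "rinse_resilience", relative_to = "coated") |>
    select("protein", "surface", "quantity", "percent", "direction", "relative_to")

  bind_rows(alt, res) |> arrange(.data$protein, .data$surface, .data$quantity)
}
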