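CT_STAGES <- c("Myc", "Pri", "Yfb", "Mfb")

#' Read a qPCR Ct table
#'
#' Expects a TSV with columns `gene`, `stage`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return a validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Ct table not found: %s", path))
  ct <- utils::read.delim(path, stringsAsFactors = FALSE) |> as_tibble()
  validate_ct_table(ct)
}

validate_ct_table <- function(ct) {
  need <- c("gene", "stage", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    abort(sprintf("Ct table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0 | ct$ct >= 45)) {
    abort("All Ct values must lie in (0, 45) cycles.")
  }
  ct
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference) at the same stage and
#' replicate index; ddCt = mean dCt(stage) - mean dCt(calibrator stage);
#' fold = 2^-ddCt. The calibrator-stage fold is exactly 1 by construction on
#' replicate-mean Ct. The standard deviation is reported on the fold scale
#' via the delta method, fold * ln(2) * sd(dCt); amplification efficiency is
#' fixed at 2 (the pure 2^-ddCt model). No multiple-testing correction is
#' applied anywhere in this module; the number of tests performed is carried
#' as the `n_tests` attribute on reports that test.
#'
#' @param ct a Ct tibble (`gene`, `stage`, `replicate`, `ct`).
#' @param ref_gene housekeeping reference gene id (e.g. `"gapdh"`); must be
#'   measured at every stage and replicate used by the targets.
#' @param calibrator calibrator stage (e.g. `"Myc"`, mycelium).
#' @return a tibble of class `hfb_fold_change`: `gene`, `stage`, `fold`,
#'   `log2_fold`, `sd`, `n`.
#' @export
fold_change_ddct <- function(ct, ref_gene = "gapdh", calibrator = "Myc") {
  ct <- validate_ct_table(ct)
  ref <- ct |>
    filter(.data$gene == ref_gene) |>
    select("stage", "replicate", ref_ct = "ct")
  targets <- ct |> filter(.data$gene != ref_gene)
  if (nrow(ref) == 0) abort(sprintf("Reference gene '%s' not present in the table.", ref_gene))

  need_stages <- unique(targets$stage)
  missing_stages <- setdiff(need_stages, unique(ref$stage))
  if (length(missing_stages) > 0) {
    abort(sprintf(
      "Reference gene '%s' has no measurements at stage(s): %s",
      ref_gene, paste(missing_stages, collapse = ", ")
    ))
  }
  dct <- targets |>
    left_join(ref, by = c("stage", "replicate"))
  if (anyNA(dct$ref_ct)) {
    bad <- dct |> filter(is.na(.data$ref_ct))
    abort(sprintf(
      "Reference gene '%s' missing for stage/replicate pair(s): %s",
      ref_gene,
      paste(unique(paste0(bad$stage, "/r", bad$replicate)), collapse = ", ")
    ))
  }
  dct <- dct |> mutate(dct = .data$ct - .data$ref_ct)

  stage_means <- dct |>
    group_by(.data$gene, .data$stage) |>
    summarise(
      mean_dct = mean(.data$dct),
      sd_dct = sd(.data$dct),
      n = dplyr::n(),
      .groups = "drop"
    )
  cal <- stage_means |>
    filter(.data$stage == calibrator) |>
    select("gene", cal_dct = "mean_dct")
  no_cal <- setdiff(unique(stage_means$gene), cal$gene)
  if (length(no_cal) > 0) {
    abort(sprintf(
      "No calibrator-stage ('%s') measurements for gene(s): %s",
      calibrator, paste(no_cal, collapse = ", ")
    ))
  }
  out <- stage_means |>
    left_join(cal, by = "gene") |>
    mutate(
      ddct = .data$mean_dct - .data$cal_dct,
      fold = 2^(-.data$ddct),
      log2_fold = -.data$ddct,
      sd = .data$fold * log(2) * dplyr::coalesce(.data$sd_dct, 0)
    ) |>
    mutate(stage = factor(.data$stage, levels = union(CT_STAGES, unique(.data$stage)))) |>
    arrange(.data$gene, .data$stage) |>
    select("gene", "stage", "fold", "log2_fold", "sd", "n")
  class(out) <- c("hfb_fold_change", class(out))
  attr(out, "ref_gene") <- ref_gene
  attr(out, "calibrator") <- calibrator
  out
}

#' One-way analysis of variance
#'
#' Classical equal-variance between/within F statistic with p-value from the
#' F distribution. Accepts either a tidy data frame (`value`, `group`) or a
#' bare list of numeric vectors. When every observation is identical (zero
#' between- and within-group variance) the F statistic is defined as 0 with
#' p = 1.
#'
#' @param x data frame with columns `value` and `group`, or a list of >= 2
#'   numeric vectors each of length >= 2.
#' @return an object of class `hfb_anova`; use [tidy()]/[glance()].
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7)))
#' @export
one_way_anova <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("value", "group") %in% names(x)))
    groups <- split(x$value, x$group)
  } else if (is.list(x)) {
    groups <- x
  } else {
    abort("`x` must be a data frame (value, group) or a list of numeric vectors.")
  }
  if (length(groups) < 2) abort("Need at least 2 groups.")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("Each group needs at least 2 observations.")
  }
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  df1 <- k - 1L
  df2 <- length(values) - k
  if (isTRUE(all(values == values[1]))) {
    f <- 0
    p <- 1
  } else {
    g <- factor(rep(seq_along(groups), lengths(groups)))
    fit <- oneway.test(values ~ g, var.equal = TRUE)
    f <- unname(fit$statistic)
    p <- fit$p.value
  }
  structure(
    list(statistic = f, p.value = p, df_between = df1, df_within = df2,
         n_groups = k, n_obs = length(values)),
    class = "hfb_anova"
  )
}

#' @export
print.hfb_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
    x$df_between, x$df_within, x$statistic, x$p.value
  ))
  invisible(x)
}

#' @rdname one_way_anova
#' @param x an `hfb_anova` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.hfb_anova <- function(x, ...) {
  tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    statistic = c(x$statistic, NA_real_),
    p.value = c(x$p.value, NA_real_)
  )
}

#' @rdname one_way_anova
#' @exportS3Method generics::glance
glance.hfb_anova <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p.value,
    df_between = x$df_between, df_within = x$df_within,
    n_groups = x$n_groups, n_obs = x$n_obs
  )
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "gap",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Stage-transition expression report
#'
#' For each gene, the fold change of each developmental stage relative to the
#' previous one (ratio of 2^-ddCt folds), with a two-group equal-variance
#' t-test on the replicate dCt values of the two stages. Stars mark p < 0.05
#' (`*`) and p < 0.01 (`**`); transitions across a missing stage are reported
#' as gaps with no ratio. The `n_tests` attribute counts the tests performed
#' (no multiplicity correction is applied).
#'
#' @inheritParams fold_change_ddct
#' @param stages stage order defining "previous stage".
#' @return a tibble: `gene`, `from`, `to`, `ratio`, `log2_ratio`, `p.value`,
#'   `stars`.
#' @export
stage_transition_report <- function(ct, ref_gene = "gapdh", calibrator = "Myc",
                                    stages = CT_STAGES) {
  fc <- fold_change_ddct(ct, ref_gene, calibrator)
  ref <- ct |>
    filter(.data$gene == ref_gene) |>
    select("stage", "replicate", ref_ct = "ct")
  dct <- ct |>
    filter(.data$gene != ref_gene) |>
    left_join(ref, by = c("stage", "replicate")) |>
    mutate(dct = .data$ct - .data$ref_ct)

  rows <- list()
  for (g in unique(fc$gene)) {
    fg <- fc |> filter(.data$gene == g)
    for (k in 2:length(stages)) {
      from <- stages[k - 1]
      to <- stages[k]
      f_from <- fg$fold[fg$stage == from]
      f_to <- fg$fold[fg$stage == to]
      if (length(f_from) == 0 || length(f_to) == 0) {
        rows[[length(rows) + 1]] <- tibble(
          gene = g, from = from, to = to,
          ratio = NA_real_, log2_ratio = NA_real_, p.value = NA_real_
        )
        next
      }
      a <- dct$dct[dct$gene == g & dct$stage == from]
      b <- dct$dct[dct$gene == g & dct$stage == to]
      p <- if (sd(c(a, b)) == 0) 1 else t.test(a, b, var.equal = TRUE)$p.value
      rows[[length(rows) + 1]] <- tibble(
        gene = g, from = from, to = to,
        ratio = f_to / f_from, log2_ratio = log2(f_to / f_from), p.value = p
      )
    }
  }
  out <- list_rbind(rows) |> mutate(stars = significance_stars(.data$p.value))
  attr(out, "n_tests") <- sum(!is.na(out$p.value))
  attr(out, "ref_gene") <- ref_gene
  out
}

#' @rdname fold_change_ddct
#' @param object an `hfb_fold_change` tibble.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hfb_fold_change <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$stage, y = .data$fold)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$fold - .data$sd, 0), ymax = .data$fold + .data$sd),
      width = 0.25
    ) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(
      x = "developmental stage",
      y = sprintf("fold change (2^-ddCt, calibrator %s)",
                  attr(object, "calibrator") %||% "calibrator")
    ) +
    ggplot2::theme_minimal()
}
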