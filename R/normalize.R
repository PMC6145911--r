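#' Percent-of-control normalization and log2 transform
#'
#' Each well's cell number and per-cell ALP activity are expressed as a
#' percentage of the mean over the Non-Targeting control wells of the same
#' plate (so the NT mean is 100% by construction), and the per-cell ALP
#' activity is additionally binary-logarithmized for z-scoring and testing.
#' Wells with `alp_per_cell = 0` would have no logarithm; they receive half
#' the smallest positive measured value on the plate as a pseudocount and
#' are flagged in `log2_pseudocount`.
#'
#' @param wells Annotated well-measurement tibble (columns `plate_id`,
#'   `well`, `gene_symbol`, `role`, `cell_number`, `alp_per_cell`).
#' @param layout Optional plate layout; only needed when `wells` lacks
#'   `role`/`gene_symbol`.
#' @return `wells` with `pct_cell_number`, `pct_alp`, `log2_alp`,
#'   `log2_pseudocount` columns.
#' @export
normalize_to_nt <- function(wells, layout = NULL) {
  if (!is.null(layout)) wells <- annotate_wells(wells, layout)
  stopifnot(all(c("plate_id", "well", "role", "cell_number", "alp_per_cell")
                %in% names(wells)))
  wells |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(function(df, key) {
      nt <- df$role == "non_targeting"
      if (!any(nt)) {
        stop("plate ", key$plate_id, " has no non_targeting wells; ",
             "cannot normalize", call. = FALSE)
      }
      nt_cells <- mean(df$cell_number[nt])
      nt_alp <- mean(df$alp_per_cell[nt], na.rm = TRUE)
      if (!is.finite(nt_cells) || nt_cells == 0 ||
          !is.finite(nt_alp) || nt_alp == 0) {
        stop("plate ", key$plate_id,
             ": Non-Targeting control mean is zero or undefined",
             call. = FALSE)
      }
      eps <- {
        pos <- df$alp_per_cell[!is.na(df$alp_per_cell) & df$alp_per_cell > 0]
        if (length(pos)) min(pos) / 2 else NA_real_
      }
      zero <- !is.na(df$alp_per_cell) & df$alp_per_cell == 0
      df$pct_cell_number <- 100 * df$cell_number / nt_cells
      df$pct_alp <- 100 * df$alp_per_cell / nt_alp
      df$log2_alp <- log2(ifelse(zero, eps, df$alp_per_cell))
      df$log2_pseudocount <- zero
      df
    }) |>
    dplyr::ungroup()
}

#' Per-plate z-score of log2 ALP activity
#'
#' Standardizes `log2_alp` within each plate over the included well roles
#' (sample standard deviation, n-1). The mean z-score of the plate's
#' Non-Targeting wells is attached as `z_nt` so the hit criterion can be
#' centred on the control rather than on zero.
#'
#' @param normalized Output of [normalize_to_nt()].
#' @param include_roles Roles entering the mean/SD pool. The default pools
#'   library, Non-Targeting and positive-control wells; Kif11, mock and
#'   untreated wells are excluded (their ALP is not part of the screened
#'   distribution).
#' @return `normalized` with `z_alp` and `z_nt` columns (z_alp is `NA` for
#'   wells outside the pool, which still get the plate's `z_nt`).
#' @export
zscore_log2 <- function(normalized,
                        include_roles = c("library", "non_targeting",
                                          "positive_control")) {
  normalized |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(function(df, key) {
      inc <- df$role %in% include_roles & !is.na(df$log2_alp)
      if (sum(inc) < 2) {
        stop("plate ", key$plate_id, ": fewer than 2 wells in the z-score pool",
             call. = FALSE)
      }
      mu <- mean(df$log2_alp[inc])
      sdv <- stats::sd(df$log2_alp[inc])
      if (!is.finite(sdv) || sdv == 0) {
        stop("plate ", key$plate_id,
             ": zero variance of log2 ALP in the z-score pool", call. = FALSE)
      }
      df$z_alp <- ifelse(inc, (df$log2_alp - mu) / sdv, NA_real_)
      df$z_nt <- mean(df$z_alp[df$role == "non_targeting"], na.rm = TRUE)
      df
    }) |>
    dplyr::ungroup()
}

#' Two-sample t-test of a gene against the Non-Targeting control
#'
#' Unpaired, homoscedastic (pooled-variance), two-tailed Student's t-test on
#' binary-logarithmized values, as used for replicate hit testing. Two
#' degenerate cases are defined explicitly: both groups constant and equal
#' gives p = 1; both constant but different gives p = 0 (the limit), with a
#' warning.
#'
#' @param gene_values,nt_values Numeric vectors (log2 scale), each of
#'   length >= 2.
#' @return The two-tailed p-value.
#' @export
test_vs_nt <- function(gene_values, nt_values) {
  gene_values <- gene_values[!is.na(gene_values)]
  nt_values <- nt_values[!is.na(nt_values)]
  stopifnot(length(gene_values) >= 2, length(nt_values) >= 2)
  if (stats::sd(gene_values) == 0 && stats::sd(nt_values) == 0) {
    if (gene_values[1] == nt_values[1]) return(1)
    warning("both groups constant but different; p-value is the limit 0",
            call. = FALSE)
    return(0)
  }
  stats::t.test(gene_values, nt_values, var.equal = TRUE,
                alternative = "two.sided")$p.value
}

#' Summarise replicate wells per gene
#'
#' Collapses normalized replicate wells (one well per gene per replicate
#' plate) into per-gene results: mean percent cell number, mean percent ALP,
#' mean z-score, and the pooled-variance t-test p-value of the gene's log2
#' values against all Non-Targeting log2 values of the replicate group.
#' Genes observed on fewer than 2 plates get no p-value.
#'
#' @param normalized Output of [zscore_log2()] for all replicate plates of
#'   one screen.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`, as the screen used unadjusted p-values;
#'   `"BH"` enables Benjamini-Hochberg).
#' @return Tibble with one row per gene: `gene_symbol`, `role`,
#'   `mean_pct_cell_number`, `mean_pct_alp`, `mean_z_alp`, `p_value`,
#'   `n_replicates`, plus the replicate-group `z_nt` mean.
#' @export
summarize_genes <- function(normalized, p_adjust = "none") {
  nt_log2 <- normalized$log2_alp[normalized$role == "non_targeting" &
                                   !is.na(normalized$log2_alp)]
  res <- normalized |>
    dplyr::filter(.data$role %in% c("library", "positive_control")) |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      role = dplyr::first(.data$role),
      mean_pct_cell_number = mean(.data$pct_cell_number),
      mean_pct_alp = mean(.data$pct_alp, na.rm = TRUE),
      mean_z_alp = mean(.data$z_alp, na.rm = TRUE),
      p_value = if (dplyr::n() >= 2 && length(nt_log2) >= 2) {
        test_vs_nt(.data$log2_alp, nt_log2)
      } else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  res$z_nt <- mean(normalized$z_nt[!duplicated(normalized$plate_id)])
  res
}
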