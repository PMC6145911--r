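#' Hit-calling thresholds
#'
#' The three-criterion hit definition of the screen: wells whose cell number
#' drops below 60% of the Non-Targeting mean are excluded as viability
#' casualties; among the rest, a suppressor raises per-cell ALP activity to
#' at least 160% of control and an activator lowers it to at most 40%
#' (an arbitrary +/-60% band around the 100% control), each with an
#' unadjusted p < 0.05; finally the mean z-score of log2 ALP must lie at
#' least `z_margin` above (suppressor) or below (activator) the
#' Non-Targeting wells' mean z-score.
#'
#' @param viability_pct_min Viability exclusion bound (percent of NT mean;
#'   the boundary itself passes).
#' @param alp_pct_up,alp_pct_down Suppressor / activator ALP bounds
#'   (percent, inclusive).
#' @param p_max Significance bound (strict).
#' @param z_margin z-score margin around the Non-Targeting mean z.
#' @return List of class `hit_thresholds`.
#' @export
hit_thresholds <- function(viability_pct_min = 60,
                           alp_pct_up = 160,
                           alp_pct_down = 40,
                           p_max = 0.05,
                           z_margin = 1.0) {
  structure(as.list(environment()), class = "hit_thresholds")
}

#' Call hits from per-gene results
#'
#' Applies the three criteria in order. Genes failing viability are
#' `excluded_viability` regardless of their ALP readout; remaining genes are
#' `suppressor` when `mean_pct_alp >= alp_pct_up`, `p < p_max` and
#' `mean_z_alp >= z_nt + z_margin`; `activator` when
#' `mean_pct_alp <= alp_pct_down`, `p < p_max` and
#' `mean_z_alp <= z_nt - z_margin`; otherwise `not_hit`. A missing p-value
#' (single replicate) can never satisfy the significance criterion, so such
#' genes are `not_hit` with `passed_p = FALSE`.
#'
#' @param results Per-gene tibble from [summarize_genes()] (needs
#'   `gene_symbol`, `mean_pct_cell_number`, `mean_pct_alp`, `mean_z_alp`,
#'   `p_value`, `z_nt`).
#' @param thresholds A [hit_thresholds()].
#' @return `results` with `category` and the four pass flags
#'   (`passed_viability`, `passed_alp_threshold`, `passed_p`, `passed_z`).
#' @export
call_hits <- function(results, thresholds = hit_thresholds()) {
  th <- thresholds
  z_nt <- if ("z_nt" %in% names(results)) results$z_nt else 0
  up <- results$mean_pct_alp >= th$alp_pct_up
  down <- results$mean_pct_alp <= th$alp_pct_down
  passed_viability <- results$mean_pct_cell_number >= th$viability_pct_min
  passed_alp <- up | down
  passed_p <- !is.na(results$p_value) & results$p_value < th$p_max
  passed_z <- (up & results$mean_z_alp >= z_nt + th$z_margin) |
    (down & results$mean_z_alp <= z_nt - th$z_margin)
  category <- dplyr::case_when(
    !passed_viability ~ "excluded_viability",
    up & passed_p & passed_z ~ "suppressor",
    down & passed_p & passed_z ~ "activator",
    TRUE ~ "not_hit"
  )
  dplyr::bind_cols(results,
                   tibble::tibble(category = category,
                                  passed_viability = passed_viability,
                                  passed_alp_threshold = passed_alp,
                                  passed_p = passed_p,
                                  passed_z = passed_z))
}

#' Classify a printed candidate table
#'
#' Applies only the ALP-threshold and p-value criteria to rows of
#' (gene, percent ALP, p-value upper bound) -- the form in which candidate
#' hit lists are published, after the viability and z-score filters have
#' already been applied. Returns the per-row category and per-category
#' counts.
#'
#' @param rows Tibble with columns `gene_symbol`, `pct_alp`, `p_bound`
#'   (the p-value or its printed upper bound, e.g. 0.05 for "<0.05").
#' @param thresholds A [hit_thresholds()].
#' @return List with `rows` (input plus `category`) and `counts` (tibble of
#'   per-category gene counts, all categories present).
#' @export
classify_table <- function(rows, thresholds = hit_thresholds()) {
  stopifnot(all(c("gene_symbol", "pct_alp", "p_bound") %in% names(rows)))
  th <- thresholds
  category <- dplyr::case_when(
    rows$pct_alp >= th$alp_pct_up & rows$p_bound <= th$p_max ~ "suppressor",
    rows$pct_alp <= th$alp_pct_down & rows$p_bound <= th$p_max ~ "activator",
    TRUE ~ "not_hit"
  )
  rows <- dplyr::bind_cols(rows, tibble::tibble(category = category))
  counts <- tibble::tibble(category = c("suppressor", "activator", "not_hit")) |>
    dplyr::left_join(dplyr::count(rows, .data$category), by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  list(rows = rows, counts = counts)
}

#' Published candidate hit list
#'
#' The 65 printed candidate rows (5 suppressor candidates, 60 activator
#' candidates) of the screen's published hit tables, as shipped in
#' `inst/extdata/published_candidates.csv`: gene symbol, percent ALP
#' activity per cell, and the printed p-value upper bound.
#'
#' @return Tibble with columns `gene_symbol`, `pct_alp`, `p_bound`,
#'   `table` (1 = suppressors, 2 = activators).
#' @export
published_candidates <- function() {
  path <- system.file("extdata", "published_candidates.csv",
                      package = "osteoscreen", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    gene_symbol = readr::col_character(),
    pct_alp = readr::col_double(),
    p_bound = readr::col_double(),
    table = readr::col_integer()
  ))
}

#' Full screen analysis of well measurements
#'
#' Chains [normalize_to_nt()], [zscore_log2()], [summarize_genes()] and
#' [call_hits()] and returns everything as one object.
#'
#' @param wells Annotated well-measurement tibble for all replicate plates.
#' @param layout Optional layout for annotation.
#' @param thresholds A [hit_thresholds()].
#' @param p_adjust Multiplicity correction (see [summarize_genes()]).
#' @param include_roles z-score pool (see [zscore_log2()]).
#' @return An object of class `osteo_screen` with elements `wells`
#'   (normalized per-well table), `results` (per-gene), `hits` (per-gene
#'   with categories) and `thresholds`.
#' @export
screen_analysis <- function(wells, layout = NULL,
                            thresholds = hit_thresholds(),
                            p_adjust = "none",
                            include_roles = c("library", "non_targeting",
                                              "positive_control")) {
  normalized <- normalize_to_nt(wells, layout) |>
    zscore_log2(include_roles = include_roles)
  results <- summarize_genes(normalized, p_adjust = p_adjust)
  hits <- call_hits(results, thresholds)
  structure(list(wells = normalized, results = results, hits = hits,
                 thresholds = thresholds),
            class = "osteo_screen")
}

#' @export
print.osteo_screen <- function(x, ...) {
  n <- table(factor(x$hits$category,
                    levels = c("suppressor", "activator",
                               "excluded_viability", "not_hit")))
  cat("osteoblast differentiation screen:",
      nrow(x$hits), "genes on",
      length(unique(x$wells$plate_id)), "plate(s)\n")
  cat(sprintf("  suppressors: %d, activators: %d, excluded (viability): %d, not hits: %d\n",
              n["suppressor"], n["activator"], n["excluded_viability"],
              n["not_hit"]))
  invisible(x)
}

#' Tidy a screen analysis
#'
#' @param x An `osteo_screen` object.
#' @param ... Unused.
#' @method tidy osteo_screen
#' @return The per-gene hit table as a tibble (one row per gene with
#'   normalized means, p-value, z-score, category and pass flags).
#' @export
tidy.osteo_screen <- function(x, ...) {
  tibble::as_tibble(x$hits)
}

#' One-row summary of a screen analysis
#'
#' @param x An `osteo_screen` object.
#' @param ... Unused.
#' @method glance osteo_screen
#' @return One-row tibble: gene and plate counts, hit counts per category,
#'   and the Non-Targeting mean z-score.
#' @export
glance.osteo_screen <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$hits),
    n_plates = length(unique(x$wells$plate_id)),
    n_suppressors = sum(x$hits$category == "suppressor"),
    n_activators = sum(x$hits$category == "activator"),
    n_excluded_viability = sum(x$hits$category == "excluded_viability"),
    z_nt = mean(x$hits$z_nt)
  )
}

#' Write a hit table
#'
#' Comma-separated hit table with the documented column order.
#'
#' @param hits Hit tibble from [call_hits()] or [tidy.osteo_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("gene_symbol", "mean_pct_cell_number", "mean_pct_alp",
            "mean_z_alp", "p_value", "category", "passed_viability",
            "passed_alp_threshold", "passed_p", "passed_z")
  readr::write_csv(hits[cols], path, na = "")
  invisible(path)
}
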