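#' Well roles recognised on a screening plate
#'
#' Treatment roles used throughout the pipeline. `library` wells carry the
#' siRNA library genes; `non_targeting` wells define the 100% baseline for
#' normalization; `positive_control` wells carry known regulators of
#' osteoblast differentiation (Alpl, Il11, Sp7, Runx2); `kif11_control` wells
#' report transfection efficiency via cell loss; `mock` received transfection
#' reagent only and `untreated` received medium only.
#'
#' @return Character vector of valid roles.
#' @export
well_roles <- function() {
  c("library", "non_targeting", "positive_control", "kif11_control",
    "mock", "untreated")
}

roles_needing_gene <- function() c("library", "positive_control", "kif11_control")

#' Validate a plate layout
#'
#' A plate layout is a tibble with one row per annotated well and columns
#' `plate_id`, `well`, `role`, `gene_symbol`, `n_fields_expected` and
#' `replicate_group`. Wells must be unique within a plate and lie on the
#' 384-well grid; `gene_symbol` must be non-empty exactly for roles that
#' target a gene (library, positive_control, kif11_control). A plate without
#' Non-Targeting wells is flagged with a warning here and is fatal only at
#' normalization time.
#'
#' @param layout A plate-layout tibble.
#' @return The layout, invisibly, with canonicalised well addresses.
#' @export
validate_plate_layout <- function(layout) {
  req <- c("plate_id", "well", "role", "gene_symbol")
  missing_cols <- setdiff(req, names(layout))
  if (length(missing_cols)) {
    stop("plate layout is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"n_fields_expected" %in% names(layout)) layout$n_fields_expected <- 15L
  if (!"replicate_group" %in% names(layout)) layout$replicate_group <- layout$plate_id

  layout$well <- parse_well(layout$well)$well
  dup <- layout |>
    dplyr::count(.data$plate_id, .data$well) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicate well address(es): ",
         paste(paste0(dup$plate_id, ":", dup$well), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- !layout$role %in% well_roles()
  if (any(bad_role)) {
    i <- which(bad_role)[1L]
    stop(sprintf("unknown role '%s' in row %d (well %s); valid roles: %s",
                 layout$role[i], i, layout$well[i],
                 paste(well_roles(), collapse = ", ")), call. = FALSE)
  }
  layout$gene_symbol[is.na(layout$gene_symbol)] <- ""
  needs <- layout$role %in% roles_needing_gene()
  if (any(needs & layout$gene_symbol == "")) {
    i <- which(needs & layout$gene_symbol == "")[1L]
    stop(sprintf("row %d (well %s, role %s) requires a gene_symbol",
                 i, layout$well[i], layout$role[i]), call. = FALSE)
  }
  if (any(!needs & layout$gene_symbol != "")) {
    i <- which(!needs & layout$gene_symbol != "")[1L]
    stop(sprintf("row %d (well %s, role %s) must have an empty gene_symbol",
                 i, layout$well[i], layout$role[i]), call. = FALSE)
  }
  no_nt <- layout |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(has_nt = any(.data$role == "non_targeting")) |>
    dplyr::filter(!.data$has_nt)
  if (nrow(no_nt)) {
    warning("plate(s) without non_targeting wells (fatal at normalization): ",
            paste(no_nt$plate_id, collapse = ", "), call. = FALSE)
  }
  invisible(tibble::as_tibble(layout))
}

#' Read a plate map from a delimited file
#'
#' Expects comma-separated columns `well`, `role`, `gene_symbol` and
#' optionally `n_fields_expected`. Returns a validated plate layout.
#'
#' @param path Path to the plate-map CSV.
#' @param plate_id Plate identifier attached to every well (default: file
#'   name without extension).
#' @param replicate_group Replicate group label (default: `plate_id`).
#' @return A validated plate-layout tibble.
#' @export
read_plate_map <- function(path, plate_id = NULL, replicate_group = NULL) {
  if (!file.exists(path)) stop("plate map not found: ", path, call. = FALSE)
  if (is.null(plate_id)) plate_id <- tools::file_path_sans_ext(basename(path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  df$gene_symbol <- if ("gene_symbol" %in% names(df)) {
    dplyr::coalesce(df$gene_symbol, "")
  } else {
    stop("plate map must contain columns well, role, gene_symbol", call. = FALSE)
  }
  df$n_fields_expected <- if ("n_fields_expected" %in% names(df)) {
    as.integer(df$n_fields_expected)
  } else 15L
  df$plate_id <- plate_id
  df$replicate_group <- replicate_group %||% plate_id
  validate_plate_layout(df[c("plate_id", "well", "role", "gene_symbol",
                             "n_fields_expected", "replicate_group")])
  res <- df[c("plate_id", "well", "role", "gene_symbol",
              "n_fields_expected", "replicate_group")]
  res$well <- parse_well(res$well)$well
  tibble::as_tibble(res)
}

#' Write a plate map
#'
#' Emits the columns `well`, `role`, `gene_symbol`, `n_fields_expected`;
#' round-trips losslessly through [read_plate_map()].
#'
#' @param layout A plate-layout tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(layout, path) {
  layout <- validate_plate_layout(layout)
  readr::write_csv(layout[c("well", "role", "gene_symbol", "n_fields_expected")],
                   path)
  invisible(path)
}

#' Default 384-well screen layout
#'
#' The screen targeted 320 library genes on one 384-well plate alongside
#' control wells. The exact control placement was a configurable choice; the
#' default here places the 320 library genes in columns 3--22 (16 rows x 20
#' columns), Non-Targeting controls in column 1, positive controls
#' (Alpl, Il11, Sp7, Runx2) in column 2, and Kif11 transfection controls,
#' mock and untreated wells in columns 23--24.
#'
#' @param genes Character vector of library gene symbols (length <= 320).
#'   Defaults to `g001 ... g320` placeholders.
#' @param plate_id,replicate_group Identifiers for the plate.
#' @param n_fields_expected Fields imaged per well (default 15).
#' @return A validated plate-layout tibble with 384 annotated wells.
#' @export
default_screen_layout <- function(genes = sprintf("g%03d", 1:320),
                                  plate_id = "plate1",
                                  replicate_group = plate_id,
                                  n_fields_expected = 15L) {
  stopifnot(length(genes) <= 320L, !anyDuplicated(genes))
  grid <- expand.grid(col = 1:24, row = 1:16)
  lay <- tibble::tibble(
    plate_id = plate_id,
    well = format_well(grid$row, grid$col),
    role = "untreated",
    gene_symbol = "",
    n_fields_expected = as.integer(n_fields_expected),
    replicate_group = replicate_group,
    row = grid$row, col = grid$col
  )
  lay$role[lay$col == 1L] <- "non_targeting"
  pos <- rep(c("Alpl", "Il11", "Sp7", "Runx2"), each = 4L)
  lay$role[lay$col == 2L] <- "positive_control"
  lay$gene_symbol[lay$col == 2L] <- pos[lay$row[lay$col == 2L]]
  lib_idx <- which(lay$col >= 3L & lay$col <= 22L)
  lib_idx <- lib_idx[order(lay$row[lib_idx], lay$col[lib_idx])]
  lay$role[lib_idx[seq_along(genes)]] <- "library"
  lay$gene_symbol[lib_idx[seq_along(genes)]] <- genes
  lay$role[lay$col == 23L] <- "kif11_control"
  lay$gene_symbol[lay$col == 23L] <- "Kif11"
  lay$role[lay$col == 24L & lay$row <= 8L] <- "mock"
  lay$role[lay$col == 24L & lay$row > 8L] <- "untreated"
  validate_plate_layout(lay[, c("plate_id", "well", "role", "gene_symbol",
                                "n_fields_expected", "replicate_group")])
}

#' Replicate a layout across plates
#'
#' @param layout A single-plate layout.
#' @param n_replicates Number of replicate plates.
#' @return Layout tibble for `n_replicates` plates; plate ids get a
#'   `_r<k>` suffix, all sharing one replicate group.
#' @export
replicate_layout <- function(layout, n_replicates = 3L) {
  base_id <- unique(layout$plate_id)
  stopifnot(length(base_id) == 1L)
  purrr::map_dfr(seq_len(n_replicates), function(k) {
    l <- layout
    l$plate_id <- sprintf("%s_r%d", base_id, k)
    l$replicate_group <- base_id
    l
  })
}
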