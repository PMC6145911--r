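#' Well address utilities for 384-well plates
#'
#' A 384-well plate has 16 rows (letters A--P) and 24 columns (1--24).
#' Addresses are written as row letter plus 1-based column number without zero
#' padding ("A1", not "A01"); the parser accepts both forms, formatting always
#' emits the unpadded form.
#'
#' @param well Character vector of well addresses (e.g. "A1", "P24", "b03").
#' @return `parse_well()` returns a tibble with columns `well` (canonical
#'   form), `row` (1--16) and `col` (1--24). `format_well()` returns a
#'   character vector of canonical addresses.
#' @examples
#' parse_well(c("A1", "p24", "B03"))
#' format_well(2, 3)
#' @export
parse_well <- function(well) {
  well <- as.character(well)
  m <- regmatches(well, regexec("^([A-Pa-p])0*([1-9][0-9]?)$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("invalid well address(es): ", paste(unique(well[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- match(toupper(vapply(m, `[`, "", 2L)), LETTERS[1:16])
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col > 24L)) {
    stop("well column out of range (1-24): ",
         paste(unique(well[col > 24L]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(well = paste0(LETTERS[row], col), row = row, col = col)
}

#' @param row,col Integer row (1--16) and column (1--24) indices.
#' @rdname parse_well
#' @export
format_well <- function(row, col) {
  stopifnot(all(row >= 1 & row <= 16), all(col >= 1 & col <= 24))
  paste0(LETTERS[row], as.integer(col))
}

#' All 384 well addresses in row-major order
#' @return Character vector of length 384 ("A1" ... "P24").
#' @export
all_wells_384 <- function() {
  grid <- expand.grid(col = 1:24, row = 1:16)
  format_well(grid$row, grid$col)
}
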