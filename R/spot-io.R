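#' Build a SpotTable from coordinates
#'
#' @param x_um,y_um,z_um world coordinates in micrometres.
#' @param intensity peak intensities (recycled).
#' @param source one of \code{"conventional"}, \code{"matched"},
#'   \code{"consolidated"}, \code{"truth"}.
#' @param region_id optional region assignment.
#' @param border,out_of_grid logical flags.
#' @return a [SpotTable].
#' @export
spotTable <- function(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), intensity = NA_real_,
                      source = "truth", region_id = NA_integer_,
                      border = FALSE, out_of_grid = FALSE) {
    n <- length(x_um)
    df <- data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                     z_um = as.numeric(z_um),
                     intensity = rep_len(as.numeric(intensity), n),
                     source = rep_len(as.character(source), n),
                     score = rep_len(NA_real_, n),
                     is_cell = rep_len(NA, n),
                     region_id = rep_len(as.integer(region_id), n),
                     border = rep_len(as.logical(border), n),
                     out_of_grid = rep_len(as.logical(out_of_grid), n),
                     stringsAsFactors = FALSE)
    new("SpotTable", spots = df)
}

.spotXYZ <- function(st) as.matrix(spots(st)[, c("x_um", "y_um", "z_um")])

#' Read / write spot tables as CSV
#'
#' Columns: \code{x_um,y_um,z_um,intensity,source,score,is_cell,region_id,
#' border,out_of_grid}; unknown fields are empty.
#'
#' @param st a [SpotTable].
#' @param path CSV path.
#' @return \code{writeSpots} returns \code{path} invisibly; \code{readSpots}
#'   returns a [SpotTable].
#' @export
writeSpots <- function(st, path) {
    write.csv(spots(st), path, row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeSpots
#' @export
readSpots <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(x_um = "numeric", y_um = "numeric",
                                  z_um = "numeric", intensity = "numeric",
                                  source = "character", score = "numeric",
                                  is_cell = "logical",
                                  region_id = "integer",
                                  border = "logical",
                                  out_of_grid = "logical"))
    new("SpotTable", spots = df[, .spotCols, drop = FALSE])
}

#' Subset a SpotTable
#'
#' @param st a [SpotTable].
#' @param i logical or integer row index.
#' @return a [SpotTable].
#' @export
spotSubset <- function(st, i) new("SpotTable",
                                  spots = spots(st)[i, , drop = FALSE])

#' Concatenate SpotTables
#'
#' @param ... [SpotTable] objects.
#' @return a [SpotTable].
#' @export
spotBind <- function(...) {
    new("SpotTable", spots = do.call(rbind, lapply(list(...), spots)))
}
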