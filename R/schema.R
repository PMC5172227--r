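## Shared feature-table schema: the five readouts and their per-cell
## feature sets. Simulated and image-extracted tables use the same columns
## so they are interchangeable downstream.

#' Screen readouts
#'
#' The five readouts profiled per cell: nuclear morphology (DAPI / H2B),
#' 53BP1 foci, gamma-H2AX, p53 and EdU incorporation.
#'
#' @return character vector of readout names.
#' @export
screenReadouts <- function() {
  c("morphology", "b53bp1", "gh2ax", "p53", "edu")
}

#' Per-readout feature sets
#'
#' Morphology carries seven shape/intensity features; 53BP1 three focus
#' features; gamma-H2AX ten features spanning focal to pan-nuclear
#' patterns; p53 and EdU two nuclear-intensity features each.
#'
#' @param readout optional readout name; if given, only that readout's
#'   feature names are returned.
#' @return named list of feature-name vectors, or one character vector.
#' @export
readoutFeatures <- function(readout = NULL) {
  schema <- list(
    morphology = c("integrated_intensity", "average_intensity", "area",
                   "perimeter", "length", "breadth", "form_factor"),
    b53bp1 = c("foci_count", "foci_area", "foci_intensity"),
    gh2ax = c("nuc_integrated", "nuc_average", "min_average", "max_average",
              "foci_count", "foci_area", "foci_intensity", "foci_average",
              "foci_min", "foci_max"),
    p53 = c("average_intensity", "integrated_intensity"),
    edu = c("average_intensity", "integrated_intensity")
  )
  if (is.null(readout)) return(schema)
  if (!readout %in% names(schema))
    stop("unknown readout: ", readout, call. = FALSE)
  schema[[readout]]
}

#' Feature-table column names for a readout
#'
#' @param readout readout name.
#' @return character vector of `<readout>.<feature>` column names.
#' @export
featureColumns <- function(readout) {
  paste(readout, readoutFeatures(readout), sep = ".")
}

#' Key columns of the per-cell feature table
#' @return character vector of the condition-key column names.
#' @export
keyColumns <- function() {
  c("target", "sirna_id", "replicate", "well", "cell_id")
}

## internal: check a feature table carries the keys and a readout's columns
.checkFeatureTable <- function(cells, readout = NULL) {
  need <- keyColumns()
  if (!is.null(readout)) need <- c(need, featureColumns(readout))
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("feature table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
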