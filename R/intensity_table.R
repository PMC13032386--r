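#' Protein-group intensity table
#'
#' The central container of the pipeline: a proteins x samples matrix of
#' raw (linear-scale) intensities with missing values encoded explicitly
#' as \code{NA}, never as 0, plus the gene symbol of each protein group.
#' Row names are protein accessions, column names are sample ids; both
#' must be unique.
#'
#' @param values numeric matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample ids). \code{NA} marks a cell in
#'   which the protein was not detected.
#' @param genes character vector of gene symbols parallel to the rows;
#'   blanks/\code{NA} allowed. Defaults to the accessions.
#' @param scale either \code{"raw"} (linear intensities, the state in which
#'   search engines export the matrix) or \code{"log2"}.
#' @return an object of class \code{intensity_table}: a list with elements
#'   \code{values}, \code{genes} and \code{scale}.
#' @seealso [read_protein_matrix()], [simulate_dataset()]
#' @export
intensity_table <- function(values, genes = NULL, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry protein accessions as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein accession(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s)")
  if (is.null(genes)) genes <- rownames(values)
  genes <- as.character(genes)
  if (length(genes) != nrow(values))
    stop("'genes' must be parallel to the rows of 'values'")
  det <- !is.na(values)
  if (any(!is.finite(values[det])))
    stop("detected intensities must be finite")
  if (scale == "raw" && any(values[det] < 0))
    stop("raw intensities must be non-negative")
  structure(list(values = values, genes = genes, scale = scale),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  det <- detection_mask(x)
  cat(sprintf("intensity_table: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  detected cells: %d/%d (%.1f%%)\n",
              sum(det), length(det), 100 * mean(det)))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

#' Detection mask of an intensity table
#'
#' @param table an \code{intensity_table}
#' @return logical matrix, \code{TRUE} where the protein was detected.
#' @export
detection_mask <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  !is.na(table$values)
}

## internal row/column subsetting that keeps genes aligned
it_subset <- function(table, rows = NULL, cols = NULL) {
  v <- table$values
  g <- table$genes
  if (!is.null(rows)) {
    v <- v[rows, , drop = FALSE]
    g <- g[if (is.character(rows)) match(rows, rownames(table$values)) else rows]
  }
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  out <- intensity_table(v, g, scale = table$scale)
  attr(out, "filter_log") <- attr(table, "filter_log")
  out
}

#' Drop proteins with no detections
#'
#' After filtering, protein groups can lose every remaining detection;
#' such rows carry no information and are removed before imputation.
#'
#' @param table an \code{intensity_table}
#' @return the table without all-missing rows; the number removed is
#'   available as \code{attr(, "n_dropped")}.
#' @export
drop_empty_proteins <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  keep <- rowSums(!is.na(table$values)) > 0L
  out <- it_subset(table, rows = which(keep))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' log2-transform a raw intensity table
#'
#' @param table an \code{intensity_table} on the raw scale
#' @return the same table with \code{log2} values and \code{scale = "log2"}.
#'   Detected values must be strictly positive.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale == "log2") return(table)
  det <- !is.na(table$values)
  if (any(table$values[det] <= 0))
    stop("cannot log2-transform: non-positive detected intensity present")
  v <- table$values
  v[det] <- log2(v[det])
  out <- intensity_table(v, table$genes, scale = "log2")
  attr(out, "filter_log") <- attr(table, "filter_log")
  out
}
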