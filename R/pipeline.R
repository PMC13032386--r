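#' Run the preprocessing pipeline
#'
#' Chains the standard preprocessing of a contaminant-free,
#' QC-passed protein-group matrix: replicate-support filter (Filter 1),
#' optionally the donor-support filter (Filter 2), removal of
#' all-missing proteins, log2 transform, QRILC imputation, per-sample
#' median normalization, and replicate averaging. The post-filter,
#' pre-imputation detection mask is kept alongside the processed values
#' because uniqueness and signature classification must never look at
#' imputed cells.
#'
#' @param table an [intensity_table()] on the raw scale
#' @param meta sample metadata
#' @param filters which filters to apply: subset of \code{c(1, 2)}
#'   (default both)
#' @param min_detected Filter 1 threshold (default 2)
#' @param min_donors Filter 2 threshold (default 2)
#' @param impute run QRILC imputation (default \code{TRUE}; otherwise
#'   missing values are left \code{NA})
#' @param tune_sigma QRILC imputation SD multiplier (default 1)
#' @param normalize per-sample median normalization (default \code{TRUE})
#' @param seed seed for the imputation draws
#' @return list of class \code{fiber_prep}:
#'   \describe{
#'     \item{processed}{\code{processed_matrix} of per-sample log2 values}
#'     \item{averaged}{\code{averaged_matrix} (one column per donor x
#'       subtype) and its metadata}
#'     \item{mask}{post-filter, pre-imputation detection mask}
#'     \item{meta}{per-sample metadata aligned to \code{mask}}
#'     \item{genes}{gene symbols parallel to the retained proteins}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 200, seed = 3))
#' prep <- preprocess_pipeline(sim$table, sim$meta, seed = 3)
#' prep$averaged
#' @export
preprocess_pipeline <- function(table, meta, filters = c(1, 2),
                                min_detected = 2, min_donors = 2,
                                impute = TRUE, tune_sigma = 1,
                                normalize = TRUE, seed = 1) {
  stopifnot(inherits(table, "intensity_table"))
  meta <- align_meta(table, meta)
  if (1 %in% filters)
    table <- filter_replicate_support(table, meta, min_detected = min_detected)
  if (2 %in% filters)
    table <- filter_donor_support(table, meta, min_donors = min_donors)
  table <- drop_empty_proteins(table)
  mask <- detection_mask(table)
  lt <- log2_transform(table)
  pm <- if (impute) impute_qrilc(lt, tune_sigma = tune_sigma, seed = seed)
        else processed_matrix(lt$values, filter_log = attr(lt, "filter_log"))
  if (normalize) pm <- median_normalize(pm)
  avg <- average_replicates(pm, meta)
  structure(list(processed = pm, averaged = avg, mask = mask, meta = meta,
                 genes = table$genes),
            class = "fiber_prep")
}

#' @export
print.fiber_prep <- function(x, ...) {
  cat("fiber_prep pipeline result\n")
  print(x$processed)
  print(x$averaged)
  invisible(x)
}
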