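#' Fit the QRILC censored-normal model to one sample
#'
#' QRILC (quantile regression imputation of left-censored data) treats the
#' observed intensities of a sample as the upper \eqn{(1 - p_{NA})} tail
#' of a complete normal distribution, where \eqn{p_{NA}} is the missing
#' fraction. The complete-distribution mean and SD are estimated by
#' ordinary least squares of the observed empirical quantiles on the
#' corresponding standard-normal quantiles:
#' empirical quantiles are taken at probabilities
#' \eqn{0, 1/\mathrm{grid}, \ldots, q_{up}} of the observed values, and
#' regressed on \eqn{\Phi^{-1}} evaluated on an equally long grid spanning
#' \eqn{[p_{NA}, q_{up}]} of the complete distribution. The intercept is
#' \eqn{\hat\mu}, the slope \eqn{\hat\sigma}, and the censoring threshold
#' is \eqn{\Phi^{-1}(p_{NA}; \hat\mu, \hat\sigma)}.
#'
#' @param x numeric vector (one sample's log2 intensities) with \code{NA}
#'   for missing values
#' @param upper_quantile top of the quantile grid (default 0.99; the
#'   extreme upper tail is left out for robustness)
#' @param grid number of grid points (default 100)
#' @return an object of class \code{qrilc_fit}: list with \code{mu},
#'   \code{sigma}, \code{pna}, \code{threshold}, \code{n_obs}.
#' @seealso [impute_qrilc()]
#' @export
fit_qrilc <- function(x, upper_quantile = 0.99, grid = 100) {
  obs <- x[!is.na(x)]
  pna <- mean(is.na(x))
  if (length(obs) < 30)
    stop("need >= 30 observed values to fit the censored-normal model")
  if (pna >= upper_quantile)
    stop(sprintf("missing fraction (%.2f) >= upper_quantile (%.2f): too censored to fit",
                 pna, upper_quantile))
  p_emp <- seq(0, upper_quantile, length.out = grid)
  q_emp <- stats::quantile(obs, probs = p_emp, names = FALSE, type = 7)
  q_theo <- stats::qnorm(seq(pna, upper_quantile, length.out = grid))
  ok <- is.finite(q_theo) & is.finite(q_emp)  # pna = 0 puts -Inf at the grid start
  q_emp <- q_emp[ok]; q_theo <- q_theo[ok]
  sxx <- sum((q_theo - mean(q_theo))^2)
  if (sxx == 0) stop("degenerate quantile grid")
  sigma <- sum((q_theo - mean(q_theo)) * (q_emp - mean(q_emp))) / sxx
  mu <- mean(q_emp) - sigma * mean(q_theo)
  if (sigma <= 0)
    stop("degenerate column: estimated sigma <= 0 (constant observed values?)")
  threshold <- if (pna > 0) stats::qnorm(pna, mu, sigma) else -Inf
  structure(list(mu = mu, sigma = sigma, pna = pna, threshold = threshold,
                 n_obs = length(obs),
                 upper_quantile = upper_quantile, grid = grid),
            class = "qrilc_fit")
}

#' @export
print.qrilc_fit <- function(x, ...) {
  cat(sprintf(
    "qrilc_fit: mu = %.3f, sigma = %.3f (pNA = %.1f%%, threshold = %.3f, n_obs = %d)\n",
    x$mu, x$sigma, 100 * x$pna, x$threshold, x$n_obs))
  invisible(x)
}

#' @export
coef.qrilc_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

## inverse-CDF draw from N(mu, sd^2) truncated above at 'upper' (exact, seedable)
rtruncnorm_upper <- function(n, mu, sd, upper) {
  p_up <- stats::pnorm(upper, mu, sd)
  if (p_up <= 0) return(rep(upper, n))  # numerically all mass above: pin at bound
  u <- stats::runif(n) * p_up
  pmin(stats::qnorm(u, mu, sd), upper)
}

#' Impute missing values by QRILC
#'
#' Replaces each missing cell of a log2-scale table by a draw from the
#' sample's fitted complete distribution \eqn{N(\hat\mu_j,
#' (\texttt{tune\_sigma}\cdot\hat\sigma_j)^2)} truncated above at that
#' sample's censoring threshold, i.e. from the lower tail below the
#' detection limit. Sampling uses the inverse CDF on the truncated region,
#' so results are exact and reproducible for a given seed.
#'
#' @param table an [intensity_table()] on the log2 scale (or a numeric
#'   matrix of log2 intensities with \code{NA} for missing)
#' @param fits optional named list of [fit_qrilc()] objects per sample;
#'   fitted from the data when \code{NULL}
#' @param tune_sigma multiplier on the fitted SD of the imputation
#'   distribution (default 1)
#' @param seed integer seed for the truncated-normal draws
#' @return a \code{processed_matrix}: list with complete \code{values},
#'   logical \code{imputed_mask} (\code{TRUE} where a value was drawn),
#'   and the per-sample \code{fits}.
#' @export
impute_qrilc <- function(table, fits = NULL, tune_sigma = 1, seed = 1) {
  vals <- if (inherits(table, "intensity_table")) {
    if (table$scale != "log2")
      stop("impute_qrilc expects log2-scale data; call log2_transform() first")
    table$values
  } else table
  stopifnot(is.matrix(vals))
  imputed <- is.na(vals)
  if (is.null(fits)) {
    fits <- lapply(seq_len(ncol(vals)), function(j) {
      if (any(imputed[, j])) fit_qrilc(vals[, j]) else NULL
    })
    names(fits) <- colnames(vals)
  }
  set.seed(seed)
  for (j in seq_len(ncol(vals))) {
    mis <- which(imputed[, j])
    if (!length(mis)) next
    f <- fits[[colnames(vals)[j]]]
    if (is.null(f)) f <- fits[[j]]
    if (is.null(f)) stop("no QRILC fit for sample '", colnames(vals)[j], "'")
    vals[mis, j] <- rtruncnorm_upper(length(mis), f$mu,
                                     tune_sigma * f$sigma, f$threshold)
  }
  processed_matrix(vals, imputed_mask = imputed, fits = fits,
                   filter_log = attr(table, "filter_log"))
}

#' Processed (log2, complete) matrix container
#'
#' @param values log2 intensity matrix (complete after imputation)
#' @param imputed_mask logical matrix, \code{TRUE} where imputed
#' @param offsets per-sample normalization offsets (filled by
#'   [median_normalize()])
#' @param fits per-sample QRILC fits, if imputation was run
#' @param filter_log record of cells blanked by the filters
#' @return object of class \code{processed_matrix}
#' @export
processed_matrix <- function(values, imputed_mask = NULL, offsets = NULL,
                             fits = NULL, filter_log = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(imputed_mask))
    imputed_mask <- matrix(FALSE, nrow(values), ncol(values),
                           dimnames = dimnames(values))
  stopifnot(dim(imputed_mask) == dim(values))
  structure(list(values = values, imputed_mask = imputed_mask,
                 offsets = offsets, fits = fits, filter_log = filter_log),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("processed_matrix: %d proteins x %d samples (log2)\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  imputed cells: %d (%.1f%%); normalized: %s\n",
              sum(x$imputed_mask), 100 * mean(x$imputed_mask),
              if (is.null(x$offsets)) "no" else "yes"))
  invisible(x)
}

#' Median-normalize a log2 matrix
#'
#' Subtracts each sample's median log2 intensity, equalizing loading
#' across samples; after normalization every sample's median is 0. A
#' global variant subtracts the single overall median instead (centers
#' the matrix without changing between-sample differences).
#'
#' @param x a \code{processed_matrix}, or a log2 matrix
#' @param method \code{"per_sample"} (default) or \code{"global"}
#' @return a \code{processed_matrix} with subtracted \code{offsets} stored.
#' @export
median_normalize <- function(x, method = c("per_sample", "global")) {
  method <- match.arg(method)
  pm <- if (inherits(x, "processed_matrix")) x else processed_matrix(x)
  v <- pm$values
  if (method == "per_sample") {
    off <- apply(v, 2, stats::median, na.rm = TRUE)
    v <- sweep(v, 2, off, `-`)
  } else {
    off <- rep(stats::median(v, na.rm = TRUE), ncol(v))
    names(off) <- colnames(v)
    v <- v - off[1]
  }
  processed_matrix(v, pm$imputed_mask, offsets = off, fits = pm$fits,
                   filter_log = pm$filter_log)
}

#' log2 transform plus median normalization
#'
#' Convenience composition used on complete (or not-yet-imputed) data:
#' detected intensities are log2-transformed and per-sample medians
#' subtracted; missing cells stay missing.
#'
#' @param table an [intensity_table()] on the raw scale
#' @param method passed to [median_normalize()]
#' @return a \code{processed_matrix} (may still contain \code{NA} if the
#'   input was incomplete).
#' @export
log2_and_median_normalize <- function(table, method = "per_sample") {
  lt <- log2_transform(table)
  out <- median_normalize(processed_matrix(lt$values,
                                           filter_log = attr(lt, "filter_log")),
                          method = method)
  out
}

#' Average replicates into one column per donor and subtype
#'
#' All downstream group comparisons run on the mean of the replicate
#' columns of each (donor, subtype) pair, reducing technical variation
#' from individual captures.
#'
#' @param x a \code{processed_matrix} or log2 matrix
#' @param meta sample metadata aligned to the columns
#' @return list of class \code{averaged_matrix} with \code{values} (one
#'   column per donor x subtype, named \code{donor_subtype}) and
#'   \code{meta} (sample_id, donor_id, condition, subtype).
#' @export
average_replicates <- function(x, meta) {
  v <- if (inherits(x, "processed_matrix")) x$values else x
  stopifnot(is.matrix(v))
  meta <- validate_sample_metadata(meta)
  i <- match(colnames(v), meta$sample_id)
  if (anyNA(i)) stop("metadata missing sample(s): ",
                     paste(colnames(v)[is.na(i)], collapse = ", "))
  meta <- meta[i, , drop = FALSE]
  key <- paste(meta$donor_id, meta$subtype, sep = "\r")
  groups <- unique(key)
  avg <- matrix(NA_real_, nrow(v), length(groups))
  out_meta <- data.frame(sample_id = character(length(groups)),
                         donor_id = character(length(groups)),
                         condition = character(length(groups)),
                         subtype = character(length(groups)),
                         n_replicates = integer(length(groups)),
                         stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    cols <- which(key == groups[g])
    if (!length(cols)) stop("empty replicate group")
    avg[, g] <- rowMeans(v[, cols, drop = FALSE])
    out_meta$sample_id[g] <- gsub("\r", "_", groups[g])
    out_meta$donor_id[g] <- meta$donor_id[cols[1]]
    out_meta$condition[g] <- meta$condition[cols[1]]
    out_meta$subtype[g] <- meta$subtype[cols[1]]
    out_meta$n_replicates[g] <- length(cols)
  }
  dimnames(avg) <- list(rownames(v), out_meta$sample_id)
  structure(list(values = avg, meta = out_meta), class = "averaged_matrix")
}

#' @export
print.averaged_matrix <- function(x, ...) {
  cat(sprintf("averaged_matrix: %d proteins x %d donor-subtype samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
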