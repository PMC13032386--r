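#' Benjamini-Yekutieli and Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector. The BY
#' procedure multiplies by the harmonic factor
#' \eqn{c(m) = \sum_{i=1}^m 1/i}, which makes it valid under arbitrary
#' dependence of the tests; BH is the same step-up with \eqn{c(m) = 1}.
#' For sorted p-values the adjusted value is
#' \deqn{q_{(i)} = \min_{j \ge i} \min\{1,\; p_{(j)} \, m \, c(m) / j\},}
#' returned in the input order. Consequently \eqn{q \ge p} everywhere and
#' BH never exceeds BY.
#'
#' @param pvalues numeric vector of p-values in \eqn{[0, 1]}
#' @return vector of adjusted q-values, same length and order.
#' @examples
#' adjust_by(c(0.01, 0.02, 0.03))  # all 0.055 = 0.03 * 3 * (11/6) / 3
#' adjust_bh(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
adjust_by <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "BY")
}

#' @rdname adjust_by
#' @export
adjust_bh <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}

check_pvalues <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("p-value(s) outside [0, 1]: ",
         paste(utils::head(p[bad], 3), collapse = ", "))
  invisible(p)
}
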