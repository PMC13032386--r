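#' Row-wise two-sample t-test between conditions
#'
#' Tests each protein for a mean difference between two sample groups on
#' the (averaged, normalized) log2 matrix. The default is the
#' pooled-variance Student t-test; Welch's unequal-variance variant is
#' available. P-values are adjusted with the Benjamini-Yekutieli
#' procedure ([adjust_by()]), which remains valid under the dependence
#' between co-regulated proteins.
#'
#' Degenerate rows follow the convention: zero pooled variance with equal
#' means gives \eqn{t = 0, p = 1}; zero variance with unequal means gives
#' \eqn{p = 0}.
#'
#' @param x an \code{averaged_matrix} (from [average_replicates()]) or a
#'   log2 matrix
#' @param meta metadata with a \code{condition} column; taken from \code{x}
#'   when it is an \code{averaged_matrix}
#' @param group_a,group_b condition labels to compare; fold changes are
#'   \code{mean(group_a) - mean(group_b)} in log2 units
#' @param variant \code{"student"} (pooled variance, default) or
#'   \code{"welch"}
#' @param genes optional gene symbols parallel to the rows
#' @param mask,mask_meta optional pre-imputation detection mask (logical,
#'   per original sample) and its metadata; used to attach the uniqueness
#'   class of each protein (detected only in one condition) — never
#'   derived from imputed values
#' @param q_threshold significance threshold on the BY q-value (default 0.05)
#' @param fc_threshold optional linear fold-change threshold (e.g. 1.5):
#'   significance then additionally requires
#'   \code{|log2fc| >= log2(fc_threshold)}
#' @return a \code{fiber_de} data.frame: protein, gene, group means,
#'   log2fc, statistic, df, p, q, unique_class, significant.
#' @export
ttest_condition <- function(x, meta = NULL, group_a, group_b,
                            variant = c("student", "welch"), genes = NULL,
                            mask = NULL, mask_meta = NULL,
                            q_threshold = 0.05, fc_threshold = NULL) {
  variant <- match.arg(variant)
  if (inherits(x, "averaged_matrix")) {
    if (is.null(meta)) meta <- x$meta
    x <- x$values
  }
  stopifnot(is.matrix(x))
  if (is.null(meta)) stop("metadata required")
  i <- match(colnames(x), meta$sample_id)
  if (anyNA(i)) stop("metadata missing sample(s)")
  cond <- meta$condition[i]
  a <- which(cond == group_a); b <- which(cond == group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 samples per group (", group_a, ": ", length(a),
         ", ", group_b, ": ", length(b), ")")
  na <- length(a); nb <- length(b)
  ma <- rowMeans(x[, a, drop = FALSE])
  mb <- rowMeans(x[, b, drop = FALSE])
  va <- apply(x[, a, drop = FALSE], 1, stats::var)
  vb <- apply(x[, b, drop = FALSE], 1, stats::var)
  diff <- ma - mb
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(x))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- diff / se
  zero_se <- se == 0
  tstat[zero_se & diff == 0] <- 0
  tstat[zero_se & diff != 0] <- sign(diff[zero_se & diff != 0]) * Inf
  df[zero_se] <- na + nb - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  p[zero_se & diff == 0] <- 1
  q <- adjust_by(p)
  if (any(zero_se & diff == 0))
    message(sum(zero_se & diff == 0),
            " protein(s) with zero variance and equal means: p set to 1")
  unique_class <- rep(NA_character_, nrow(x))
  if (!is.null(mask))
    unique_class <- classify_uniques(mask, mask_meta, group_var = "condition",
                                     groups = c(group_a, group_b))[rownames(x)]
  sig <- q < q_threshold
  if (!is.null(fc_threshold)) sig <- sig & abs(diff) >= log2(fc_threshold)
  out <- data.frame(protein = rownames(x),
                    gene = if (is.null(genes)) rownames(x) else genes,
                    mean_a = ma, mean_b = mb, log2fc = diff,
                    statistic = tstat, df = df, p = p, q = q,
                    unique_class = unname(unique_class),
                    significant = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("fiber_de", "data.frame"),
            test = paste0("two-sample t (", variant, "), BY-adjusted"),
            groups = c(a = group_a, b = group_b),
            q_threshold = q_threshold, fc_threshold = fc_threshold)
}

#' Row-wise ANOVA for fiber-subtype effects
#'
#' Fits, per protein, an additive two-way ANOVA \code{value ~ donor +
#' subtype} on the averaged log2 matrix and reports the subtype
#' main-effect F-test (adjusted for donor); with \code{one_way = TRUE}
#' the donor term is dropped. All proteins share one design, so the
#' model is solved once by QR decomposition and applied to every row.
#' P-values are BY-adjusted.
#'
#' @param x an \code{averaged_matrix} or log2 matrix
#' @param meta metadata with \code{subtype} and \code{donor_id} columns
#' @param condition restrict to samples of this condition (e.g. the
#'   disease condition whose subtypes are compared); \code{NULL} uses all
#'   samples passed
#' @param one_way drop the donor term (default \code{FALSE})
#' @param genes optional gene symbols parallel to rows
#' @param q_threshold significance threshold on the q-value (default 0.05)
#' @return a \code{fiber_de} data.frame with per-subtype means, F
#'   statistic, df, p, q and significance flag.
#' @export
anova_subtypes <- function(x, meta = NULL, condition = NULL, one_way = FALSE,
                           genes = NULL, q_threshold = 0.05) {
  if (inherits(x, "averaged_matrix")) {
    if (is.null(meta)) meta <- x$meta
    x <- x$values
  }
  stopifnot(is.matrix(x))
  i <- match(colnames(x), meta$sample_id)
  if (anyNA(i)) stop("metadata missing sample(s)")
  meta <- meta[i, , drop = FALSE]
  if (!is.null(condition)) {
    keep <- meta$condition == condition
    x <- x[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  subtype <- factor(meta$subtype)
  donor <- factor(meta$donor_id)
  if (nlevels(subtype) < 2) stop("need >= 2 subtype levels")
  X_red <- if (one_way) stats::model.matrix(~1, data = meta)
           else stats::model.matrix(~donor)
  X_full <- if (one_way) stats::model.matrix(~subtype)
            else stats::model.matrix(~donor + subtype)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- ncol(x) - ncol(X_full)
  if (df2 < 1) stop("fewer than 1 residual degree of freedom")
  ty <- t(x)
  rss_full <- colSums(stats::lm.fit(X_full, ty)$residuals^2)
  rss_red <- colSums(stats::lm.fit(X_red, ty)$residuals^2)
  ss_eff <- rss_red - rss_full
  Fstat <- (ss_eff / df1) / (rss_full / df2)
  eps <- 1e-12 * pmax(1, rowMeans(x)^2)
  degenerate <- rss_full < eps & ss_eff < eps  # flat rows: F = 0, p = 1
  Fstat[degenerate] <- 0
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[degenerate] <- 1
  q <- adjust_by(p)
  means <- vapply(levels(subtype), function(s)
    rowMeans(x[, subtype == s, drop = FALSE]), numeric(nrow(x)))
  colnames(means) <- paste0("mean_", levels(subtype))
  out <- data.frame(protein = rownames(x),
                    gene = if (is.null(genes)) rownames(x) else genes,
                    means, statistic = Fstat, df1 = df1, df2 = df2,
                    p = p, q = q, significant = q < q_threshold,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  structure(out, class = c("fiber_de", "data.frame"),
            test = paste0(if (one_way) "one-way" else "two-way (subtype + donor)",
                          " ANOVA, BY-adjusted"),
            q_threshold = q_threshold)
}

#' @export
print.fiber_de <- function(x, n = 6, ...) {
  cat("fiber_de:", attr(x, "test"), "\n")
  cat(sprintf("  %d proteins, %d significant at q < %g\n",
              nrow(x), sum(x$significant, na.rm = TRUE),
              attr(x, "q_threshold")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Classify proteins unique to one sample group
#'
#' A protein is unique to group G when it is detected in at least one
#' sample of G and in no sample of any other group, judged on the
#' post-filter, pre-imputation detection mask — imputed values never
#' count as detections.
#'
#' @param mask logical detection matrix (proteins x samples)
#' @param meta metadata aligned to the mask columns
#' @param group_var metadata column defining the groups (default
#'   \code{"condition"})
#' @param groups optional subset/order of group labels to consider
#' @return named character vector per protein: \code{"unique-to-<G>"},
#'   \code{"shared"}, or \code{"none"} (no detections at all).
#' @export
classify_uniques <- function(mask, meta, group_var = "condition",
                             groups = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask))
  i <- match(colnames(mask), meta$sample_id)
  if (anyNA(i)) stop("metadata missing sample(s)")
  g <- meta[[group_var]][i]
  if (is.null(groups)) groups <- unique(g)
  det <- vapply(groups, function(gr)
    rowSums(mask[, g == gr, drop = FALSE]) > 0L, logical(nrow(mask)))
  if (nrow(mask) == 1L) det <- matrix(det, nrow = 1,
                                      dimnames = list(rownames(mask), groups))
  ndet <- rowSums(det)
  out <- rep("shared", nrow(mask))
  out[ndet == 0L] <- "none"
  one <- ndet == 1L
  out[one] <- paste0("unique-to-", groups[apply(det[one, , drop = FALSE], 1,
                                                which.max)])
  names(out) <- rownames(mask)
  out
}

#' PCA summary of sample variation
#'
#' Column-centered principal component analysis over samples of a
#' complete log2 matrix; reports per-component variance fractions and
#' sample scores.
#'
#' @param x an \code{averaged_matrix}, \code{processed_matrix} or matrix
#'   (proteins x samples)
#' @return list of class \code{fiber_pca}: \code{scores} (samples x
#'   components), \code{var_explained} (fractions summing to 1),
#'   \code{sdev}.
#' @export
pca_summary <- function(x) {
  v <- if (inherits(x, c("averaged_matrix", "processed_matrix"))) x$values else x
  stopifnot(is.matrix(v))
  if (ncol(v) < 2) stop("need >= 2 samples")
  if (all(apply(v, 1, stats::var) == 0)) stop("constant matrix: no variation")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, var_explained = ve, sdev = pc$sdev),
            class = "fiber_pca")
}

#' @export
print.fiber_pca <- function(x, ...) {
  k <- min(3, length(x$var_explained))
  cat("fiber_pca:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample log2 ratio of two proteins with a group contrast
#'
#' Computes the per-sample difference of two proteins' log2 values
#' (their log2 expression ratio) — e.g. the fast/slow myosin balance
#' MYH2/MYH7 — and tests it between two conditions with a pooled-variance
#' t-test.
#'
#' @param x an \code{averaged_matrix} or log2 matrix
#' @param meta metadata with a \code{condition} column
#' @param protein_a,protein_b row identifiers: matched against rownames
#'   first, then against \code{genes}
#' @param genes optional gene symbols parallel to rows
#' @param group_a,group_b conditions to contrast (defaults: the two
#'   condition levels in metadata order)
#' @return list of class \code{ratio_contrast}: per-sample \code{ratio},
#'   \code{condition}, group \code{means}, \code{statistic}, \code{p}.
#' @export
ratio_contrast <- function(x, meta = NULL, protein_a = "MYH2",
                           protein_b = "MYH7", genes = NULL,
                           group_a = NULL, group_b = NULL) {
  if (inherits(x, "averaged_matrix")) {
    if (is.null(meta)) meta <- x$meta
    x <- x$values
  }
  find_row <- function(id) {
    i <- match(id, rownames(x))
    if (is.na(i) && !is.null(genes)) i <- match(id, genes)
    if (is.na(i)) stop("protein '", id, "' not found in the matrix")
    i
  }
  ia <- find_row(protein_a); ib <- find_row(protein_b)
  ratio <- x[ia, ] - x[ib, ]
  i <- match(colnames(x), meta$sample_id)
  cond <- meta$condition[i]
  lev <- unique(cond)
  if (is.null(group_a)) group_a <- lev[1]
  if (is.null(group_b)) group_b <- lev[2]
  ra <- ratio[cond == group_a]; rb <- ratio[cond == group_b]
  if (length(ra) < 2 || length(rb) < 2) stop("need >= 2 samples per group")
  sp2 <- ((length(ra) - 1) * stats::var(ra) + (length(rb) - 1) * stats::var(rb)) /
    (length(ra) + length(rb) - 2)
  se <- sqrt(sp2 * (1 / length(ra) + 1 / length(rb)))
  d <- mean(ra) - mean(rb)
  tstat <- if (se == 0 && d == 0) 0 else d / se
  p <- if (se == 0 && d == 0) 1 else
    2 * stats::pt(-abs(tstat), length(ra) + length(rb) - 2)
  structure(list(ratio = ratio, condition = cond,
                 means = stats::setNames(c(mean(ra), mean(rb)),
                                         c(group_a, group_b)),
                 statistic = tstat, p = p,
                 proteins = c(a = protein_a, b = protein_b)),
            class = "ratio_contrast")
}

#' @export
print.ratio_contrast <- function(x, ...) {
  cat(sprintf("ratio_contrast: log2(%s) - log2(%s)\n",
              x$proteins["a"], x$proteins["b"]))
  cat(sprintf("  means: %s = %.3f, %s = %.3f; t = %.3f, p = %.4g\n",
              names(x$means)[1], x$means[1], names(x$means)[2], x$means[2],
              x$statistic, x$p))
  invisible(x)
}
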