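#' Subtype signature patterns of significant proteins
#'
#' Assigns every ANOVA-significant protein the set of fiber subtypes in
#' which it is detected on the post-filter, pre-imputation mask. The
#' pattern (e.g. \code{"eMyH-F&CN-F"}) is the protein's exclusive
#' signature group; per-subtype totals additionally count every
#' significant protein detected in that subtype, whether or not it is
#' also detected elsewhere. Presence/absence defines the groups — not
#' heatmap clustering — because detection after donor-support filtering
#' is reproducible.
#'
#' @param de a \code{fiber_de} from [anova_subtypes()]
#' @param mask logical detection matrix, post-Filter-2 and pre-imputation
#' @param meta metadata aligned to the mask columns
#' @param subtypes subtype labels defining the pattern space (default:
#'   the subtypes present in \code{meta}, in order of appearance)
#' @param q_threshold significance cut on \code{de$q} (default 0.05)
#' @return a \code{signature_table} data.frame (protein, gene, pattern,
#'   n_subtypes) with attributes \code{group_counts} (exclusive, summing
#'   to the number of classified proteins), \code{subtype_totals}
#'   (inclusive) and \code{dropped} (significant proteins with an empty
#'   detection pattern, excluded with a log message).
#' @export
signature_patterns <- function(de, mask, meta, subtypes = NULL,
                               q_threshold = 0.05) {
  stopifnot(inherits(de, "fiber_de"), is.matrix(mask), is.logical(mask))
  i <- match(colnames(mask), meta$sample_id)
  if (anyNA(i)) stop("metadata missing sample(s)")
  meta <- meta[i, , drop = FALSE]
  if (is.null(subtypes)) subtypes <- unique(meta$subtype)
  sig <- de$protein[!is.na(de$q) & de$q < q_threshold]
  sig <- sig[sig %in% rownames(mask)]
  det <- vapply(subtypes, function(s)
    rowSums(mask[sig, meta$subtype == s, drop = FALSE]) > 0L,
    logical(length(sig)))
  if (length(sig) == 1L) det <- matrix(det, nrow = 1,
                                       dimnames = list(sig, subtypes))
  pattern <- apply(det, 1, function(r) paste(subtypes[r], collapse = "&"))
  empty <- pattern == ""
  if (any(empty))
    message(sum(empty), " significant protein(s) with no remaining ",
            "detections excluded from signature classification")
  keep <- !empty
  genes <- de$gene[match(sig, de$protein)]
  out <- data.frame(protein = sig[keep], gene = genes[keep],
                    pattern = unname(pattern[keep]),
                    n_subtypes = rowSums(det)[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  group_counts <- table(factor(out$pattern,
                               levels = pattern_levels(subtypes)))
  subtype_totals <- colSums(det[keep, , drop = FALSE])
  structure(out, class = c("signature_table", "data.frame"),
            subtypes = subtypes,
            group_counts = group_counts,
            subtype_totals = subtype_totals,
            dropped = sig[empty])
}

## canonical pattern labels: all non-empty subsets in subset-size order
pattern_levels <- function(subtypes) {
  out <- character(0)
  for (k in seq_along(subtypes))
    out <- c(out, utils::combn(subtypes, k, FUN = paste, collapse = "&"))
  out
}

#' @export
print.signature_table <- function(x, ...) {
  cat(sprintf("signature_table: %d significant proteins over subtypes %s\n",
              nrow(x), paste(attr(x, "subtypes"), collapse = ", ")))
  gc <- attr(x, "group_counts")
  gc <- gc[gc > 0]
  for (g in names(gc)) cat(sprintf("  %-30s %d\n", g, gc[[g]]))
  invisible(x)
}

#' Venn region counts for 2-5 named sets
#'
#' Exact counts for every intersection region (exclusive regions, by
#' inclusion-exclusion over memberships) plus, per set, the percentage of
#' its members exclusive to it.
#'
#' @param sets named list of 2 to 5 vectors (coerced to unique elements)
#' @return list of class \code{venn_counts} with \code{regions}
#'   (data.frame \code{region}, \code{count}; region labels join set
#'   names with \code{"&"}), \code{members} (elements per region) and
#'   \code{exclusive_pct} (named vector).
#' @export
venn_counts <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  if (length(sets) < 2 || length(sets) > 5)
    stop("venn_counts handles 2-5 sets; report larger collections as a matrix")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L)
    memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  lev <- pattern_levels(names(sets))
  counts <- table(factor(key, levels = lev))
  members <- split(universe, factor(key, levels = lev))
  excl <- vapply(names(sets), function(nm)
    100 * counts[[nm]] / length(sets[[nm]]), numeric(1))
  structure(list(regions = data.frame(region = lev,
                                      count = as.integer(counts),
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 members = members, exclusive_pct = excl),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("venn_counts:\n")
  print.data.frame(x$regions)
  invisible(x)
}

#' Row z-scores with hierarchical ordering
#'
#' Centers and scales each protein row to zero mean and unit variance
#' (the heatmap transform; population SD, i.e. the n-denominator
#' convention, so a row over n samples maps exactly onto standard-normal
#' quantile positions) and orders rows and columns by hierarchical
#' clustering (Euclidean distance, average linkage). Constant rows are
#' set to zero and flagged rather than producing NaN.
#'
#' @param x an \code{averaged_matrix} or matrix
#' @param proteins optional subset of row identifiers (e.g. the
#'   significant signature proteins)
#' @return list of class \code{zscore_matrix}: \code{z} (z-scored rows),
#'   \code{row_order}, \code{col_order}, \code{constant_rows}.
#' @export
zscore_matrix <- function(x, proteins = NULL) {
  v <- if (inherits(x, c("averaged_matrix", "processed_matrix"))) x$values else x
  stopifnot(is.matrix(v))
  if (!is.null(proteins)) {
    miss <- setdiff(proteins, rownames(v))
    if (length(miss)) stop("protein(s) not in matrix: ",
                           paste(utils::head(miss, 3), collapse = ", "))
    v <- v[proteins, , drop = FALSE]
  }
  if (ncol(v) < 2) stop("need >= 2 samples to z-score")
  mu <- rowMeans(v)
  sd <- sqrt(rowMeans((v - mu)^2))  # population SD
  const <- sd == 0
  sd[const] <- 1
  z <- (v - mu) / sd
  z[const, ] <- 0
  row_order <- if (nrow(z) > 2)
    stats::hclust(stats::dist(z), method = "average")$order
  else seq_len(nrow(z))
  col_order <- if (ncol(z) > 2)
    stats::hclust(stats::dist(t(z)), method = "average")$order
  else seq_len(ncol(z))
  structure(list(z = z, row_order = row_order, col_order = col_order,
                 constant_rows = rownames(v)[const]),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("zscore_matrix: %d proteins x %d samples (%d constant row(s))\n",
              nrow(x$z), ncol(x$z), length(x$constant_rows)))
  invisible(x)
}
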