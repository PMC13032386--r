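#' Replicate-support filter (Filter 1)
#'
#' Within each replicate group — the triplicate of one donor and one fiber
#' subtype — a protein detected in fewer than \code{min_detected}
#' replicates is treated as noise and all its detections in that group are
#' blanked. With the default \code{min_detected = 2} this removes counts
#' found in only one replicate of a group.
#'
#' @param table an [intensity_table()]
#' @param meta sample metadata aligned to the table's columns
#' @param min_detected minimum detected replicates for a group to keep its
#'   counts (default 2)
#' @return the filtered table. Cells blanked by the filter are recorded in
#'   \code{attr(, "filter_log")}; the filter never creates detections, so
#'   the output mask is a subset of the input mask, and it is idempotent.
#' @export
filter_replicate_support <- function(table, meta, min_detected = 2) {
  stopifnot(inherits(table, "intensity_table"))
  meta <- align_meta(table, meta)
  vals <- table$values
  grp <- paste(meta$donor_id, meta$subtype, sep = "\r")
  blanked <- 0L
  singletons <- character(0)
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) < min_detected && min_detected > 1)
      singletons <- c(singletons, gsub("\r", " / ", g))
    nd <- rowSums(!is.na(vals[, cols, drop = FALSE]))
    drop <- nd > 0L & nd < min_detected
    if (any(drop)) {
      blanked <- blanked + sum(!is.na(vals[drop, cols, drop = FALSE]))
      vals[drop, cols] <- NA_real_
    }
  }
  if (length(singletons))
    message("replicate group(s) smaller than min_detected, detections removed: ",
            paste(unique(singletons), collapse = "; "))
  out <- intensity_table(vals, table$genes, scale = table$scale)
  attr(out, "filter_log") <- rbind(
    attr(table, "filter_log"),
    data.frame(filter = "replicate_support", cells_blanked = blanked,
               stringsAsFactors = FALSE))
  out
}

#' Donor-support filter (Filter 2)
#'
#' A protein counts as detected in a donor (within one fiber subtype) if
#' at least one replicate survives Filter 1. If fewer than
#' \code{min_donors} donors of a subtype detect the protein, all of that
#' subtype's cells for the protein are blanked. Applied per subtype
#' independently; subtype labels are condition-specific, so conditions are
#' handled independently too.
#'
#' @inheritParams filter_replicate_support
#' @param min_donors minimum number of detecting donors (default 2)
#' @return the filtered table, with \code{attr(, "filter_log")} extended.
#' @export
filter_donor_support <- function(table, meta, min_donors = 2) {
  stopifnot(inherits(table, "intensity_table"))
  meta <- align_meta(table, meta)
  vals <- table$values
  blanked <- 0L
  for (s in unique(meta$subtype)) {
    cols <- which(meta$subtype == s)
    donors <- unique(meta$donor_id[cols])
    if (length(donors) < min_donors && min_donors > 1)
      warning("subtype '", s, "' has fewer than ", min_donors,
              " donors; donor-support rule degenerates there")
    det_by_donor <- vapply(donors, function(d) {
      dc <- cols[meta$donor_id[cols] == d]
      rowSums(!is.na(vals[, dc, drop = FALSE])) > 0L
    }, logical(nrow(vals)))
    if (nrow(vals) == 1L) det_by_donor <- matrix(det_by_donor, nrow = 1)
    ndon <- rowSums(det_by_donor)
    drop <- ndon > 0L & ndon < min_donors
    if (any(drop)) {
      blanked <- blanked + sum(!is.na(vals[drop, cols, drop = FALSE]))
      vals[drop, cols] <- NA_real_
    }
  }
  out <- intensity_table(vals, table$genes, scale = table$scale)
  attr(out, "filter_log") <- rbind(
    attr(table, "filter_log"),
    data.frame(filter = "donor_support", cells_blanked = blanked,
               stringsAsFactors = FALSE))
  out
}

#' Detection rate as a function of protein intensity
#'
#' Ranks proteins by their mean detected log2 intensity, splits them into
#' quantile bins, and reports the detection proportion per bin. On
#' left-censored (MNAR) data the proportion increases with intensity; on
#' completely-at-random missingness it is flat. This profile is the
#' diagnostic that justifies (or not) left-censored imputation.
#'
#' @param table an [intensity_table()]
#' @param n_bins number of quantile bins (default 10)
#' @return data.frame with columns \code{bin}, \code{mean_log2_intensity},
#'   \code{detection_rate}, \code{n_proteins}.
#' @export
detection_intensity_profile <- function(table, n_bins = 10) {
  stopifnot(inherits(table, "intensity_table"))
  det <- !is.na(table$values)
  keep <- rowSums(det) > 0L
  if (!any(keep)) stop("no detected proteins")
  if (sum(keep) < n_bins)
    stop("need at least ", n_bins, " proteins with >= 1 detection")
  v <- table$values[keep, , drop = FALSE]
  d <- det[keep, , drop = FALSE]
  lv <- if (table$scale == "log2") v else log2(v)
  mean_int <- rowSums(lv * d, na.rm = TRUE) / rowSums(d)
  br <- stats::quantile(mean_int, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  bin <- cut(mean_int, breaks = br, labels = FALSE)
  out <- data.frame(bin = seq_len(n_bins),
                    mean_log2_intensity = NA_real_,
                    detection_rate = NA_real_,
                    n_proteins = 0L)
  for (b in seq_len(n_bins)) {
    i <- which(bin == b)
    out$mean_log2_intensity[b] <- mean(mean_int[i])
    out$detection_rate[b] <- mean(d[i, , drop = FALSE])
    out$n_proteins[b] <- length(i)
  }
  out
}
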