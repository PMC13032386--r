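#' Read a protein-group matrix (DIA-NN pg_matrix-style TSV)
#'
#' Expects a wide tab-separated file with one row per protein group: an
#' accession column, optionally a gene-symbol column, and one numeric
#' column per sample. Blank cells, \code{NA}, \code{NaN} and (by default)
#' literal \code{0} are read as "not detected".
#'
#' @param path path to the TSV file
#' @param id_col column name or index holding protein accessions (default 1)
#' @param gene_col column name or index holding gene symbols, or \code{NULL}
#'   if the file has none (default 2)
#' @param zero_as_missing treat literal 0 as missing (default \code{TRUE};
#'   some exports write 0 where the search engine found no reads)
#' @return an [intensity_table()] on the raw scale
#' @export
read_protein_matrix <- function(path, id_col = 1L, gene_col = 2L,
                                zero_as_missing = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  if (ncol(df) < 2L) stop("matrix file needs an id column and >= 1 sample column")
  idx <- function(col) if (is.character(col)) match(col, colnames(df)) else as.integer(col)
  ic <- idx(id_col)
  gc <- if (is.null(gene_col)) NA_integer_ else idx(gene_col)
  if (is.na(ic)) stop("id column not found")
  ids <- trimws(df[[ic]])
  if (anyDuplicated(ids))
    stop("duplicate protein accession(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- if (!is.na(gc)) trimws(df[[gc]]) else ids
  samp_cols <- setdiff(seq_len(ncol(df)), c(ic, gc))
  if (length(samp_cols) < 1L) stop("no sample columns found")
  vals <- matrix(NA_real_, nrow(df), length(samp_cols),
                 dimnames = list(ids, colnames(df)[samp_cols]))
  for (j in seq_along(samp_cols)) {
    raw <- trimws(df[[samp_cols[j]]])
    missing <- raw == "" | toupper(raw) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(raw))
    bad <- !missing & is.na(num)
    if (any(bad))
      stop(sprintf("malformed numeric cell in column '%s', row %d (protein %s): '%s'",
                   colnames(df)[samp_cols[j]], which(bad)[1], ids[which(bad)[1]],
                   raw[which(bad)[1]]))
    if (zero_as_missing) missing <- missing | (!is.na(num) & num == 0)
    num[missing] <- NA_real_
    vals[, j] <- num
  }
  intensity_table(vals, genes, scale = "raw")
}

#' Write a protein-group matrix as TSV
#'
#' Inverse of [read_protein_matrix()]: missing cells are written blank, so
#' a write/read round trip reproduces values and detection mask exactly.
#'
#' @param table an \code{intensity_table}
#' @param path output path
#' @export
write_protein_matrix <- function(table, path) {
  stopifnot(inherits(table, "intensity_table"))
  num <- apply(table$values, 2, function(col)
    ifelse(is.na(col), "", sprintf("%.17g", col)))  # 17 sig. digits: bit-exact round trip
  df <- data.frame(Protein.Group = rownames(table$values),
                   Genes = table$genes,
                   num, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write sample metadata
#'
#' The metadata table must carry the columns \code{sample_id},
#' \code{donor_id}, \code{condition}, \code{subtype} and
#' \code{replicate_index}; \code{(donor_id, subtype, replicate_index)}
#' must be unique.
#'
#' @param path TSV path
#' @return a validated \code{data.frame}
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta a metadata data.frame to write / validate
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(validate_sample_metadata(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_metadata
#' @export
validate_sample_metadata <- function(meta) {
  req <- c("sample_id", "donor_id", "condition", "subtype", "replicate_index")
  miss <- setdiff(req, colnames(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  key <- paste(meta$donor_id, meta$subtype, meta$replicate_index)
  if (anyDuplicated(key))
    stop("(donor_id, subtype, replicate_index) not unique in metadata")
  if (any(meta$replicate_index < 1)) stop("replicate_index must be >= 1")
  meta
}

## align metadata rows to the sample columns of a table; error on mismatch
align_meta <- function(table, meta) {
  meta <- validate_sample_metadata(meta)
  samples <- colnames(table$values)
  i <- match(samples, meta$sample_id)
  if (anyNA(i))
    stop("metadata missing sample(s): ",
         paste(samples[is.na(i)], collapse = ", "))
  meta[i, , drop = FALSE]
}

#' Remove contaminant protein groups
#'
#' Search engines flag contamination (keratins, trypsin, ...) with a
#' dedicated accession prefix; such rows are removed before any analysis.
#'
#' @param table an \code{intensity_table}
#' @param prefix accession prefix marking contaminants (default
#'   \code{"contam"}, matching the "contam sp|..." convention)
#' @param field match the prefix against the \code{"accession"} (default)
#'   or the \code{"gene"} annotation
#' @return the table without contaminant rows; the number removed is in
#'   \code{attr(, "n_contaminants_removed")}.
#' @export
exclude_contaminants <- function(table, prefix = "contam",
                                 field = c("accession", "gene")) {
  stopifnot(inherits(table, "intensity_table"))
  field <- match.arg(field)
  lab <- if (field == "accession") rownames(table$values) else table$genes
  hit <- startsWith(lab, prefix)
  out <- it_subset(table, rows = which(!hit))
  attr(out, "n_contaminants_removed") <- sum(hit)
  if (sum(hit) > 0)
    message(sum(hit), " contaminant protein group(s) removed")
  out
}

#' Exclude low-depth samples
#'
#' A sample whose detected-protein count falls below a fraction of the
#' median per-sample count (default one half) is considered a failed
#' acquisition and removed from both matrix and metadata.
#'
#' @param table an \code{intensity_table}
#' @param meta sample metadata (one row per sample column)
#' @param min_fraction_of_median exclusion threshold relative to the
#'   median per-sample detection count (default 0.5)
#' @return a list with the filtered \code{table}, the matching \code{meta}
#'   and a \code{report} data.frame (sample_id, n_detected, excluded);
#'   replicate groups emptied by the exclusion are listed in
#'   \code{attr(report, "emptied_groups")} and flagged with a warning.
#' @export
qc_exclude_low_depth <- function(table, meta, min_fraction_of_median = 0.5) {
  stopifnot(inherits(table, "intensity_table"))
  meta <- align_meta(table, meta)
  if (ncol(table$values) < 3L) stop("need >= 3 samples for depth QC")
  counts <- colSums(!is.na(table$values))
  cutoff <- min_fraction_of_median * stats::median(counts)
  excl <- counts < cutoff
  report <- data.frame(sample_id = colnames(table$values),
                       n_detected = as.integer(counts),
                       excluded = excl, row.names = NULL,
                       stringsAsFactors = FALSE)
  keep_meta <- meta[!excl, , drop = FALSE]
  grp_before <- unique(paste(meta$donor_id, meta$subtype, sep = "\r"))
  grp_after <- unique(paste(keep_meta$donor_id, keep_meta$subtype, sep = "\r"))
  emptied <- setdiff(grp_before, grp_after)
  attr(report, "emptied_groups") <- gsub("\r", " / ", emptied)
  if (length(emptied))
    warning("depth QC emptied replicate group(s): ",
            paste(gsub("\r", " / ", emptied), collapse = "; "))
  list(table = it_subset(table, cols = which(!excl)),
       meta = keep_meta, report = report)
}
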