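#' Gene sets
#'
#' A named set of gene symbols. Symbols are normalized (uppercased,
#' whitespace-trimmed) and deduplicated at construction so that lists
#' from different sources join cleanly on the symbol.
#'
#' @param members character vector of gene symbols
#' @param name set name
#' @param source optional source label (or vector parallel to members)
#' @return object of class \code{gene_set}
#' @export
gene_set <- function(members, name = "gene_set", source = NULL) {
  m <- normalize_symbols(members)
  if (!is.null(source)) {
    if (length(source) == 1L) source <- rep(source, length(members))
    src <- split(source[m$keep], m$symbols)
    src <- vapply(src, function(s) paste(sort(unique(s)), collapse = ";"),
                  character(1))
  } else src <- NULL
  u <- unique(m$symbols)
  if (!length(u)) stop("gene set '", name, "' is empty after normalization")
  structure(list(name = name, members = u,
                 source = if (is.null(src)) NULL else src[u]),
            class = "gene_set")
}

normalize_symbols <- function(x) {
  s <- toupper(trimws(as.character(x)))
  keep <- !is.na(s) & s != ""
  list(symbols = s[keep], keep = keep)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d symbols\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Union of gene lists with provenance
#'
#' Combines several gene sets (e.g. the aggregation-prone lists from a
#' wet-lab insolubility study and two prion-like-domain predictors) into
#' one deduplicated set, remembering which sources contributed each gene.
#' Idempotent and order-invariant.
#'
#' @param ... \code{gene_set} objects, or a single list of them
#' @param name name of the combined set
#' @return a \code{gene_set} whose \code{source} element records, per
#'   gene, the contributing set names (";"-joined).
#' @export
union_gene_list <- function(..., name = "union") {
  lists <- list(...)
  if (length(lists) == 1L && !inherits(lists[[1]], "gene_set"))
    lists <- lists[[1]]
  if (!length(lists)) stop("no gene lists given")
  stopifnot(all(vapply(lists, inherits, logical(1), "gene_set")))
  genes <- unlist(lapply(lists, `[[`, "members"), use.names = FALSE)
  src <- unlist(lapply(lists, function(l) rep(l$name, length(l$members))),
                use.names = FALSE)
  if (!length(genes)) stop("empty union")
  gene_set(genes, name = name, source = src)
}

#' Read a gene list file
#'
#' Accepts one symbol per line, or a two-column TSV \code{(symbol,
#' source)}; lines starting with \code{#} are skipped.
#'
#' @param path file path
#' @param name set name (default: file name without extension)
#' @return a \code{gene_set}
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & trimws(lines) != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sym <- vapply(parts, `[[`, character(1), 1)
  src <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else name,
                character(1))
  gene_set(sym, name = name, source = src)
}

#' Read gene sets in GMT format
#'
#' Each GMT line is \code{set_name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path GMT file path
#' @return named list of \code{gene_set} objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  out <- lapply(lines, function(l) {
    p <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(p) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_set(p[-(1:2)], name = p[1], source = p[1])
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Annotate signature patterns with a gene set
#'
#' Intersects a [signature_patterns()] table with a gene set (by
#' normalized gene symbol) and summarizes how the set's proteins
#' distribute over the subtype patterns: per-pattern counts and, per
#' subtype, the percentage of its set-member signatures that are unique
#' to it.
#'
#' @param signatures a \code{signature_table}
#' @param set a \code{gene_set}
#' @return list of class \code{annotated_signatures}: \code{table}
#'   (set-member rows of the signature table), \code{pattern_counts},
#'   and \code{subtype_summary} (data.frame subtype, n_in_set,
#'   n_unique, pct_unique).
#' @export
annotate_signatures <- function(signatures, set) {
  stopifnot(inherits(signatures, "signature_table"),
            inherits(set, "gene_set"))
  if (!nrow(signatures)) stop("empty signature table")
  sym <- toupper(trimws(signatures$gene))
  hit <- sym %in% set$members
  tab <- signatures[hit, , drop = FALSE]
  if (!nrow(tab))
    message("gene set '", set$name, "' does not intersect the signatures")
  subtypes <- attr(signatures, "subtypes")
  pattern_counts <- table(factor(tab$pattern, levels = pattern_levels(subtypes)))
  in_sub <- vapply(subtypes, function(s)
    vapply(strsplit(tab$pattern, "&", fixed = TRUE), function(p) s %in% p,
           logical(1)),
    logical(nrow(tab)))
  if (nrow(tab) == 1L) in_sub <- matrix(in_sub, nrow = 1,
                                        dimnames = list(NULL, subtypes))
  n_in_set <- if (nrow(tab)) colSums(in_sub) else
    stats::setNames(integer(length(subtypes)), subtypes)
  n_unique <- vapply(subtypes, function(s) sum(tab$pattern == s), integer(1))
  subtype_summary <- data.frame(subtype = subtypes,
                                n_in_set = as.integer(n_in_set),
                                n_unique = n_unique,
                                pct_unique = ifelse(n_in_set > 0,
                                                    100 * n_unique / n_in_set,
                                                    NA_real_),
                                row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, pattern_counts = pattern_counts,
                 subtype_summary = subtype_summary, set = set$name),
            class = "annotated_signatures")
}

#' @export
print.annotated_signatures <- function(x, ...) {
  cat(sprintf("annotated_signatures: %d signature protein(s) in set '%s'\n",
              nrow(x$table), x$set))
  print.data.frame(x$subtype_summary, digits = 3)
  invisible(x)
}

#' Subtype contrasts within a gene set
#'
#' Restricts the averaged matrix to members of a gene set (e.g.
#' proteasome, lysosome, or ribosome GO terms), tests each for a subtype
#' effect with a one-way ANOVA, and adjusts p-values with
#' Benjamini-Hochberg within the set — the within-category convention,
#' as opposed to the BY adjustment used proteome-wide. Set members not
#' present in the matrix are reported as not detected.
#'
#' @param x an \code{averaged_matrix} or log2 matrix
#' @param meta metadata (with \code{subtype}); taken from \code{x} if an
#'   \code{averaged_matrix}
#' @param set a \code{gene_set}
#' @param genes gene symbols parallel to the matrix rows (taken from the
#'   matrix rownames when \code{NULL})
#' @param mask optional pre-imputation detection mask used to attach the
#'   per-subtype detection pattern
#' @param mask_meta metadata for the mask columns (defaults to \code{meta})
#' @param condition restrict to this condition's samples (passed to
#'   [anova_subtypes()])
#' @param q_threshold BH significance threshold (default 0.05)
#' @return data.frame of class \code{category_contrasts}: gene, protein,
#'   per-subtype means, F, p, BH q, significance, detection pattern
#'   (\code{"not detected"} for absent set members).
#' @export
category_contrasts <- function(x, meta = NULL, set, genes = NULL,
                               mask = NULL, mask_meta = NULL,
                               condition = NULL, q_threshold = 0.05) {
  stopifnot(inherits(set, "gene_set"))
  if (inherits(x, "averaged_matrix")) {
    if (is.null(meta)) meta <- x$meta
    x <- x$values
  }
  if (is.null(genes)) genes <- rownames(x)
  sym <- toupper(trimws(genes))
  idx <- which(sym %in% set$members)
  if (length(idx) < 2)
    stop("fewer than 2 members of '", set$name, "' present in the matrix")
  sub <- x[idx, , drop = FALSE]
  de <- anova_subtypes(sub, meta = meta, condition = condition,
                       one_way = TRUE, genes = genes[idx],
                       q_threshold = q_threshold)
  de$q <- adjust_bh(de$p)   # BH within the set, by convention
  de$significant <- de$q < q_threshold
  de$pattern <- NA_character_
  if (!is.null(mask)) {
    if (is.null(mask_meta)) mask_meta <- meta
    mi <- match(colnames(mask), mask_meta$sample_id)
    msub <- mask_meta$subtype[mi]
    stl <- unique(msub)
    pr <- intersect(de$protein, rownames(mask))
    det <- vapply(stl, function(s)
      rowSums(mask[pr, msub == s, drop = FALSE]) > 0L, logical(length(pr)))
    if (length(pr) == 1L) det <- matrix(det, nrow = 1)
    de$pattern[match(pr, de$protein)] <-
      apply(det, 1, function(r) paste(stl[r], collapse = "&"))
  }
  absent <- setdiff(set$members, sym)
  if (length(absent)) {
    pad <- de[rep(NA_integer_, length(absent)), , drop = FALSE]
    pad$gene <- absent
    pad$protein <- absent
    pad$pattern <- "not detected"
    pad$significant <- FALSE
    de <- rbind(de, pad)
  }
  rownames(de) <- NULL
  structure(de, class = c("category_contrasts", "data.frame"),
            set = set$name, q_threshold = q_threshold)
}

#' Study differential-expression lists
#'
#' A published study's DE gene list, split by direction. When fold
#' changes are supplied, genes below the fold-change threshold (linear
#' scale, default 1.5) are dropped at load. A gene may appear once per
#' direction; a duplicate within a direction is a load error.
#'
#' @param genes character vector of gene symbols
#' @param direction \code{"up"}/\code{"down"} per gene (recycled if length 1)
#' @param fold_change optional linear fold changes per gene
#' @param name study name
#' @param fc_threshold linear fold-change cutoff applied when fold
#'   changes are present (default 1.5)
#' @return object of class \code{study_de_list}: name plus \code{up} and
#'   \code{down} symbol vectors.
#' @export
study_de_list <- function(genes, direction, fold_change = NULL,
                          name = "study", fc_threshold = 1.5) {
  sym <- toupper(trimws(as.character(genes)))
  if (length(direction) == 1L) direction <- rep(direction, length(sym))
  direction <- tolower(direction)
  if (!all(direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  if (!is.null(fold_change)) {
    fc <- abs(as.numeric(fold_change))
    fc[fc < 1 & fc > 0] <- 1 / fc[fc < 1 & fc > 0]  # accept ratios either way up
    keep <- !is.na(fc) & fc >= fc_threshold
    sym <- sym[keep]; direction <- direction[keep]
  }
  dup <- duplicated(paste(sym, direction))
  if (any(dup))
    stop("study '", name, "': duplicate entry for gene(s) ",
         paste(unique(sym[dup]), collapse = ", "))
  both <- intersect(sym[direction == "up"], sym[direction == "down"])
  if (length(both))
    stop("study '", name, "': conflicting directions for gene(s) ",
         paste(both, collapse = ", "))
  structure(list(name = name,
                 up = sym[direction == "up"],
                 down = sym[direction == "down"]),
            class = "study_de_list")
}

#' @export
print.study_de_list <- function(x, ...) {
  cat(sprintf("study_de_list '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' @rdname study_de_list
#' @param path TSV with columns \code{symbol}, \code{direction} and
#'   optionally \code{fold_change}
#' @export
read_study_list <- function(path, name = NULL, fc_threshold = 1.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("symbol", "direction")
  if (!all(req %in% colnames(df)))
    stop("study list needs columns: ", paste(req, collapse = ", "))
  study_de_list(df$symbol, df$direction,
                fold_change = df[["fold_change"]],
                name = name, fc_threshold = fc_threshold)
}

#' Cross-study overlap of DE gene lists
#'
#' Venn-region overlap of several studies' DE lists, computed per
#' direction (up and down separately) by default. A study that reports
#' only one direction is simply absent from the other direction's
#' diagram rather than counted as an empty set. A combined mode pools
#' each study's directions into one signature list.
#'
#' @param studies list of \code{study_de_list} objects (>= 2)
#' @param direction_aware compare up and down lists separately (default
#'   \code{TRUE})
#' @return list of class \code{study_overlap}. Direction-aware: elements
#'   \code{up} and \code{down}, each a [venn_counts()] result (or
#'   \code{NULL} if fewer than 2 studies report that direction).
#'   Combined: a single \code{all} element.
#' @export
cross_study_overlap <- function(studies, direction_aware = TRUE) {
  stopifnot(length(studies) >= 2,
            all(vapply(studies, inherits, logical(1), "study_de_list")))
  nm <- vapply(studies, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("study names must be unique")
  if (direction_aware) {
    per_dir <- function(dir) {
      sets <- lapply(studies, `[[`, dir)
      names(sets) <- nm
      sets <- sets[lengths(sets) > 0]
      if (length(sets) < 2) return(NULL)
      venn_counts(sets)
    }
    out <- list(up = per_dir("up"), down = per_dir("down"))
  } else {
    sets <- lapply(studies, function(s) union(s$up, s$down))
    names(sets) <- nm
    out <- list(all = venn_counts(sets))
  }
  structure(out, class = "study_overlap")
}

#' @export
print.study_overlap <- function(x, ...) {
  for (dir in names(x)) {
    cat("--", dir, "--\n")
    if (is.null(x[[dir]])) cat("  (fewer than 2 studies report this direction)\n")
    else print(x[[dir]])
  }
  invisible(x)
}
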