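#' Construct an omics profile matrix
#'
#' An `omics_matrix` holds one data type's profiles as a numeric matrix with
#' features in rows and samples in columns. Missing measurements are stored as
#' `NA`; the missing mask is simply `is.na()` of the values.
#'
#' @param values Numeric matrix, features x samples. Must carry unique row
#'   (feature) and column (sample) names.
#' @param data_type Free-text label for the data type (e.g. "RNAseq", "miRNA").
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, data_type = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must have row (feature) and column (sample) names")
  dup_f <- unique(fid[duplicated(fid)])
  if (length(dup_f))
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  structure(list(values = values, data_type = data_type),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%.1f%% missing)\n",
              x$data_type, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Read a profile matrix from delimited text
#'
#' Expects a header row of sample IDs and feature IDs in the first column.
#' Cells equal to one of `missing_tokens` become `NA`. Duplicated IDs and
#' ragged rows are hard errors (naming the offending IDs / line).
#'
#' @param path Path to the file.
#' @param delimiter Field separator, default tab.
#' @param missing_tokens Character vector of tokens treated as missing.
#' @param data_type Data-type label attached to the result.
#' @return An [omics_matrix()].
#' @export
read_profile_matrix <- function(path, delimiter = "\t",
                                missing_tokens = c("NA", "NaN", ""),
                                data_type = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty file: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  # tolerate an empty / label cell above the feature-ID column
  sids <- header[-1L]
  dup_s <- unique(sids[duplicated(sids)])
  if (length(dup_s))
    stop("duplicate sample IDs in header: ", paste(dup_s, collapse = ", "))
  ncol_expect <- length(sids) + 1L
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != ncol_expect)
  if (length(bad))
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad[1L] + 1L, ncol_expect, widths[bad[1L]]))
  fids <- vapply(body, `[`, "", 1L)
  dup_f <- unique(fids[duplicated(fids)])
  if (length(dup_f))
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  cells[cells %in% missing_tokens] <- NA_character_
  vals <- suppressWarnings(as.numeric(cells))
  bad_cell <- !is.na(cells) & is.na(vals)
  if (any(bad_cell))
    stop("non-numeric cell value: ", cells[which(bad_cell)[1L]])
  values <- matrix(vals, nrow = length(fids), ncol = length(sids),
                   byrow = TRUE, dimnames = list(fids, sids))
  omics_matrix(values, data_type = data_type)
}

#' Write a profile matrix as delimited text
#'
#' Exact inverse of [read_profile_matrix()]: `NA` cells are written as the
#' first element of `missing_tokens`.
#'
#' @inheritParams read_profile_matrix
#' @param m An [omics_matrix()].
#' @export
write_profile_matrix <- function(m, path, delimiter = "\t",
                                 missing_tokens = c("NA", "NaN", "")) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  txt <- matrix(format(v, trim = TRUE, digits = 15), nrow = nrow(v))
  txt[is.na(v)] <- missing_tokens[1L]
  header <- paste(c("feature_id", colnames(v)), collapse = delimiter)
  rows <- paste(rownames(v),
                apply(txt, 1L, paste, collapse = delimiter),
                sep = delimiter)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Drop features with too many missing values
#'
#' A feature is removed when its missing fraction strictly exceeds
#' `max_missing_fraction` (the conventional ">25% missing" rule at the
#' default). Idempotent.
#'
#' @param m An [omics_matrix()].
#' @param max_missing_fraction Features missing in more than this fraction of
#'   samples are removed. Default 0.25.
#' @export
filter_missing_features <- function(m, max_missing_fraction = 0.25) {
  stopifnot(inherits(m, "omics_matrix"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(m$values))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) warning("all features removed by missingness filter")
  omics_matrix(m$values[keep, , drop = FALSE], data_type = m$data_type)
}

#' Log2 transform and quantile normalization
#'
#' Applies `log2(x + pseudocount)` then quantile normalization across samples:
#' each sample's sorted values are replaced by the across-sample mean of sorted
#' values; tied values receive the mean of the reference values over their rank
#' span. Missing entries are excluded from the quantile computation and stay
#' missing. With a single sample only the log step applies.
#'
#' @param m An [omics_matrix()].
#' @param pseudocount Offset added before the log; use 1 for count-like data,
#'   0 (with `log = FALSE`) for pre-logged data.
#' @param log Apply the log2 step (default `TRUE`).
#' @export
normalize_log2_quantile <- function(m, pseudocount = 1, log = TRUE) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  if (log) {
    if (any(v + pseudocount < 0, na.rm = TRUE))
      stop("negative values under log2 transform; check pseudocount")
    v <- log2(v + pseudocount)
  }
  if (ncol(v) > 1L) {
    vq <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(vq) <- dimnames(v)
    v <- vq
  }
  omics_matrix(v, data_type = m$data_type)
}

#' Drop low-information features
#'
#' Genotype features (dosage-coded 0/1/2) with minor allele frequency at or
#' below `maf_min` are removed; continuous features with zero variance are
#' removed. Rationale: features driven by rare events carry almost no
#' per-sample identity information.
#'
#' @param m An [omics_matrix()].
#' @param kind `"genotype"` (values in 0/1/2/NA) or `"continuous"`.
#' @param maf_min Minor-allele-frequency floor; loci with MAF <= this are
#'   removed. Default 0.05.
#' @export
filter_low_information <- function(m, kind = c("continuous", "genotype"),
                                   maf_min = 0.05) {
  stopifnot(inherits(m, "omics_matrix"))
  kind <- match.arg(kind)
  v <- m$values
  if (kind == "genotype") {
    ok <- is.na(v) | v %in% c(0, 1, 2)
    if (!all(ok)) stop("genotype matrix must contain only 0/1/2/NA dosages")
    p <- rowMeans(v, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep <- !is.na(maf) & maf > maf_min
  } else {
    vv <- apply(v, 1L, stats::var, na.rm = TRUE)
    keep <- !is.na(vv) & vv > 0
  }
  omics_matrix(v[keep, , drop = FALSE], data_type = m$data_type)
}

#' Read a genomic annotation table
#'
#' Four-column delimited text: feature_id, chromosome, position (1-based),
#' strand (`+`, `-` or `*`/unknown).
#'
#' @param path Path to the file.
#' @param delimiter Field separator, default tab.
#' @param header Whether the file has a header row (default `TRUE`).
#' @return A data.frame with columns feature_id, chrom, position, strand.
#' @export
read_annotation <- function(path, delimiter = "\t", header = TRUE) {
  df <- utils::read.table(path, sep = delimiter, header = header,
                          stringsAsFactors = FALSE,
                          col.names = c("feature_id", "chrom", "position",
                                        "strand"))
  genomic_annotation(df$feature_id, df$chrom, df$position, df$strand)
}

#' Construct a genomic annotation table
#'
#' @param feature_id Character vector of unique feature IDs.
#' @param chrom Chromosome names (one convention throughout; "chr1" and "1"
#'   must not be mixed across tables).
#' @param position 1-based TSS or probe coordinate.
#' @param strand `+`, `-` or `*` (unknown); kept for format fidelity, not used
#'   in distance computations.
#' @export
genomic_annotation <- function(feature_id, chrom, position, strand = "*") {
  dup <- unique(feature_id[duplicated(feature_id)])
  if (length(dup))
    stop("duplicate feature IDs in annotation: ", paste(dup, collapse = ", "))
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L))
    stop("positions must be integers >= 1")
  data.frame(feature_id = as.character(feature_id),
             chrom = as.character(chrom),
             position = position,
             strand = rep_len(as.character(strand), length(feature_id)),
             stringsAsFactors = FALSE)
}
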