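#' Normal rank transformation
#'
#' Replaces each non-missing value by the standard-normal quantile of its
#' fractional rank, `qnorm((rank - 0.5) / n)`, with average ranks for ties and
#' `n` the non-missing count. Missing values stay missing. The offset 0.5
#' keeps the extremes finite.
#'
#' @param v Numeric vector, possibly with `NA`.
#' @return Numeric vector of the same length.
#' @export
normal_rank_transform <- function(v) {
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 non-missing values")
  out <- rep(NA_real_, length(v))
  r <- rank(v[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

# row-wise normal rank transform of a features x samples matrix
rank_transform_rows <- function(values) {
  out <- t(apply(values, 1L, function(v) {
    if (sum(!is.na(v)) < 2L) return(rep(NA_real_, length(v)))
    normal_rank_transform(v)
  }))
  dimnames(out) <- dimnames(values)
  out
}

#' Profile similarity matrix over significant cis features
#'
#' The similarity `S(A_i, B_j)` between sample `i` of Type A and sample `j` of
#' Type B is the Pearson correlation between the normal-rank-transformed
#' values of the two profiles over the significant cis feature pairs
#' (pairwise-complete). Each cis feature is oriented by the sign of its
#' Spearman rho (the Type-B row is negated for negative associations, as with
#' methylation-expression pairs), so that oppositely-signed associations
#' reinforce rather than cancel. Entries backed by fewer than `min_overlap`
#' complete features are undefined (`NA`).
#'
#' @param mat_a,mat_b [omics_matrix()] objects.
#' @param cis A `cis_associations` table from [test_cis_associations()]; only
#'   rows with `significant == TRUE` are used.
#' @param min_overlap Minimum complete cis features per entry; default
#'   `max(10, 0.5 * N)` with `N` the number of significant pairs.
#' @return A numeric matrix (class `similarity_matrix`), rows = Type-A
#'   samples, columns = Type-B samples, with attribute `n_cis`.
#' @export
similarity_matrix <- function(mat_a, mat_b, cis, min_overlap = NULL) {
  sig <- cis[cis$significant, , drop = FALSE]
  n_cis <- nrow(sig)
  if (n_cis == 0L)
    stop("no intrinsic barcode: zero significant cis pairs")
  if (is.null(min_overlap)) min_overlap <- max(10, 0.5 * n_cis)
  ta <- rank_transform_rows(
    mat_a$values[match(sig$feature_a, feature_ids(mat_a)), , drop = FALSE])
  tb <- rank_transform_rows(
    mat_b$values[match(sig$feature_b, feature_ids(mat_b)), , drop = FALSE])
  tb <- tb * ifelse(sig$rho < 0, -1, 1)   # orient by association sign
  similarity_from_transformed(ta, tb, min_overlap)
}

# Pearson correlation of columns of ta (N x nA) against columns of tb
# (N x nB), pairwise-complete, entries with < min_overlap defined features
# masked NA. Kept as a pure function of its inputs.
similarity_from_transformed <- function(ta, tb, min_overlap = 1) {
  if (anyNA(ta) || anyNA(tb)) {
    s <- suppressWarnings(stats::cor(ta, tb, use = "pairwise.complete.obs"))
    overlap <- crossprod(!is.na(ta) + 0, !is.na(tb) + 0)
    s[overlap < min_overlap] <- NA_real_
  } else {
    s <- stats::cor(ta, tb)
    if (nrow(ta) < min_overlap) s[] <- NA_real_
  }
  structure(s, n_cis = nrow(ta), class = c("similarity_matrix", "matrix"))
}

#' Export a similarity matrix as TSV
#'
#' @param s A `similarity_matrix`.
#' @param path Output path.
#' @export
write_similarity_matrix <- function(s, path) {
  df <- data.frame(sample_a = rownames(s), as.data.frame(unclass(s)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
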