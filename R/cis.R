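#' Candidate cis feature pairs by genomic proximity
#'
#' Pairs Type-A features with Type-B features on the same chromosome. In
#' `"window"` mode every pair within `window_bp` (inclusive) is a candidate;
#' in `"nearest_tss"` mode each A feature is paired only with the B feature
#' whose position is nearest (ties broken to the lexicographically smaller B
#' feature ID), provided the distance is within the window. Strand is ignored.
#'
#' @param annot_a,annot_b Annotation tables from [genomic_annotation()].
#' @param window_bp Maximum distance in bases (inclusive). Default 1e6.
#' @param mode `"window"` or `"nearest_tss"`.
#' @return A `cis_candidates` data.frame with columns feature_a, feature_b
#'   and a `provenance` attribute.
#' @export
map_candidates_by_proximity <- function(annot_a, annot_b, window_bp = 1e6,
                                        mode = c("window", "nearest_tss")) {
  mode <- match.arg(mode)
  if (nrow(annot_a) == 0L || nrow(annot_b) == 0L)
    stop("annotations must be non-empty")
  chra <- unique(annot_a$chrom)
  chrb <- unique(annot_b$chrom)
  pref_a <- any(grepl("^chr", chra))
  pref_b <- any(grepl("^chr", chrb))
  if (length(intersect(chra, chrb)) == 0L && pref_a != pref_b)
    stop("chromosome naming conventions differ between annotations ",
         "(e.g. 'chr1' vs '1'); harmonize them before mapping")
  out <- list()
  for (ch in intersect(chra, chrb)) {
    a <- annot_a[annot_a$chrom == ch, , drop = FALSE]
    b <- annot_b[annot_b$chrom == ch, , drop = FALSE]
    d <- abs(outer(a$position, b$position, "-"))
    if (mode == "window") {
      hit <- which(d <= window_bp, arr.ind = TRUE)
      if (nrow(hit))
        out[[ch]] <- data.frame(feature_a = a$feature_id[hit[, 1L]],
                                feature_b = b$feature_id[hit[, 2L]],
                                stringsAsFactors = FALSE)
    } else {
      # nearest B per A, lexicographic tie-break on B feature id
      pick <- vapply(seq_len(nrow(a)), function(i) {
        dmin <- min(d[i, ])
        if (dmin > window_bp) return(NA_character_)
        cand <- b$feature_id[d[i, ] == dmin]
        sort(cand)[1L]
      }, "")
      keep <- !is.na(pick)
      if (any(keep))
        out[[ch]] <- data.frame(feature_a = a$feature_id[keep],
                                feature_b = pick[keep],
                                stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_a = character(), feature_b = character(),
               stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  pairs <- unique(pairs)
  structure(pairs, provenance = "proximity", class = c("cis_candidates",
                                                       "data.frame"))
}

#' Candidate cis feature pairs from an explicit map
#'
#' Two-column table of (A feature, B feature) pairs, e.g. miRNA and host gene,
#' or protein and its coding transcript. Duplicated rows collapse to one pair.
#'
#' @param id_map Data.frame or 2-column matrix; first column A feature IDs,
#'   second column B feature IDs.
#' @return A `cis_candidates` data.frame.
#' @export
map_candidates_by_identity <- function(id_map) {
  id_map <- as.data.frame(id_map, stringsAsFactors = FALSE)
  if (ncol(id_map) < 2L) stop("id_map needs two columns")
  pairs <- unique(data.frame(feature_a = as.character(id_map[[1L]]),
                             feature_b = as.character(id_map[[2L]]),
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(pairs, provenance = "explicit", class = c("cis_candidates",
                                                      "data.frame"))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH with monotonicity enforcement; order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Spearman rho + two-sided p for each row pair of two matrices over matched
# columns. t-approximation for n >= 10; exact enumeration for n <= 7;
# t-approximation in between (pairs that small are normally dropped by min_n).
spearman_rows <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  n_used <- rowSums(!is.na(a) & !is.na(b))
  rho <- p <- rep(NA_real_, nrow(a))
  for (i in seq_len(nrow(a))) {
    ok <- !is.na(a[i, ]) & !is.na(b[i, ])
    n <- sum(ok)
    if (n < 3L) next
    x <- rank(a[i, ok])
    y <- rank(b[i, ok])
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx == 0 || sy == 0) next   # constant vector: correlation undefined
    r <- stats::cor(x, y)
    rho[i] <- r
    if (n <= 7L) {
      p[i] <- spearman_exact_p(x, y)
    } else {
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p = pmin(p, 1), n_used = n_used)
}

# exact two-sided permutation p-value for Spearman rho, small n
spearman_exact_p <- function(x, y) {
  n <- length(x)
  perms <- permutations_all(n)
  r_obs <- abs(stats::cor(x, y))
  rs <- apply(perms, 1L, function(pm) abs(stats::cor(x, y[pm])))
  mean(rs >= r_obs - 1e-12)
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  k <- 1L
  for (i in seq_len(n)) {
    block <- cbind(rep.int(i, nrow(sub)),
                   matrix(seq_len(n)[-i][sub], nrow(sub)))
    out[k:(k + nrow(sub) - 1L), ] <- block
    k <- k + nrow(sub)
  }
  out
}

#' Test candidate cis-associations by Spearman correlation with BH control
#'
#' For each candidate feature pair, the Spearman correlation and two-sided
#' p-value are computed over pairwise-complete matched samples; BH adjustment
#' is applied across all tested pairs and pairs with q below `alpha` are
#' flagged significant. Pairs with fewer than `min_n` complete samples, or a
#' constant vector, are dropped with a reason.
#'
#' @param mat_a,mat_b [omics_matrix()] objects for the two data types.
#' @param candidates A `cis_candidates` table.
#' @param matched_pairs Data.frame with columns sample_a, sample_b giving the
#'   currently matched sample pairs.
#' @param alpha Significance level on the BH q-value. Default 0.05.
#' @param min_n Minimum complete sample pairs per feature pair. Default 10.
#' @return A `cis_associations` data.frame with columns feature_a, feature_b,
#'   rho, p, q, n_used, significant; dropped pairs in attribute `"dropped"`.
#' @export
test_cis_associations <- function(mat_a, mat_b, candidates, matched_pairs,
                                  alpha = 0.05, min_n = 10L) {
  stopifnot(inherits(mat_a, "omics_matrix"), inherits(mat_b, "omics_matrix"))
  if (nrow(candidates) == 0L) stop("no candidate pairs")
  if (nrow(matched_pairs) == 0L) stop("no matched sample pairs")
  ia <- match(matched_pairs$sample_a, sample_ids(mat_a))
  ib <- match(matched_pairs$sample_b, sample_ids(mat_b))
  if (anyNA(ia) || anyNA(ib)) stop("matched pair sample ID not found")
  if (length(ia) < min_n)
    stop("fewer than min_n matched samples overall")
  fa <- match(candidates$feature_a, feature_ids(mat_a))
  fb <- match(candidates$feature_b, feature_ids(mat_b))
  resolvable <- !is.na(fa) & !is.na(fb)
  a <- mat_a$values[fa[resolvable], ia, drop = FALSE]
  b <- mat_b$values[fb[resolvable], ib, drop = FALSE]
  sp <- spearman_rows(a, b)
  res <- data.frame(feature_a = candidates$feature_a[resolvable],
                    feature_b = candidates$feature_b[resolvable],
                    rho = sp$rho, p = sp$p, n_used = sp$n_used,
                    stringsAsFactors = FALSE)
  drop_reason <- rep(NA_character_, nrow(res))
  drop_reason[is.na(res$rho) & res$n_used >= min_n] <- "zero variance"
  drop_reason[res$n_used < min_n] <- "insufficient overlap"
  dropped <- data.frame(feature_a = c(candidates$feature_a[!resolvable],
                                      res$feature_a[!is.na(drop_reason)]),
                        feature_b = c(candidates$feature_b[!resolvable],
                                      res$feature_b[!is.na(drop_reason)]),
                        reason = c(rep("unresolvable ID", sum(!resolvable)),
                                   drop_reason[!is.na(drop_reason)]),
                        stringsAsFactors = FALSE)
  res <- res[is.na(drop_reason), , drop = FALSE]
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < alpha
  rownames(res) <- NULL
  structure(res, dropped = dropped, alpha = alpha,
            class = c("cis_associations", "data.frame"))
}
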