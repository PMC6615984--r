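#' Rank-based self/cross alignment
#'
#' The rank matcher annotates the candidate pair (i, i) as self-aligned when
#' its similarity score ranks within the top k of its row and of its column,
#' where k = `ceiling(top_frac * n)` for n <= `cap_threshold` samples and
#' `top_cap` otherwise. Among profiles left unaligned, (i, j) is cross-aligned
#' when its score is rank 1 in both its full row and full column (reciprocal
#' best match). Tied scores occupy the best tied rank.
#'
#' @param s A `similarity_matrix` (row names = Type-A sample IDs, column names
#'   = Type-B sample IDs; shared IDs define the candidate self pairs).
#' @param top_frac Fraction defining the self-alignment rank threshold.
#'   Default 0.05.
#' @param top_cap Absolute rank threshold used for large sample sizes.
#'   Default 20.
#' @param cap_threshold Sample size above which `top_cap` replaces the
#'   fractional rule. Default 400.
#' @return An `alignment_result` data.frame: sample_a, sample_b, status
#'   (self_aligned / cross_aligned / unaligned), score, rank_row, rank_col.
#' @export
match_by_rank <- function(s, top_frac = 0.05, top_cap = 20,
                          cap_threshold = 400) {
  if (nrow(s) < 2L || ncol(s) < 2L) stop("similarity matrix too small")
  ra <- rownames(s); cb <- colnames(s)
  selfs <- intersect(ra, cb)
  if (length(selfs) == 0L) stop("no candidate self pairs (no shared IDs)")
  nb <- ncol(s); na_ <- nrow(s)
  k_row <- if (nb > cap_threshold) top_cap else ceiling(top_frac * nb)
  k_col <- if (na_ > cap_threshold) top_cap else ceiling(top_frac * na_)
  # rank 1 = highest score; ties take the best tied rank (favors alignment)
  rank_row <- t(apply(-s, 1L, rank, ties.method = "min", na.last = "keep"))
  rank_col <- apply(-s, 2L, rank, ties.method = "min", na.last = "keep")
  res <- data.frame(sample_a = selfs, sample_b = selfs,
                    status = "unaligned", score = NA_real_,
                    rank_row = NA_real_, rank_col = NA_real_,
                    stringsAsFactors = FALSE)
  for (t in seq_along(selfs)) {
    i <- match(selfs[t], ra); j <- match(selfs[t], cb)
    sc <- s[i, j]
    res$score[t] <- sc
    if (is.na(sc)) next   # undefined diagonal entry stays unaligned
    rr <- rank_row[i, j]; rc <- rank_col[i, j]
    res$rank_row[t] <- rr; res$rank_col[t] <- rc
    if (rr <= k_row && rc <= k_col) res$status[t] <- "self_aligned"
  }
  # reciprocal best match among profiles not self-aligned
  aligned_a <- res$sample_a[res$status == "self_aligned"]
  aligned_b <- res$sample_b[res$status == "self_aligned"]
  free_a <- setdiff(ra, aligned_a)
  free_b <- setdiff(cb, aligned_b)
  cross <- list()
  for (an in free_a) {
    i <- match(an, ra)
    j <- which(rank_row[i, ] == 1L)
    if (length(j) != 1L) next          # tie: conservative, no alignment
    if (!(cb[j] %in% free_b)) next
    if (an %in% cb && cb[j] == an) next  # that's the self pair, already judged
    if (is.na(rank_col[i, j]) || rank_col[i, j] != 1L) next
    if (sum(rank_col[, j] == 1L, na.rm = TRUE) != 1L) next
    cross[[length(cross) + 1L]] <- data.frame(
      sample_a = an, sample_b = cb[j], status = "cross_aligned",
      score = s[i, j], rank_row = 1, rank_col = 1,
      stringsAsFactors = FALSE)
  }
  if (length(cross)) {
    cross <- do.call(rbind, cross)
    hit <- match(cross$sample_a, res$sample_a)
    replace <- !is.na(hit)
    res[hit[replace], ] <- cross[replace, ]
    if (any(!replace)) res <- rbind(res, cross[!replace, , drop = FALSE])
  }
  rownames(res) <- NULL
  structure(res, method = "rank", class = c("alignment_result", "data.frame"))
}
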