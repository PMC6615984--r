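#' Configuration for the probabilistic matcher
#'
#' @param p0 Prior probability of self-alignment; `NULL` (default) means
#'   `1 / N_s` with `N_s` the number of candidate self pairs.
#' @param self_cutoff,cross_cutoff Optional overrides of the similarity-score
#'   floors; `NULL` means estimate them from the self-self scores via
#'   [compute_cutoffs()].
#' @param rescue_rank Rank threshold for the rescue step (the pair's p-value
#'   must be at or below the `rescue_rank`-th smallest of its row and of its
#'   column). Default 5.
#' @param n_permuted Number of permuted pseudo-profile pairs augmenting each
#'   score cloud. Default 1000.
#' @param max_iter Maximum alignment iterations. Default 20.
#' @param seed Integer seed controlling the permutation augmentation.
#' @export
match_config <- function(p0 = NULL, self_cutoff = NULL, cross_cutoff = NULL,
                         rescue_rank = 5L, n_permuted = 1000L,
                         max_iter = 20L, seed = 1L) {
  if (!is.null(p0) && (p0 <= 0 || p0 > 1)) stop("p0 must be in (0, 1]")
  structure(list(p0 = p0, self_cutoff = self_cutoff,
                 cross_cutoff = cross_cutoff,
                 rescue_rank = as.integer(rescue_rank),
                 n_permuted = as.integer(n_permuted),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "match_config")
}

#' Similarity-score cutoffs from the self-self score distribution
#'
#' The self-alignment floor is the lower bound of the central 99% of the
#' self-self similarity scores (mean - 2.576 sd) and the cross-alignment floor
#' the lower bound of the central 68% (mean - 1 sd). The cross floor is the
#' higher of the two: moving a profile to another sample demands stronger
#' score evidence than confirming its annotated identity.
#'
#' @param self_scores Numeric vector of self-self similarity scores.
#' @return Named list with `self_cutoff` and `cross_cutoff`.
#' @export
compute_cutoffs <- function(self_scores) {
  self_scores <- self_scores[!is.na(self_scores)]
  if (length(self_scores) < 10L) stop("need at least 10 self scores")
  m <- mean(self_scores)
  s <- stats::sd(self_scores)
  if (s == 0) {
    warning("self scores have zero spread; cutoffs collapse to the mean")
    return(list(self_cutoff = m, cross_cutoff = m))
  }
  list(self_cutoff = m - 2.576 * s, cross_cutoff = m - 1 * s)
}

# Permuted pseudo-profile scores. For K pseudo-profiles, each cis feature's
# values over the matched samples are independently permuted (fresh
# permutation per feature per block of matched-sample size), destroying the
# cis structure while preserving marginals. Returns
#   pa: n_A x K scores S(A_i, Btilde_k)
#   pb: K x n_B scores S(Atilde_k, B_j)
permuted_scores <- function(ta, tb, cols_a, cols_b, n_permuted, seed) {
  if (n_permuted == 0L)
    return(list(pa = matrix(numeric(0), ncol(ta), 0),
                pb = matrix(numeric(0), 0, ncol(tb))))
  set.seed(seed)
  pseudo <- function(tm, cols, K) {
    sub <- tm[, cols, drop = FALSE]
    n <- nrow(sub); m <- ncol(sub)
    blocks <- ceiling(K / m)
    idx <- matrix(NA_integer_, n, blocks * m)
    for (b in seq_len(blocks)) {
      keys <- matrix(stats::runif(n * m), n, m)
      ord <- order(row(keys), keys)          # per-row permutation, one pass
      idx[, ((b - 1L) * m + 1L):(b * m)] <- matrix(col(keys)[ord], n, m,
                                                   byrow = TRUE)
    }
    idx <- idx[, seq_len(K), drop = FALSE]
    matrix(sub[cbind(rep(seq_len(n), K), as.vector(idx))], n, K)
  }
  btil <- pseudo(tb, cols_b, n_permuted)
  atil <- pseudo(ta, cols_a, n_permuted)
  pa <- unclass(similarity_from_transformed(ta, btil, 1))
  pb <- unclass(similarity_from_transformed(atil, tb, 1))
  list(pa = pa, pb = pb)
}

#' Fit the bivariate-normal score model for one profile pair
#'
#' The reference cloud for pair (i, j) consists of the 2-D points
#' `(S(A_i, B_m), S(A_m, B_j))` over the currently matched profile pairs `m`
#' (excluding the pairs containing `i` or `j`), augmented with `n_permuted`
#' points scored against permuted pseudo-profiles. The model is the sample
#' mean and covariance of that cloud; a near-singular covariance is
#' regularized by `+1e-6 I`.
#'
#' @param s A `similarity_matrix`.
#' @param matched Data.frame (sample_a, sample_b) of matched pairs.
#' @param i,j Row / column sample IDs (or indices) of the pair under test.
#' @param ta,tb Rank-transformed cis-feature matrices (features x samples)
#'   aligned with the rows/columns of `s`; used to build pseudo-profiles.
#' @param n_permuted Number of permuted augmentation pairs. Default 1000.
#' @param seed Seed for the permutation augmentation.
#' @return A `score_model` list: `mu` (length 2), `sigma` (2 x 2), `n_real`,
#'   `n_permuted`, `context = c(i, j)`.
#' @export
fit_score_distribution <- function(s, matched, i, j, ta, tb,
                                   n_permuted = 1000L, seed = 1L) {
  if (is.character(i)) i <- match(i, rownames(s))
  if (is.character(j)) j <- match(j, colnames(s))
  ia <- match(matched$sample_a, rownames(s))
  ib <- match(matched$sample_b, colnames(s))
  keep <- ia != i & ib != j
  if (sum(keep) < 10L) stop("need >= 10 matched pairs excluding i and j")
  x <- s[i, ib[keep]]
  y <- s[ia[keep], j]
  if (n_permuted > 0L) {
    ps <- permuted_scores(ta, tb, ia, ib, n_permuted, seed)
    x <- c(x, ps$pa[i, ])
    y <- c(y, ps$pb[, j])
  }
  cloud <- cbind(x, y)
  cloud <- cloud[stats::complete.cases(cloud), , drop = FALSE]
  if (all(abs(cloud[, 1] - cloud[1, 1]) < 1e-12) &&
      all(abs(cloud[, 2] - cloud[1, 2]) < 1e-12))
    stop("degenerate score cloud: all points identical")
  mu <- colMeans(cloud)
  sigma <- stats::cov(cloud)
  if (det(sigma) < 1e-10) sigma <- sigma + diag(1e-6, 2)
  structure(list(mu = as.numeric(mu), sigma = sigma,
                 n_real = sum(keep), n_permuted = n_permuted,
                 context = c(i = i, j = j)),
            class = "score_model")
}

#' Matching p-value of a similarity score under a fitted score model
#'
#' The score `s` is evaluated at the diagonal point `x = (s, s)`. With
#' Mahalanobis distance `r` to the model's center, the p-value of the pair
#' matching by chance is `exp(-r^2 / 2)`, multiplied by the self-alignment
#' prior `p0` for candidate self pairs. Affine-invariant: rescaling the cloud
#' and the score together leaves the p-value unchanged.
#'
#' @param model A `score_model` from [fit_score_distribution()].
#' @param s Similarity score (finite scalar).
#' @param is_self Whether the pair is a candidate self pair.
#' @param p0 Self-alignment prior in (0, 1].
#' @return The p-value.
#' @export
match_pvalue <- function(model, s, is_self = FALSE, p0 = 1) {
  if (!is.finite(s)) stop("score must be finite")
  x <- c(s, s) - model$mu
  r2 <- drop(x %*% solve(model$sigma) %*% x)
  p <- exp(-r2 / 2)
  if (is_self) p0 * p else p
}

# Vectorized log p-value matrix: for every (i, j) the per-context model is
# the cloud {(S[i, b_m], S[a_m, j]) : m matched, a_m != i, b_m != j} plus the
# shared permuted augmentation. All moments reduce to matrix products.
# Comparisons downstream use the log scale so that extreme Mahalanobis
# distances cannot collapse into ties at p = 0.
log_pvalue_matrix <- function(s, matched_idx, ps, p0, self_idx) {
  sm <- unclass(s)
  a <- matched_idx$a; b <- matched_idx$b
  nm <- length(a)
  na_ <- nrow(sm); nb <- ncol(sm)
  R <- sm[, b, drop = FALSE]          # x-scores: R[i, m] = S(A_i, B_{b_m})
  C <- sm[a, , drop = FALSE]          # y-scores: C[m, j] = S(A_{a_m}, B_j)
  pair_of_a <- integer(na_); pair_of_a[a] <- seq_len(nm)
  pair_of_b <- integer(nb);  pair_of_b[b] <- seq_len(nm)
  has_a <- pair_of_a > 0              # row i belongs to some matched pair
  has_b <- pair_of_b > 0
  diag_a <- rep(0, na_)               # x-coord of row i's own pair
  diag_a[has_a] <- sm[cbind(which(has_a), b[pair_of_a[has_a]])]
  diag_b <- rep(0, nb)                # y-coord of column j's own pair
  diag_b[has_b] <- sm[cbind(a[pair_of_b[has_b]], which(has_b))]
  M_pair <- matrix(FALSE, na_, nb)    # is (i, j) itself a matched pair?
  M_pair[cbind(a, b)] <- TRUE
  ex_a <- matrix(has_a, na_, nb)      # pair containing i excluded
  ex_b <- matrix(has_b, na_, nb, byrow = TRUE)
  both <- ex_a & ex_b & M_pair        # same pair: do not exclude twice
  n_real <- nm - ex_a - ex_b + both
  K <- ncol(ps$pa)

  sx <- rowSums(R) + rowSums(ps$pa)
  sxx <- rowSums(R^2) + rowSums(ps$pa^2)
  sy <- colSums(C) + colSums(ps$pb)
  syy <- colSums(C^2) + colSums(ps$pb^2)
  sxy <- R %*% C + ps$pa %*% ps$pb

  DA <- matrix(diag_a, na_, nb) * ex_a
  DB <- matrix(diag_b, na_, nb, byrow = TRUE) * ex_b
  SX <- matrix(sx, na_, nb) - DA - sm * ex_b + sm * both
  SXX <- matrix(sxx, na_, nb) - DA^2 - sm^2 * ex_b + sm^2 * both
  SY <- matrix(sy, na_, nb, byrow = TRUE) - sm * ex_a - DB + sm * both
  SYY <- matrix(syy, na_, nb, byrow = TRUE) - sm^2 * ex_a - DB^2 +
    sm^2 * both
  SXY <- sxy - DA * sm - sm * DB + sm^2 * both

  n_tot <- n_real + K
  mux <- SX / n_tot
  muy <- SY / n_tot
  vxx <- (SXX - n_tot * mux^2) / (n_tot - 1)
  vyy <- (SYY - n_tot * muy^2) / (n_tot - 1)
  vxy <- (SXY - n_tot * mux * muy) / (n_tot - 1)
  dt <- vxx * vyy - vxy^2
  reg <- !is.na(dt) & dt < 1e-10
  if (any(reg)) {
    vxx[reg] <- vxx[reg] + 1e-6
    vyy[reg] <- vyy[reg] + 1e-6
    dt[reg] <- vxx[reg] * vyy[reg] - vxy[reg]^2
  }
  dx <- sm - mux
  dy <- sm - muy
  r2 <- (dx^2 * vyy - 2 * dx * dy * vxy + dy^2 * vxx) / dt
  lp <- -r2 / 2
  lp[self_idx] <- lp[self_idx] + log(p0)
  dimnames(lp) <- dimnames(sm)
  lp
}

#' Probabilistic self/cross alignment of one similarity matrix
#'
#' One round of the probabilistic decision procedure. Every pair (i, j) is
#' assigned a matching p-value from its per-context bivariate-normal score
#' model ([fit_score_distribution()] semantics, computed vectorized), with the
#' self-alignment prior applied on candidate self pairs. Then:
#' \enumerate{
#'   \item Self-align (i, i) when its score exceeds the self floor and its
#'     p-value is the strict unique minimum of row i and of column i.
#'   \item Among profiles not self-aligned, cross-align (i, j) when the score
#'     exceeds the cross floor and the p-value is the strict unique minimum of
#'     row i and of column j.
#'   \item Rescue remaining candidates (i, i) whose score exceeds the self
#'     floor and whose p-value is at or below the `rescue_rank`-th smallest of
#'     row i and of column i (ties inclusive).
#' }
#' Ties at the minimum break toward "not aligned".
#'
#' @param s A `similarity_matrix`.
#' @param matched Data.frame (sample_a, sample_b) of matched pairs defining
#'   the score clouds (typically the previous iteration's alignment).
#' @param ta,tb Rank-transformed cis-feature matrices backing `s`.
#' @param config A [match_config()].
#' @return An `alignment_result` data.frame with columns sample_a, sample_b,
#'   status, score, p_value, plus attributes `cutoffs` and `p0`.
#' @export
match_by_probability <- function(s, matched, ta = NULL, tb = NULL,
                                 config = match_config()) {
  ra <- rownames(s); cb <- colnames(s)
  selfs <- intersect(ra, cb)
  if (length(selfs) == 0L) stop("no candidate self pairs (no shared IDs)")
  sm <- unclass(s)
  self_idx <- cbind(match(selfs, ra), match(selfs, cb))
  self_scores <- sm[self_idx]
  p0 <- if (is.null(config$p0)) 1 / length(selfs) else config$p0
  cuts <- if (is.null(config$self_cutoff) || is.null(config$cross_cutoff)) {
    compute_cutoffs(self_scores)
  } else {
    list(self_cutoff = config$self_cutoff, cross_cutoff = config$cross_cutoff)
  }
  matched_idx <- list(a = match(matched$sample_a, ra),
                      b = match(matched$sample_b, cb))
  if (config$n_permuted > 0L && (is.null(ta) || is.null(tb)))
    stop("ta and tb are required when n_permuted > 0")
  if (config$n_permuted == 0L && is.null(ta)) {
    ta <- matrix(numeric(0), 0, nrow(sm))
    tb <- matrix(numeric(0), 0, ncol(sm))
  }
  ps <- permuted_scores(ta, tb, matched_idx$a, matched_idx$b,
                        config$n_permuted, config$seed)
  lp <- log_pvalue_matrix(s, matched_idx, ps, p0, self_idx)
  lpb <- lp
  lpb[is.na(lpb)] <- Inf
  row_min <- apply(lpb, 1L, min)
  col_min <- apply(lpb, 2L, min)
  row_nmin <- rowSums(lpb == row_min)
  col_nmin <- colSums(lpb == rep(col_min, each = nrow(lpb)))
  is_unique_min <- (lpb <= row_min) & (row_nmin == 1L) &
    (lpb <= rep(col_min, each = nrow(lpb))) &
    (rep(col_nmin, each = nrow(lpb)) == 1L)

  res <- data.frame(sample_a = selfs, sample_b = selfs,
                    status = "unaligned", score = self_scores,
                    p_value = exp(lp[self_idx]), stringsAsFactors = FALSE)
  # Step 1: confident self-alignments
  ok1 <- !is.na(self_scores) & self_scores > cuts$self_cutoff &
    is_unique_min[self_idx]
  res$status[ok1] <- "self_aligned"
  # Step 2: reciprocal cross-alignments among the rest
  free_a <- !(ra %in% res$sample_a[res$status == "self_aligned"])
  free_b <- !(cb %in% res$sample_b[res$status == "self_aligned"])
  cand <- outer(free_a, free_b) & outer(ra, cb, "!=") &
    !is.na(sm) & sm > cuts$cross_cutoff & is_unique_min
  hits <- which(cand, arr.ind = TRUE)
  if (nrow(hits)) {
    cross <- data.frame(sample_a = ra[hits[, 1L]], sample_b = cb[hits[, 2L]],
                        status = "cross_aligned", score = sm[hits],
                        p_value = exp(lp[hits]), stringsAsFactors = FALSE)
    hit <- match(cross$sample_a, res$sample_a)
    replace <- !is.na(hit)
    res[hit[replace], ] <- cross[replace, , drop = FALSE]
    if (any(!replace)) res <- rbind(res, cross[!replace, , drop = FALSE])
  }
  # Step 3: rescue self pairs whose p-value ranks in the top rescue_rank
  kth <- function(v, k) {
    v <- sort(v[is.finite(v)])
    if (length(v) == 0L) return(-Inf)
    v[min(k, length(v))]
  }
  taken_b <- res$sample_b[res$status == "cross_aligned"]
  for (t in seq_len(nrow(res))) {
    if (res$status[t] != "unaligned" || res$sample_a[t] != res$sample_b[t])
      next
    if (res$sample_b[t] %in% taken_b) next
    i <- match(res$sample_a[t], ra); j <- match(res$sample_b[t], cb)
    sc <- sm[i, j]; lv <- lpb[i, j]
    if (is.na(sc) || !is.finite(lv)) next
    if (sc > cuts$self_cutoff &&
        lv <= kth(lpb[i, ], config$rescue_rank) &&
        lv <= kth(lpb[, j], config$rescue_rank))
      res$status[t] <- "self_aligned"
  }
  rownames(res) <- NULL
  structure(res, method = "probability", cutoffs = cuts, p0 = p0,
            class = c("alignment_result", "data.frame"))
}
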