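# small in-code fixtures shared across test files

# random omics_matrix with optional missingness
rand_omics <- function(n_feat, n_samp, missing = 0, prefix = "f",
                       data_type = "test", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_feat)),
                              sprintf("s%03d", seq_len(n_samp))))
  if (missing > 0) v[runif(length(v)) < missing] <- NA
  omics_matrix(v, data_type = data_type)
}

# three coupled data types sharing the same underlying individuals, with
# reciprocal label swaps planted in type X only; used for the patient-centric
# error-source scenarios
make_multiomics <- function(m = 60, n_cis = 150, r = 0.6, swap_pairs = 1,
                            seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(m))
  fx <- sprintf("gx%04d", seq_len(n_cis))
  fy <- sprintf("gy%04d", seq_len(n_cis))
  fz <- sprintf("gz%04d", seq_len(n_cis))
  x <- matrix(rnorm(n_cis * m), n_cis, m, dimnames = list(fx, ids))
  lam <- r / sqrt(1 - r^2)
  y <- lam * x + matrix(rnorm(n_cis * m), n_cis, m)
  z <- lam * x + matrix(rnorm(n_cis * m), n_cis, m)
  dimnames(y) <- list(fy, ids)
  dimnames(z) <- list(fz, ids)
  # plant reciprocal swaps in X's labels
  swapped <- matrix(sample(ids, 2 * swap_pairs), ncol = 2)
  cnx <- colnames(x)
  for (k in seq_len(swap_pairs)) {
    i <- match(swapped[k, 1], cnx); j <- match(swapped[k, 2], cnx)
    cnx[c(i, j)] <- cnx[c(j, i)]
  }
  colnames(x) <- cnx
  list(X = omics_matrix(x, "X"), Y = omics_matrix(y, "Y"),
       Z = omics_matrix(z, "Z"),
       map_xy = map_candidates_by_identity(data.frame(fx, fy)),
       map_xz = map_candidates_by_identity(data.frame(fx, fz)),
       map_yz = map_candidates_by_identity(data.frame(fy, fz)),
       swapped = swapped, ids = ids)
}

# independent step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- rep(NA_real_, m)
  running <- Inf
  for (k in seq_len(m)) {
    i <- o[k]
    rank_i <- m - k + 1L
    running <- min(running, p[i] * m / rank_i)
    q[i] <- min(running, 1)
  }
  q
}
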