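test_that("cutoffs follow the mean - z * sd rule", {
  set.seed(1)
  scores <- rnorm(50)
  scores <- (scores - mean(scores)) / sd(scores) * 0.1 + 0.8  # mean .8 sd .1
  cuts <- compute_cutoffs(scores)
  expect_equal(cuts$self_cutoff, 0.8 - 2.576 * 0.1, tolerance = 1e-12)
  expect_equal(cuts$cross_cutoff, 0.7, tolerance = 1e-12)
  # the cross floor always sits above the self floor (1 < 2.576)
  expect_gte(cuts$cross_cutoff, cuts$self_cutoff)
  expect_warning(c2 <- compute_cutoffs(rep(0.6, 12)), "zero spread")
  expect_equal(c2$self_cutoff, 0.6)
  expect_equal(c2$cross_cutoff, 0.6)
  expect_error(compute_cutoffs(c(0.1, 0.2)), "at least 10")
})

test_that("match_pvalue reproduces the closed-form Mahalanobis cases", {
  model <- structure(list(mu = c(0, 0), sigma = diag(2)),
                     class = "score_model")
  expect_equal(match_pvalue(model, 1, is_self = FALSE), exp(-1))   # r^2 = 2
  expect_equal(match_pvalue(model, 0, is_self = TRUE, p0 = 0.01), 0.01)
  model2 <- structure(list(mu = c(0.3, 0.3), sigma = diag(2)),
                      class = "score_model")
  expect_equal(match_pvalue(model2, 0.3, is_self = TRUE, p0 = 0.05), 0.05)
  expect_error(match_pvalue(model, NaN), "finite")
})

test_that("p-values are invariant under affine rescaling of the scores", {
  set.seed(3)
  cloud <- cbind(rnorm(200, 0.2, 0.1), rnorm(200, 0.1, 0.05))
  fit <- function(cl) {
    structure(list(mu = colMeans(cl), sigma = cov(cl)),
              class = "score_model")
  }
  s0 <- 0.45
  p0 <- match_pvalue(fit(cloud), s0)
  for (sc in c(0.5, 2, 10)) for (off in c(-1, 0, 0.3)) {
    p1 <- match_pvalue(fit(cloud * sc + off), s0 * sc + off)
    expect_equal(p1, p0, tolerance = 1e-9)
  }
})

test_that("mahalanobis radii follow the stated cumulative function", {
  set.seed(11)
  mu <- c(0.1, 0.2)
  sigma <- matrix(c(0.04, 0.015, 0.015, 0.09), 2)
  ch <- chol(sigma)
  z <- matrix(rnorm(2e4), ncol = 2)
  pts <- sweep(z %*% ch, 2, mu, "+")
  si <- solve(sigma)
  d <- sweep(pts, 2, mu)
  r <- sqrt(rowSums((d %*% si) * d))
  grid <- seq(0.05, 4, by = 0.05)
  emp <- ecdf(r)(grid)
  theo <- 1 - exp(-grid^2 / 2)
  expect_lt(max(abs(emp - theo)), 0.05)
})

test_that("a hand-built four-point cloud gives mu = 0, sigma = identity", {
  s <- matrix(0.5, 14, 14,
              dimnames = list(sprintf("a%02d", 1:14), sprintf("a%02d", 1:14)))
  matched <- data.frame(sample_a = rownames(s)[1:13],
                        sample_b = colnames(s)[1:13])
  # pair (14, 14): cloud x = S[14, matched], y = S[matched, 14]
  pts <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  s[14, 1:13] <- c(rep(pts[, 1], 3), 1)
  s[1:13, 14] <- c(rep(pts[, 2], 3), 1)
  # 13 matched points: use only the first 12 (three repeats of the 4 corners)
  matched <- matched[1:12, ]
  model <- fit_score_distribution(s, matched, 14, 14, n_permuted = 0)
  expect_equal(model$mu, c(0, 0))
  expect_equal(unclass(model$sigma),
               matrix(c(12 / 11, 0, 0, 12 / 11), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(model$n_real, 12L)
})

test_that("the score-distribution fit is deterministic under a fixed seed", {
  set.seed(21)
  d <- simulate_dataset(sim_config(100, 40, n_null = 200, seed = 9))
  cis <- test_cis_associations(d$mat_a, d$mat_b, d$candidates, d$truth)
  sig <- cis[cis$significant, ]
  ta <- omicsalign:::rank_transform_rows(
    d$mat_a$values[match(sig$feature_a, rownames(d$mat_a$values)), ])
  tb <- omicsalign:::rank_transform_rows(
    d$mat_b$values[match(sig$feature_b, rownames(d$mat_b$values)), ])
  tb <- tb * ifelse(sig$rho < 0, -1, 1)
  s <- omicsalign:::similarity_from_transformed(ta, tb, 10)
  dimnames(s) <- list(colnames(d$mat_a$values), colnames(d$mat_b$values))
  m1 <- fit_score_distribution(s, d$truth, 5, 5, ta, tb,
                               n_permuted = 200, seed = 42)
  m2 <- fit_score_distribution(s, d$truth, 5, 5, ta, tb,
                               n_permuted = 200, seed = 42)
  expect_identical(m1, m2)
  m3 <- fit_score_distribution(s, d$truth, 5, 5, ta, tb,
                               n_permuted = 200, seed = 43)
  expect_false(identical(m1$sigma, m3$sigma))
})

test_that("permuted pseudo-profile scores center near zero", {
  d <- simulate_dataset(sim_config(500, 150, seed = 17))
  cis <- test_cis_associations(d$mat_a, d$mat_b, d$candidates, d$truth)
  sig <- cis[cis$significant, ]
  ta <- omicsalign:::rank_transform_rows(
    d$mat_a$values[match(sig$feature_a, rownames(d$mat_a$values)), ])
  tb <- omicsalign:::rank_transform_rows(
    d$mat_b$values[match(sig$feature_b, rownames(d$mat_b$values)), ])
  ia <- match(d$truth$sample_a, colnames(d$mat_a$values))
  ib <- match(d$truth$sample_b, colnames(d$mat_b$values))
  ps <- omicsalign:::permuted_scores(ta, tb, ia, ib, 500, seed = 7)
  expect_lt(abs(mean(ps$pa)), 0.05)
  expect_lt(abs(mean(ps$pb)), 0.05)
})

test_that("vectorized p-values agree with the per-pair model fit", {
  set.seed(31)
  d <- simulate_dataset(sim_config(80, 30, n_null = 150, seed = 13))
  cis <- test_cis_associations(d$mat_a, d$mat_b, d$candidates, d$truth)
  sig <- cis[cis$significant, ]
  ta <- omicsalign:::rank_transform_rows(
    d$mat_a$values[match(sig$feature_a, rownames(d$mat_a$values)), ])
  tb <- omicsalign:::rank_transform_rows(
    d$mat_b$values[match(sig$feature_b, rownames(d$mat_b$values)), ])
  tb <- tb * ifelse(sig$rho < 0, -1, 1)
  s <- omicsalign:::similarity_from_transformed(ta, tb, 10)
  dimnames(s) <- list(colnames(d$mat_a$values), colnames(d$mat_b$values))
  matched <- d$truth
  ia <- match(matched$sample_a, rownames(s))
  ib <- match(matched$sample_b, colnames(s))
  ps <- omicsalign:::permuted_scores(ta, tb, ia, ib, 100, seed = 5)
  selfs <- intersect(rownames(s), colnames(s))
  self_idx <- cbind(match(selfs, rownames(s)), match(selfs, colnames(s)))
  p0 <- 1 / length(selfs)
  lp <- omicsalign:::log_pvalue_matrix(s, list(a = ia, b = ib), ps, p0,
                                       self_idx)
  for (i in sample(nrow(s), 3)) for (j in sample(ncol(s), 3)) {
    model <- fit_score_distribution(s, matched, i, j, ta, tb,
                                    n_permuted = 100, seed = 5)
    is_self <- !is.na(rownames(s)[i]) && rownames(s)[i] == colnames(s)[j]
    expected <- match_pvalue(model, s[i, j], is_self = is_self, p0 = p0)
    expect_equal(exp(lp[i, j]), expected, tolerance = 1e-8)
  }
})

test_that("the full probabilistic run is reproducible bit for bit", {
  d <- simulate_dataset(sim_config(150, 50, n_null = 300,
                                   error_rate = 0.04, seed = 3))
  r1 <- align_profiles(d$mat_a, d$mat_b, d$candidates,
                       config = match_config(seed = 11))
  r2 <- align_profiles(d$mat_a, d$mat_b, d$candidates,
                       config = match_config(seed = 11))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("a high-scoring row with strong reciprocal evidence is rescued by
           probability but rejected by rank", {
  # one profile resembles many others (uniformly high row with several
  # row-mates above the self score, so the rank rule rejects it), yet the
  # probabilistic rule, which sees the whole row as one score cloud and
  # weighs the self prior, keeps the self pair
  set.seed(1)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  s <- matrix(rnorm(n * n, 0, 0.05), n, n, dimnames = list(ids, ids))
  diag(s) <- rnorm(n, 0.28, 0.05)
  amb <- 10
  s[amb, ] <- rnorm(n, 0.15, 0.004)
  top <- setdiff(sample(n, 4), amb)[1:3]
  s[amb, top] <- 0.166
  s[amb, amb] <- 0.162
  sm <- structure(s, class = c("similarity_matrix", "matrix"))
  rank_res <- match_by_rank(sm)
  expect_equal(rank_res$status[rank_res$sample_a == ids[amb]], "unaligned")
  matched <- data.frame(sample_a = ids, sample_b = ids)
  prob_res <- match_by_probability(sm, matched,
                                   config = match_config(n_permuted = 0))
  expect_equal(prob_res$status[prob_res$sample_a == ids[amb]],
               "self_aligned")
  expect_true(all(prob_res$status == "self_aligned"))
})
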