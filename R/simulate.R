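#' Correlation threshold for significance in the simulation design
#'
#' Returns the correlation magnitude whose two-sided p-value (t-approximation,
#' `df = M - 2`) equals the BH boundary `alpha * n_true / (n_true + n_null)`,
#' i.e. the weakest planted correlation that would still be declared
#' significant assuming the `n_true` planted pairs occupy the top ranks.
#' Monotone decreasing in `M`.
#'
#' @param M Number of samples (>= 4).
#' @param n_true Number of planted cis pairs.
#' @param n_null Number of null pairs. Default 2000.
#' @param alpha BH q-value threshold. Default 0.05.
#' @return The threshold correlation in (0, 1).
#' @export
significance_threshold_r <- function(M, n_true, n_null = 2000L,
                                     alpha = 0.05) {
  stopifnot(M >= 4, n_true >= 1, n_null >= 0)
  p_star <- alpha * n_true / (n_true + n_null)
  t_star <- stats::qt(1 - p_star / 2, df = M - 2)
  r <- t_star / sqrt(M - 2 + t_star^2)
  if (!is.finite(r) || r <= 0 || r >= 1)
    stop("no admissible threshold correlation in (0, 1)")
  r
}

#' Simulation configuration
#'
#' Defaults encode the study conditions: standard-normal Type-A profiles,
#' Type-B built as `Y = r / sqrt(1 - r^2) * X + eps` so that `cor(X, Y) = r`,
#' planted correlations drawn from a half-normal (scale `sigma_r`) truncated
#' below at the significance threshold, 2000 null pairs with centered-normal
#' correlations, and 10% extra unmatched samples appended to each type.
#'
#' @param n_cis Number of planted significant cis pairs.
#' @param m Number of core (shared) samples (>= 3).
#' @param n_null Number of null feature pairs. Default 2000.
#' @param error_rate Fraction of core Type-B labels permuted. Default 0.
#' @param extra_fraction Fraction of `m` appended as unmatched extra samples
#'   per type. Default 0.10.
#' @param sigma_r Scale of the truncated half-normal for planted
#'   correlations. Default 0.3.
#' @param sigma_null Scale of the centered normal for null-pair
#'   correlations; small so that null pairs stay predominantly below the
#'   detection threshold across the design grid. Default 0.03.
#' @param alpha Significance level defining the truncation threshold.
#' @param seed Master seed; all randomness derives from it.
#' @export
sim_config <- function(n_cis, m, n_null = 2000L, error_rate = 0,
                       extra_fraction = 0.10, sigma_r = 0.3,
                       sigma_null = 0.03, alpha = 0.05, seed = 1L) {
  stopifnot(n_cis >= 1, m >= 3, error_rate >= 0, error_rate <= 1)
  structure(list(n_cis = as.integer(n_cis), m = as.integer(m),
                 n_null = as.integer(n_null), error_rate = error_rate,
                 extra_fraction = extra_fraction, sigma_r = sigma_r,
                 sigma_null = sigma_null, alpha = alpha,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# half-normal truncated to [lo, hi], via inverse CDF
rtrunc_halfnorm <- function(n, sigma, lo, hi) {
  plo <- 2 * stats::pnorm(lo / sigma) - 1
  phi <- 2 * stats::pnorm(hi / sigma) - 1
  u <- stats::runif(n, plo, phi)
  sigma * stats::qnorm((u + 1) / 2)
}

#' Simulate a paired omics dataset with planted cis-associations
#'
#' Generates Type-A profiles as iid standard normals and Type-B profiles with
#' the planted per-feature correlation, for `m` core samples plus
#' `floor(extra_fraction * m)` unmatched extra samples per type. Planted
#' correlations are half-normal (scale `sigma_r`) truncated to
#' `[r_cut, 0.99]` with random sign; null correlations are centered normal
#' clipped to `(-0.99, 0.99)`. Label errors, if requested, are injected by
#' [inject_label_errors()].
#'
#' @param cfg A [sim_config()].
#' @return A `simulated_dataset` list: `mat_a`, `mat_b` ([omics_matrix()]),
#'   `candidates` (all feature pairs), `truth` (true sample pairing),
#'   `planted_r`, `r_cut`, `injected_errors`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$m
  r_cut <- significance_threshold_r(m, cfg$n_cis, cfg$n_null, cfg$alpha)
  if (r_cut >= 0.99)
    stop("threshold correlation >= 0.99: no admissible effect sizes")
  r_sig <- rtrunc_halfnorm(cfg$n_cis, cfg$sigma_r, r_cut, 0.99) *
    sample(c(-1, 1), cfg$n_cis, replace = TRUE)
  r_null <- pmin(pmax(stats::rnorm(cfg$n_null, 0, cfg$sigma_null),
                      -0.99), 0.99)
  r_all <- c(r_sig, r_null)
  n_feat <- cfg$n_cis + cfg$n_null
  n_extra <- floor(cfg$extra_fraction * m)
  n_tot <- m + 2L * n_extra
  x <- matrix(stats::rnorm(n_feat * n_tot), n_feat, n_tot)
  eps <- matrix(stats::rnorm(n_feat * n_tot), n_feat, n_tot)
  y <- (r_all / sqrt(1 - r_all^2)) * x + eps
  core_ids <- sprintf("S%04d", seq_len(m))
  a_ids <- c(core_ids, if (n_extra) sprintf("EA%03d", seq_len(n_extra)))
  b_ids <- c(core_ids, if (n_extra) sprintf("EB%03d", seq_len(n_extra)))
  fa <- c(sprintf("cisA_%04d", seq_len(cfg$n_cis)),
          sprintf("nullA_%04d", seq_len(cfg$n_null)))
  fb <- c(sprintf("cisB_%04d", seq_len(cfg$n_cis)),
          sprintf("nullB_%04d", seq_len(cfg$n_null)))
  va <- x[, c(seq_len(m), if (n_extra) m + seq_len(n_extra)), drop = FALSE]
  vb <- y[, c(seq_len(m),
              if (n_extra) m + n_extra + seq_len(n_extra)), drop = FALSE]
  dimnames(va) <- list(fa, a_ids)
  dimnames(vb) <- list(fb, b_ids)
  d <- structure(list(
    mat_a = omics_matrix(va, "typeA"),
    mat_b = omics_matrix(vb, "typeB"),
    candidates = map_candidates_by_identity(data.frame(fa, fb)),
    truth = data.frame(sample_a = core_ids, sample_b = core_ids,
                       stringsAsFactors = FALSE),
    planted_r = r_all,
    r_cut = r_cut,
    injected_errors = NULL,
    cfg = cfg), class = "simulated_dataset")
  if (cfg$error_rate > 0)
    d <- inject_label_errors(d, cfg$error_rate,
                             seed = (cfg$seed + 1L) %% .Machine$integer.max)
  d
}

# random derangement of n elements (no fixed points), by rejection
rderangement <- function(n) {
  stopifnot(n >= 2L)
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Inject sample-label errors into a simulated dataset
#'
#' Selects `round(rate * m)` core Type-B samples and permutes their labels by
#' a random derangement, so that the realized error rate equals `rate`
#' exactly (no selected sample keeps its label). The truth table is updated:
#' the profile truly belonging to sample `s` now carries label `sigma(s)`.
#'
#' @param d A `simulated_dataset`.
#' @param rate Error rate in \[0, 1\].
#' @param seed Seed for the selection and derangement.
#' @return The modified `simulated_dataset` with `injected_errors` set.
#' @export
inject_label_errors <- function(d, rate, seed = 1L) {
  stopifnot(inherits(d, "simulated_dataset"), rate >= 0, rate <= 1)
  if (rate == 0) return(d)
  m <- d$cfg$m
  k <- round(rate * m)
  if (k < 2L) stop("rate * m < 2: no derangement exists")
  set.seed(seed)
  core_ids <- d$truth$sample_a
  sel <- sort(sample(core_ids, k))
  sigma <- sel[rderangement(k)]        # label of sample sel[t] becomes sigma[t]
  cn <- sample_ids(d$mat_b)
  pos <- match(sel, cn)
  cn[pos] <- sigma
  colnames(d$mat_b$values) <- cn
  idx <- match(sel, d$truth$sample_a)
  d$truth$sample_b[idx] <- sigma
  d$injected_errors <- data.frame(sample = sel, new_label = sigma,
                                  stringsAsFactors = FALSE)
  d
}

#' Score an alignment result against the simulated truth
#'
#' An aligned pair (self or cross) is truly aligned when its Type-B partner
#' matches the truth mapping. Sensitivity (recall) is truly aligned over
#' simulated core pairs; precision is truly aligned over all aligned pairs;
#' `FPR = 1 - precision`; `F = 2 pr / (p + r)` (0 when both are 0).
#'
#' @param result An `alignment_result`.
#' @param truth Data.frame (sample_a, sample_b) of true pairings over the
#'   core samples.
#' @return Named list: sensitivity, precision, fpr, f_measure, n_aligned,
#'   n_true_aligned.
#' @export
evaluate_alignment <- function(result, truth) {
  aligned <- result[result$status != "unaligned", , drop = FALSE]
  truth_b <- truth$sample_b[match(aligned$sample_a, truth$sample_a)]
  truly <- sum(!is.na(truth_b) & aligned$sample_b == truth_b)
  n_sim <- nrow(truth)
  n_aligned <- nrow(aligned)
  sens <- if (n_sim > 0) truly / n_sim else NA_real_
  prec <- if (n_aligned > 0) truly / n_aligned else 0
  f <- if ((prec + sens) > 0) 2 * prec * sens / (prec + sens) else 0
  list(sensitivity = sens, precision = prec, fpr = 1 - prec, f_measure = f,
       n_aligned = n_aligned, n_true_aligned = truly)
}

#' Run a simulation grid over cis counts, sample sizes and error rates
#'
#' For every combination, simulates a dataset, injects label errors, runs the
#' requested matchers through the full iterative alignment, and scores the
#' result against the truth. Per-cell failures are caught and marked.
#'
#' @param n_cis_list,m_list,error_rates,seeds Vectors defining the grid.
#' @param methods Matchers to run. Default both.
#' @param n_null,extra_fraction,sigma_r,sigma_null,alpha Passed to
#'   [sim_config()].
#' @param config Base [match_config()]; its seed is replaced per cell.
#' @param verbose Print one line per cell.
#' @return A tidy data.frame: method, n_cis, m, error_rate, seed, converged,
#'   sensitivity, precision, fpr, f_measure, failed.
#' @export
run_grid <- function(n_cis_list, m_list, error_rates, seeds = 1L,
                     methods = c("probability", "rank"), n_null = 2000L,
                     extra_fraction = 0.10, sigma_r = 0.3,
                     sigma_null = 0.03, alpha = 0.05,
                     config = match_config(), verbose = FALSE) {
  grid <- expand.grid(n_cis = n_cis_list, m = m_list,
                      error_rate = error_rates, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, ]
    cfg <- sim_config(row$n_cis, row$m, n_null = n_null,
                      error_rate = row$error_rate,
                      extra_fraction = extra_fraction, sigma_r = sigma_r,
                      sigma_null = sigma_null, alpha = alpha,
                      seed = row$seed)
    d <- simulate_dataset(cfg)
    for (method in methods) {
      cell <- data.frame(method = method, n_cis = row$n_cis, m = row$m,
                         error_rate = row$error_rate, seed = row$seed,
                         converged = NA, sensitivity = NA_real_,
                         precision = NA_real_, fpr = NA_real_,
                         f_measure = NA_real_, failed = FALSE,
                         stringsAsFactors = FALSE)
      res <- tryCatch({
        mcfg <- config
        mcfg$seed <- (row$seed + 13L) %% .Machine$integer.max
        align_profiles(d$mat_a, d$mat_b, d$candidates, method = method,
                       config = mcfg, alpha = alpha)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        cell$failed <- TRUE
      } else {
        met <- evaluate_alignment(res, d$truth)
        cell$converged <- attr(res, "converged")
        cell$sensitivity <- met$sensitivity
        cell$precision <- met$precision
        cell$fpr <- met$fpr
        cell$f_measure <- met$f_measure
      }
      if (verbose)
        message(sprintf("N=%d M=%d rate=%.2f seed=%d %s: F=%.4f",
                        row$n_cis, row$m, row$error_rate, row$seed, method,
                        cell$f_measure))
      out[[length(out) + 1L]] <- cell
    }
  }
  do.call(rbind, out)
}
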