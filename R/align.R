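#' Iterative profile alignment between two omics data types
#'
#' Runs the full matching loop: test candidate cis-associations on the
#' currently matched sample pairs, build the similarity matrix over the
#' significant pairs, align profiles with the chosen matcher, and feed the
#' aligned pairs back into cis-association testing. Iteration stops when the
#' set of alignment statuses no longer changes or `max_iter` is reached.
#'
#' The initial matched pairs are the sample IDs shared between the two
#' matrices. Each feature is normal-rank-transformed across all samples of its
#' matrix before scoring.
#'
#' @param mat_a,mat_b [omics_matrix()] objects (features x samples).
#' @param candidates A `cis_candidates` table.
#' @param method `"probability"` (default) or `"rank"`.
#' @param config A [match_config()]; also supplies `max_iter` and `seed` for
#'   the rank method's iteration control.
#' @param alpha BH q-value threshold for significant cis-associations.
#' @param min_n Minimum complete sample pairs per cis test.
#' @param min_overlap Passed to [similarity_matrix()].
#' @param verbose Print per-iteration cis counts and alignment tallies.
#' @return An `alignment_result` data.frame with an `iteration` column and
#'   attributes: `converged`, `n_iter`, `cis` (final `cis_associations`),
#'   `cis_history` (significant-pair count per iteration), `method`.
#' @export
align_profiles <- function(mat_a, mat_b, candidates,
                           method = c("probability", "rank"),
                           config = match_config(), alpha = 0.05,
                           min_n = 10L, min_overlap = NULL,
                           verbose = FALSE) {
  method <- match.arg(method)
  shared <- intersect(sample_ids(mat_a), sample_ids(mat_b))
  if (length(shared) < 2L) stop("need at least 2 shared sample IDs")
  matched <- data.frame(sample_a = shared, sample_b = shared,
                        stringsAsFactors = FALSE)
  prev_key <- ""
  cis_history <- integer(0)
  converged <- FALSE
  res <- NULL
  cis <- NULL
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    cis <- test_cis_associations(mat_a, mat_b, candidates, matched,
                                 alpha = alpha, min_n = min_n)
    n_sig <- sum(cis$significant)
    cis_history <- c(cis_history, n_sig)
    if (n_sig == 0L) stop("no intrinsic barcode: zero significant cis pairs")
    sig <- cis[cis$significant, , drop = FALSE]
    ta <- rank_transform_rows(
      mat_a$values[match(sig$feature_a, feature_ids(mat_a)), , drop = FALSE])
    tb <- rank_transform_rows(
      mat_b$values[match(sig$feature_b, feature_ids(mat_b)), , drop = FALSE])
    tb <- tb * ifelse(sig$rho < 0, -1, 1)   # orient by association sign
    mo <- if (is.null(min_overlap)) max(10, 0.5 * n_sig) else min_overlap
    s <- similarity_from_transformed(ta, tb, mo)
    dimnames(s) <- list(sample_ids(mat_a), sample_ids(mat_b))
    res <- if (method == "probability") {
      cfg_it <- config
      cfg_it$seed <- (config$seed + 101L * iter) %% .Machine$integer.max
      match_by_probability(s, matched, ta, tb, cfg_it)
    } else {
      match_by_rank(s)
    }
    res$iteration <- iter
    aligned <- res[res$status != "unaligned", , drop = FALSE]
    if (verbose)
      message(sprintf(
        "iteration %d: %d significant cis pairs, %d self, %d cross",
        iter, n_sig, sum(res$status == "self_aligned"),
        sum(res$status == "cross_aligned")))
    key <- paste(res$sample_a, res$sample_b, res$status,
                 sep = ":", collapse = ";")
    if (identical(key, prev_key)) {
      converged <- TRUE
      break
    }
    prev_key <- key
    if (nrow(aligned) < min_n) {
      warning("fewer aligned pairs than min_n; stopping")
      break
    }
    matched <- aligned[, c("sample_a", "sample_b")]
  }
  structure(res, converged = converged, n_iter = iter, cis = cis,
            cis_history = cis_history, method = method,
            class = c("alignment_result", "data.frame"))
}

#' @export
print.alignment_result <- function(x, ...) {
  tab <- table(factor(x$status,
                      c("self_aligned", "cross_aligned", "unaligned")))
  cat(sprintf(
    "alignment_result [%s]: %d self-aligned, %d cross-aligned, %d unaligned",
    attr(x, "method") %||% "?", tab[1L], tab[2L], tab[3L]))
  if (!is.null(attr(x, "converged")))
    cat(sprintf(" (converged: %s, %d iterations)",
                attr(x, "converged"), attr(x, "n_iter")))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an alignment result as TSV
#'
#' @param res An `alignment_result`.
#' @param path Output path.
#' @export
write_alignment_result <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
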