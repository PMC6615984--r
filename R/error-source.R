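#' Patient-centric view of pairwise alignment results
#'
#' Combines pairwise alignment results from several data-type pairs into a
#' graph over (patient, data type) nodes. Self-aligned pairs connect the two
#' data types of the same patient; cross-aligned pairs connect the aligned
#' partner nodes; unaligned candidate pairs are kept as "unaligned" edges.
#'
#' @param results List of `alignment_result` objects.
#' @param type_pairs Data.frame (or 2-column matrix) with one row per result:
#'   the Type-A and Type-B data-type labels.
#' @return A `patient_view` object: list with `edges` (patient_a, type_a,
#'   patient_b, type_b, status, score) and `types`.
#' @export
build_patient_view <- function(results, type_pairs) {
  type_pairs <- as.data.frame(type_pairs, stringsAsFactors = FALSE)
  if (length(results) != nrow(type_pairs))
    stop("one type pair per alignment result required")
  edges <- list()
  for (k in seq_along(results)) {
    r <- as.data.frame(results[[k]])
    if (nrow(r) == 0L) next
    edges[[k]] <- data.frame(
      patient_a = r$sample_a, type_a = type_pairs[k, 1L],
      patient_b = r$sample_b, type_b = type_pairs[k, 2L],
      status = r$status, score = r$score, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(patient_a = character(), type_a = character(),
               patient_b = character(), type_b = character(),
               status = character(), score = numeric(),
               stringsAsFactors = FALSE)
  key <- with(edges, paste(patient_a, type_a, patient_b, type_b))
  if (anyDuplicated(key)) {
    d <- split(edges$status, key)
    conf <- names(d)[vapply(d, function(s) length(unique(s)) > 1L, TRUE)]
    if (length(conf))
      stop("conflicting duplicate edges: ", paste(conf, collapse = "; "))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 types = unique(c(type_pairs[[1L]], type_pairs[[2L]]))),
            class = "patient_view")
}

# edges where a given patient's profile of a given type is cross-aligned to
# the other patient; returns the partner (patient, type) rows
cross_links <- function(edges, patient, type) {
  ca <- edges$status == "cross_aligned"
  fwd <- ca & edges$patient_a == patient & edges$type_a == type
  rev <- ca & edges$patient_b == patient & edges$type_b == type
  data.frame(partner = c(edges$patient_b[fwd], edges$patient_a[rev]),
             partner_type = c(edges$type_b[fwd], edges$type_a[rev]),
             stringsAsFactors = FALSE)
}

# do the non-T profiles of a patient self-align among themselves
# (every existing edge not involving type T for this patient is self)?
others_consistent <- function(edges, patient, type) {
  inv <- (edges$patient_a == patient | edges$patient_b == patient) &
    edges$type_a != type & edges$type_b != type
  sub <- edges[inv, , drop = FALSE]
  all(sub$status != "cross_aligned")
}

#' Infer the source of labeling errors from a patient view
#'
#' For each data type `T` and patient pair (i, j): a swap-in-T verdict is
#' emitted when i's T profile is cross-aligned to at least `min_support`
#' other-type profiles of patient j and vice versa (reciprocal pattern),
#' while the non-T profiles of both patients stay mutually self-aligned. A
#' single profile is called mislabeled when it is cross-aligned away, its
#' patient's other profiles are mutually self-aligned, and no reciprocal
#' pattern exists. Nodes with only self-aligned edges are correct; a final
#' pass also marks as correct the "victim" nodes whose cross edges are all
#' explained by a swapped/mislabeled node at the other end. Everything else
#' is unresolved (the safe sink).
#'
#' @param view A `patient_view` from [build_patient_view()].
#' @param min_support Minimum number of independent data-type pairings backing
#'   a swap verdict. Default 1.
#' @return Data.frame: patient, data_type, verdict (correct / mislabeled /
#'   swapped / unresolved), partner (patient for swaps, patient whose identity
#'   the profile carries for mislabels), evidence (supporting pairing count).
#' @export
infer_error_source <- function(view, min_support = 1L) {
  edges <- view$edges
  nodes <- unique(rbind(
    data.frame(patient = edges$patient_a, data_type = edges$type_a,
               stringsAsFactors = FALSE),
    data.frame(patient = edges$patient_b, data_type = edges$type_b,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$patient, nodes$data_type), , drop = FALSE]
  rownames(nodes) <- NULL
  verdict <- rep("unresolved", nrow(nodes))
  partner <- rep(NA_character_, nrow(nodes))
  evidence <- rep(0L, nrow(nodes))
  for (t in seq_len(nrow(nodes))) {
    pt <- nodes$patient[t]; ty <- nodes$data_type[t]
    links <- cross_links(edges, pt, ty)
    inv_self <- edges$status == "self_aligned" &
      ((edges$patient_a == pt & edges$type_a == ty) |
         (edges$patient_b == pt & edges$type_b == ty))
    if (nrow(links) == 0L) {
      if (any(inv_self)) verdict[t] <- "correct"
      next
    }
    cand <- unique(links$partner)
    for (pj in cand) {
      support_ij <- sum(links$partner == pj & links$partner_type != ty)
      back <- cross_links(edges, pj, ty)      # j's same-type profile
      support_ji <- sum(back$partner == pt & back$partner_type != ty)
      if (support_ij >= min_support && support_ji >= min_support &&
          others_consistent(edges, pt, ty) &&
          others_consistent(edges, pj, ty)) {
        verdict[t] <- "swapped"
        partner[t] <- pj
        evidence[t] <- support_ij
        break
      }
      if (support_ij >= min_support && support_ji == 0L &&
          others_consistent(edges, pt, ty)) {
        # no reciprocal pattern: this single profile is mislabeled; it
        # carries the identity of patient pj
        verdict[t] <- "mislabeled"
        partner[t] <- pj
        evidence[t] <- support_ij
        break
      }
    }
  }
  # explanation pass: a node whose cross edges all touch an already-called
  # node at the other end is a victim of that error, not an error itself
  called <- paste(nodes$patient, nodes$data_type)[
    verdict %in% c("swapped", "mislabeled")]
  for (t in which(verdict == "unresolved")) {
    pt <- nodes$patient[t]; ty <- nodes$data_type[t]
    links <- cross_links(edges, pt, ty)
    if (nrow(links) == 0L) next
    if (all(paste(links$partner, links$partner_type) %in% called) ||
        all(paste(links$partner, ty) %in% called))
      verdict[t] <- "correct"
  }
  data.frame(patient = nodes$patient, data_type = nodes$data_type,
             verdict = verdict, partner = partner, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Apply swap / mislabel corrections to profile matrices
#'
#' Swap verdicts exchange the two implicated sample columns within the
#' implicated data type. Mislabeled profiles are relabeled to the inferred
#' partner when that label is free, and dropped otherwise when
#' `drop_ambiguous = TRUE`; a relabel collision with `drop_ambiguous = FALSE`
#' is an error and nothing is applied for that data type. Unresolved verdicts
#' are never acted on.
#'
#' @param matrices Named list of [omics_matrix()] objects, names = data types.
#' @param verdicts Verdict table from [infer_error_source()].
#' @param apply_classes Verdict classes to act on. Default
#'   `c("swapped", "mislabeled")`.
#' @param drop_ambiguous Drop mislabeled profiles whose relabel target
#'   collides with an existing column. Default `TRUE`.
#' @return List with `matrices` (corrected) and `log` (one row per change:
#'   data_type, action, sample, new_label).
#' @export
apply_correction <- function(matrices, verdicts,
                             apply_classes = c("swapped", "mislabeled"),
                             drop_ambiguous = TRUE) {
  log <- list()
  act <- verdicts[verdicts$verdict %in% apply_classes, , drop = FALSE]
  for (ty in unique(act$data_type)) {
    if (!ty %in% names(matrices)) next
    v <- act[act$data_type == ty, , drop = FALSE]
    m <- matrices[[ty]]
    cn <- colnames(m$values)
    done_swap <- character(0)
    for (t in seq_len(nrow(v))) {
      pt <- v$patient[t]; pj <- v$partner[t]
      if (v$verdict[t] == "swapped") {
        key <- paste(sort(c(pt, pj)), collapse = "|")
        if (key %in% done_swap) next
        i <- match(pt, cn); j <- match(pj, cn)
        if (is.na(i) || is.na(j)) next
        cn[c(i, j)] <- cn[c(j, i)]
        done_swap <- c(done_swap, key)
        log[[length(log) + 1L]] <- data.frame(
          data_type = ty, action = "swap", sample = pt, new_label = pj,
          stringsAsFactors = FALSE)
      } else if (v$verdict[t] == "mislabeled") {
        i <- match(pt, cn)
        if (is.na(i)) next
        if (pj %in% cn) {
          if (!drop_ambiguous)
            stop("relabel target collision for ", pj, " in ", ty)
          cn[i] <- NA_character_    # mark for drop
          log[[length(log) + 1L]] <- data.frame(
            data_type = ty, action = "drop", sample = pt,
            new_label = NA_character_, stringsAsFactors = FALSE)
        } else {
          cn[i] <- pj
          log[[length(log) + 1L]] <- data.frame(
            data_type = ty, action = "relabel", sample = pt, new_label = pj,
            stringsAsFactors = FALSE)
        }
      }
    }
    keep <- !is.na(cn)
    vals <- m$values[, keep, drop = FALSE]
    colnames(vals) <- cn[keep]
    matrices[[ty]] <- omics_matrix(vals, data_type = m$data_type)
  }
  list(matrices = matrices,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(data_type = character(), action = character(),
                    sample = character(), new_label = character(),
                    stringsAsFactors = FALSE))
}

#' Per-pair correlation gain from label-error correction
#'
#' For each candidate cis pair, the Spearman correlation is computed over the
#' corrected (aligned) sample pairs, and compared with the mean correlation
#' over `n_resample` random subsets of the initially matched pairs of the
#' same size (so that sample size does not bias the comparison).
#'
#' @param mat_a,mat_b [omics_matrix()] objects.
#' @param candidates `cis_candidates` table.
#' @param pairs_before Data.frame (sample_a, sample_b): initially matched
#'   pairs.
#' @param pairs_after Data.frame (sample_a, sample_b): aligned pairs after
#'   correction; must not outnumber `pairs_before`.
#' @param n_resample Number of random subsets. Default 100.
#' @param seed Seed for the resampling.
#' @return Data.frame: feature_a, feature_b, rho_before (resampled mean),
#'   rho_after, gain.
#' @export
correction_gain <- function(mat_a, mat_b, candidates, pairs_before,
                            pairs_after, n_resample = 100L, seed = 1L) {
  if (n_resample < 1L) stop("n_resample must be >= 1")
  if (nrow(pairs_after) > nrow(pairs_before))
    stop("pairs_after must not outnumber pairs_before")
  set.seed(seed)
  fa <- match(candidates$feature_a, feature_ids(mat_a))
  fb <- match(candidates$feature_b, feature_ids(mat_b))
  ok <- !is.na(fa) & !is.na(fb)
  rho_pairs <- function(pairs) {
    ia <- match(pairs$sample_a, sample_ids(mat_a))
    ib <- match(pairs$sample_b, sample_ids(mat_b))
    a <- mat_a$values[fa[ok], ia, drop = FALSE]
    b <- mat_b$values[fb[ok], ib, drop = FALSE]
    vapply(seq_len(nrow(a)), function(i) {
      suppressWarnings(stats::cor(a[i, ], b[i, ], method = "spearman",
                                  use = "pairwise.complete.obs"))
    }, 0)
  }
  rho_after <- rho_pairs(pairs_after)
  n_after <- nrow(pairs_after)
  before_mat <- vapply(seq_len(n_resample), function(r) {
    rho_pairs(pairs_before[sample(nrow(pairs_before), n_after), ,
                           drop = FALSE])
  }, numeric(sum(ok)))
  rho_before <- rowMeans(before_mat, na.rm = TRUE)
  data.frame(feature_a = candidates$feature_a[ok],
             feature_b = candidates$feature_b[ok],
             rho_before = rho_before, rho_after = rho_after,
             gain = rho_after - rho_before, stringsAsFactors = FALSE)
}
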