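# build a tiny patient view by hand from alignment-result-like data.frames
ar <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("sample_a", "sample_b", "status")
  df$score <- 0.5
  structure(df, class = c("alignment_result", "data.frame"))
}

test_that("an all-self graph yields only correct verdicts", {
  r1 <- ar(c("p1", "p2"), c("p1", "p2"), "self_aligned")
  view <- build_patient_view(list(r1, r1, r1),
                             rbind(c("mRNA", "miRNA"), c("mRNA", "CNV"),
                                   c("miRNA", "CNV")))
  v <- infer_error_source(view)
  expect_true(all(v$verdict == "correct"))
})

test_that("conflicting duplicate edges are rejected", {
  r1 <- ar("p1", "p1", "self_aligned")
  r2 <- ar("p1", "p1", "unaligned")
  expect_error(build_patient_view(list(r1, r2),
                                  rbind(c("mRNA", "miRNA"),
                                        c("mRNA", "miRNA"))),
               "conflicting")
})

test_that("an empty result list yields an empty graph", {
  view <- build_patient_view(list(), data.frame(a = character(),
                                                b = character()))
  expect_equal(nrow(view$edges), 0L)
  expect_equal(nrow(infer_error_source(view)), 0L)
})

test_that("a reciprocal cross pattern with consistent other types is a swap", {
  # Agilent profiles of p1/p2 swapped: Agilent(p1) matches miRNA(p2) and
  # CNV(p2), and vice versa; miRNA-CNV alignments stay self
  agi_mir <- ar(c("p1", "p2", "p3"), c("p2", "p1", "p3"),
                c("cross_aligned", "cross_aligned", "self_aligned"))
  agi_cnv <- ar(c("p1", "p2", "p3"), c("p2", "p1", "p3"),
                c("cross_aligned", "cross_aligned", "self_aligned"))
  mir_cnv <- ar(c("p1", "p2", "p3"), c("p1", "p2", "p3"), "self_aligned")
  view <- build_patient_view(list(agi_mir, agi_cnv, mir_cnv),
                             rbind(c("Agilent", "miRNA"),
                                   c("Agilent", "CNV"),
                                   c("miRNA", "CNV")))
  v <- infer_error_source(view)
  key <- paste(v$patient, v$data_type)
  expect_equal(v$verdict[key == "p1 Agilent"], "swapped")
  expect_equal(v$partner[key == "p1 Agilent"], "p2")
  expect_equal(v$verdict[key == "p2 Agilent"], "swapped")
  expect_equal(v$partner[key == "p2 Agilent"], "p1")
  expect_true(all(v$verdict[!grepl("Agilent", key) | grepl("p3", key)] ==
                    "correct"))
  # swap verdicts are mutual and respect min_support
  v2 <- infer_error_source(view, min_support = 3)
  expect_true(all(v2$verdict != "swapped"))
})

test_that("a one-way cross pattern is a mislabeled single profile", {
  # miRNA profile labeled p2 actually belongs to p1; p2's own other profiles
  # agree with each other, and nothing of p1 points back the other way
  rna_mir <- ar(c("p1", "p2", "p3"), c("p2", "p2", "p3"),
                c("cross_aligned", "unaligned", "self_aligned"))
  agi_mir <- ar(c("p1", "p2", "p3"), c("p2", "p2", "p3"),
                c("cross_aligned", "unaligned", "self_aligned"))
  rna_agi <- ar(c("p1", "p2", "p3"), c("p1", "p2", "p3"), "self_aligned")
  view <- build_patient_view(list(rna_mir, agi_mir, rna_agi),
                             rbind(c("RNAseq", "miRNA"),
                                   c("Agilent", "miRNA"),
                                   c("RNAseq", "Agilent")))
  v <- infer_error_source(view)
  key <- paste(v$patient, v$data_type)
  expect_equal(v$verdict[key == "p2 miRNA"], "mislabeled")
  expect_equal(v$partner[key == "p2 miRNA"], "p1")
  expect_equal(v$verdict[key == "p1 RNAseq"], "correct")
})

test_that("swap correction exchanges columns and no-verdict leaves data alone", {
  set.seed(1)
  mats <- list(X = rand_omics(5, 4, prefix = "g", seed = 2))
  colnames(mats$X$values) <- paste0("p", 1:4)
  verdicts <- data.frame(
    patient = c("p1", "p2"), data_type = "X", verdict = "swapped",
    partner = c("p2", "p1"), evidence = 1L, stringsAsFactors = FALSE)
  out <- apply_correction(mats, verdicts)
  expect_equal(out$matrices$X$values[, "p1"],
               mats$X$values[, "p2"], ignore_attr = TRUE)
  expect_equal(out$matrices$X$values[, "p2"],
               mats$X$values[, "p1"], ignore_attr = TRUE)
  expect_equal(nrow(out$log), 1L)  # one swap action for the mutual pair
  none <- apply_correction(mats, verdicts[0, ])
  expect_identical(none$matrices$X$values, mats$X$values)
  expect_equal(nrow(none$log), 0L)
})

test_that("mislabel correction relabels when free and drops on collision", {
  mats <- list(Y = rand_omics(4, 3, seed = 3))
  colnames(mats$Y$values) <- c("p1", "p2", "p3")
  v_relabel <- data.frame(patient = "p3", data_type = "Y",
                          verdict = "mislabeled", partner = "p9",
                          evidence = 1L, stringsAsFactors = FALSE)
  out <- apply_correction(mats, v_relabel)
  expect_true("p9" %in% colnames(out$matrices$Y$values))
  expect_false("p3" %in% colnames(out$matrices$Y$values))
  expect_equal(out$log$action, "relabel")
  v_clash <- data.frame(patient = "p3", data_type = "Y",
                        verdict = "mislabeled", partner = "p1",
                        evidence = 1L, stringsAsFactors = FALSE)
  out2 <- apply_correction(mats, v_clash)
  expect_false("p3" %in% colnames(out2$matrices$Y$values))
  expect_equal(out2$log$action, "drop")
  expect_error(apply_correction(mats, v_clash, drop_ambiguous = FALSE),
               "collision")
})

test_that("planted swaps are localized, corrected, and realign to self", {
  mo <- make_multiomics(m = 40, n_cis = 150, r = 0.65, swap_pairs = 1,
                        seed = 1)
  cfg <- match_config(seed = 2, n_permuted = 300)
  res_xy <- align_profiles(mo$X, mo$Y, mo$map_xy, config = cfg)
  res_xz <- align_profiles(mo$X, mo$Z, mo$map_xz, config = cfg)
  res_yz <- align_profiles(mo$Y, mo$Z, mo$map_yz, config = cfg)
  view <- build_patient_view(list(res_xy, res_xz, res_yz),
                             rbind(c("X", "Y"), c("X", "Z"), c("Y", "Z")))
  v <- infer_error_source(view)
  swapped <- sort(as.vector(mo$swapped))
  called <- sort(v$patient[v$verdict == "swapped" & v$data_type == "X"])
  expect_identical(called, swapped)
  expect_true(all(v$verdict[v$data_type != "X"] == "correct"))
  out <- apply_correction(list(X = mo$X, Y = mo$Y, Z = mo$Z), v)
  res2 <- align_profiles(out$matrices$X, mo$Y, mo$map_xy, config = cfg)
  expect_true(all(res2$status == "self_aligned"))
  expect_equal(nrow(out$log), 1L)
})

test_that("correction gain is near zero when nothing changed and is seeded", {
  mo <- make_multiomics(m = 40, n_cis = 20, swap_pairs = 1, seed = 7)
  pairs <- data.frame(sample_a = mo$ids, sample_b = mo$ids,
                      stringsAsFactors = FALSE)
  g1 <- correction_gain(mo$Y, mo$Z, mo$map_yz, pairs, pairs,
                        n_resample = 20, seed = 4)
  expect_true(all(abs(g1$gain) <= 0.02))
  g2 <- correction_gain(mo$Y, mo$Z, mo$map_yz, pairs, pairs,
                        n_resample = 20, seed = 4)
  expect_identical(g1, g2)
  expect_error(correction_gain(mo$Y, mo$Z, mo$map_yz, pairs, pairs,
                               n_resample = 0), "n_resample")
})

test_that("correcting planted swaps improves cis correlations", {
  mo <- make_multiomics(m = 160, n_cis = 60, r = 0.7, swap_pairs = 4,
                        seed = 9)
  ids <- mo$ids
  # X carries swapped labels; before = naive ID matching, after = truth
  before <- data.frame(sample_a = colnames(mo$X$values),
                       sample_b = colnames(mo$X$values),
                       stringsAsFactors = FALSE)
  # truth: X column labeled l holds the profile of the swap partner
  truth_map <- setNames(colnames(mo$X$values), ids)
  after <- data.frame(sample_a = unname(truth_map), sample_b = ids,
                      stringsAsFactors = FALSE)
  g <- correction_gain(mo$X, mo$Y, mo$map_xy, before, after,
                       n_resample = 30, seed = 11)
  expect_gte(mean(g$gain >= 0), 0.9)
})
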