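sig_default <- build_signature_matrix(default_panel())
mk_all <- colnames(sig_default)

# positivity matrix with named markers, everything FALSE
blank_pos <- function(n_clusters) {
  matrix(FALSE, n_clusters, length(mk_all),
         dimnames = list(seq_len(n_clusters), mk_all))
}

test_that("positivity calling: z-score rule matches the hand computation", {
  cm <- matrix(c(0.9, rep(0.05, 9)), ncol = 1,
               dimnames = list(1:10, "CD3"))
  pos <- call_marker_positivity(cm, method = "zscore", z = 1)
  cutoff <- mean(cm) + sd(cm)              # hand rule
  expect_identical(unname(pos[, 1]), unname(cm[, 1] > cutoff))
  expect_true(pos[1, 1])
  expect_false(any(pos[-1, 1]))
})

test_that("positivity calling: degenerate inputs are all-negative", {
  # marker at zero everywhere
  cm <- matrix(0, 5, 1, dimnames = list(1:5, "CD3"))
  expect_false(any(call_marker_positivity(cm, "kmeans")))
  expect_false(any(call_marker_positivity(cm, "zscore")))
  # all clusters equal: zero variance, no exceedance
  cm2 <- matrix(0.4, 6, 1, dimnames = list(1:6, "CD3"))
  expect_false(any(call_marker_positivity(cm2, "zscore")))
  expect_false(any(call_marker_positivity(cm2, "kmeans")))
})

test_that("positivity calling: default separates high from intermediate-free low", {
  cm <- matrix(c(0.9, rep(0.05, 9)), ncol = 1,
               dimnames = list(1:10, "CD3"))
  pos <- call_marker_positivity(cm)
  expect_true(pos[1, 1]); expect_false(any(pos[-1, 1]))
  # pan-marker positive in most clusters still called in all of them
  cm3 <- matrix(c(rep(0.6, 7), rep(0.05, 3)), ncol = 1,
                dimnames = list(1:10, "PanCK"))
  pos3 <- call_marker_positivity(cm3)
  expect_true(all(pos3[1:7, 1]))
  expect_false(any(pos3[8:10, 1]))
})

test_that("signature scoring assigns the canonical profiles", {
  pos <- blank_pos(3)
  pos[1, c("AQP5", "PDPN", "RAGE", "HOP")] <- TRUE
  pos[2, c("SPD", "NKX2-1", "ABCA3", "AQP5", "HOP")] <- TRUE
  pos[3, c("PanCK", "CD206")] <- TRUE
  asg <- assign_cluster_types(pos, sig_default)
  expect_equal(asg$type[1], "AT1")
  expect_equal(asg$type[2], "transitional_AT")
  expect_equal(asg$type[3], "DISCARD")
  expect_match(asg$reason[3], "hybrid lineage")
})

test_that("null-phenotype clusters are discarded", {
  pos <- blank_pos(2)
  pos[2, "CD3"] <- TRUE
  asg <- assign_cluster_types(pos, sig_default)
  expect_equal(asg$type[1], "DISCARD")
  expect_match(asg$reason[1], "null phenotype")
  expect_equal(asg$type[2], "T_cell")
})

test_that("every cluster gets exactly one of type or DISCARD", {
  set.seed(4)
  pos <- blank_pos(12)
  for (i in 1:12) pos[i, sample(mk_all, sample(0:4, 1))] <- TRUE
  asg <- assign_cluster_types(pos, sig_default)
  expect_equal(nrow(asg), 12)
  expect_true(all(asg$type %in% c(cell_type_labels(), "DISCARD")))
})

test_that("major-type merging follows the published grouping", {
  pos <- blank_pos(5)
  pos[1, "MUC5b"] <- TRUE; pos[1, "PanCK"] <- TRUE   # bronchial/goblet
  pos[2, "PanCK"] <- TRUE                            # epithelial, generic
  pos[3, c("COLL1", "VIM", "FGF10")] <- TRUE         # stromal
  pos[4, c("aSMA", "SM22", "DESM")] <- TRUE          # myofibroblast/SMC
  pos[5, c("AQP5", "PDPN")] <- TRUE                  # AT1
  asg <- assign_cluster_types(pos, sig_default)
  mm <- merge_major_types(asg)
  expect_equal(unname(mm[as.character(1)]), "bronchial_goblet")
  expect_equal(unname(mm[as.character(5)]), "alveolar")
  # stromal vs myofibroblast kept separate by default, groupable on demand
  expect_equal(unname(mm[as.character(3)]), "stromal")
  expect_equal(unname(mm[as.character(4)]), "myofibroblast_smc")
  ms <- merge_major_types(asg, all_stromal = TRUE)
  expect_equal(unname(ms[as.character(3)]), "all_stromal")
  expect_equal(unname(ms[as.character(4)]), "all_stromal")
  # empty assignment
  expect_length(merge_major_types(asg[0, ]), 0)
})

test_that("end-to-end phenotyping on a simulated core: >= 85% correct, < 10% discarded", {
  p <- normal_lung_params("core2mm", n_cells = 3000)
  sim <- simulate_cell_table(p, seed = 17)
  cr <- phenocluster(sim$table, markers = classification_markers(default_panel()),
                     k = 30, seed = 17)
  tab <- classify_cells(sim$table, cr)
  keep <- tab$cell_type != "DISCARD"
  expect_lt(mean(!keep), 0.10)
  mm <- major_type_map()
  acc <- mean(tab$major_type[keep] == mm[sim$truth$true_type[keep]])
  expect_gte(acc, 0.85)
  # counts conserve
  expect_equal(sum(keep) + sum(!keep), nrow(tab))
})
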