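test_that("composition presets are proper compositions", {
  comp <- normal_lung_composition()
  expect_equal(sum(comp), 1, tolerance = 1e-12)
  expect_setequal(names(comp), cell_type_labels())
  for (tp in c("saline", "d7", "d14", "d21", "d28")) {
    e <- treatment_preset(tp)
    expect_equal(sum(e$composition_override), 1, tolerance = 1e-12)
    expect_equal(unname(e$pgp_multiplier["bronchial_goblet"]), 1)
  }
  expect_true(all(treatment_preset("saline")$pgp_multiplier == 1))
  expect_error(treatment_preset("d99"), "arg")
})

test_that("treatment presets encode the published course", {
  sal <- treatment_preset("saline")$composition_override
  d7 <- treatment_preset("d7")$composition_override
  d14 <- treatment_preset("d14")$composition_override
  d21 <- treatment_preset("d21")$composition_override
  d28 <- treatment_preset("d28")$composition_override
  # stromal monotone increase d7 -> d21, above saline
  expect_gt(d21[["stromal"]], d14[["stromal"]])
  expect_gt(d14[["stromal"]], d7[["stromal"]])
  expect_gt(d7[["stromal"]], sal[["stromal"]])
  # AT2 + transitional decline through d21
  at2t <- function(x) x[["AT2"]] + x[["transitional_AT"]]
  expect_gt(at2t(sal), at2t(d7))
  expect_gt(at2t(d7), at2t(d14))
  expect_gt(at2t(d14), at2t(d21))
  # d28 is closer (L1) to saline than d14
  expect_lt(sum(abs(d28 - sal)), sum(abs(d14 - sal)))
  # delayed stromal P-gP onset, induction elsewhere from d7
  expect_equal(unname(treatment_preset("d7")$pgp_multiplier[["stromal"]]), 1)
  expect_gt(treatment_preset("d14")$pgp_multiplier[["stromal"]], 1)
  expect_gt(treatment_preset("d7")$pgp_multiplier[["AT1"]], 1)
})

test_that("generator determinism: identical seeds give identical output", {
  p <- flat_params(n_cells = 30, seed = 5)
  a <- generate_section(p, seed = 5)
  b <- generate_section(p, seed = 5)
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$truth, b$truth)
})

test_that("degenerate inputs: empty field and single-type composition", {
  p0 <- flat_params(n_cells = 0, seed = 1)
  sec <- generate_section(p0, seed = 1)
  expect_equal(nrow(sec$truth), 0)
  dapi <- stack_image(sec$stack, round = 1, channel = "DAPI")
  expect_lt(mean(dapi), 15)               # background + noise only
  fitc_af <- stack_image(sec$stack, round = 0, channel = "FITC")
  expect_gt(mean(fitc_af), mean(dapi))    # AF present in the blank round

  p1 <- flat_params(n_cells = 100, composition = c(AT1 = 1),
                    misalignment = c(0, 0), seed = 2)
  s1 <- generate_section(p1, seed = 2)
  expect_equal(nrow(s1$truth), 100)
  expect_true(all(s1$truth$true_type == "AT1"))
  expect_true(all(s1$truth$true_AQP5 > 0))
  expect_true(all(s1$truth$true_CD3 == 0))
  # rendered contrast: AQP5 high at AT1 nuclei, CD3 at background
  aq <- stack_image(s1$stack, marker = "AQP5")
  cd3 <- stack_image(s1$stack, marker = "CD3")
  idx <- cbind(round(s1$truth$x_px), round(s1$truth$y_px))
  expect_gt(mean(aq[idx]), 80)
  expect_lt(mean(cd3[idx]), 40)
})

test_that("overcrowded fields and invalid compositions are rejected", {
  expect_error(tissue_params(composition = c(AT1 = 0.6, AT2 = 0.6)),
               "sum to 1")
  p <- tissue_params(field_um = c(100, 100), n_cells = 2000,
                     placement = "field")
  expect_error(generate_section(p, seed = 1), "overcrowded")
})

test_that("ground-truth composition tracks the preset within binomial error", {
  p <- normal_lung_params("core2mm", seed = 3)
  sim <- simulate_cell_table(p, seed = 3)
  frac <- mean(sim$truth$true_type == "AT1")
  p0 <- normal_lung_composition()[["AT1"]]
  se <- sqrt(p0 * (1 - p0) / nrow(sim$truth))
  expect_lt(abs(frac - p0), 3 * se)
  expect_equal(nrow(sim$truth), 6029)
  # ids unique, all cells inside the field
  expect_false(anyDuplicated(sim$truth$cell_id) > 0)
  mpp <- p$microns_per_pixel
  expect_true(all(sim$truth$x_px >= 0 & sim$truth$x_px <= p$field_um[1] / mpp))
})

test_that("signal fidelity: POS pairs exceed background, NEG pairs do not", {
  p <- flat_params(n_cells = 120, field_um = c(500, 500),
                   composition = c(AT1 = 0.5, T_cell = 0.5),
                   touching_fraction = 0, misalignment = c(0, 0), seed = 8)
  sec <- generate_section(p, seed = 8)
  aq <- stack_image(sec$stack, marker = "AQP5")
  at1 <- sec$truth$true_type == "AT1"
  at_idx <- cbind(round(sec$truth$x_px[at1]), round(sec$truth$y_px[at1]))
  t_idx <- cbind(round(sec$truth$x_px[!at1]), round(sec$truth$y_px[!at1]))
  expect_gt(mean(aq[at_idx]), mean(aq[t_idx]) + 50)
  tst <- t.test(aq[at_idx], aq[t_idx])
  expect_lt(tst$p.value, 1e-6)
})

test_that("core layout packs circles at the requested scale", {
  p <- tissue_params(field_um = c(6000, 6000), microns_per_pixel = 1,
                     n_cells = 10)
  set.seed(2)
  one <- plant_core_layout(p, 2)
  expect_equal(one$radius_px, 1000)
  lay <- plant_core_layout(p, rep(c(1, 2), each = 4))
  expect_equal(nrow(lay), 8)
  d <- as.matrix(dist(lay[, c("x_px", "y_px")]))
  rr <- outer(lay$radius_px, lay$radius_px, "+")
  expect_true(all(d[upper.tri(d)] > rr[upper.tri(rr)]))
  p_small <- tissue_params(field_um = c(1000, 1000), microns_per_pixel = 1,
                           n_cells = 10)
  expect_error(plant_core_layout(p_small, 2), "exceeds field")
})

test_that("spillover contaminates touching cells more than isolated ones", {
  p <- normal_lung_params("core2mm", n_cells = 1500,
                          touching_fraction = 0.2, seed = 6)
  sim <- simulate_cell_table(p, seed = 6)
  # for T cells (CD3-only), contamination shows up as non-CD3 signal
  tcell <- sim$truth$true_type == "T_cell"
  other_mk <- setdiff(table_markers(sim$table), c("CD3", "P-gP"))
  leak <- rowSums(as.data.frame(sim$table)[tcell, paste0(other_mk, "_raw")])
  touching <- sim$truth$touching[tcell]
  skip_if(sum(touching) < 5)
  expect_gt(mean(leak[touching]), mean(leak[!touching]))
})
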