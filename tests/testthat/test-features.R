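test_that("uniform marker image gives exact means and 0-1 rescale", {
  sec <- generate_section(flat_params(n_cells = 20, seed = 4), seed = 4)
  stack <- sec$stack
  # overwrite one marker image with a constant
  i <- which(stack$key$marker == "CD3" & !is.na(stack$key$marker))
  stack$images[[i]] <- matrix(80L, nrow(stack$images[[i]]),
                              ncol(stack$images[[i]]))
  nuc <- segment_nuclei(stack_image(stack, round = 1, channel = "DAPI"))
  tab <- extract_features(stack, expand_to_cells(nuc, 2), default_panel())
  expect_true(all(abs(tab$CD3_raw - 80) < 1e-12))
  expect_equal(tab$CD3_scaled, tab$CD3_raw / 255)
})

test_that("ROI means equal a brute-force pixel loop", {
  sec <- generate_section(flat_params(n_cells = 15, field_um = c(300, 300),
                                      seed = 9), seed = 9)
  nuc <- segment_nuclei(stack_image(sec$stack, round = 1, channel = "DAPI"))
  cells <- expand_to_cells(nuc, 2)
  tab <- extract_features(sec$stack, cells, default_panel())
  img <- stack_image(sec$stack, marker = "AQP5")
  for (lab in head(cells$table$label, 5)) {
    px <- img[cells$mask == lab]
    expect_equal(tab$AQP5_raw[tab$cell_id == lab], mean(px))
  }
})

test_that("zero cells yield an empty table with the full header", {
  sec <- generate_section(flat_params(n_cells = 5, seed = 2), seed = 2)
  empty <- label_mask(matrix(0L, dim(sec$stack$images[[1]])[1],
                             dim(sec$stack$images[[1]])[2]))
  tab <- extract_features(sec$stack, empty, default_panel())
  expect_equal(nrow(tab), 0)
  expect_true(all(c("cell_id", "x_px", "y_um", "area_px",
                    "AQP5_raw", "AQP5_scaled", "sample_id") %in% names(tab)))
})

test_that("a panel marker without an image is reported by name", {
  sec <- generate_section(flat_params(n_cells = 5, seed = 2), seed = 2)
  stack <- sec$stack
  drop <- which(!is.na(stack$key$marker) & stack$key$marker == "CD206")
  stack$images <- stack$images[-drop]
  stack$key <- stack$key[-drop, ]
  nuc <- segment_nuclei(stack_image(stack, round = 1, channel = "DAPI"))
  expect_error(extract_features(stack, expand_to_cells(nuc, 2),
                                default_panel()),
               "CD206")
})

test_that("per-cell marker recovery is within 5% of the generative mean", {
  sec <- generate_section(flat_params(
    n_cells = 120, field_um = c(500, 500), composition = c(AT1 = 1),
    touching_fraction = 0, misalignment = c(0, 0), seed = 13), seed = 13)
  nuc <- segment_nuclei(stack_image(sec$stack, round = 1, channel = "DAPI"))
  tab <- extract_features(subtract_stack_af(sec$stack),
                          expand_to_cells(nuc, 2), default_panel())
  m <- match_to_truth(as.data.frame(tab), sec$truth, 5)
  rel <- abs(tab$AQP5_raw[m$cell_idx] - sec$truth$true_AQP5[m$truth_idx]) /
    sec$truth$true_AQP5[m$truth_idx]
  expect_lt(median(rel), 0.05)
})

test_that("feature normalization variants behave as documented", {
  sim <- simulate_cell_table(flat_params(n_cells = 40, seed = 3), seed = 3)
  X <- feature_matrix(sim$table)
  Z <- feature_matrix(sim$table, normalize = "zscore")
  expect_equal(unname(colMeans(Z)), rep(0, ncol(Z)), tolerance = 1e-12)
  A <- feature_matrix(sim$table, normalize = "arcsinh:5")
  expect_equal(A[1, 1], asinh(X[1, 1] * 255 / 5))
  expect_error(feature_matrix(sim$table, normalize = "log"), "unknown")
})

test_that("cell table round-trips through CSV", {
  sim <- simulate_cell_table(flat_params(n_cells = 50, seed = 6), seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(sim$table, f)
  back <- read_cell_table(f)
  expect_equal(nrow(back), 50)
  expect_setequal(table_markers(back), table_markers(sim$table))
  num <- vapply(as.data.frame(sim$table), is.numeric, logical(1))
  for (cn in names(num)[num])
    expect_equal(back[[cn]], sim$table[[cn]], tolerance = 1e-6)
})

test_that("missing marker column is reported on read", {
  sim <- simulate_cell_table(flat_params(n_cells = 10, seed = 6), seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(sim$table)
  df$AQP5_raw <- NULL
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_cell_table(f, markers = table_markers(sim$table)),
               "AQP5")
})

test_that("a 6029-row table survives the CSV round trip intact", {
  sim <- simulate_cell_table(normal_lung_params("core2mm", seed = 8), seed = 8)
  expect_equal(nrow(sim$table), 6029)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(sim$table, f)
  expect_equal(nrow(read_cell_table(f)), 6029)
})
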