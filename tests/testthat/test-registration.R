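# One small synthetic section shared across registration tests.
reg_fixture <- local({
  sec <- NULL
  function() {
    if (is.null(sec))
      sec <<- generate_section(tiny_params(seed = 7), seed = 7)
    sec
  }
})

test_that("transform algebra: inverse composes to identity", {
  tr <- rigid_transform(1.7, 4.2, -6.3)
  id <- compose_transforms(tr, invert_transform(tr))
  expect_lt(abs(id$rotation), 1e-6)
  expect_lt(abs(id$dx), 1e-6)
  expect_lt(abs(id$dy), 1e-6)
})

test_that("identical images register as the identity", {
  ref <- stack_image(reg_fixture()$stack, round = 1, channel = "DAPI")
  tr <- estimate_rigid(ref, ref)
  expect_lt(abs(tr$rotation), 0.05)
  expect_lt(abs(tr$dx), 0.1)
  expect_lt(abs(tr$dy), 0.1)
})

test_that("planted shifts and rotations are recovered (inverse convention)", {
  ref <- stack_image(reg_fixture()$stack, round = 1, channel = "DAPI")

  mov <- warp_rigid(ref, 0, 5, -3)
  tr <- estimate_rigid(ref, mov)
  expect_lt(abs(tr$rotation), 0.1)
  expect_lt(abs(tr$dx - (-5)), 0.5)
  expect_lt(abs(tr$dy - 3), 0.5)

  mov2 <- warp_rigid(ref, 2.0, 0, 0)
  tr2 <- estimate_rigid(ref, mov2)
  expect_lt(abs(tr2$rotation - (-2.0)), 0.1)
  expect_lt(abs(tr2$dx), 0.5)
  expect_lt(abs(tr2$dy), 0.5)
})

test_that("all misaligned rounds are recovered within 0.5 px / 0.1 deg", {
  sec <- reg_fixture()
  truetr <- attr(sec$stack, "true_transforms")
  al <- register_stack(sec$stack)
  est <- attr(al, "transforms")
  for (r in setdiff(truetr$round, 1)) {
    i <- which(truetr$round == r)
    inv <- invert_transform(rigid_transform(truetr$rotation[i],
                                            truetr$dx[i], truetr$dy[i]))
    e <- est[[as.character(r)]]
    expect_lt(abs(e$rotation - inv$rotation), 0.1)
    expect_lt(abs(e$dx - inv$dx), 0.5)
    expect_lt(abs(e$dy - inv$dy), 0.5)
  }
})

test_that("blank images are refused", {
  blank <- matrix(0L, 64, 64)
  expect_error(estimate_rigid(blank, blank), "no registration signal")
})

test_that("apply_transform: identity is bit-exact, alignment reduces DAPI residual", {
  sec <- reg_fixture()
  stack <- sec$stack
  ident <- lapply(stats::setNames(nm = as.character(unique(stack$key$round))),
                  function(r) rigid_transform())
  same <- apply_transform(stack, ident)
  expect_identical(same$images, stack$images)

  ref <- stack_image(stack, round = 1, channel = "DAPI")
  pre <- mean(abs(stack_image(stack, round = 5, channel = "DAPI") - ref))
  al <- register_stack(stack)
  post <- mean(abs(stack_image(al, round = 5, channel = "DAPI") - ref))
  expect_lt(post, pre)
})

test_that("translation off-frame zero-pads the border", {
  img <- matrix(100L, 40, 40)
  out <- warp_rigid(img, 0, 10, 0)
  expect_true(all(out[1:10, ] == 0))
  expect_true(all(out[11:40, ] == 100))
})

test_that("autofluorescence subtraction clips at zero and is idempotent at af = 0", {
  m <- matrix(100L, 10, 10)
  af0 <- matrix(0L, 10, 10)
  expect_identical(subtract_autofluorescence(m, af0), m)
  expect_equal(unique(as.vector(
    subtract_autofluorescence(m, matrix(30L, 10, 10)))), 70L)
  expect_equal(unique(as.vector(
    subtract_autofluorescence(matrix(20L, 10, 10), matrix(50L, 10, 10)))), 0L)
  expect_error(subtract_autofluorescence(m, matrix(0L, 5, 5)), "shape")
})

test_that("registered per-cell intensities match the aligned-stack oracle", {
  # pixel noise off: independent noise realizations alone cost ~1.5% and
  # would mask the registration-induced error this checks
  sec <- generate_section(tiny_params(seed = 19, pixel_noise_sd = 0),
                          seed = 19, keep_aligned = TRUE)
  panel <- default_panel()
  process <- function(stack) {
    clean <- subtract_stack_af(stack)
    nuc <- segment_nuclei(stack_image(clean, round = 1, channel = "DAPI"))
    extract_features(clean, expand_to_cells(nuc, 2), panel)
  }
  t_reg <- process(register_stack(sec$stack))
  t_orc <- process(sec$aligned)
  m <- match_to_truth(as.data.frame(t_reg), as.data.frame(t_orc), 2)
  expect_gt(nrow(m), 0.9 * nrow(t_orc))
  mk <- paste0(table_markers(t_reg), "_raw")
  a <- as.matrix(as.data.frame(t_reg)[m$cell_idx, mk])
  b <- as.matrix(as.data.frame(t_orc)[m$truth_idx, mk])
  # mean error relative to the oracle intensity scale (per-value ratios are
  # meaningless at background level)
  expect_lt(mean(abs(a - b)) / mean(b), 0.02)
})
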