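test_that("gap_threshold scans curves in the requested direction", {
  fake <- structure(list(table = data.frame(grid = c(1, 2, 5),
                                            gap = c(0.3, 0.1, 0.005))),
                    class = "effect_curve")
  expect_equal(gap_threshold(fake, 0.01), 5)
  expect_equal(gap_threshold(fake, 0.5), 1)
  expect_true(is.na(gap_threshold(fake, 0.001)))
  snrlike <- structure(list(table = data.frame(grid = c(0.25, 1, 4),
                                               gap = c(0.001, 0.004, 0.02))),
                       class = "effect_curve")
  expect_equal(gap_threshold(snrlike, 0.01, "largest"), 1)
  expect_error(gap_threshold(fake, -1), class = "pembench_invalid_parameter")
})

test_that("spatial averaging shrinks the nonlinear advantage", {
  cv <- spatial_averaging_curve(n_ave_grid = c(1, 8), T = 1000, reps = 4,
                                seed = 3)
  expect_gt(cv$table$gap[1], cv$table$gap[2])
  expect_gt(cv$table$gap[1], 0.02)
  expect_true(all(cv$table$r2_linear <= 1 & cv$table$r2_nonlinear <= 1))
  # determinism
  cv2 <- spatial_averaging_curve(n_ave_grid = c(1, 8), T = 1000, reps = 4,
                                 seed = 3)
  expect_identical(cv$table, cv2$table)
})

test_that("correlated units keep their nonlinearity only when correlation persists", {
  curves <- sphere_averaging_curve(corr_length_grid = c(0.1, Inf),
                                   n_ave_grid = c(1, 20), T = 1000,
                                   reps = 4, seed = 5)
  finite <- curves[["corr_length=0.1"]]$table
  perfect <- curves[["corr_length=Inf"]]$table
  expect_gt(finite$gap[1], finite$gap[2])     # averaging helps
  # perfectly correlated units: averaging cannot help (within 2 se)
  expect_lt(abs(perfect$gap[2] - perfect$gap[1]),
            2 * (perfect$gap_se[1] + perfect$gap_se[2]) + 0.01)
})

test_that("low-pass filtering linearizes a static sigmoid", {
  curves <- temporal_averaging_curve(f_cutoff_grid = c(1, 0.05),
                                     p_grid = 0, T = 1500, reps = 5,
                                     seed = 7)
  tab <- curves[["p=0"]]$table
  expect_gt(tab$gap[1], 0.02)       # unfiltered: nonlinearity visible
  expect_lt(tab$gap[2], tab$gap[1]) # filtering shrinks it
})

test_that("the dimensionality experiment tracks bandwidth growth", {
  cv <- dimensionality_curve(n_grid = c(1, 20), N = 400, reps = 2, seed = 9,
                             h_grid = exp(seq(log(0.1), log(10),
                                              length.out = 6)))
  expect_gt(cv$table$gap[1], 0.05)   # n = 1: the sigmoid is fully learnable
  expect_gt(cv$optimal_h[2], cv$optimal_h[1])
})

test_that("effect curves carry coherent uncertainty bookkeeping", {
  cv <- snr_curve(snr_grid = c(0.5, 8), T = 800, reps = 4, seed = 11)
  expect_equal(cv$reps, 4)
  expect_equal(dim(cv$r2_linear), c(4L, 2L))
  expect_equal(cv$table$gap,
               colMeans(cv$r2_nonlinear - cv$r2_linear), tolerance = 1e-12)
  expect_true(all(is.finite(cv$table$gap_se)))
  expect_gt(cv$table$gap[2], cv$table$gap[1])  # more SNR, more nonlinearity
})
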