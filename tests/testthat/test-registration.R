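# Smaller phantoms and reduced grids keep the unit tests quick; the full
# default-grid behaviour is exercised in the acceptance suite.

test_that("self-registration is an exact fixed point", {
  ph <- generate_phantom_pair(size = 128, seed = 20)
  fit <- register(ph$fixed, ph$fixed,
                  grid = search_grid(tau_min = -2, tau_max = 2,
                                     theta_min = -2, theta_max = 2))
  expect_identical(fit$best_transform$theta, 0)
  expect_identical(fit$best_transform$tau_x, 0)
  expect_identical(fit$best_transform$tau_y, 0)
  expect_equal(fit$fre$rms, 0)
  expect_equal(fit$fre$mean, 0)
  # MI at the optimum equals the image's self-MI
  self_mi <- mi_hog(ph$fixed, ph$fixed)
  expect_equal(max(fit$mi_trace$mi), self_mi, tolerance = 1e-12)
  expect_false(fit$at_boundary)
})

test_that("a known multi-modal misalignment is recovered on the grid", {
  ph <- generate_phantom_pair(size = 256, seed = 30,
                              true_transform = rigid_transform(-2, -4.5, -4.5))
  fit <- register(ph$fixed, ph$moving)
  expect_equal(fit$best_transform$theta, -2)
  expect_lte(abs(fit$best_transform$tau_x - (-4.5)), 0.5)
  expect_lte(abs(fit$best_transform$tau_y - (-4.5)), 0.5)
  # estimates lie on the 21-point grids
  grid <- search_grid()
  expect_true(fit$best_transform$theta %in% grid$theta_values)
  expect_true(fit$best_transform$tau_x %in% grid$tau_values)
  expect_length(grid$theta_values, 21L)
  expect_length(grid$tau_values, 21L)
  # the trace covers every grid angle
  expect_equal(sort(fit$mi_trace$theta), grid$theta_values)
  expect_equal(fit$fre$omega, 30L)
})

test_that("a pure translation with noise is recovered within half a pixel", {
  ph <- generate_phantom_pair(size = 128, seed = 31,
                              true_transform = rigid_transform(0, 2.5, 2.5))
  fit <- register(ph$fixed, ph$moving)
  expect_lte(abs(fit$best_transform$tau_x - 2.5), 0.5)
  expect_lte(abs(fit$best_transform$tau_y - 2.5), 0.5)
  expect_lte(abs(fit$best_transform$theta), 0.5)
})

test_that("a transform outside the grid is flagged at the boundary", {
  ph <- generate_phantom_pair(size = 128, seed = 32,
                              true_transform = rigid_transform(8, 0, 0))
  expect_warning(
    fit <- register(ph$fixed, ph$moving,
                    grid = search_grid(theta_min = -5, theta_max = 5)),
    "boundary"
  )
  expect_true(fit$at_boundary)
  expect_equal(abs(fit$best_transform$theta), 5)  # clamped to the grid edge
})

test_that("the coarse stage alone recovers translations", {
  ph <- generate_phantom_pair(size = 128, seed = 33,
                              true_transform = rigid_transform(0, -3, 2))
  out <- coarse_translation(ph$fixed, ph$moving)
  expect_lte(abs(out$tau[1] - (-3)), 0.5)
  expect_lte(abs(out$tau[2] - 2), 0.5)
  expect_equal(nrow(out$ed_surface), 21L * 21L)
  expect_gte(out$n_pairs, 5L)
})

test_that("the fine stage alone recovers rotations at known translation", {
  ph <- generate_phantom_pair(size = 256, seed = 34,
                              true_transform = rigid_transform(-3, 1, -1))
  out <- fine_rotation(ph$fixed, ph$moving, tau = c(1, -1))
  expect_lte(abs(out$theta - (-3)), 0.5)
  expect_equal(nrow(out$mi_trace), 21L)
})

test_that("the intensity-MI mode runs end to end", {
  ph <- generate_phantom_pair(size = 128, seed = 35,
                              true_transform = rigid_transform(1.5, -1, 2))
  fit <- suppressWarnings(
    register(ph$fixed, ph$moving, similarity = "mi_intensity",
             grid = search_grid(tau_min = -3, tau_max = 3,
                                theta_min = -3, theta_max = 3))
  )
  expect_equal(fit$method, "mi_intensity")
  expect_equal(nrow(fit$mi_trace), 13L)
})

test_that("results tidy, glance, plot and export", {
  ph <- generate_phantom_pair(size = 128, seed = 36,
                              true_transform = rigid_transform(-1, 1, 0.5))
  fit <- register(ph$fixed, ph$moving,
                  grid = search_grid(tau_min = -3, tau_max = 3,
                                     theta_min = -3, theta_max = 3))
  td <- tidy(fit)
  expect_named(td, c("theta", "mi"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("theta", "tau_x", "tau_y", "fre_rms", "omega")
                  %in% names(gl)))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(plot_ed_surface(fit), "ggplot")

  dir <- withr::local_tempdir()
  write_registration(fit, dir)
  expect_true(file.exists(file.path(dir, "result.json")))
  js <- jsonlite::fromJSON(file.path(dir, "result.json"))
  expect_equal(js$transform$theta_deg, fit$best_transform$theta)
  expect_equal(js$fre$omega, fit$fre$omega)
  trace <- utils::read.csv(file.path(dir, "mi_trace.csv"))
  expect_equal(nrow(trace), nrow(fit$mi_trace))
  reg <- load_image(file.path(dir, "registered.nii.gz"))
  expect_equal(reg$pixels, fit$registered$pixels, tolerance = 0)
})

test_that("search grids are validated", {
  expect_error(search_grid(tau_step = 0), "> 0")
  expect_error(search_grid(tau_min = 5, tau_max = -5), "min")
  g <- search_grid(tau_min = -1, tau_max = 1, tau_step = 0.5)
  expect_equal(g$tau_values, c(-1, -0.5, 0, 0.5, 1))
})
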