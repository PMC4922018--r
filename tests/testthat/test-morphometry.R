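test_that("section stack validates labels and dimensions", {
  arr <- array(0L, c(4, 4, 2)); arr[2, 2, 1] <- 1L
  st <- section_stack(arr, 10, 5)
  expect_s3_class(st, "section_stack")
  arr[1, 1, 1] <- 3L
  expect_error(section_stack(arr, 10, 5), "labels outside")
  expect_error(section_stack(array(0L, c(4, 4, 2)), -1, 5), "pixel_size")
})

test_that("tissue volume counts anisotropic voxels and is label-additive", {
  arr <- array(0L, c(20, 20, 1))
  arr[1:10, 1:10, 1] <- 1L  # 100 kidney pixels
  st <- section_stack(arr, pixel_size_um = 1, section_thickness_um = 5)
  expect_identical(tissue_volume(st, 1L), 500)
  expect_identical(tissue_volume(st, integer(0)), 0)
  expect_error(tissue_volume(st, 7L), "unknown label")
  # additivity over disjoint label sets
  arr[1:5, 1:5, 1] <- 2L
  st2 <- section_stack(arr, 1, 5)
  expect_identical(tissue_volume(st2, c(1L, 2L)),
                   tissue_volume(st2, 1L) + tissue_volume(st2, 2L))
})

test_that("voxelized ellipsoid volume matches the analytic value within 2%", {
  p <- section_sim_params(semi_axes_um = c(50, 50, 50),
                          center_um = c(100, 100, 52.5),
                          grid_shape = c(200L, 200L), pixel_size_um = 1,
                          n_sections = 21L, thickness_um = 5,
                          blood_fraction = 0, margin_px = 10, seed = 1)
  g <- gen_section_stack(p)
  v_analytic <- 4 / 3 * pi * 50^3
  expect_equal(g$truth$analytic_volume_um3, v_analytic)
  expect_equal(tissue_volume(g$stack), v_analytic, tolerance = 0.02)
  # voxelization error shrinks as the grid is refined
  p2 <- section_sim_params(semi_axes_um = c(50, 50, 50),
                           center_um = c(100, 100, 51.25),
                           grid_shape = c(400L, 400L), pixel_size_um = 0.5,
                           n_sections = 41L, thickness_um = 2.5,
                           blood_fraction = 0, margin_px = 10, seed = 1)
  g2 <- gen_section_stack(p2)
  err1 <- abs(tissue_volume(g$stack) - v_analytic)
  err2 <- abs(tissue_volume(g2$stack) - v_analytic)
  expect_lt(err2, err1)
})

test_that("alignment recovers applied jitter and preserves volume", {
  # zero jitter: all shifts zero
  g0 <- gen_section_stack(section_sim_params(seed = 2))
  al0 <- align_stack(g0$stack)
  ne0 <- setdiff(seq_len(nrow(al0$shifts)), al0$flagged)
  expect_true(all(al0$shifts[ne0, ] == 0))

  # known integer jitter: recovered shifts (relative to the reference)
  # undo the applied ones exactly
  g <- gen_section_stack(section_sim_params(jitter_sd_px = 3, seed = 5))
  al <- align_stack(g$stack)
  ref <- al$reference_index
  ne <- setdiff(seq_len(nrow(al$shifts)), al$flagged)
  rel_true <- sweep(g$truth$shifts_px, 2, g$truth$shifts_px[ref, ])
  expect_true(all(al$shifts[ne, ] + rel_true[ne, ] == 0))

  # volume is invariant under alignment (margin >= max jitter)
  expect_identical(tissue_volume(al$aligned), tissue_volume(g$stack))

  # subpixel Gaussian jitter sigma = 1 px: within 0.5 px RMS of the
  # unrounded truth
  g1 <- gen_section_stack(section_sim_params(jitter_sd_px = 1, seed = 8))
  al1 <- align_stack(g1$stack)
  ref1 <- al1$reference_index
  ne1 <- setdiff(seq_len(nrow(al1$shifts)), al1$flagged)
  rel_raw <- sweep(g1$truth$shifts_raw_px, 2, g1$truth$shifts_raw_px[ref1, ])
  rms <- sqrt(mean((al1$shifts[ne1, ] + rel_raw[ne1, ])^2))
  expect_lt(rms, 0.5)
})

test_that("empty sections inherit a neighbour's shift and are flagged", {
  g <- gen_section_stack(section_sim_params(jitter_sd_px = 2, seed = 4))
  lab <- g$stack$labels
  mid <- dim(lab)[3] %/% 2
  lab[, , mid] <- 0L  # knock out a middle section
  st <- section_stack(lab, g$stack$pixel_size_um,
                      g$stack$section_thickness_um)
  al <- align_stack(st)
  expect_true(mid %in% al$flagged)
  expect_identical(al$shifts[mid, ], al$shifts[mid - 1, ])
})

test_that("blood profile reports per-section and voxel-weighted fractions", {
  # uniform 20% labeling: flat profile
  arr <- array(1L, c(10, 10, 4))
  arr[1:2, , ] <- 2L  # exactly 20 of 100 pixels per section
  st <- section_stack(arr, 1, 5)
  pr <- blood_cell_profile(st)
  expect_equal(pr$per_section, rep(0.2, 4))
  expect_equal(pr$total, 0.2)
  # all-background section: NA at that index, excluded from the total
  arr[, , 2] <- 0L
  pr2 <- blood_cell_profile(section_stack(arr, 1, 5))
  expect_true(is.na(pr2$per_section[2]))
  expect_equal(pr2$per_section[-2], rep(0.2, 3))
  expect_equal(pr2$total, 0.2)
  # total equals the voxel-weighted mean of the per-section profile
  g <- gen_section_stack(section_sim_params(seed = 6))
  pr3 <- blood_cell_profile(g$stack)
  counts <- apply(g$stack$labels > 0, 3, sum)
  keep <- !is.na(pr3$per_section)
  expect_equal(pr3$total,
               sum(pr3$per_section[keep] * counts[keep]) / sum(counts[keep]))
})

test_that("generated blood fractions match the Bernoulli ground truth", {
  g <- gen_section_stack(section_sim_params(seed = 10))
  pr <- blood_cell_profile(g$stack)
  expect_equal(pr$total, 0.25, tolerance = 0.02)
  keep <- !is.na(pr$per_section) &
    apply(g$stack$labels > 0, 3, sum) > 500
  expect_true(all(abs(pr$per_section[keep] -
                        g$truth$per_section_blood_p[keep]) < 0.08))
})

test_that("regional split localizes a dorsal depletion band", {
  # uniform labeling: dorsal and ventral halves agree
  gu <- gen_section_stack(section_sim_params(seed = 11))
  rs_u <- regional_split(gu$stack)
  expect_equal(rs_u$dorsal_fraction, rs_u$ventral_fraction, tolerance = 0.05)

  # dorsal band fully depleted: in-field fraction ~0, ventral keeps baseline
  depth_um <- 520  # band reaching just past the organ's dorsal half
  pd <- section_sim_params(depletion = "dorsal_band",
                           depletion_depth_um = depth_um,
                           depletion_factor = 1, seed = 12)
  gd <- gen_section_stack(pd)
  mask_rows <- (seq_len(100) - 0.5) * 10 <= depth_um
  irr <- array(rep(mask_rows, 120 * 70), c(100, 120, 70))
  rs <- regional_split(gd$stack, irradiated = irr)
  expect_lt(rs$infield_fraction, 0.005)
  expect_equal(rs$outfield_fraction, 0.25, tolerance = 0.05)
  expect_lt(rs$dorsal_fraction, rs$ventral_fraction)

  # whole-organ depletion to 20% of baseline: uniform everywhere
  gw <- gen_section_stack(section_sim_params(depletion = "whole",
                                             depletion_factor = 0.8,
                                             seed = 13))
  rw <- regional_split(gw$stack, irradiated = irr)
  expect_equal(rw$dorsal_fraction, 0.05, tolerance = 0.25)
  expect_equal(rw$ventral_fraction, 0.05, tolerance = 0.25)
  expect_equal(blood_cell_profile(gw$stack)$total, 0.05, tolerance = 0.1)
  expect_equal(rw$infield_fraction, rw$outfield_fraction, tolerance = 0.1)

  # an all-true mask reproduces the total blood fraction in-field
  all_true <- array(TRUE, dim(gu$stack$labels))
  rs_all <- regional_split(gu$stack, irradiated = all_true)
  expect_equal(rs_all$infield_fraction, blood_cell_profile(gu$stack)$total)
})

test_that("volume export round-trips labels and metadata", {
  g <- gen_section_stack(section_sim_params(grid_shape = c(40L, 40L),
                                            semi_axes_um = c(120, 120, 60),
                                            n_sections = 30L,
                                            margin_px = 5, seed = 14))
  path <- file.path(withr::local_tempdir(), "kidney.tif")
  export_volume(g$stack, path)
  back <- read_label_stack(path, paste0(path, ".json"))
  expect_identical(back$labels, g$stack$labels)
  expect_equal(back$pixel_size_um, g$stack$pixel_size_um)
  expect_equal(back$section_thickness_um, g$stack$section_thickness_um)
  # page count equals section count
  expect_length(tiff::readTIFF(path, all = TRUE), 30L)
  # empty stack still writes a valid all-zero file
  empty <- section_stack(array(0L, c(8, 8, 3)), 10, 5)
  p2 <- file.path(withr::local_tempdir(), "empty.tif")
  export_volume(empty, p2)
  b2 <- read_label_stack(p2, paste0(p2, ".json"))
  expect_true(all(b2$labels == 0L))
})
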