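test_that("cell image generator is seeded, exact and noise-free-clean", {
  a <- gen_cell_image(2, 1, 4, 0.1, 0, seed = 7)
  b <- gen_cell_image(2, 1, 4, 0.1, 0, seed = 7)
  expect_identical(a, b)                       # bit-identical at equal seed
  c2 <- gen_cell_image(2, 1, 4, 0.1, 0, seed = 8)
  expect_false(identical(a$image, c2$image))

  # planted single fragment of 4 um^2 at 0.1 um/px is exactly 400 px
  expect_identical(vapply(a$truth$golgi_fragment_masks, sum, integer(1)),
                   rep(400L, 2))
  expect_equal(a$truth$per_fragment_area_um2, rep(4, 2))

  # all recorded areas equal brute-force pixel counts x px^2
  for (i in seq_along(a$truth$golgi_fragment_masks))
    expect_equal(a$truth$per_fragment_area_um2[i],
                 sum(a$truth$golgi_fragment_masks[[i]]) * 0.1^2)

  # noise-free background is exactly zero outside the planted masks
  all_masks <- Reduce(`|`, a$truth$golgi_fragment_masks) | a$truth$nucleus_mask
  expect_true(all(a$image$channels$golgi[!all_masks] == 0))
  expect_true(all(a$image$channels$dapi[!all_masks] == 0))

  # fragment masks pairwise disjoint even when rings overlap geometrically
  r <- gen_cell_image(1, 6, 2, 0.1, 0, seed = 3)
  overlap <- Reduce(`+`, lapply(r$truth$golgi_fragment_masks, as.integer))
  expect_lte(max(overlap), 1L)

  expect_error(gen_cell_image(6, 1, 8, 0.1, 0, seed = 1, shape = c(60, 60)),
               "place")
})

test_that("tissue generator plants the requested region areas per tubule", {
  g <- gen_tissue_image(1, list(c(3, 7)), 0.1, seed = 5)
  expect_identical(length(g$truth$region_masks), 2L)
  above <- g$truth$region_area_um2 > 5
  expect_identical(sum(above), 1L)             # one above, one below 5 um^2
  expect_equal(g$truth$region_area_um2,
               vapply(g$truth$region_masks, sum, integer(1)) * 0.01)
  expect_identical(g, gen_tissue_image(1, list(c(3, 7)), 0.1, seed = 5))

  m <- gen_tissue_image(3, list(c(1, 2), 4, c(2, 2, 6)), 0.1, seed = 6)
  expect_identical(length(m$truth$region_masks), 6L)
  expect_identical(m$truth$region_tubule, c(1L, 1L, 2L, 3L, 3L, 3L))
  expect_error(gen_tissue_image(1, list(5000), 0.1, seed = 1), "too large")
})

test_that("curve generator agrees with closed forms at zero noise", {
  gt <- curve_ground_truth("4PL", list(top = 0.9, bottom = 0.1,
                                       logIC50 = -5, hill = 1.3))
  expect_equal(gen_curve(gt, -5)$y, (0.9 + 0.1) / 2)   # 4PL midpoint
  gtb <- curve_ground_truth("boltzmann", list(f_min = 10, f_max = 90,
                                              tm_c = 55, slope_a = 2))
  expect_equal(gen_curve(gtb, 55)$y, 50)               # sigmoid midpoint
  gti <- curve_ground_truth("wiseman_one_site",
                            list(n_sites = 1, K_A = 1e5, delta_H = 0,
                                 cell_conc = 5e-5))
  expect_true(all(gen_curve(gti, seq(0.1, 2, 0.1))$y == 0))
  expect_error(curve_ground_truth("5PL", list()), "unknown model")
  expect_error(curve_ground_truth("4PL", list(top = 1, bottom = 0,
                                              logIC50 = -5, hill = 0)),
               "hill")
  expect_error(gen_curve(gtb, c(30, 20, 50)), "increasing")
  noisy <- curve_ground_truth("4PL", list(top = 1, bottom = 0,
                                          logIC50 = -5, hill = 1),
                              noise_sd = 0.05, seed = 4)
  expect_identical(gen_curve(noisy, -7:-3), gen_curve(noisy, -7:-3))
})

test_that("two-state generator builds an exact hinge", {
  still <- gen_two_state(30, angle_deg = 0, jitter_sd = 0, seed = 2)
  expect_equal(still$open_coords, still$closed_coords)
  expect_error(gen_two_state(30, 33, axis = c(0, 0, 0), seed = 1), "nonzero")
  ts <- gen_two_state(50, 33, c(0, 0, 1), 0, seed = 2)
  expect_equal(ts$open_coords[ts$domain1_idx, ],
               ts$closed_coords[ts$domain1_idx, ])
  # rotation preserves all pairwise distances within domain 2
  d2o <- dist(ts$open_coords[ts$domain2_idx, ])
  d2c <- dist(ts$closed_coords[ts$domain2_idx, ])
  expect_equal(as.vector(d2o), as.vector(d2c))
})

test_that("flow-event generator respects fractions, means and labels", {
  one <- gen_flow_events(200, c(1, 0, 0, 0), c(0.45, 1, 2, 4), 0.05, seed = 3)
  expect_true(all(one$true_label == "ES"))
  ev <- gen_flow_events(1e4, c(0.3, 0.4, 0.2, 0.1), c(0.45, 1, 2, 4), 0.05,
                        seed = 4)
  emp <- as.numeric(table(ev$true_label)) / 1e4
  req <- c(0.3, 0.4, 0.2, 0.1)
  se <- sqrt(req * (1 - req) / 1e4)
  expect_true(all(abs(emp - req) <= 3 * se))   # binomial sampling bound
  # near-zero cv: nearest-mean classification recovers every label
  tight <- gen_flow_events(2000, c(0.25, 0.25, 0.25, 0.25),
                           c(0.45, 1, 2, 4), cv = 1e-3, seed = 5)
  nearest <- c("ES", "RS", "2C", "4C")[
    apply(abs(outer(tight$intensity, c(0.45, 1, 2, 4), `-`)), 1, which.min)]
  expect_identical(nearest, as.character(tight$true_label))
  expect_error(gen_flow_events(100, c(.25, .25, .25, .25), c(1, 3, 2, 4),
                               0.05, seed = 1), "increasing")
  expect_error(gen_flow_events(100, c(.5, .4, .2, .1), c(1, 2, 3, 4),
                               0.05, seed = 1), "sum to 1")
})

test_that("calibrated images round-trip through 16-bit TIFF + sidecar", {
  g <- gen_cell_image(1, 1, 4, 0.1, 0, seed = 9)
  path <- tempfile(fileext = ".tif")
  write_calibrated_tiff(g$image, path, extra = list(seed = 9))
  back <- read_calibrated_tiff(path)
  expect_identical(names(back$channels), c("dapi", "golgi"))
  expect_equal(back$pixel_size_um, 0.1)
  # 16-bit quantisation: intensities agree to one grey level
  expect_lt(max(abs(back$channels$golgi - g$image$channels$golgi)), 1.01)
  unlink(c(path, paste0(path, ".json")))
})
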