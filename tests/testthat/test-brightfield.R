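# shared synthetic brightfield scene
bf_scene <- local({
  geo <- make_cell_geometry()
  p <- lunula_params()
  pr <- light_protocol(c(10, 0.2), c(12, 18))
  trace <- simulate_area_trace(p, pr, noise_sd = 0, seed = 1, out_dt = 2)
  img <- imaging_spec(background_level = 100, noise_sd = 1.5, seed = 3)
  bs <- render_brightfield_series(geo, trace, img, absorption = 1)
  list(geo = geo, trace = trace, bs = bs, img = img)
})

test_that("triangle threshold separates a dark object from background", {
  set.seed(1)
  v <- c(stats::rnorm(9000, 100, 3), stats::rnorm(500, 20, 3))
  thr <- triangle_threshold(v)
  expect_gt(thr, 30)
  expect_lt(thr, 100)
  expect_equal(triangle_threshold(v * 10) / 10, thr, tolerance = 0.02)
})

test_that("ROI generation recovers the cell body", {
  roi <- generate_roi(bf_scene$bs$frames[[1]], sigma_px = 1.5, close_diameter_px = 7)
  truth <- bf_scene$geo$outer
  iou <- sum(roi & truth) / sum(roi | truth)
  expect_gte(iou, 0.8)
  # closing filled all holes: single simply connected component
  expect_equal(euler_characteristic(roi), 1L)
  # uniform frame has no foreground
  expect_error(generate_roi(matrix(50, 220, 150)), "empty|foreground")
})

test_that("background statistics set the area threshold", {
  fr <- matrix(100, 50, 50)
  roi <- matrix(FALSE, 50, 50); roi[20:30, 20:30] <- TRUE
  bg <- background_threshold(fr, roi)
  expect_equal(bg$threshold, 100)  # zero SD
  set.seed(2)
  fr2 <- matrix(stats::rnorm(200 * 200, 100, 5), 200)
  bg2 <- background_threshold(fr2, roi = matrix(FALSE, 200, 200))
  expect_equal(bg2$threshold, 95, tolerance = 0.5 / 95)
  expect_error(background_threshold(fr, matrix(TRUE, 50, 50)), "background")
})

test_that("area trace recovers the generating contraction to 3%", {
  # clean background isolates the pipeline bookkeeping
  img0 <- imaging_spec(background_level = 100, noise_sd = 0, seed = 3)
  bs0 <- render_brightfield_series(bf_scene$geo, bf_scene$trace, img0,
                                   absorption = 1)
  roi <- generate_roi(bs0$frames[[1]], sigma_px = 1.5, close_diameter_px = 7)
  bg <- background_threshold(bs0$frames[[1]], roi)
  at <- area_trace(bs0, roi, bg$threshold)
  expect_equal(at$relative_area, bf_scene$trace$relative_area,
               tolerance = 0.03)
  # with Gaussian background noise, the mean-minus-one-SD rule counts a
  # known pnorm(-1) fraction of vacated ROI pixels as chloroplast; the
  # measured area sits between the truth and that bound
  roi_n <- generate_roi(bf_scene$bs$frames[[1]], sigma_px = 1.5,
                        close_diameter_px = 7)
  bg_n <- background_threshold(bf_scene$bs$frames[[1]], roi_n)
  at_n <- area_trace(bf_scene$bs, roi_n, bg_n$threshold)$relative_area
  rel <- bf_scene$trace$relative_area
  ub <- rel + stats::pnorm(-1) * (1 - rel) + 0.03
  expect_true(all(at_n >= rel - 0.03 & at_n <= ub))
  # all-bright ROI counts no chloroplast pixels
  bright <- list(matrix(100, 220, 150))
  expect_equal(area_trace(bright, roi, threshold = 50)$area_px, 0)
  # constant series gives a constant area
  const <- list(bf_scene$bs$frames[[1]], bf_scene$bs$frames[[1]])
  ac <- area_trace(const, roi, bg$threshold)
  expect_equal(ac$area_px[1], ac$area_px[2])
})

test_that("loss ratio tracks the projected area for an opaque chloroplast", {
  roi <- generate_roi(bf_scene$bs$frames[[1]], sigma_px = 1.5, close_diameter_px = 7)
  bg_roi <- !roi & !EBImage::dilate(EBImage::Image(roi * 1),
                                    EBImage::makeBrush(15, "disc")) > 0.5
  lt <- loss_trace(bf_scene$bs, roi, bg_roi)
  expect_equal(lt$loss_ratio[1], 1)
  # equal frames give loss ratio 1 throughout
  const <- list(bf_scene$bs$frames[[1]], bf_scene$bs$frames[[1]])
  expect_equal(loss_trace(const, roi, bg_roi)$loss_ratio, c(1, 1),
               tolerance = 1e-12)
  # opaque case: loss ratio and relative area share the dynamics
  rel <- bf_scene$trace$relative_area
  expect_lt(sqrt(mean((lt$loss_ratio - rel)^2)), 0.03)
  expect_equal(min(lt$loss_ratio), min(rel), tolerance = 0.05)
  # error when the "cell" is brighter than the background
  inv <- lapply(bf_scene$bs$frames, function(f) max(f) - f)
  expect_error(loss_trace(inv, roi, bg_roi), "darker")
})

test_that("pipeline is invariant to global intensity scaling", {
  scaled <- lapply(bf_scene$bs$frames, function(f) f * 7.3)
  roi1 <- generate_roi(bf_scene$bs$frames[[1]], sigma_px = 1.5, close_diameter_px = 7)
  roi2 <- generate_roi(scaled[[1]], sigma_px = 1.5, close_diameter_px = 7)
  expect_equal(roi1, roi2, ignore_attr = TRUE)
  bg1 <- background_threshold(bf_scene$bs$frames[[1]], roi1)
  bg2 <- background_threshold(scaled[[1]], roi2)
  a1 <- area_trace(bf_scene$bs, roi1, bg1$threshold)
  a2 <- area_trace(scaled, roi2, bg2$threshold)
  expect_equal(a1$area_px, a2$area_px)
  bg_roi <- !EBImage::dilate(EBImage::Image(roi1 * 1),
                             EBImage::makeBrush(15, "disc")) > 0.5
  expect_equal(loss_trace(bf_scene$bs, roi1, bg_roi)$loss_ratio,
               loss_trace(scaled, roi1, bg_roi)$loss_ratio, tolerance = 1e-12)
})

test_that("half-cell ROIs partition the measured area", {
  roi <- generate_roi(bf_scene$bs$frames[[1]], sigma_px = 1.5, close_diameter_px = 7)
  cut <- round(mean(which(rowSums(roi) > 0)))
  left <- roi; left[(cut + 1):nrow(roi), ] <- FALSE
  right <- roi; right[1:cut, ] <- FALSE
  bg <- background_threshold(bf_scene$bs$frames[[1]], roi)
  a_full <- area_trace(bf_scene$bs, roi, bg$threshold)$area_px
  a_l <- area_trace(bf_scene$bs, left, bg$threshold)$area_px
  a_r <- area_trace(bf_scene$bs, right, bg$threshold)$area_px
  expect_equal(a_l + a_r, a_full)
})
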