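test_that("circularity matches closed forms and decreases with elongation", {
  cal2 <- pixel_calibration(2)
  disk <- make_explant_mask(400, 400, 0, calibration = cal2)$mask
  expect_equal(circularity(disk), 1, tolerance = 0.02)

  rect <- matrix(FALSE, 120, 420)
  rect[11:110, 11:410] <- TRUE                       # 400 x 100 px
  c_rect <- circularity(explant_mask(rect, pixel_calibration(1)))
  expect_equal(c_rect, 4 * pi * 400 * 100 / (2 * (400 + 100))^2,
               tolerance = 0.02 / 0.503)             # 0.503 +/- 0.02

  extended <- make_explant_mask(600, 200, 0.4, indentation_depth = 60,
                                calibration = cal2)$mask
  body <- make_explant_mask(360, 200, 0, calibration = cal2)$mask
  expect_lt(circularity(extended), circularity(body))

  # scale invariance: same raster, different calibration
  expect_equal(circularity(explant_mask(rect, pixel_calibration(0.5))),
               c_rect)
})

test_that("extension classification finds the neck and honours thresholds", {
  cal <- pixel_calibration(2)
  fx <- make_explant_mask(600, 200, 0.4, indentation_depth = 60,
                          calibration = cal)
  cls <- classify_extension(fx$mask)
  expect_true(cls$extended)
  expect_lt(sqrt(sum((cls$indentation_point - fx$truth$indentation_point)^2)),
            10)

  convex <- make_explant_mask(500, 260, 0, calibration = cal)
  expect_false(classify_extension(convex$mask)$extended)

  shallow <- make_explant_mask(600, 200, 0.4, indentation_depth = 20,
                               calibration = cal)
  expect_message(res <- classify_extension(shallow$mask), "borderline")
  expect_false(res$extended)

  # manual override wins and is logged
  manual <- explant_mask(fx$mask$mask, cal, indentation_point = c(100, 100))
  expect_message(mres <- classify_extension(manual), "manual")
  expect_true(mres$extended)
  expect_equal(mres$indentation_point, c(100, 100))
})

test_that("extension length is the geodesic tip-to-indentation fraction", {
  cal <- pixel_calibration(2)
  fx <- make_explant_mask(600, 200, 0.4, indentation_depth = 60,
                          calibration = cal)
  expect_equal(extension_length(fx$mask, fx$truth$indentation_point), 0.4,
               tolerance = 0.03 / 0.4)

  # straight bar, indentation at the midpoint -> 0.5
  bar <- matrix(FALSE, 40, 220)
  bar[11:30, 11:210] <- TRUE
  bm <- explant_mask(bar, pixel_calibration(1))
  expect_equal(extension_length(bm, c(110, 20)), 0.5, tolerance = 0.02 / 0.5)
  # indentation at the tip -> ~0
  expect_lt(extension_length(bm, c(209, 20)), 0.05)
})

test_that("geodesic distance map equals Dijkstra shortest paths, C-shape included", {
  set.seed(31)
  # random blobby masks
  for (rep in 1:3) {
    m <- matrix(FALSE, 24, 24)
    m[6:20, 4:21] <- TRUE
    m[cbind(sample(6:20, 25, TRUE), sample(4:21, 25, TRUE))] <- FALSE
    m <- EBImage::bwlabel(m * 1) == 1   # keep one component
    if (!any(m)) next
    seed_px <- which(m, arr.ind = TRUE)[1, , drop = FALSE]
    expect_equal(explantr:::geodesic_distance_map(m, seed_px),
                 oracle_geodesic(m, seed_px), tolerance = 1e-12)
  }
  # C-shaped mask, 64 x 64: the path must wrap around the gap
  cm <- matrix(FALSE, 64, 64)
  g <- expand.grid(r = 1:64, c = 1:64)
  rad <- sqrt((g$r - 32)^2 + (g$c - 32)^2)
  ang <- atan2(g$r - 32, g$c - 32)
  cm[as.matrix(g[rad >= 12 & rad <= 26 & abs(ang) > 0.5, ])] <- TRUE
  cm <- EBImage::bwlabel(cm * 1) == 1
  # seed at one end of the C, so the far end must be reached the long way
  fg <- which(cm, arr.ind = TRUE)
  fg_ang <- atan2(fg[, 1] - 32, fg[, 2] - 32)
  seed_px <- fg[which.min(abs(fg_ang - 0.6)), , drop = FALSE]
  dm <- explantr:::geodesic_distance_map(cm, seed_px)
  or <- oracle_geodesic(cm, seed_px)
  expect_equal(dm, or, tolerance = 1e-12)
  # geodesic exceeds Euclidean across the hook
  eu <- sqrt((g$r - seed_px[1])^2 + (g$c - seed_px[2])^2)
  expect_gt(max(dm - matrix(eu, 64, 64), na.rm = TRUE), 10)
})

test_that("shape profile reconstructs half-widths from the reference axis", {
  rect <- matrix(FALSE, 84, 204)
  rect[13:72, 3:202] <- TRUE                        # 200 x 60 px bar
  em <- explant_mask(rect, pixel_calibration(1))
  box <- list(start = c(20, 42), end = c(180, 42), width_px = 1)
  pr <- shape_profile(em, box, side = "left")
  mid <- pr[pr$station_um > 30 & pr$station_um < 130, ]
  expect_true(all(abs(mid$halfwidth_um - 30) <= 1.5))

  # disk: profile maximal at the central station
  diskm <- make_explant_mask(200, 200, 0, calibration = pixel_calibration(1))$mask
  dbox <- list(start = c(60, 104), end = c(150, 104), width_px = 1)
  dpr <- shape_profile(diskm, dbox)
  centre <- dpr$station_um[which.max(dpr$halfwidth_um)]
  expect_lt(abs(centre - 45), 12)   # box start is 60 um; disk centre ~104

  expect_error(shape_profile(em, list(start = c(20, 2), end = c(180, 2))),
               "outside")
})

test_that("domain length/width follows the axis and analytic ellipses", {
  rectm <- matrix(FALSE, 70, 220)
  rectm[11:60, 11:210] <- TRUE                       # 200 x 50 um at 1 um/px
  cal <- pixel_calibration(1)
  expect_equal(domain_length_width(rectm, 0, cal), 4, tolerance = 0.01)
  expect_equal(domain_length_width(rectm, 90, cal), 0.25, tolerance = 0.01)
  for (th in c(0, 30, 60)) {
    el <- raster_ellipse(90, 30, theta_deg = th)
    expect_equal(domain_length_width(el, th, cal), 3, tolerance = 0.05)
  }
})

test_that("area fractions and domain areas count pixels correctly", {
  cal <- pixel_calibration(1)
  dom <- matrix(FALSE, 60, 60); dom[11:50, 11:30] <- TRUE
  # region polygon = right half of the domain's bounding square
  region_all <- cbind(c(10, 50, 50, 10), c(10, 10, 50, 50))
  expect_equal(domain_area_fraction(dom, cbind(c(10, 30, 30, 10),
                                               c(10, 10, 50, 50)), cal),
               1, tolerance = 0.05)
  expect_equal(domain_area_fraction(dom, region_all, cal), 0.5,
               tolerance = 0.02)
  far <- cbind(c(52, 58, 58, 52), c(52, 52, 58, 58))
  expect_equal(domain_area_fraction(dom, far, cal), 0)

  expl <- matrix(FALSE, 60, 60); expl[6:55, 6:55] <- TRUE
  quarter <- matrix(FALSE, 60, 60); quarter[6:30, 6:30] <- TRUE
  expect_equal(expression_domain_area(quarter, explant_mask(expl, cal)),
               0.25, tolerance = 0.01)
  expect_equal(expression_domain_area(expl, explant_mask(expl, cal)), 1)
  expect_equal(expression_domain_area(matrix(FALSE, 60, 60),
                                      explant_mask(expl, cal)), 0)
  stray <- matrix(FALSE, 60, 60); stray[1:20, 56:60] <- TRUE
  expect_warning(expression_domain_area(stray, explant_mask(expl, cal)),
                 "outside")
})

test_that("embryo axis ratio reproduces closed-form arcs", {
  seg <- rbind(c(0, 0), c(600, 0))
  expect_equal(embryo_axis_ratio(seg, seg), 1)
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(300 * cos(th), 300 * sin(th))
  expect_equal(embryo_axis_ratio(semi, rbind(c(-300, 0), c(300, 0))),
               pi / 2, tolerance = 0.01 / 1.57)
  poly <- cbind(seq(0, 900, by = 10), 0)             # arc 900, height 600
  expect_equal(embryo_axis_ratio(poly, rbind(c(0, 0), c(600, 0))), 1.5)
  expect_error(embryo_axis_ratio(seg, rbind(c(1, 1), c(1, 1))), "height")
})

test_that("dimensionless shape measures are invariant to uniform rescaling", {
  fx <- make_explant_mask(600, 200, 0.4, indentation_depth = 60,
                          calibration = pixel_calibration(2))
  m <- fx$mask$mask
  for (psz in c(1, 4)) {
    em <- explant_mask(m, pixel_calibration(psz))
    expect_equal(circularity(em), circularity(fx$mask))
    ip <- fx$truth$indentation_point / 2 * psz
    expect_equal(extension_length(em, ip),
                 extension_length(fx$mask, fx$truth$indentation_point),
                 tolerance = 1e-9)
  }
})
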