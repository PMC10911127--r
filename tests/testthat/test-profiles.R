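test_that("the spot detector closes the rendering loop", {
  cal <- pixel_calibration(1, 2)
  set.seed(7)
  gx <- expand.grid(x = seq(20, 160, 20), y = seq(20, 140, 20))[1:50, ]
  tab <- as_nucleus_table(data.frame(
    id = 1:50, t = 0, x = gx$x + runif(50, -3, 3), y = gx$y + runif(50, -3, 3),
    z = runif(50, 6, 14), dapi = 100, psmad5 = 50))
  rc <- render_channels(tab, cal, blob_sd_um = 3, snr = 20, seed = 2)
  det <- quiet(detect_nuclei(rc$channels$dapi, cal,
                             channels = rc$channels["psmad5"]))
  d <- as.matrix(dist(rbind(cbind(tab$x, tab$y, tab$z),
                            cbind(det$x, det$y, det$z))))
  d <- d[1:50, 50 + seq_len(nrow(det)), drop = FALSE]
  expect_gte(sum(apply(d, 1, min) <= 1.5), 48)           # matched within ~1 px
  expect_lte(nrow(det) - sum(apply(d, 2, min) <= 1.5), 2) # spurious

  expect_equal(nrow(detect_nuclei(array(0, c(32, 32, 4)), cal)), 0L)

  # two nuclei closer than the nuclear scale merge into one detection
  close2 <- as_nucleus_table(data.frame(id = 1:2, t = 0, x = c(30, 38),
                                        y = 30, z = 10, dapi = 100))
  rcc <- render_channels(close2, cal, blob_sd_um = 3, snr = Inf)
  expect_message(dd <- detect_nuclei(rcc$channels$dapi, cal), "merged")
  expect_equal(nrow(dd), 1L)
})

test_that("QC filtering removes flagged nuclei and out-of-depth rows", {
  sim <- simulate_gradient_nuclei(gradient_params(n_nuclei = 100, seed = 6),
                                  geometry = list(axis_length_um = 500,
                                                  width_um = 200,
                                                  depth_range_um = c(0, 170)))
  tb <- sim$table
  tb$enveloping_layer[1:6] <- TRUE
  tb$dividing[7:10] <- TRUE
  tb$depth_um[11:15] <- 200            # out of the 180 um window
  tb$z[11:15] <- 200
  out <- quiet(qc_filter(tb, run_config("explant")))
  expect_equal(nrow(out), 85L)
  rem <- attr(out, "removed")
  expect_equal(unname(rem[c("enveloping_layer", "dividing", "depth")]),
               c(6L, 4L, 5L))
  # identity on clean tables
  clean <- quiet(qc_filter(sim$table, run_config("explant")))
  expect_equal(nrow(clean), 100L)
})

test_that("projected reference distances match the brute-force oracle", {
  tab <- as_nucleus_table(data.frame(id = 1:2, t = 0, x = c(3, 1), y = c(4, 0),
                                     z = c(50, 10)))
  d <- distance_to_reference(tab, data.frame(x = 0, y = 0))
  expect_equal(d$dist_um[1], 5)        # 3-4-5, z ignored
  expect_equal(max(d$dist_norm), 1)

  set.seed(23)
  for (rep in 1:5) {
    n <- sample(20:200, 1); m <- sample(3:50, 1)
    tb <- as_nucleus_table(data.frame(id = 1:n, t = 0,
                                      x = runif(n, 0, 500),
                                      y = runif(n, 0, 300), z = 0))
    ct <- data.frame(x = runif(m, 0, 500), y = runif(m, 0, 300))
    got <- distance_to_reference(tb, ct)
    want <- oracle_min_dist(tb$x, tb$y, ct$x, ct$y)
    expect_equal(got$dist_um, want, tolerance = 1e-12)
    expect_equal(got$dist_norm, want / max(want), tolerance = 1e-12)
  }
  expect_error(distance_to_reference(tab[1, ], data.frame(x = 0, y = 0)),
               "single nucleus")
})

test_that("cytoplasmic background is recovered and subtracted with clamping", {
  sim <- simulate_gradient_nuclei(gradient_params(background_level = 20,
                                                  intensity_cv = 0.02,
                                                  seed = 14))
  bs <- quiet(background_subtract(sim$table, sim$background_spots))
  expect_equal(unname(attr(bs, "background")["psmad5"]), 20,
               tolerance = 0.02)      # 12 spots at 2% CV
  tb <- as_nucleus_table(data.frame(id = 1:2, t = 0, x = 0, y = 0, z = 0,
                                    psmad5 = c(100, 10), dapi = 50))
  expect_warning(out <- background_subtract(tb, c(18, 20, 22)), "clamped")
  expect_equal(out$psmad5_corrected, c(80, 0))
  expect_error(background_subtract(tb, numeric(0)), "no background spots")
})

test_that("profiles bin, exclude edges and reference as configured", {
  cfg <- run_config("explant")
  # flat fixture, self-referenced: every reported bin = 1
  fl <- simulate_gradient_nuclei(gradient_params(profile_shape = "flat",
                                                 intensity_cv = 0, dapi_cv = 0,
                                                 n_nuclei = 3000, seed = 5))
  ftab <- run_gradient_pipeline(fl)
  fpr <- quiet(build_profile(ftab, cfg))
  expect_equal(nrow(fpr), 25L)
  expect_equal(sum(fpr$excluded), 2L)
  expect_equal(sum(!fpr$excluded & !is.na(fpr$intensity)), 23L)
  expect_equal(fpr$intensity[!fpr$excluded], rep(1, 23), tolerance = 1e-9)
  expect_equal(sum(fpr$n), nrow(ftab))   # bin conservation incl. edges

  # embryo mode: w = 0.02 with two excluded bins per edge (4% per edge)
  epr <- quiet(build_profile(ftab, run_config("embryo")))
  expect_equal(nrow(epr), 50L)
  expect_equal(sum(epr$excluded), 4L)

  # exponential fixture: reported bins match the analytic bin average
  ex <- simulate_gradient_nuclei(gradient_params(decay_length = 0.25,
                                                 intensity_cv = 0, dapi_cv = 0,
                                                 n_nuclei = 20000, seed = 11))
  etab <- run_gradient_pipeline(ex)
  pr <- quiet(build_profile(etab, cfg))
  lam <- 0.25; w <- 0.04
  bin_avg <- function(k) lam / w * (exp(-k * w / lam) - exp(-(k + 1) * w / lam))
  want <- bin_avg(pr$bin) / bin_avg(1)   # referenced to the first reported bin
  ok <- !pr$excluded
  expect_equal(pr$intensity[ok], want[ok], tolerance = 0.01)

  expect_error(quiet(build_profile(etab, cfg, reference = 0)), "positive")
})

test_that("control referencing averages the designated bin across replicates", {
  prs <- lapply(1:3, function(s) {
    sim <- simulate_gradient_nuclei(gradient_params(intensity_cv = 0.05,
                                                    seed = s))
    quiet(build_profile(run_gradient_pipeline(sim), run_config("explant"),
                        reference = 1))
  })
  ref <- control_reference(prs)
  expect_equal(ref, mean(vapply(prs, function(p)
    attr(p, "designated_bin_mean"), 0)))
  sim <- simulate_gradient_nuclei(gradient_params(seed = 99))
  pr <- quiet(build_profile(run_gradient_pipeline(sim), run_config("explant"),
                            reference = ref))
  expect_equal(attr(pr, "reference_value"), ref)
})

test_that("top-decile position tracks the gradient range and handles ties", {
  # n = 20, intensity strictly decreasing with distance: top 2 are nearest
  tb <- as_nucleus_table(data.frame(id = 1:20, t = 0, x = 1:20, y = 0, z = 0,
                                    psmad5_corrected = 20:1, dapi = 1))
  tb <- distance_to_reference(tb, data.frame(x = 0, y = 0))
  expect_equal(top_decile_position(tb), mean(c(1, 2) / 20))

  tied <- tb
  tied$psmad5_corrected <- 1
  expect_message(p <- top_decile_position(tied), "tie")
  expect_equal(p, mean(tied$dist_norm))

  # under the generators' reference noise level (10% CV) a longer-ranged
  # gradient lets high-intensity nuclei sit farther out in every seeded run
  for (s in 1:10) {
    pos <- vapply(c(0.15, 0.40), function(dl) {
      sim <- simulate_gradient_nuclei(gradient_params(decay_length = dl,
                                                      seed = 310 + s))
      top_decile_position(run_gradient_pipeline(sim))
    }, 0)
    expect_lt(pos[1], pos[2])
  }
  expect_error(top_decile_position(tb[1:5, ]), ">= 10")
})

test_that("domain extent finds the positive front along the axis", {
  # pSmad5-positive back half by construction
  set.seed(41)
  n <- 400
  u <- runif(n)
  # low side carries bounded uniform noise: the mean + 2 sd rule then sits
  # above its maximum, so positivity is exact by construction
  tb <- as_nucleus_table(data.frame(
    id = 1:n, t = 0, x = u * 500, y = runif(n, 0, 200), z = 0,
    psmad5_corrected = ifelse(u < 0.5, 60 + rnorm(n, 0, 1.5),
                              runif(n, 0, 5)),
    dapi = 50))
  tb <- distance_to_reference(tb, data.frame(x = 0, y = seq(0, 200, 10)))
  ext <- domain_extent(tb, "psmad5")
  expect_equal(as.numeric(ext), 0.5, tolerance = 0.04 / 0.5)

  allpos <- tb; allpos$psmad5_corrected <- 60
  expect_equal(as.numeric(domain_extent(allpos, "psmad5", threshold = 0.5)), 1,
               tolerance = 0.02)
  allneg <- tb; allneg$psmad5_corrected <- 0
  expect_warning(z <- domain_extent(allneg, "psmad5", threshold = 0.5),
                 "extent = 0")
  expect_equal(as.numeric(z), 0)

  # EGFP enters from the tip: first positive position
  egfp <- tb
  egfp$psmad5_corrected <- ifelse(u > 0.6, 60, 0)
  expect_equal(as.numeric(domain_extent(egfp, "egfp", threshold = 0.5)), 0.6,
               tolerance = 0.05)

  # mask variant
  dom <- matrix(FALSE, 50, 200); dom[, 1:100] <- TRUE
  expect_equal(domain_extent_mask(dom, c(0, 25), c(199, 25),
                                  calibration = pixel_calibration(1)),
               0.5, tolerance = 0.02)
})

test_that("graded/radial calls follow the ratio and trend thresholds", {
  cfg <- run_config("explant")
  fl <- simulate_gradient_nuclei(gradient_params(profile_shape = "flat",
                                                 intensity_cv = 0.02,
                                                 dapi_cv = 0, seed = 3))
  fpr <- quiet(build_profile(run_gradient_pipeline(fl), cfg))
  expect_equal(classify_profile(fpr)$class, "radial")

  ex <- simulate_gradient_nuclei(gradient_params(decay_length = 0.25,
                                                 intensity_cv = 0,
                                                 dapi_cv = 0, seed = 3))
  epr <- quiet(build_profile(run_gradient_pipeline(ex), cfg))
  cls <- classify_profile(epr)
  expect_equal(cls$class, "graded")
  expect_gt(cls$high_low_ratio, 2)
  expect_lt(cls$spearman_rho, -0.5)

  # threshold sweep on a logistic fixture flips the call exactly once
  lg <- simulate_gradient_nuclei(gradient_params(profile_shape = "logistic",
                                                 decay_length = 1.2,
                                                 intensity_cv = 0,
                                                 dapi_cv = 0, seed = 4))
  lpr <- quiet(build_profile(run_gradient_pipeline(lg), cfg))
  calls <- vapply(seq(1, 40, by = 0.5), function(thr)
    classify_profile(lpr, ratio_threshold = thr)$class == "graded", TRUE)
  expect_equal(sum(diff(calls) != 0), 1L)
  expect_true(calls[1])
  expect_false(calls[length(calls)])
})

test_that("DAPI normalization cancels shared depth attenuation in profiles", {
  base <- gradient_params(decay_length = 0.2, intensity_cv = 0, dapi_cv = 0,
                          background_level = 0, depth_attenuation = 0,
                          seed = 19)
  att <- gradient_params(decay_length = 0.2, intensity_cv = 0, dapi_cv = 0,
                         background_level = 0, depth_attenuation = 0.2,
                         seed = 19)
  p0 <- quiet(build_profile(run_gradient_pipeline(simulate_gradient_nuclei(base)),
                            run_config("explant")))
  p1 <- quiet(build_profile(run_gradient_pipeline(simulate_gradient_nuclei(att)),
                            run_config("explant")))
  ok <- !p0$excluded
  expect_equal(p1$intensity[ok], p0$intensity[ok], tolerance = 1e-6)
})
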