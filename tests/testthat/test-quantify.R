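test_that("scale factor matches its defining ratio and limits", {
  cst <- quant_constants()
  k <- amwf_scale_factor(cst, stair_protocol(), pd_protocol())
  # independent evaluation of the two per-unit-m0 scales
  num <- exp(-5.5 / 60)
  den <- (1 + 0.75 * exp(-250 / 220) - 1.75 * exp(-117 / 220)) * exp(-5.5 / 10)
  expect_equal(k, num / den, tolerance = 1e-12)
  expect_equal(k, 7.44, tolerance = 1e-3)
  # no decay and no inversion effect: both signals reduce to m0
  cst1 <- quant_constants(q_mw = 1)
  k1 <- amwf_scale_factor(cst1, seq_params(9000, 8999, 0), seq_params(9000, NULL, 0))
  expect_equal(k1, 1, tolerance = 1e-12)
  # k grows with the total-water T2* (less PD decay to divide out)
  k2 <- amwf_scale_factor(quant_constants(t2s_total_ms = 120))
  expect_gt(k2, k)
})

test_that("noiseless model-matched forward + quantify is the identity", {
  spec <- tiny_spec(seed = 4)
  lab <- build_label_map(spec, "patient")
  cls <- tissue_classes()
  st <- simulate_acquisition(lab, cls, stair_protocol(), noise_sigma = 0)
  pd <- simulate_acquisition(lab, cls, pd_protocol(), noise_sigma = 0)
  map <- compute_amwf_map(st, pd)
  truth <- c(NAWM = 0.085, GM = 0.03, lesion = 0.036)
  codes <- c(NAWM = 1, GM = 2, lesion = 4)
  for (cl in names(truth)) {
    sel <- (lab$tissue == codes[[cl]]) & map$mask
    expect_gt(sum(sel), 0)
    expect_lt(max(abs(map$data[sel] - truth[[cl]])), 1e-10)
  }
  expect_equal(map$n_clipped_low, 0)
  # scale invariance: common intensity scaling cancels in the ratio
  st2 <- mwi_volume(vol <- as.array(st) * 3.7, attr(st, "voxel_mm"))
  pd2 <- mwi_volume(as.array(pd) * 3.7, attr(pd, "voxel_mm"))
  map2 <- compute_amwf_map(st2, pd2)
  expect_equal(map2$data[map2$mask], map$data[map$mask], tolerance = 1e-12)
})

test_that("two-pool forward produces the known apparent-MWF bias that shrinks toward the null", {
  cst <- quant_constants()
  k <- amwf_scale_factor(cst)
  apparent <- function(t1_long, amwf = 0.099, t2s_long = 60) {
    mwp <- (1 + 0.75 * exp(-250 / 220) - 1.75 * exp(-117 / 220)) * exp(-5.5 / 10)
    lng <- (1 + exp(-250 / t1_long) - 2 * exp(-117 / t1_long)) *
      exp(-5.5 / t2s_long)
    pdv <- amwf * exp(-5.5 / 10) + (1 - amwf) * exp(-5.5 / t2s_long)
    k * (amwf * mwp + (1 - amwf) * lng) / pdv
  }
  # frozen two-pool WM value: apparent aMWF ~ 0.119 for truth 0.099
  expect_equal(apparent(850), 0.1193, tolerance = 1e-3)

  # the same number must come out of the simulation + map pipeline
  spec <- tiny_spec(seed = 4, mode = "two_pool")
  lab <- build_label_map(spec, "control")
  cls <- tissue_classes()
  st <- simulate_acquisition(lab, cls, stair_protocol(), mode = "two_pool",
                             noise_sigma = 0)
  pd <- simulate_acquisition(lab, cls, pd_protocol(), mode = "two_pool",
                             noise_sigma = 0)
  map <- compute_amwf_map(st, pd)
  wm <- (lab$tissue == 1) & map$mask
  cls_nwm <- cls[cls$name == "NWM", ]
  expect_equal(mean(map$data[wm]),
               apparent(cls_nwm$t1_long_ms, cls_nwm$amwf_true),
               tolerance = 1e-10)
  # positive leakage bias, shrinking monotonically toward the band null
  bias <- vapply(c(700, 800, 850, 900), function(t1)
    apparent(t1) - 0.099, numeric(1))
  expect_true(all(bias > 0))
  expect_true(all(diff(bias) < 0))
})

test_that("map handles degenerate inputs and accounts for clipping", {
  dims <- c(8, 8, 3)
  ones <- mwi_volume(array(1, dims))
  zeros_st <- mwi_volume(array(0, dims))
  mask <- array(TRUE, dims)
  map0 <- compute_amwf_map(zeros_st, ones, mask = mask)
  expect_true(all(map0$data[map0$mask] == 0))

  # negatives are clipped to zero and counted
  st <- array(0.01, dims); st[1:5] <- -0.01
  mapn <- compute_amwf_map(mwi_volume(st), ones, mask = mask)
  expect_equal(mapn$n_clipped_low, 5)
  expect_true(all(mapn$data[mapn$mask] >= 0))

  expect_error(compute_amwf_map(mwi_volume(array(1, c(4, 4, 4))), ones),
               class = "stairmwi_geometry_error")
})

test_that("PD-driven mask covers the brain and shrinks with the threshold", {
  spec <- phantom_spec(seed = 6)
  lab <- build_label_map(spec, "control")
  pd <- simulate_acquisition(lab, tissue_classes(), pd_protocol(),
                             noise_sigma = 0)
  mask <- make_mask(pd, 0.1)
  brain <- lab$tissue %in% 1:2
  expect_true(all(mask[brain]))
  expect_false(any(mask[lab$tissue == 0]))
  # monotone shrinkage with the threshold
  tighter <- make_mask(pd, 0.9)
  expect_true(all(mask[tighter]))
  expect_lt(sum(tighter), sum(mask))
  expect_error(make_mask(mwi_volume(array(0, c(8, 8, 3)))), "Empty mask")
  expect_error(make_mask(pd, 1.5), "0, 1")
})

test_that("mask keeps only the largest connected component", {
  x <- array(0, c(12, 12, 3))
  x[2:9, 2:9, 1:3] <- 1       # big blob
  x[11:12, 11:12, 1] <- 1     # detached speck
  m <- make_mask(mwi_volume(x), 0.5)
  expect_true(all(m[2:9, 2:9, 1:3]))
  expect_false(any(m[11:12, 11:12, 1]))
})

test_that("ROI statistics report means, empty ROIs and name lookups", {
  spec <- tiny_spec(seed = 9)
  lab <- build_label_map(spec, "control")
  cls <- tissue_classes()
  st <- simulate_acquisition(lab, cls, stair_protocol(), noise_sigma = 0)
  pd <- simulate_acquisition(lab, cls, pd_protocol(), noise_sigma = 0)
  map <- compute_amwf_map(st, pd)
  stats <- extract_roi_stats(map, lab$roi, subject_id = "s1")
  expect_equal(nrow(stats), spec$n_rois)
  expect_true(all(abs(stats$mean - 0.099) < 1e-10))
  expect_true(all(stats$n_voxels > 0))
  expect_equal(stats$subject_id, rep("s1", spec$n_rois))

  # ROI entirely outside the mask -> n_voxels = 0, absent mean
  empty_mask <- map
  empty_mask$mask <- map$mask & !(as.array(lab$roi) == 1)
  s2 <- extract_roi_stats(empty_mask, lab$roi)
  expect_equal(s2$n_voxels[s2$roi_name == "roi1"], 0)
  expect_true(is.na(s2$mean[s2$roi_name == "roi1"]))

  expect_error(extract_roi_stats(map, lab$roi, roi_names = "only_one"),
               class = "stairmwi_lookup_error")
})

test_that("cohort quantification labels groups and recovers subject truths exactly without noise", {
  spec <- tiny_spec(seed = 21, noise_sigma = 0)
  coh <- simulate_cohort(spec, n_controls = 2, n_patients = 2, seed = 21)
  obs <- quantify_cohort(coh)
  expect_setequal(unique(obs$group), c("NWM", "NAWM", "lesion"))
  truth <- coh$truth
  for (r in seq_len(nrow(obs))) {
    cl <- if (obs$group[r] == "lesion") "lesion" else obs$group[r]
    tv <- truth$amwf_true[truth$subject_id == obs$subject_id[r] &
                            truth$name == cl]
    expect_equal(obs$value[r], tv, tolerance = 1e-10)
  }
})
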