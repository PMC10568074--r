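test_that("label maps are deterministic and anatomically consistent", {
  spec <- phantom_spec(seed = 7)
  a <- build_label_map(spec, "patient")
  b <- build_label_map(spec, "patient")
  expect_identical(as.array(a$tissue), as.array(b$tissue))
  expect_identical(as.array(a$roi), as.array(b$roi))
  expect_identical(as.array(a$lesion), as.array(b$lesion))

  # lesions occupy what would otherwise be white matter (tissue geometry is
  # seed-independent, so the control map gives the pre-lesion anatomy)
  ctrl <- build_label_map(spec, "control")
  expect_true(all(ctrl$tissue[a$lesion > 0] == 1))
  expect_true(all(a$tissue[a$lesion > 0] == 4))
  expect_equal(max(a$lesion), spec$n_lesions)
  # controls carry no lesion label
  expect_false(any(ctrl$tissue == 4))
  expect_false(any(ctrl$lesion > 0))
  # ROIs sit in lesion-free white matter, every voxel labelled
  expect_true(all(a$tissue[a$roi > 0] == 1))
  expect_equal(sort(unique(as.integer(a$roi[a$roi > 0]))), 1:spec$n_rois)
  expect_true(all(a$tissue %in% 0:4))
  expect_equal(ctrl$wm_class, "NWM")
  expect_equal(a$wm_class, "NAWM")
})

test_that("noiseless voxel values follow the forward equations in both modes", {
  spec <- tiny_spec(seed = 3)
  lab <- build_label_map(spec, "patient")
  cls <- tissue_classes()
  cst <- quant_constants()
  st_mm <- simulate_acquisition(lab, cls, stair_protocol(), cst,
                                mode = "model_matched", noise_sigma = 0)
  pd_mm <- simulate_acquisition(lab, cls, pd_protocol(), cst,
                                mode = "model_matched", noise_sigma = 0)
  wm <- lab$tissue == 1  # patient WM -> NAWM parameters
  ratio <- st_mm[wm] / pd_mm[wm]
  expect_equal(unique(round(ratio, 12)),
               0.085 * mw_signal_scale(cst, stair_protocol()) /
                 exp(-5.5 / cst$t2s_total_ms),
               tolerance = 1e-10)
  # background voxels carry no signal
  expect_true(all(st_mm[lab$tissue == 0] == 0))

  # two-pool mode adds positive long-T1 leakage in white matter at TI ~ 117
  st_tp <- simulate_acquisition(lab, cls, stair_protocol(), cst,
                                mode = "two_pool", noise_sigma = 0)
  expect_true(all(st_tp[wm] > st_mm[wm]))
})

test_that("NEX-averaged complex noise has the Rayleigh floor where signal is absent", {
  spec <- phantom_spec(seed = 5)
  lab <- build_label_map(spec, "control")
  sigma <- 0.005
  st <- simulate_acquisition(lab, tissue_classes(),
                             seq_params(250, 117, 5.5, nex = 1L,
                                        label = "STAIR-EPI"),
                             noise_sigma = sigma, seed = 11)
  bg <- st[lab$tissue == 0]
  expect_gt(length(bg), 10000)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("averaged-image noise SD scales as 1/sqrt(NEX)", {
  spec <- tiny_spec(seed = 2, noise_sigma = 0.005)
  lab <- build_label_map(spec, "control")
  cls <- tissue_classes()
  pd0 <- simulate_acquisition(lab, cls, pd_protocol(), noise_sigma = 0)
  wm <- lab$tissue == 1
  sd_at_nex <- function(nex, seed) {
    seqp <- seq_params(250, NULL, 5.5, flip_deg = 5, nex = nex, label = "PD")
    pdn <- simulate_acquisition(lab, cls, seqp, noise_sigma = 0.005,
                                seed = seed)
    sd(pdn[wm] - pd0[wm])
  }
  # PD white matter is deep in the linear (high-SNR) regime at every NEX, so
  # the magnitude image inherits the Gaussian 1/sqrt(NEX) law; WM has enough
  # voxels that each SD estimate is tight
  s1 <- sd_at_nex(1L, 21); s10 <- sd_at_nex(10L, 22); s30 <- sd_at_nex(30L, 23)
  expect_equal(s1 / s10, sqrt(10), tolerance = 0.1)
  expect_equal(s1 / s30, sqrt(30), tolerance = 0.1)
  expect_equal(s1, 0.005, tolerance = 0.1)
})

test_that("between-subject jitter reproduces the requested SD and truncates", {
  set.seed(99)
  draws <- replicate(2000, {
    stairmwi:::jitter_classes(tissue_classes(),
                              c(NWM = 0.013, NAWM = 0.012, lesion = 0.013))
  }, simplify = FALSE)
  nwm <- vapply(draws, function(d) d$amwf_true[d$name == "NWM"], 1)
  les <- vapply(draws, function(d) d$amwf_true[d$name == "lesion"], 1)
  gm <- vapply(draws, function(d) d$amwf_true[d$name == "GM"], 1)
  expect_equal(sd(nwm), 0.013, tolerance = 0.05)
  expect_equal(mean(nwm), 0.099, tolerance = 0.01)
  expect_true(all(gm == 0.03))      # unnamed classes are left alone
  expect_true(all(les >= 0))        # truncated to the physical range
})

test_that("cohorts are reproducible from the master seed", {
  spec <- tiny_spec(seed = 13, noise_sigma = 0.005)
  a <- simulate_cohort(spec, n_controls = 1, n_patients = 1, seed = 13)
  b <- simulate_cohort(spec, n_controls = 1, n_patients = 1, seed = 13)
  for (i in 1:2) {
    expect_identical(as.array(a$subjects[[i]]$stair),
                     as.array(b$subjects[[i]]$stair))
    expect_identical(as.array(a$subjects[[i]]$pd),
                     as.array(b$subjects[[i]]$pd))
  }
  expect_identical(a$truth, b$truth)
  # zero jitter: every subject shares the class means
  c0 <- simulate_cohort(spec, n_controls = 3, n_patients = 0,
                        jitter_sd = c(NWM = 0), seed = 5)
  expect_equal(length(unique(c0$truth$amwf_true[c0$truth$name == "NWM"])), 1)
})

test_that("phantom spec validates its inputs", {
  expect_error(phantom_spec(shape = c(4, 4, 4)), ">= 6")
  expect_error(phantom_spec(n_lesions = -1), ">= 0")
  expect_error(phantom_spec(noise_sigma = -0.1), ">= 0")
  bad <- tissue_classes(); bad$amwf_true[1] <- 0.9
  expect_error(phantom_spec(classes = bad), "0, 0.5")
})
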