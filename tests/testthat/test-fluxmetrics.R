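test_that("the default schedule matches the extended mito stress test", {
  s <- injection_schedule()
  expect_equal(s$n_cycles, 12L)
  expect_equal(s$measure_min, 3)
  expect_equal(s$mix_min, 2)
  expect_equal(s$injections$compound,
               c("oligomycin", "FCCP", "rotenone+antimycin A",
                 "2-deoxyglucose"))
  expect_equal(s$injections$concentration,
               c("1.5 uM", "1 uM", "1.25 uM + 2.5 uM", "50 mM"))
  ph <- schedule_phases(s)
  expect_equal(ph[1:3], rep("basal", 3))
  expect_equal(unique(ph),
               c("basal", "post_om", "post_fccp", "post_rotaa", "post_2dg"))
  expect_length(ph, 12)
})

test_that("schedule validation rejects malformed injections", {
  inj <- injection_schedule()$injections
  inj$first_cycle <- c(4L, 3L, 9L, 11L)
  expect_error(injection_schedule(inj), "increasing")
  inj2 <- injection_schedule()$injections
  inj2$first_cycle[1] <- 1L
  expect_error(injection_schedule(inj2), "\\[2, n_cycles\\]")
})

test_that("flux CSV writer and parser are mutual inverses", {
  p <- synth_flux_plate(n_subjects = 2, wells_per_subject = 3, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_flux_csv(p$flux, f)
  back <- parse_flux_csv(f, injection_schedule())
  expect_equal(back$ocr, p$flux$ocr, tolerance = 1e-12)
  expect_equal(back$ecar, p$flux$ecar, tolerance = 1e-12)
  expect_equal(back$phase, p$flux$phase)
  expect_equal(back$well, p$flux$well)
})

test_that("a full 96-well synthetic plate parses into 96 complete traces", {
  p <- synth_flux_plate(n_subjects = 12, wells_per_subject = 8, seed = 10)
  f <- tempfile(fileext = ".csv")
  write_flux_csv(p$flux, f)
  back <- parse_flux_csv(f)
  expect_equal(length(unique(back$well)), 96)
  expect_true(all(table(back$well) == 12))
})

test_that("the parser rejects duplicates, bad headers and non-monotone time", {
  p <- synth_flux_plate(n_subjects = 1, wells_per_subject = 2, seed = 1)
  f <- tempfile(fileext = ".csv")

  dup <- p$flux[c(seq_len(nrow(p$flux)), 3), ]
  write.csv(data.frame(plate_id = dup$plate_id, well = dup$well,
                       cycle = dup$cycle, time_min = dup$time_min,
                       ocr_pmol_min = dup$ocr, ecar_mph_min = dup$ecar),
            f, row.names = FALSE)
  expect_error(parse_flux_csv(f), "duplicate \\(well, cycle\\)")

  bad <- p$flux
  bad$time_min[5] <- bad$time_min[4] - 1
  write_flux_csv(bad, f)
  expect_error(parse_flux_csv(f), "non-monotone time for well A01")

  writeLines("plate,well,cycle", f)
  expect_error(parse_flux_csv(f), "malformed flux header")
})

test_that("phase_level computes tail means and extrema", {
  tr <- make_trace(c(basal = 0, post_om = 0, post_fccp = 0, post_rotaa = 0,
                     post_2dg = 0))
  tr$ocr[tr$phase == "basal"] <- c(100, 98, 96)
  expect_equal(phase_level(tr, "basal", "last_k_mean", k = 3), 98)

  tr$ocr[tr$phase == "post_om"] <- 55
  expect_equal(phase_level(tr, "post_om", "last_k_mean", k = 3), 55)
  expect_equal(phase_level(tr, "post_om", "extremum"), 55)

  tr$ocr[tr$phase == "post_fccp"] <- c(160, 150)
  expect_equal(phase_level(tr, "post_fccp", "extremum"), 160)  # max for FCCP
  tr$ocr[tr$phase == "post_rotaa"] <- c(22, 20)
  expect_equal(phase_level(tr, "post_rotaa", "extremum"), 20)  # min otherwise

  expect_error(phase_level(tr, "nonsense"), "absent")
  expect_error(phase_level(tr, "post_fccp", "last_k_mean", k = 3), "fewer")
})

test_that("phase_level matches an independent loop on noisy traces", {
  set.seed(15)
  for (i in 1:10) {
    tr <- make_trace(c(basal = 80, post_om = 60, post_fccp = 110,
                       post_rotaa = 20, post_2dg = 10), ocr_noise_sd = 5)
    v <- tr$ocr[tr$phase == "basal"]
    s <- 0; for (x in v[(length(v) - 2):length(v)]) s <- s + x
    expect_equal(phase_level(tr, "basal", "last_k_mean", k = 3), s / 3)
    mn <- Inf; for (x in tr$ocr[tr$phase == "post_rotaa"]) mn <- min(mn, x)
    expect_equal(phase_level(tr, "post_rotaa", "extremum"), mn)
  }
})

test_that("compute_metrics derives the stress-test anatomy from exact steps", {
  tr <- make_trace(c(basal = 100, post_om = 55, post_fccp = 160,
                     post_rotaa = 20, post_2dg = 12))
  m <- compute_metrics(tr)
  expect_equal(m$basal_ocr, 100)
  expect_equal(m$atp_linked, 45)
  expect_equal(m$proton_leak, 35)
  expect_equal(m$src, 60)
  expect_equal(m$nonmito_ocr, 20)
  expect_equal(m$dg_sensitive_nonmito, 8)
  expect_equal(m$basal_ocr_corrected, 80)
})

test_that("a flat trace yields zero for every derived delta", {
  tr <- make_trace(setNames(rep(40, 5),
                            c("basal", "post_om", "post_fccp", "post_rotaa",
                              "post_2dg")))
  m <- compute_metrics(tr)
  expect_equal(m$atp_linked, 0)
  expect_equal(m$proton_leak, 0)
  expect_equal(m$src, 0)
  expect_equal(m$dg_sensitive_nonmito, 0)
  expect_equal(m$om_ecar_response, 0)
})

test_that("the respiration decomposition identity holds on random traces", {
  set.seed(30)
  for (i in 1:30) {
    lv <- c(basal = runif(1, 40, 120), post_om = runif(1, 30, 100),
            post_fccp = runif(1, 50, 200), post_rotaa = runif(1, 5, 40),
            post_2dg = runif(1, 2, 30))
    tr <- make_trace(lv, ocr_noise_sd = 4)
    m <- compute_metrics(tr)
    expect_equal(m$basal_ocr, m$atp_linked + m$proton_leak + m$nonmito_ocr,
                 tolerance = 1e-12)
  }
})

test_that("mitochondrial metrics ignore appended post-2DG cycles", {
  sched_no2dg <- injection_schedule(
    injections = injection_schedule()$injections[1:3, ], n_cycles = 10)
  lv <- c(basal = 90, post_om = 70, post_fccp = 120, post_rotaa = 15,
          post_2dg = 8)
  set.seed(77)
  noise <- rnorm(12, sd = 2)
  full <- make_trace(lv)
  full$ocr <- full$ocr + noise
  short <- full[full$cycle <= 10, ]
  short$phase <- schedule_phases(sched_no2dg)[short$cycle]
  m_full <- compute_metrics(full)
  m_short <- compute_metrics(short)
  for (f in c("basal_ocr", "post_om_ocr", "max_ocr", "nonmito_ocr",
              "atp_linked", "proton_leak", "src"))
    expect_identical(m_full[[f]], m_short[[f]])
  expect_true(is.na(m_short$post_2dg_ocr))
  expect_true(is.na(m_short$dg_sensitive_nonmito))
})

test_that("missing trailing phases yield explicit absent markers", {
  basal_only <- make_trace(c(basal = 50, post_om = 40, post_fccp = 60,
                             post_rotaa = 10, post_2dg = 5))[1:3, ]
  m <- compute_metrics(basal_only)
  expect_equal(m$basal_ocr, 50)
  expect_true(all(is.na(c(m$post_om_ocr, m$max_ocr, m$nonmito_ocr,
                          m$atp_linked, m$proton_leak, m$src))))
  empty <- basal_only[0, ]
  expect_error(compute_metrics(empty, well_id = "B02"), "empty basal phase")
})

test_that("the detection-limit QC boundary is inclusive", {
  m <- data.frame(well = c("A01", "A02", "A03"),
                  basal_ocr = c(19, 20, 110))
  out <- qc_detection_limit(m, 20)
  expect_equal(out$qc_pass, c(FALSE, TRUE, TRUE))
  expect_error(qc_detection_limit(m, 0), "limit > 0")
})

test_that("the phase-level estimator is calibrated on noisy steps", {
  # many replicate traces: the last-3-cycle basal mean is unbiased and its
  # spread matches sigma / sqrt(3)
  sigma <- 5
  set.seed(55)
  est <- replicate(400, {
    tr <- make_trace(c(basal = 100, post_om = 80, post_fccp = 120,
                       post_rotaa = 20, post_2dg = 10), ocr_noise_sd = sigma)
    phase_level(tr, "basal", "last_k_mean", k = 3)
  })
  theo_se <- sigma / sqrt(3)
  expect_lt(abs(mean(est) - 100), 3 * theo_se / sqrt(length(est)))
  expect_lt(abs(sd(est) - theo_se), 3 * theo_se / sqrt(2 * (length(est) - 1)))
})
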