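make_trace <- function(pre = c(190, 200, 200, 210, 220),
                       post = c(300, 320, 310),
                       raa = c(30, 28, 32)) {
  n <- length(pre) + length(post) + length(raa)
  times <- 5 * seq_len(n)
  inj <- tibble::tibble(
    label = c("fccp", "raa"),
    time_min = c(times[length(pre)] + 2.5,
                 times[length(pre) + length(post)] + 2.5)
  )
  ocr_trace(times, c(pre, post, raa), inj)
}

test_that("OCR summary follows the basal / maximal / nonmito rules exactly", {
  tr <- make_trace(pre = c(150, 190, 200, 210, 220))
  s <- ocr_summary(tr)
  # basal = mean of the last three pre-FCCP points
  expect_equal(s$basal, mean(c(200, 210, 220)))
  # default maximal rule: mean of the last three points before R+AA
  expect_equal(s$maximal, mean(c(300, 320, 310)))
  # alternative: maximum observed after FCCP
  expect_equal(ocr_summary(tr, "max_after_fccp")$maximal, 320)
  # nonmitochondrial and mitochondrial basal, exact arithmetic
  expect_equal(s$nonmitochondrial, 30)
  expect_equal(s$mitochondrial_basal, s$basal - s$nonmitochondrial)
  expect_false(s$excluded)

  # basal depends only on the last three pre-FCCP points
  tr2 <- make_trace(pre = c(999, 1, 200, 210, 220))
  expect_equal(ocr_summary(tr2)$basal, s$basal)
})

test_that("FCCP non-responders are flagged, responders never", {
  nonresp <- make_trace(pre = c(200, 200, 210, 210, 210),
                        post = c(150, 140, 150))
  s <- ocr_summary(nonresp)
  expect_true(s$excluded)
  expect_match(s$reason, "FCCP")
  # metrics still reported, trace retained
  expect_equal(s$basal, 210)

  # exclusion on generator traces matches the planted responder flag
  flags <- sapply(1:40, function(i) {
    resp <- i %% 2 == 0
    sim <- make_ocr_trace(responder = resp, noise_sd = 5, seed = 500 + i)
    ocr_summary(sim$trace)$excluded == !resp
  })
  expect_true(all(flags))
})

test_that("OCR summary validates its preconditions", {
  short <- ocr_trace(c(5, 10, 15), c(200, 300, 30),
                     tibble::tibble(label = "fccp", time_min = 7.5))
  expect_error(ocr_summary(short), class = "lc3_validation_error")
  no_fccp <- ocr_trace(c(5, 10, 15, 20), c(200, 200, 200, 200))
  expect_error(ocr_summary(no_fccp), class = "lc3_validation_error")
  expect_error(ocr_trace(c(5, 5, 10), c(1, 2, 3)),
               class = "lc3_validation_error")
  expect_error(ocr_trace(c(5, 10), c(1, 2),
                         tibble::tibble(label = c("fccp", "fccp"),
                                        time_min = c(6, 7))),
               class = "lc3_validation_error")
})

test_that("noise-free generator traces give exact plateau metrics", {
  sim <- make_ocr_trace(basal_level = 210, uncoupled_level = 320,
                        nonmito_level = 30, noise_sd = 0, seed = 1)
  s <- ocr_summary(sim$trace)
  expect_identical(s$basal, 210)
  expect_identical(s$maximal, 320)
  expect_identical(s$nonmitochondrial, 30)
  expect_identical(s$mitochondrial_basal, 180)
})

test_that("control-chamber normalization divides matched timepoints", {
  tr <- ocr_trace(c(5, 10, 15), c(150, 150, 150))
  ct <- ocr_trace(c(5, 10, 15), c(200, 200, 200), role = "control_chamber")
  nz <- normalize_to_control_chamber(tr, ct)
  expect_equal(nz$normalized, rep(0.75, 3))
  # treated = control -> 1 at every step
  expect_equal(normalize_to_control_chamber(ct, ct)$normalized, rep(1, 3))
  # control <= 0 errors
  bad <- ocr_trace(c(5, 10, 15), c(200, 0, 200))
  expect_error(normalize_to_control_chamber(tr, bad),
               class = "lc3_validation_error")
})

test_that("titration generator feeds the 4PL fit to the planted IC50", {
  tt <- make_titration_traces(ic50 = 300, hill = 1.5, noise_sd = 0,
                              seed = 33)
  nz <- normalize_to_control_chamber(tt$treated, tt$control)
  dr <- dose_response_from_titration(nz, tt$segments)
  expect_equal(dr$response, tt$truth$expected_response, tolerance = 1e-12)
  fit <- fit_ic50(dr$dose_um, dr$response)
  expect_lt(abs(fit$ic50 - 300) / 300, 0.001)

  # with noise the downstream fit stays within 5%
  tt2 <- make_titration_traces(ic50 = 300, hill = 1.5, noise_sd = 4,
                               seed = 34)
  nz2 <- normalize_to_control_chamber(tt2$treated, tt2$control)
  dr2 <- dose_response_from_titration(nz2, tt2$segments)
  fit2 <- fit_ic50(dr2$dose_um, dr2$response)
  expect_lt(abs(fit2$ic50 - 300) / 300, 0.05)
})

test_that("activity score is the vacated fraction with exact endpoints", {
  m0 <- matrix(FALSE, 10, 10); m0[3:6, 3:6] <- TRUE
  expect_equal(activity_score(m0, m0), 0)
  m_out <- matrix(FALSE, 10, 10); m_out[8:9, 8:9] <- TRUE
  expect_equal(activity_score(m0, m_out), 1)
  # exactly half the worm pixels retained -> 0.5
  m_half <- m0; m_half[3:4, 3:6] <- FALSE
  expect_equal(activity_score(m0, m_half), 0.5)
  # empty t0 mask -> NA with "worm not found"
  expect_warning(out <- activity_score(matrix(FALSE, 4, 4),
                                       matrix(FALSE, 4, 4)), "not found")
  expect_true(is.na(out))

  # translation invariance: shifting both masks leaves the score unchanged
  shift2 <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[3:nrow(m), 3:ncol(m)] <- m[1:(nrow(m) - 2), 1:(ncol(m) - 2)]
    out
  }
  expect_equal(activity_score(shift2(m0), shift2(m_half)),
               activity_score(m0, m_half))

  # score stays in [0, 1] for random mask pairs
  set.seed(600)
  ok <- replicate(200, {
    a <- matrix(runif(64) < 0.4, 8, 8)
    if (!any(a)) a[1, 1] <- TRUE
    b <- matrix(runif(64) < 0.4, 8, 8)
    s <- activity_score(a, b)
    s >= 0 && s <= 1
  })
  expect_true(all(ok))
})

test_that("active fraction counts scores above threshold per timepoint", {
  rec <- tibble::tibble(
    timepoint_h = rep(c(0, 32), each = 10),
    score = c(rep(0.9, 7), rep(0.1, 3), rep(0.9, 10)),
    alive = c(rep(TRUE, 10), rep(FALSE, 10))
  )
  af <- active_fraction(rec, active_threshold = 0.5)
  expect_equal(af$pct_active[af$timepoint_h == 0], 70)
  # all dead -> 0% regardless of recorded scores
  expect_equal(af$pct_active[af$timepoint_h == 32], 0)
  expect_equal(af$n, c(10, 10))
})
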