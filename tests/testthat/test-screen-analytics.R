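test_that("vehicle normalization computes fold changes within plate/phase", {
  records <- constant_records(vehicle = 0.02, treatment = 0.04)
  nr <- normalize_to_vehicle(records, tiny_platemap())
  drug <- dplyr::filter(nr, compound == "drugA")
  veh <- dplyr::filter(nr, compound == "DMSO")
  expect_equal(drug$fc, c(2, 2))
  # vehicle's own fold change is 1 by construction
  expect_equal(veh$fc, c(1, 1))
  expect_equal(unique(drug$n), 4)

  # treatment identical to vehicle -> FC 1
  nr2 <- normalize_to_vehicle(constant_records(0.02, 0.02), tiny_platemap())
  expect_equal(dplyr::filter(nr2, compound == "drugA")$fc, c(1, 1))

  # displaced larvae are omitted from group means and n
  rec3 <- constant_records(0.02, 0.04)
  rec3$excluded[rec3$well == "A02"][1] <- TRUE
  rec3$exclusion_reason[rec3$well == "A02"][1] <- "displaced"
  rec3$relative_puncta_area[rec3$well == "A02"][1] <- NA
  nr3 <- normalize_to_vehicle(rec3, tiny_platemap())
  expect_equal(dplyr::filter(nr3, compound == "drugA", phase ==
                               "pre_nh4cl")$n, 3)

  # stratum without vehicle larvae errors, naming the stratum
  rec4 <- dplyr::filter(constant_records(0.02, 0.04), well != "A01")
  expect_error(normalize_to_vehicle(rec4, tiny_platemap()),
               "pre_nh4cl", class = "lc3_validation_error")
})

test_that("planted screen effects are recovered by normalization", {
  hits <- 0
  for (i in 1:20) {
    s <- make_screen(n_compounds = 1, active_indices = 1, true_fc = 1.8,
                     n_larvae_per_group = 20, noise_cv = 0.2, seed = 400 + i,
                     ed50 = 20)
    nr <- normalize_to_vehicle(s$results, s$platemap)
    fc <- dplyr::filter(nr, compound == "cmpd01", dose_um == 250,
                        phase == "post_nh4cl")$fc
    truth_fc <- dplyr::filter(s$truth$groups, compound == "cmpd01",
                              dose_um == 250, phase == "post_nh4cl")$fc_expected
    if (abs(fc - truth_fc) <= 0.2) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("flux ratio reports post/pre fold-change ratio with reasons", {
  records <- constant_records(vehicle = 0.02, treatment = 0.03)
  records$relative_puncta_area[records$phase == "post_nh4cl" &
                                 records$well == "A02"] <- 0.06
  records$relative_puncta_area[records$phase == "post_nh4cl" &
                                 records$well == "A01"] <- 0.02
  nr <- normalize_to_vehicle(records, tiny_platemap())
  fx <- compute_flux(nr)
  drug <- dplyr::filter(fx, compound == "drugA")
  expect_equal(drug$flux_ratio, 2)

  # identical phase means -> ratio 1 (no flux)
  nr1 <- normalize_to_vehicle(constant_records(0.02, 0.05), tiny_platemap())
  expect_equal(dplyr::filter(compute_flux(nr1),
                             compound == "drugA")$flux_ratio, 1)

  # group missing a phase -> flux absent with a reason
  pre_only <- constant_records(0.02, 0.04, phases = "pre_nh4cl")
  post_veh <- constant_records(0.02, 0.04, phases = "post_nh4cl")
  post_veh <- dplyr::filter(post_veh, well == "A01")
  nr2 <- normalize_to_vehicle(dplyr::bind_rows(pre_only, post_veh),
                              tiny_platemap())
  fx2 <- compute_flux(nr2)
  miss <- dplyr::filter(fx2, compound == "drugA")
  expect_true(is.na(miss$flux_ratio))
  expect_match(miss$reason, "post_nh4cl")
})

test_that("planted flux ratio is recovered from a simulated screen", {
  s <- make_screen(n_compounds = 1, active_indices = integer(),
                   flux_ratio = 1.5, n_larvae_per_group = 30, seed = 314)
  nr <- normalize_to_vehicle(s$results, s$platemap)
  fx <- compute_flux(nr)
  drug <- dplyr::filter(fx, compound == "cmpd01", dose_um == 250)
  expect_lt(abs(drug$flux_ratio - 1.5), 0.1)
  expect_lt(abs(drug$paired_flux - 1.5), 0.1)
})

test_that("dose-response profiles mask toxicity in E_max", {
  fc_table <- tibble::tibble(
    compound = "drugA", dose_um = c(10, 50, 100, 250),
    phase = "post_nh4cl", fc = c(1.0, 1.2, 1.8, 2.5), n = 10,
    reason = NA_character_
  )
  class(fc_table) <- c("lc3_normalized", class(fc_table))
  pm <- function(toxic_doses = numeric()) {
    as_platemap(tibble::tibble(
      plate = "P1", well = sprintf("A%02d", 1:5),
      compound = c("DMSO", rep("drugA", 4)),
      dose_um = c(0, 10, 50, 100, 250), phase = "post_nh4cl",
      role = c("vehicle", rep("treatment", 4)),
      toxic = c(FALSE, c(10, 50, 100, 250) %in% toxic_doses)
    ))
  }
  p0 <- build_dose_response(fc_table, pm())
  expect_equal(p0$e_max, 2.5)
  expect_false(p0$excluded)

  # toxic top dose is masked from E_max but kept in the profile
  p1 <- build_dose_response(fc_table, pm(250))
  expect_equal(p1$e_max, 1.8)
  expect_true(p1$doses[[1]]$toxic[4])

  # all doses toxic -> compound excluded, no E_max
  p2 <- build_dose_response(fc_table, pm(c(10, 50, 100, 250)))
  expect_true(p2$excluded)
  expect_true(is.na(p2$e_max))

  # appending a non-toxic dose never decreases E_max
  more <- dplyr::bind_rows(fc_table,
                           tibble::tibble(compound = "drugA", dose_um = 500,
                                          phase = "post_nh4cl", fc = 1.1,
                                          n = 10, reason = NA_character_))
  class(more) <- class(fc_table)
  pm5 <- as_platemap(tibble::tibble(
    plate = "P1", well = sprintf("A%02d", 1:6),
    compound = c("DMSO", rep("drugA", 5)),
    dose_um = c(0, 10, 50, 100, 250, 500), phase = "post_nh4cl",
    role = c("vehicle", rep("treatment", 5)), toxic = FALSE
  ))
  expect_gte(build_dose_response(more, pm5)$e_max, p0$e_max)
})

test_that("hit ranking sorts by E_max with the dose tie rule", {
  prof <- tibble::tibble(
    compound = c("a", "b", "c"),
    e_max = c(2.5, 1.1, 1.9), e_max_dose = c(50, 50, 100),
    excluded = FALSE,
    doses = list(tibble::tibble(dose_um = 50, fc_pre = 1, fc_post = 2.5,
                                toxic = FALSE))
  )
  rk <- rank_hits(prof, hit_fc_threshold = 1.5)
  expect_equal(rk$e_max, c(2.5, 1.9, 1.1))
  expect_equal(rk$hit, c(TRUE, TRUE, FALSE))

  # tie at E_max 2.0: the 50 uM achiever ranks before the 100 uM achiever
  tie <- tibble::tibble(
    compound = c("late", "early"), e_max = 2, e_max_dose = c(100, 50),
    excluded = FALSE, doses = list(tibble::tibble())
  )
  expect_equal(rank_hits(tie)$compound, c("early", "late"))
})

test_that("rank order is invariant to global rescaling of all areas", {
  s <- make_screen(n_compounds = 8, active_indices = c(3, 5), seed = 77)
  rank1 <- rank_hits(build_dose_response(
    normalize_to_vehicle(s$results, s$platemap), s$platemap))
  scaled <- s$results
  scaled$relative_puncta_area <- scaled$relative_puncta_area * 3.7
  rank2 <- rank_hits(build_dose_response(
    normalize_to_vehicle(scaled, s$platemap), s$platemap))
  expect_equal(rank1$compound, rank2$compound)
  expect_equal(rank1$e_max, rank2$e_max)
})

test_that("heatmap matrix encodes toxic cells distinctly and orders rows", {
  s <- make_screen(n_compounds = 3, active_indices = 1, seed = 88,
                   toxic_cells = tibble::tibble(compound = "cmpd02",
                                                dose_um = 250))
  prof <- build_dose_response(normalize_to_vehicle(s$results, s$platemap),
                              s$platemap)
  f <- withr::local_tempfile(fileext = ".csv")
  m <- export_heatmap_matrix(prof, f)
  expect_equal(dim(m), c(3, 4))
  expect_equal(sum(attr(m, "toxic")), 1)
  expect_true(is.na(m[attr(m, "toxic")]))
  expect_match(paste(readLines(f), collapse = "\n"), "TOXIC")
  # row order equals rank order
  expect_equal(rownames(m), rank_hits(prof)$compound)
  # empty profile list -> empty matrix
  empty <- prof[0, ]
  expect_equal(dim(export_heatmap_matrix(empty)), c(0, 0))
})

test_that("4PL fit is exact on noise-free data and flags flat curves", {
  doses <- c(10, 20, 40, 80, 160, 320, 640, 1280)
  y <- 0 + (1 - 0) / (1 + (doses / 100)^1)
  fit <- fit_ic50(doses, y)
  expect_lt(abs(fit$ic50 - 100) / 100, 0.001)
  expect_lt(abs(fit$hill - 1), 0.001)
  expect_true(fit$ic50 > 0)
  expect_lte(fit$bottom, fit$top)
  expect_equal(unname(predict(fit, 100)), 0.5, tolerance = 1e-6)

  td <- tidy(fit)
  expect_equal(td$term, c("bottom", "top", "ic50", "hill"))
  expect_true(glance(fit)$converged)

  # flat responses -> "no transition" signal
  expect_error(fit_ic50(doses, rep(1, 8) + rnorm(8, sd = 0.005)),
               class = "lc3_no_transition")
  # too few dose levels
  expect_error(fit_ic50(c(1, 10, 100), c(1, 0.5, 0)),
               class = "lc3_usage_error")
})

test_that("4PL fit recovers IC50 within 5% median error under 5% noise", {
  # replicated titration design: 16 log-spaced doses, 12 wells per dose
  doses <- rep(10^seq(1, 3.1, length.out = 16), each = 12)
  truth <- 1 / (1 + (doses / 100))
  set.seed(2024)
  errs <- replicate(100, {
    y <- truth + rnorm(length(doses), sd = 0.05)
    f <- fit_ic50(doses, y)
    abs(f$ic50 - 100) / 100
  })
  expect_lte(median(errs), 0.05)
})
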