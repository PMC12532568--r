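test_that("larvae are located at their planted mid-body positions", {
  w <- make_well_image(n_larvae = 1, seed = 101)
  rois <- locate_larvae(w$image)
  expect_equal(nrow(rois), 1)
  expect_lt(sqrt((rois$anchor_y - w$truth$center_y)^2 +
                 (rois$anchor_x - w$truth$center_x)^2), 10)

  # blank well (noise only) -> empty list, not an error
  b <- make_well_image(n_larvae = 0, seed = 102)
  expect_equal(nrow(locate_larvae(b$image)), 0)

  # three non-overlapping larvae -> exactly three ROIs
  w3 <- make_well_image(n_larvae = 3, seed = 103)
  rois3 <- locate_larvae(w3$image)
  expect_equal(nrow(rois3), 3)
  # stable indexing: sorted by position
  expect_equal(rois3$anchor_x, sort(rois3$anchor_x))
  # every ROI within image bounds
  expect_true(all(rois3$y0 >= 1 & rois3$y1 <= nrow(w3$image) &
                  rois3$x0 >= 1 & rois3$x1 <= ncol(w3$image)))
})

test_that("maximal projection takes the per-pixel maximum over Z", {
  # Z = 1 is the identity
  m <- matrix(runif(30), 5, 6)
  expect_identical(max_project(image_stack(m)), m)

  # disjoint bright spots on two planes both survive at full intensity
  a <- matrix(0, 5, 6); a[2, 2] <- 9
  b <- matrix(0, 5, 6); b[4, 5] <- 7
  proj <- max_project(image_stack(array(c(a, b), c(5, 6, 2))))
  expect_equal(proj[2, 2], 9)
  expect_equal(proj[4, 5], 7)

  # every planted punctum's peak appears in the projection at full level
  sim <- make_larva_stack(n_puncta = 6, seed = 104, noise = FALSE)
  proj <- max_project(sim$stack)
  for (i in seq_len(nrow(sim$truth$objects))) {
    o <- sim$truth$objects[i, ]
    expect_equal(proj[o$y, o$x],
                 sim$truth$params$body_level +
                   sim$truth$params$dark_level + o$amplitude)
  }

  # multi-channel input needs a channel selection first
  cs <- image_stack(array(0, c(4, 4, 2)), planes = "c")
  expect_error(max_project(cs), class = "lc3_usage_error")
})

test_that("body mask matches the planted silhouette minus the erosion rim", {
  sim <- make_larva_stack(n_puncta = 0, seed = 105)
  bm <- compute_body_mask(max_project(sim$stack))
  expected <- body_area_after_erosion(sim$truth, 5)
  expect_lt(abs(sum(bm$mask) - expected) / expected, 0.10)
  # single connected component
  expect_equal(max(lc3screen:::label_mask(bm$mask)), 1)

  # blank image -> "no larva detected" carrying the well identity
  blank <- matrix(abs(rnorm(160 * 256, 10, 3)), 160, 256)
  err <- tryCatch(compute_body_mask(blank, well = "B07"),
                  lc3_no_larva = function(e) e)
  expect_s3_class(err, "lc3_no_larva")
  expect_equal(err$well, "B07")

  # a dust speck below min_body_area does not survive area filtering
  proj <- max_project(sim$stack)
  proj[5:8, 5:8] <- 400
  bm2 <- compute_body_mask(proj)
  expect_equal(max(lc3screen:::label_mask(bm2$mask)), 1)
  expect_false(any(bm2$mask[1:12, 1:12]))
})

test_that("puncta segmentation recovers planted objects and containment", {
  sim <- make_larva_stack(n_puncta = 12, seed = 106)
  out <- run_puncta_chain(sim)
  expect_equal(nrow(out$seg$objects), 12)
  # puncta mask is contained in the body mask, pixelwise
  expect_true(all(!out$seg$puncta_mask | out$seg$body_mask))
  # puncta count equals the number of labeled objects
  expect_equal(max(out$seg$puncta_labels), nrow(out$seg$objects))

  # a bright spot outside the body mask is excluded by containment
  proj <- out$proj
  stopifnot(!any(out$bm$mask[1:20, 1:20]))
  proj[6:9, 6:9] <- proj[6:9, 6:9] + 300
  seg2 <- segment_puncta(proj, out$bm$smoothed, out$bm$mask)
  expect_equal(nrow(seg2$objects), 12)
  expect_false(any(seg2$puncta_mask[1:20, 1:20]))

  # uniform body with zero puncta -> empty mask, count 0
  sim0 <- make_larva_stack(n_puncta = 0, seed = 107)
  out0 <- run_puncta_chain(sim0)
  expect_equal(nrow(out0$seg$objects), 0)
  expect_equal(out0$meas$puncta_count, 0)
  expect_equal(out0$meas$relative_puncta_area, 0)

  # empty body mask is a usage error
  expect_error(segment_puncta(proj, out$bm$smoothed,
                              matrix(FALSE, nrow(proj), ncol(proj))),
               class = "lc3_usage_error")
})

test_that("puncta measurement arithmetic and unit conversion are exact", {
  sim <- make_larva_stack(n_puncta = 10, seed = 108)
  out <- run_puncta_chain(sim)
  m <- measure_puncta(out$seg, pixel_size_um = 0.5)
  expect_equal(m$puncta_total_area_px2, sum(out$seg$objects$area_px2))
  expect_equal(m$relative_puncta_area,
               m$puncta_total_area_px2 / m$body_area_px2)
  expect_equal(m$puncta_total_area_um2, m$puncta_total_area_px2 * 0.25)
  expect_equal(m$body_area_um2, m$body_area_px2 * 0.25)
  expect_true(m$relative_puncta_area >= 0 && m$relative_puncta_area <= 1)
})

test_that("noise-free step-profile puncta are recovered with exact areas", {
  sim <- make_larva_stack(n_puncta = 8, punctum_diameter = 5, seed = 109,
                          noise = FALSE, profile = "disk")
  out <- run_puncta_chain(sim)
  expect_equal(nrow(out$seg$objects), 8)
  expect_equal(sort(out$seg$objects$area_px2),
               sort(sim$truth$objects$area_px2))
})

test_that("puncta count is invariant to global intensity rescaling", {
  sim <- make_larva_stack(n_puncta = 9, seed = 110)
  proj <- max_project(sim$stack)
  counts <- sapply(c(1, 0.25, 3, 10), function(k) {
    bm <- compute_body_mask(proj * k)
    nrow(segment_puncta(proj * k, bm$smoothed, bm$mask)$objects)
  })
  expect_true(all(counts == counts[1]))
})

test_that("adding one planted punctum adds exactly one object of its area", {
  sim <- make_larva_stack(n_puncta = 5, seed = 111, noise = FALSE)
  out <- run_puncta_chain(sim)
  n_before <- nrow(out$seg$objects)
  area_before <- sum(out$seg$objects$area_px2)

  # plant one more step punctum at the body centre region, non-overlapping
  proj <- out$proj
  cy <- round(sim$truth$body$center[1]); cx <- round(sim$truth$body$center[2])
  spot <- expand.grid(dy = -2:2, dx = -2:2)
  spot <- spot[spot$dy^2 + spot$dx^2 <= 4, ]
  free <- FALSE
  for (off in seq(0, 40, by = 5)) {
    ys <- cy + spot$dy; xs <- cx + off + spot$dx
    window <- out$seg$puncta_mask[(cy - 5):(cy + 5),
                                  (cx + off - 5):(cx + off + 5)]
    if (!any(window) && all(out$bm$mask[cbind(ys, xs)])) {
      free <- TRUE; break
    }
  }
  stopifnot(free)
  proj[cbind(ys, xs)] <- proj[cbind(ys, xs)] + 200
  seg2 <- segment_puncta(proj, out$bm$smoothed, out$bm$mask)
  expect_equal(nrow(seg2$objects), n_before + 1)
  expect_equal(sum(seg2$objects$area_px2), area_before + nrow(spot))
})

test_that("process_well pairs larvae across phases and flags displaced", {
  pm_row <- tibble::tibble(plate = "P1", well = "C03")
  cfg <- lc3_config()
  cfg$puncta$head_tail_offset <- 20
  pre <- make_larva_stack(seed = 112)
  post <- make_larva_stack(seed = 113)
  rec <- process_well(pre$stack, post$stack, pm_row, cfg)
  expect_equal(nrow(rec), 2) # one larva per stack, both phases
  expect_setequal(rec$phase, c("pre_nh4cl", "post_nh4cl"))
  expect_false(any(rec$excluded))
  expect_true(all(rec$puncta_count == 12))

  # larva detectable pre but absent post -> displaced record, metrics absent
  blank <- image_stack(matrix(abs(rnorm(160 * 256, 10, 3)), 160, 256),
                       pixel_size_um = 0.7)
  rec2 <- process_well(pre$stack, blank, pm_row, cfg)
  displaced <- dplyr::filter(rec2, phase == "post_nh4cl")
  expect_true(all(displaced$excluded))
  expect_match(displaced$exclusion_reason, "displaced")
  expect_true(all(is.na(displaced$relative_puncta_area)))

  # baseline-only design: records for the pre phase only
  rec3 <- process_well(pre$stack, NULL, pm_row, cfg)
  expect_equal(unique(rec3$phase), "pre_nh4cl")

  expect_error(process_well(pre$stack, NULL, NULL, cfg),
               class = "lc3_validation_error")
})
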