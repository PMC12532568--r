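# Seeded generators for every input modality, each returning the simulated
# object together with a ground-truth record, so downstream recovery tests
# never hard-code expected numbers. All randomness goes through the seed:
# the same seed and parameters give bit-identical output.

with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Simulate a larva Z-stack with planted LC3 puncta
#'
#' Emulates a 20x confocal acquisition of one transgenic larva: an
#' elongated body of mid-level autofluorescence on a dark background,
#' imaged as `z_planes` Z planes (26 by default, matching the screen's
#' acquisition), with `n_puncta` bright puncta planted at random in-body
#' positions and random Z planes. Noise is Poisson shot noise plus
#' additive Gaussian read noise; `snr` sets the read-noise sd as
#' `punctum_amplitude / snr`. Puncta are uniform-intensity discs by
#' default, so every planted area is an exact pixel count (`"gaussian"`
#' gives soft-edged spots whose nominal area is the disc of
#' `punctum_diameter`).
#'
#' @param n_puncta Number of planted puncta.
#' @param punctum_diameter Punctum diameter, px.
#' @param snr Punctum amplitude over read-noise sd; `Inf` disables read
#'   noise.
#' @param body_area Target body silhouette area, px^2.
#' @param z_planes Number of Z planes.
#' @param seed Integer seed (`NULL` leaves the RNG alone).
#' @param width,height Canvas size, px.
#' @param body_level,dark_level,punctum_amplitude Intensity levels.
#' @param profile `"disk"` or `"gaussian"`.
#' @param noise Apply Poisson + read noise (`FALSE` gives the noise-free
#'   oracle image).
#' @param pixel_size_um Pixel size recorded on the stack.
#' @return List with `stack` (an `lc3_stack`) and `truth`: `objects`
#'   (planted puncta table), `body` (area, semi-axes, centre, angle,
#'   perimeter), and `params`.
#' @export
make_larva_stack <- function(n_puncta = 12, punctum_diameter = 4, snr = 20,
                             body_area = 12000, z_planes = 26, seed = 1,
                             width = 256, height = 160, body_level = 40,
                             dark_level = 5, punctum_amplitude = 200,
                             profile = c("disk", "gaussian"), noise = TRUE,
                             pixel_size_um = 0.7) {
  profile <- match.arg(profile)
  with_sim_seed(seed, {
    aspect <- 4
    b <- sqrt(body_area / (pi * aspect))
    a <- aspect * b
    angle <- runif(1, -12, 12) * pi / 180
    cy <- height / 2; cx <- width / 2
    ext_x <- sqrt((a * cos(angle))^2 + (b * sin(angle))^2)
    ext_y <- sqrt((a * sin(angle))^2 + (b * cos(angle))^2)
    if (ext_x > width / 2 - 4 || ext_y > height / 2 - 4) {
      abort("body does not fit the canvas; enlarge width/height",
            class = "lc3_infeasible")
    }
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    u <- (xx - cx) * cos(angle) + (yy - cy) * sin(angle)
    v <- -(xx - cx) * sin(angle) + (yy - cy) * cos(angle)
    body <- (u / a)^2 + (v / b)^2 <= 1
    body_px <- sum(body)

    # rejection-sample non-overlapping punctum centres in the body interior
    # (LC3 puncta sit in the trunk musculature, away from the skin edge)
    r <- punctum_diameter / 2
    margin <- r + 10
    inner <- (u / (a - margin))^2 + (v / (b - margin))^2 <= 1
    eligible <- which(inner)
    centres <- matrix(numeric(), 0, 2)
    tries <- 0
    while (nrow(centres) < n_puncta) {
      tries <- tries + 1
      if (tries > 5000 || length(eligible) == 0) {
        abort("cannot place puncta without overlap; lower n_puncta",
              class = "lc3_infeasible")
      }
      pick <- eligible[sample.int(length(eligible), 1)]
      py <- (pick - 1) %% height + 1
      px <- (pick - 1) %/% height + 1
      if (nrow(centres) > 0) {
        dmin <- min(sqrt((centres[, 1] - py)^2 + (centres[, 2] - px)^2))
        if (dmin < punctum_diameter + 3) next
      }
      centres <- rbind(centres, c(py, px))
    }

    clean <- array(dark_level, c(height, width, z_planes))
    for (z in seq_len(z_planes)) clean[, , z] <- clean[, , z] + body_level * body

    objects <- NULL
    if (n_puncta > 0) {
      zs <- sample.int(z_planes, n_puncta, replace = TRUE)
      dy <- rep(seq(-ceiling(r), ceiling(r)), times = 2 * ceiling(r) + 1)
      dx <- rep(seq(-ceiling(r), ceiling(r)), each = 2 * ceiling(r) + 1)
      in_disc <- dy^2 + dx^2 <= r^2
      rows <- vector("list", n_puncta)
      for (i in seq_len(n_puncta)) {
        py <- centres[i, 1]; px <- centres[i, 2]; z <- zs[i]
        if (profile == "disk") {
          ys <- py + dy[in_disc]; xs <- px + dx[in_disc]
          clean[cbind(ys, xs, z)] <- clean[cbind(ys, xs, z)] +
            punctum_amplitude
          area <- sum(in_disc)
        } else {
          sg <- punctum_diameter / (2 * sqrt(2 * log(2)))
          win <- ceiling(3 * sg)
          gy <- rep(seq(-win, win), times = 2 * win + 1)
          gx <- rep(seq(-win, win), each = 2 * win + 1)
          amp <- punctum_amplitude * exp(-(gy^2 + gx^2) / (2 * sg^2))
          ys <- py + gy; xs <- px + gx
          clean[cbind(ys, xs, z)] <- clean[cbind(ys, xs, z)] + amp
          area <- sum(in_disc)
        }
        rows[[i]] <- tibble(type = "punctum", y = py, x = px, z = z,
                            diameter = punctum_diameter, area_px2 = area,
                            amplitude = punctum_amplitude)
      }
      objects <- list_rbind(rows)
    } else {
      objects <- tibble(type = character(), y = numeric(), x = numeric(),
                        z = integer(), diameter = numeric(),
                        area_px2 = numeric(), amplitude = numeric())
    }

    read_sd <- if (is.finite(snr)) punctum_amplitude / snr else 0
    px_out <- clean
    if (noise) {
      n <- length(clean)
      px_out <- array(rpois(n, lambda = clean) +
                        rnorm(n, sd = read_sd), dim(clean))
      px_out[px_out < 0] <- 0
    }
    # Ramanujan approximation to the ellipse perimeter, for the analytic
    # erosion-rim correction body_area - perimeter*r + pi*r^2
    h <- ((a - b) / (a + b))^2
    perimeter <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    truth <- list(
      objects = objects,
      body = list(area_px2 = body_px, a = a, b = b, center = c(cy, cx),
                  angle = angle, perimeter = perimeter),
      params = list(n_puncta = n_puncta, punctum_diameter = punctum_diameter,
                    snr = snr, read_sd = read_sd, body_level = body_level,
                    dark_level = dark_level,
                    punctum_amplitude = punctum_amplitude,
                    z_planes = z_planes, seed = seed, profile = profile)
    )
    list(stack = image_stack(px_out, planes = "z",
                             pixel_size_um = pixel_size_um,
                             meta = list(simulated = TRUE)),
         truth = truth)
  })
}

#' Expected body-mask area after a disc erosion
#'
#' Analytic inner-offset area of the planted elliptical body:
#' `area - perimeter * r + pi * r^2` (exact for a convex silhouette when
#' `r` is below the minimum curvature radius `b^2 / a`).
#'
#' @param truth Truth record from [make_larva_stack()].
#' @param radius Erosion disc radius, px.
#' @return Expected eroded area, px^2.
#' @export
body_area_after_erosion <- function(truth, radius) {
  truth$body$area_px2 - truth$body$perimeter * radius + pi * radius^2
}

#' Simulate a low-magnification well image with larva silhouettes
#'
#' Emulates the 4x whole-well localization image: up to three elongated
#' larva bodies at random non-overlapping poses on a dark background, with
#' Gaussian noise.
#'
#' @param n_larvae Number of larvae (0 gives a blank, noise-only well).
#' @param seed Integer seed.
#' @param width,height Canvas size, px.
#' @param larva_area Silhouette area per larva, px^2.
#' @param body_level,bg_level,noise_sd Intensities.
#' @return List with `image` (matrix) and `truth` (per-larva centre, angle,
#'   semi-axes, area).
#' @export
make_well_image <- function(n_larvae = 3, seed = 1, width = 640,
                            height = 480, larva_area = 2500,
                            body_level = 60, bg_level = 8, noise_sd = 4) {
  with_sim_seed(seed, {
    aspect <- 5
    b <- sqrt(larva_area / (pi * aspect))
    a <- aspect * b
    img <- matrix(bg_level, height, width)
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    rows <- list()
    tries <- 0
    while (length(rows) < n_larvae) {
      tries <- tries + 1
      if (tries > 2000) {
        abort("cannot place larvae without overlap",
              class = "lc3_infeasible")
      }
      cy <- runif(1, a + 10, height - a - 10)
      cx <- runif(1, a + 10, width - a - 10)
      if (length(rows) > 0) {
        prev <- list_rbind(rows)
        if (min(sqrt((prev$center_y - cy)^2 + (prev$center_x - cx)^2)) <
            2.4 * a) next
      }
      angle <- runif(1, 0, pi)
      u <- (xx - cx) * cos(angle) + (yy - cy) * sin(angle)
      v <- -(xx - cx) * sin(angle) + (yy - cy) * cos(angle)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      img[inside] <- body_level
      rows[[length(rows) + 1]] <- tibble(center_y = cy, center_x = cx,
                                         angle = angle, a = a, b = b,
                                         area_px2 = sum(inside))
    }
    img <- img + rnorm(length(img), sd = noise_sd)
    img[img < 0] <- 0
    truth <- if (length(rows)) list_rbind(rows) else {
      tibble(center_y = numeric(), center_x = numeric(), angle = numeric(),
             a = numeric(), b = numeric(), area_px2 = numeric())
    }
    list(image = img, truth = truth)
  })
}

# Curvilinear mitochondrial network mask: thickened random walks, grown
# until the requested pixel density is reached.
make_mito_network <- function(size, density) {
  mask <- matrix(FALSE, size, size)
  target <- density * size^2
  brush <- EBImage::makeBrush(3, "disc")
  while (sum(mask) < target) {
    y <- runif(1, 10, size - 10); x <- runif(1, 10, size - 10)
    dir <- runif(1, 0, 2 * pi)
    steps <- sample(40:120, 1)
    path <- matrix(FALSE, size, size)
    for (s in seq_len(steps)) {
      dir <- dir + rnorm(1, sd = 0.3)
      y <- min(max(y + sin(dir), 2), size - 1)
      x <- min(max(x + cos(dir), 2), size - 1)
      path[round(y), round(x)] <- TRUE
    }
    path <- EBImage::imageData(EBImage::dilate(EBImage::Image(path * 1),
                                               brush)) > 0
    mask <- mask | path
  }
  mask
}

# Grow contiguous blobs inside `mask` totalling exactly `target` pixels
# (4-neighbour BFS region growth from random seeds).
grow_blobs_in_mask <- function(mask, target) {
  chosen <- matrix(FALSE, nrow(mask), ncol(mask))
  n_chosen <- 0
  avail <- mask
  while (n_chosen < target && any(avail)) {
    remaining <- target - n_chosen
    blob_target <- min(sample(20:60, 1), remaining)
    if (remaining - blob_target < 8) blob_target <- remaining
    seeds <- which(avail)
    start <- seeds[sample.int(length(seeds), 1)]
    queue <- start
    blob <- integer()
    visited <- matrix(FALSE, nrow(mask), ncol(mask))
    visited[start] <- TRUE
    nr <- nrow(mask)
    while (length(queue) > 0 && length(blob) < blob_target) {
      cur <- queue[1]; queue <- queue[-1]
      blob <- c(blob, cur)
      y <- (cur - 1) %% nr + 1
      x <- (cur - 1) %/% nr + 1
      for (nb in c(if (y > 1) cur - 1, if (y < nr) cur + 1,
                   if (x > 1) cur - nr, if (x < ncol(mask)) cur + nr)) {
        if (!visited[nb] && avail[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    chosen[blob] <- TRUE
    avail[blob] <- FALSE
    n_chosen <- n_chosen + length(blob)
  }
  chosen
}

#' Simulate a mito-QC two-channel field with a planted mitolysosome fraction
#'
#' A curvilinear mitochondrial network is present in both channels
#' (colocalized mCherry and GFP); a planted, spatially contiguous subset of
#' its area is mCherry-only (GFP at background), emulating mitolysosomes.
#' The truth records the exact planted area fraction.
#'
#' @param mitolysosome_fraction Planted mCherry-only area fraction in
#'   `[0, 1]`.
#' @param network_density Mitochondrial area as a fraction of the field.
#' @param seed Integer seed.
#' @param size Field edge, px.
#' @param intensity,bg_level,noise_sd Intensities.
#' @return List with `field` (an `lc3_field`, A = mCherry, B = GFP) and
#'   `truth` (`fraction` realized, areas, masks).
#' @export
make_mitoqc_field <- function(mitolysosome_fraction = 0.2,
                              network_density = 0.10, seed = 1, size = 256,
                              intensity = 150, bg_level = 10, noise_sd = 5) {
  stopifnot(mitolysosome_fraction >= 0, mitolysosome_fraction <= 1)
  with_sim_seed(seed, {
    mito <- make_mito_network(size, network_density)
    n_mito <- sum(mito)
    target <- round(mitolysosome_fraction * n_mito)
    lyso <- if (target == 0) {
      matrix(FALSE, size, size)
    } else if (target >= n_mito) {
      mito
    } else {
      grow_blobs_in_mask(mito, target)
    }
    a <- matrix(bg_level, size, size); a[mito] <- intensity
    b <- matrix(bg_level, size, size); b[mito & !lyso] <- intensity
    a <- pmax(a + rnorm(length(a), sd = noise_sd), 0)
    b <- pmax(b + rnorm(length(b), sd = noise_sd), 0)
    list(
      field = two_channel_field(a, b, channels = c("mCherry", "GFP")),
      truth = list(fraction = sum(lyso) / n_mito, mito_area = n_mito,
                   mitolysosome_area = sum(lyso), mito_mask = mito,
                   mitolysosome_mask = lyso,
                   params = list(seed = seed, intensity = intensity,
                                 bg_level = bg_level, noise_sd = noise_sd))
    )
  })
}

#' Simulate a TMRM/MitoTracker field with a planted depolarized fraction
#'
#' MitoTracker stains the whole planted network; TMRM is absent from a
#' contiguous planted subset of it (the depolarized fraction).
#'
#' @param depolarized_fraction Fraction of network pixels without TMRM.
#' @inheritParams make_mitoqc_field
#' @return List with `field` (A = TMRM, B = MitoTracker) and `truth`.
#' @export
make_tmrm_field <- function(depolarized_fraction = 0.4,
                            network_density = 0.10, seed = 1, size = 256,
                            intensity = 150, bg_level = 10, noise_sd = 5) {
  stopifnot(depolarized_fraction >= 0, depolarized_fraction <= 1)
  with_sim_seed(seed, {
    mito <- make_mito_network(size, network_density)
    n_mito <- sum(mito)
    target <- round(depolarized_fraction * n_mito)
    depol <- if (target == 0) {
      matrix(FALSE, size, size)
    } else if (target >= n_mito) {
      mito
    } else {
      grow_blobs_in_mask(mito, target)
    }
    a <- matrix(bg_level, size, size); a[mito & !depol] <- intensity
    b <- matrix(bg_level, size, size); b[mito] <- intensity
    a <- pmax(a + rnorm(length(a), sd = noise_sd), 0)
    b <- pmax(b + rnorm(length(b), sd = noise_sd), 0)
    list(
      field = two_channel_field(a, b, channels = c("TMRM", "MitoTracker")),
      truth = list(depolarized_fraction = sum(depol) / n_mito,
                   polarized_fraction = 1 - sum(depol) / n_mito,
                   mito_area = n_mito,
                   params = list(seed = seed, noise_sd = noise_sd))
    )
  })
}

#' Simulate a plateaued OCR trace with injection steps
#'
#' Basal plateau, FCCP injection stepping to the uncoupled plateau, then
#' rotenone + antimycin A stepping to the nonmitochondrial plateau, with
#' Gaussian noise. Non-responder traces (`responder = FALSE`) have an
#' uncoupled plateau below basal (capped at 75% of basal if needed), which
#' the analysis must flag and exclude.
#'
#' @param basal_level,uncoupled_level,nonmito_level Plateau OCR levels
#'   (pmol O2/min).
#' @param noise_sd Gaussian noise sd.
#' @param responder Does the trace respond to FCCP?
#' @param seed Integer seed.
#' @param interval_min Sampling interval (min).
#' @param n_basal,n_uncoupled,n_raa Points per segment.
#' @param subject,role Passed to [ocr_trace()].
#' @return List with `trace` (an `lc3_ocr_trace`) and `truth`.
#' @export
make_ocr_trace <- function(basal_level = 210, uncoupled_level = 320,
                           nonmito_level = 30, noise_sd = 0,
                           responder = TRUE, seed = 1, interval_min = 5,
                           n_basal = 8, n_uncoupled = 6, n_raa = 6,
                           subject = "chamber1", role = "treatment") {
  stopifnot(basal_level >= 0, uncoupled_level >= 0, nonmito_level >= 0)
  with_sim_seed(seed, {
    unc <- if (!responder) min(uncoupled_level, 0.75 * basal_level) else {
      uncoupled_level
    }
    n <- n_basal + n_uncoupled + n_raa
    times <- interval_min * seq_len(n)
    levels <- c(rep(basal_level, n_basal), rep(unc, n_uncoupled),
                rep(nonmito_level, n_raa))
    vals <- levels + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    inj <- tibble(
      label = c("fccp", "raa"),
      time_min = c(times[n_basal] + interval_min / 2,
                   times[n_basal + n_uncoupled] + interval_min / 2)
    )
    list(
      trace = ocr_trace(times, vals, inj, subject = subject, role = role),
      truth = list(basal = basal_level, uncoupled = unc,
                   nonmito = nonmito_level, responder = responder,
                   params = list(seed = seed, noise_sd = noise_sd))
    )
  })
}

#' Simulate a compound-titration pair of respirometry traces
#'
#' Treated and control (carrier-only) chamber traces from a known 4PL
#' inhibition truth: after a 3-point baseline, each titration step adds
#' compound to the treated chamber, whose OCR falls along
#' `1 / (1 + (dose / ic50)^hill)` of baseline; the control chamber stays at
#' baseline throughout.
#'
#' @param ic50 Planted IC50 (uM).
#' @param hill Planted Hill slope.
#' @param doses Ascending titration concentrations (uM).
#' @param baseline Baseline OCR level.
#' @param noise_sd Gaussian noise sd on both traces.
#' @param points_per_step Measurements per titration step.
#' @param seed Integer seed.
#' @return List with `treated`, `control` (both `lc3_ocr_trace`), `segments`
#'   (tibble `dose_um, t_start, t_end`) and `truth`.
#' @export
make_titration_traces <- function(ic50 = 300, hill = 1.5,
                                  doses = c(25, 50, 100, 200, 400, 800,
                                            1600),
                                  baseline = 200, noise_sd = 0,
                                  points_per_step = 3, seed = 1) {
  with_sim_seed(seed, {
    frac <- 1 / (1 + (doses / ic50)^hill)
    n_steps <- length(doses)
    n <- points_per_step * (1 + n_steps)
    times <- 2 * seq_len(n)
    lv_treat <- c(rep(baseline, points_per_step),
                  rep(baseline * frac, each = points_per_step))
    treat <- lv_treat + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    ctrl <- rep(baseline, n) + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    seg_start <- times[points_per_step * seq_len(n_steps)] + 1
    inj <- tibble(label = paste0("dose:", doses), time_min = seg_start)
    segments <- tibble(
      dose_um = doses, t_start = seg_start,
      t_end = c(seg_start[-1], max(times) + 1)
    )
    list(
      treated = ocr_trace(times, treat, inj, subject = "treated"),
      control = ocr_trace(times, ctrl, subject = "control",
                          role = "control_chamber"),
      segments = segments,
      truth = list(ic50 = ic50, hill = hill, baseline = baseline,
                   expected_response = frac,
                   params = list(seed = seed, noise_sd = noise_sd))
    )
  })
}

#' Collapse a control-normalized titration series to dose-response points
#'
#' @param normalized Output of [normalize_to_control_chamber()].
#' @param segments Segment table from [make_titration_traces()] (or any
#'   tibble `dose_um, t_start, t_end`).
#' @return Tibble `dose_um, response` (mean normalized OCR per step).
#' @export
dose_response_from_titration <- function(normalized, segments) {
  pmap(segments, function(dose_um, t_start, t_end) {
    sel <- normalized$time_min >= t_start & normalized$time_min < t_end
    tibble(dose_um = dose_um, response = mean(normalized$normalized[sel]))
  }) %>% list_rbind()
}

#' Simulate a worm mask pair with an exact vacated fraction
#'
#' A thick random-walk worm blob at `t0`; at `t1` the blob is displaced and
#' then adjusted pixel-by-pixel so that exactly
#' `round(displacement_fraction * area)` of the `t0` pixels are vacated.
#' The realized fraction (an exact rational number) is in the truth.
#'
#' @param displacement_fraction Target vacated fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param size Bounding-box edge, px.
#' @param worm_px Approximate worm area, px.
#' @return List with `mask_t0`, `mask_t1` (logical matrices) and `truth`.
#' @export
make_worm_frames <- function(displacement_fraction = 0.5, seed = 1,
                             size = 64, worm_px = 240) {
  stopifnot(displacement_fraction >= 0, displacement_fraction <= 1)
  with_sim_seed(seed, {
    path <- matrix(FALSE, size, size)
    y <- size / 2; x <- size / 4
    dir <- runif(1, -0.5, 0.5)
    brush <- EBImage::makeBrush(3, "disc")
    for (s in seq_len(ceiling(worm_px / 5))) {
      dir <- dir + rnorm(1, sd = 0.25)
      y <- min(max(y + sin(dir), 4), size - 3)
      x <- min(max(x + cos(dir), 4), size - 3)
      path[round(y), round(x)] <- TRUE
    }
    m0 <- EBImage::imageData(EBImage::dilate(EBImage::Image(path * 1),
                                             brush)) > 0
    n0 <- sum(m0)
    k <- round(displacement_fraction * n0)
    # start from a shifted copy, then adjust to the exact vacated count
    shift <- round(displacement_fraction * size / 2)
    m1 <- matrix(FALSE, size, size)
    src <- which(m0)
    sy <- (src - 1) %% size + 1
    sx <- (src - 1) %/% size + 1
    ny <- sy; nx <- pmin(sx + shift, size)
    m1[cbind(ny, nx)] <- TRUE
    vac <- which(m0 & !m1)
    n_vac <- length(vac)
    if (n_vac > k) {
      m1[sort(vac)[seq_len(n_vac - k)]] <- TRUE
    } else if (n_vac < k) {
      still <- sort(which(m0 & m1))
      m1[still[seq_len(k - n_vac)]] <- FALSE
    }
    list(mask_t0 = m0, mask_t1 = m1,
         truth = list(fraction = k / n0, n0 = n0, vacated = k,
                      params = list(seed = seed)))
  })
}

#' Simulate a whole screen with planted active compounds
#'
#' Per-larva relative puncta areas are drawn lognormally around group
#' means implied by the planted effects: active compounds follow a
#' sigmoidal dose dependence rising to `true_fc` at high dose; NH4Cl
#' multiplies every group (vehicle included) by `nh4cl_factor`, and
#' `flux_ratio` additionally multiplies treated post-NH4Cl groups
#' (a planted post/pre flux effect). Between-larva biological variation
#' (`noise_cv`, shared by the two phases of the same larva, which is
#' imaged twice) and residual acquisition noise (`residual_cv`, per phase)
#' are both lognormal. Wells hold 3 larvae each.
#'
#' @param n_compounds Number of test compounds.
#' @param active_indices Indices of planted actives.
#' @param true_fc Planted fold change of actives at saturating dose.
#' @param flux_ratio Planted post/pre flux ratio of treated groups.
#' @param noise_cv Between-larva CV of the lognormal biological variation.
#' @param residual_cv Per-acquisition residual CV.
#' @param n_larvae_per_group Larvae per compound/dose group (multiple of 3
#'   recommended).
#' @param n_vehicle Vehicle larvae per phase (default 3x the group size;
#'   screens run many vehicle wells).
#' @param toxic_cells Optional tibble `compound, dose_um` of toxic cells.
#' @param seed Integer seed.
#' @param doses Tested doses (uM).
#' @param vehicle_mean Vehicle-group mean relative puncta area, pre NH4Cl.
#' @param nh4cl_factor Puncta accumulation factor under NH4Cl.
#' @param ed50,hill_dose Sigmoidal dose-dependence parameters of the
#'   planted effect.
#' @param plate Plate id.
#' @return List with `results` (wide per-larva tibble), `platemap`
#'   (`lc3_platemap`) and `truth` (per-group expected means and fold
#'   changes).
#' @export
make_screen <- function(n_compounds = 20, active_indices = c(1, 2),
                        true_fc = 2, flux_ratio = 1, noise_cv = 0.2,
                        residual_cv = 0.08, n_larvae_per_group = 15,
                        n_vehicle = 3 * n_larvae_per_group,
                        toxic_cells = NULL, seed = 1,
                        doses = c(10, 50, 100, 250), vehicle_mean = 0.02,
                        nh4cl_factor = 2, ed50 = 50, hill_dose = 2,
                        plate = "P1") {
  with_sim_seed(seed, {
    compounds <- sprintf("cmpd%02d", seq_len(n_compounds))
    sdlog_bio <- sqrt(log(1 + noise_cv^2))
    sdlog_res <- sqrt(log(1 + residual_cv^2))
    draw_pair <- function(mean_pre, mean_post, n) {
      bio <- exp(rnorm(n, -sdlog_bio^2 / 2, sdlog_bio))
      e1 <- exp(rnorm(n, -sdlog_res^2 / 2, sdlog_res))
      e2 <- exp(rnorm(n, -sdlog_res^2 / 2, sdlog_res))
      list(pre = mean_pre * bio * e1, post = mean_post * bio * e2)
    }
    dose_fc <- function(active, dose) {
      if (!active) return(1)
      1 + (true_fc - 1) * dose^hill_dose / (dose^hill_dose + ed50^hill_dose)
    }

    well_counter <- 0
    next_wells <- function(n_larvae) {
      n_wells <- ceiling(n_larvae / 3)
      ids <- sprintf("W%03d", well_counter + seq_len(n_wells))
      well_counter <<- well_counter + n_wells
      rep(ids, each = 3)[seq_len(n_larvae)]
    }

    res_rows <- list(); pm_rows <- list(); truth_rows <- list()
    add_group <- function(compound, dose, role, active, fr) {
      n <- if (role == "vehicle") n_vehicle else n_larvae_per_group
      fc <- dose_fc(active, dose)
      mean_pre <- vehicle_mean * fc
      mean_post <- vehicle_mean * nh4cl_factor * fc * fr
      wells <- next_wells(n)
      draws <- draw_pair(mean_pre, mean_post, n)
      larva_in_well <- stats::ave(seq_len(n), wells, FUN = seq_along)
      for (ph in c("pre_nh4cl", "post_nh4cl")) {
        res_rows[[length(res_rows) + 1]] <<- tibble(
          plate = plate, well = wells, larva = larva_in_well, phase = ph,
          relative_puncta_area = if (ph == "pre_nh4cl") draws$pre else
            draws$post,
          excluded = FALSE, exclusion_reason = NA_character_
        )
        pm_rows[[length(pm_rows) + 1]] <<- tibble(
          plate = plate, well = unique(wells), compound = compound,
          dose_um = dose, phase = ph, role = role, toxic = FALSE
        )
        truth_rows[[length(truth_rows) + 1]] <<- tibble(
          compound = compound, dose_um = dose, phase = ph,
          group_mean = if (ph == "pre_nh4cl") mean_pre else mean_post,
          fc_expected = if (ph == "pre_nh4cl") fc else fc * fr
        )
      }
    }

    add_group("DMSO", 0, "vehicle", FALSE, 1)
    for (i in seq_len(n_compounds)) {
      for (d in doses) {
        add_group(compounds[i], d, "treatment", i %in% active_indices,
                  flux_ratio)
      }
    }
    platemap <- list_rbind(pm_rows)
    if (!is.null(toxic_cells)) {
      key <- paste(platemap$compound, platemap$dose_um)
      platemap$toxic <- key %in% paste(toxic_cells$compound,
                                       toxic_cells$dose_um)
    }
    list(
      results = list_rbind(res_rows),
      platemap = as_platemap(platemap),
      truth = list(groups = list_rbind(truth_rows),
                   actives = compounds[active_indices],
                   params = list(seed = seed, true_fc = true_fc,
                                 flux_ratio = flux_ratio,
                                 noise_cv = noise_cv,
                                 residual_cv = residual_cv))
    )
  })
}
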