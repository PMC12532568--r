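# Shared fixtures built in code; nothing on disk.

# Full puncta chain on one simulated stack, returning everything the
# recovery assertions need.
run_puncta_chain <- function(sim, shrink_radius = 5) {
  proj <- max_project(sim$stack)
  bm <- compute_body_mask(proj, shrink_radius = shrink_radius)
  seg <- segment_puncta(proj, bm$smoothed, bm$mask)
  list(proj = proj, bm = bm, seg = seg,
       meas = measure_puncta(seg, sim$stack$pixel_size_um))
}

# Minimal hand-built plate map covering vehicle + one compound.
tiny_platemap <- function() {
  as_platemap(tibble::tibble(
    plate = "P1",
    well = c("A01", "A01", "A02", "A02"),
    compound = c("DMSO", "DMSO", "drugA", "drugA"),
    dose_um = c(0, 0, 50, 50),
    phase = rep(c("pre_nh4cl", "post_nh4cl"), 2),
    role = c("vehicle", "vehicle", "treatment", "treatment"),
    toxic = FALSE
  ))
}

# Wide per-larva records with chosen group means and zero noise.
constant_records <- function(vehicle = 0.02, treatment = 0.04, n = 4,
                             phases = c("pre_nh4cl", "post_nh4cl")) {
  rows <- list()
  for (ph in phases) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      plate = "P1", well = "A01", larva = seq_len(n), phase = ph,
      relative_puncta_area = vehicle, excluded = FALSE,
      exclusion_reason = NA_character_)
    rows[[length(rows) + 1]] <- tibble::tibble(
      plate = "P1", well = "A02", larva = seq_len(n), phase = ph,
      relative_puncta_area = treatment, excluded = FALSE,
      exclusion_reason = NA_character_)
  }
  dplyr::bind_rows(rows)
}
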