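#' Construct an annotated oxygen-consumption-rate trace
#'
#' @param time_min Strictly increasing measurement times (min).
#' @param ocr OCR values (pmol O2/min), same length.
#' @param injections Tibble with `label` and `time_min`: injection events
#'   (e.g. `"fccp"`, `"raa"`, titration steps). Labels must be unique. A
#'   point belongs to the post-injection segment when its time is at or
#'   after the injection time.
#' @param subject Well / chamber identifier.
#' @param role `"treatment"` or `"control_chamber"`.
#' @return Tibble of class `lc3_ocr_trace` with attributes `injections`,
#'   `subject`, `role`.
#' @export
ocr_trace <- function(time_min, ocr,
                      injections = tibble(label = character(),
                                          time_min = numeric()),
                      subject = "chamber1", role = "treatment") {
  stopifnot(length(time_min) == length(ocr))
  if (any(diff(time_min) <= 0)) {
    abort("timestamps must be strictly increasing",
          class = "lc3_validation_error")
  }
  if (anyDuplicated(injections$label)) {
    abort("injection labels must be unique per trace",
          class = "lc3_validation_error")
  }
  out <- tibble(time_min = time_min, ocr = ocr)
  attr(out, "injections") <- as_tibble(injections)
  attr(out, "subject") <- subject
  attr(out, "role") <- role
  class(out) <- c("lc3_ocr_trace", class(out))
  out
}

#' Read an OCR trace from CSV
#'
#' Expected columns: `time_min`, `ocr`, `injection_label` (empty except on
#' the first measurement of each post-injection segment).
#'
#' @param path CSV path.
#' @param subject,role See [ocr_trace()].
#' @return An `lc3_ocr_trace`.
#' @export
read_ocr_trace <- function(path, subject = basename(path),
                           role = "treatment") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("time_min", "ocr")
  if (!all(req %in% names(df))) {
    abort("OCR CSV needs columns time_min, ocr", class = "lc3_schema_error")
  }
  inj <- tibble(label = character(), time_min = numeric())
  if ("injection_label" %in% names(df)) {
    has <- !is.na(df$injection_label) & df$injection_label != ""
    inj <- tibble(label = df$injection_label[has],
                  time_min = df$time_min[has])
  }
  ocr_trace(df$time_min, df$ocr, inj, subject = subject, role = role)
}

injection_time <- function(trace, labels) {
  inj <- attr(trace, "injections")
  hit <- inj$time_min[tolower(inj$label) %in% labels]
  if (length(hit) == 0) NA_real_ else hit[1]
}

#' Summarize an OCR trace into respiration metrics
#'
#' Basal respiration is the mean of the last three measurement points
#' before the FCCP injection. Maximal (uncoupled) respiration follows the
#' selected convention: `"mean_last3_before_raa"` (mean of the last three
#' points before the rotenone + antimycin A injection, the default) or
#' `"max_after_fccp"` (maximum value observed after FCCP). Both are
#' implemented because the two conventions are in genuine use; the output
#' records which rule produced it. Nonmitochondrial respiration is the
#' mean of the points after R + AA (clamped at 0), and mitochondrial basal
#' is `basal - nonmitochondrial`, exact arithmetic. Traces that do not
#' respond to FCCP (no post-FCCP value above basal) are flagged excluded;
#' the trace itself is retained.
#'
#' @param trace An `lc3_ocr_trace` with an `fccp` injection (labels are
#'   matched case-insensitively; `"raa"`, `"r+aa"` and
#'   `"rotenone+antimycinA"` all denote the electron-transport-chain
#'   block).
#' @param maximal_rule Maximal-OCR convention, see above.
#' @return One-row tibble: `subject, basal, maximal, maximal_rule,
#'   nonmitochondrial, mitochondrial_basal, excluded, reason`.
#' @export
ocr_summary <- function(trace,
                        maximal_rule = c("mean_last3_before_raa",
                                         "max_after_fccp")) {
  maximal_rule <- match.arg(maximal_rule)
  stopifnot(inherits(trace, "lc3_ocr_trace"))
  t_fccp <- injection_time(trace, "fccp")
  if (is.na(t_fccp)) {
    abort("trace has no FCCP injection", class = "lc3_validation_error")
  }
  t_raa <- injection_time(trace, c("raa", "r+aa", "rotenone+antimycina",
                                   "rotenone_antimycin_a"))
  pre <- trace$ocr[trace$time_min < t_fccp]
  if (length(pre) < 3) {
    abort("need >= 3 measurement points before FCCP",
          class = "lc3_validation_error")
  }
  basal <- mean(utils::tail(pre, 3))
  post_end <- if (is.na(t_raa)) Inf else t_raa
  post <- trace$ocr[trace$time_min >= t_fccp & trace$time_min < post_end]
  maximal <- if (maximal_rule == "max_after_fccp") {
    if (length(post) == 0) NA_real_ else max(post)
  } else {
    if (length(post) < 1) NA_real_ else mean(utils::tail(post, 3))
  }
  nonmito <- if (is.na(t_raa)) NA_real_ else {
    max(0, mean(trace$ocr[trace$time_min >= t_raa]))
  }
  excluded <- length(post) > 0 && max(post) <= basal
  tibble(
    subject = attr(trace, "subject"),
    basal = basal,
    maximal = maximal,
    maximal_rule = maximal_rule,
    nonmitochondrial = nonmito,
    mitochondrial_basal = basal - nonmito,
    excluded = excluded,
    reason = ifelse(excluded, "did not respond to FCCP", NA_character_)
  )
}

#' Normalize a treated OCR trace to the control chamber
#'
#' Each treated measurement is divided by the control chamber's OCR at the
#' nearest timestamp (within `tol`; default half the control's median
#' sampling interval). Used for compound titrations, where the control
#' chamber receives carrier-only injections and tracks baseline drift; the
#' resulting normalized series feeds [fit_ic50()].
#'
#' @param treated,control `lc3_ocr_trace` objects.
#' @param tol Maximum timestamp mismatch (min).
#' @return Tibble `time_min, treated, control, normalized`.
#' @export
normalize_to_control_chamber <- function(treated, control, tol = NULL) {
  stopifnot(inherits(treated, "lc3_ocr_trace"),
            inherits(control, "lc3_ocr_trace"))
  if (is.null(tol)) tol <- median(diff(control$time_min)) / 2
  idx <- vapply(treated$time_min, function(t) {
    which.min(abs(control$time_min - t))
  }, integer(1))
  mismatch <- abs(control$time_min[idx] - treated$time_min)
  keep <- mismatch <= tol
  ctrl <- control$ocr[idx]
  if (any(ctrl[keep] <= 0)) {
    abort("control-chamber OCR <= 0 at matched point(s)",
          class = "lc3_validation_error")
  }
  tr <- treated$ocr[keep]
  tibble(time_min = treated$time_min[keep],
         treated = tr,
         control = ctrl[keep],
         normalized = tr / ctrl[keep])
}

#' Worm activity score from a pair of masks
#'
#' The fraction of pixels covered by the worm at `t0` that were vacated by
#' `t1`, within a shared bounding-box frame. An animal that completely
#' left the box scores 1; a completely inactive animal scores 0;
#' intermediate scores mean part of the body still occupies its original
#' pixels. A symmetric-difference variant is available
#' (`method = "symmetric"`: changed pixels of either sign over the `t0`
#' area, clamped to `[0, 1]`).
#'
#' @param worm_mask_t0,worm_mask_t1 Logical matrices of identical shape.
#' @param method `"vacated"` (default) or `"symmetric"`.
#' @return Score in `[0, 1]`; `NA` with a warning when the `t0` mask is
#'   empty ("worm not found").
#' @export
#' @examples
#' m0 <- matrix(FALSE, 8, 8); m0[3:6, 3:6] <- TRUE
#' activity_score(m0, m0) # 0
activity_score <- function(worm_mask_t0, worm_mask_t1,
                           method = c("vacated", "symmetric")) {
  method <- match.arg(method)
  stopifnot(is.logical(worm_mask_t0), is.logical(worm_mask_t1),
            all(dim(worm_mask_t0) == dim(worm_mask_t1)))
  n0 <- sum(worm_mask_t0)
  if (n0 == 0) {
    warn("worm not found: empty t0 mask")
    return(NA_real_)
  }
  changed <- if (method == "vacated") {
    sum(worm_mask_t0 & !worm_mask_t1)
  } else {
    sum(xor(worm_mask_t0, worm_mask_t1))
  }
  min(1, max(0, changed / n0))
}

#' Fraction of active animals per timepoint
#'
#' @param records Tibble with `timepoint_h`, `score`, and optional `alive`
#'   (dead animals are scored 0 and counted inactive).
#' @param active_threshold Minimum score counted as active (default 0.5).
#' @return Tibble `timepoint_h, pct_active, n`.
#' @export
active_fraction <- function(records, active_threshold = 0.5) {
  stopifnot(all(c("timepoint_h", "score") %in% names(records)))
  records <- as_tibble(records)
  if (!"alive" %in% names(records)) records$alive <- TRUE
  records %>%
    mutate(score = ifelse(.data$alive, .data$score, 0)) %>%
    group_by(.data$timepoint_h) %>%
    summarise(
      pct_active = 100 * mean(.data$score >= active_threshold),
      n = dplyr::n(), .groups = "drop"
    )
}
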