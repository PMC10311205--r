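#' Canonical feature names
#'
#' The 25 features computed on a 30-min segment, in canonical order:
#' baseline statistics (`b_min`, `b_med`, `b_max`, bpm), acceleration
#' morphology (`acc_count`, `acc_total_dur` s, `acc_area` bpm.s,
#' `acc_max_depth` bpm), deceleration morphology with the late (> 2 min)
#' subset (`dec_count`, `late_dec_count`, `dec_total_dur`,
#' `late_dec_total_dur` s, `dec_area`, `late_dec_area` bpm.s,
#' `dec_max_depth` bpm), contractions (`ctr_count`, `ctr_total_dur` s,
#' `ctr_area` mm Hg.s), joint deceleration-contraction measures
#' (`dec_no_ctr_dur`, `late_dec_no_ctr_dur` s, `dec_no_ctr_area`,
#' `late_dec_no_ctr_area` bpm.s, `dec_ctr_peak_timediff`,
#' `late_dec_ctr_peak_timediff` s) and variability (`stv`, `ltv`, bpm).
#' @return character vector of length 25.
#' @export
ctg_feature_names <- function() c(
  "b_min", "b_med", "b_max",
  "acc_count", "acc_total_dur", "acc_area", "acc_max_depth",
  "dec_count", "late_dec_count", "dec_total_dur", "late_dec_total_dur",
  "dec_area", "late_dec_area", "dec_max_depth",
  "ctr_count", "ctr_total_dur", "ctr_area",
  "dec_no_ctr_dur", "late_dec_no_ctr_dur",
  "dec_no_ctr_area", "late_dec_no_ctr_area",
  "dec_ctr_peak_timediff", "late_dec_ctr_peak_timediff",
  "stv", "ltv")

#' Short-term variability
#'
#' Partitions the series into consecutive epochs of `epoch_s` seconds
#' (3.75 s by default), computes the mean FHR of each epoch, and returns
#' the mean absolute difference between successive epoch means. Trailing
#' samples that do not fill an epoch are dropped; a 30-min segment at 4 Hz
#' divides evenly into 480 epochs.
#'
#' @param fhr gap-free FHR series (bpm).
#' @param epoch_s epoch duration, seconds.
#' @param sample_rate Hz.
#' @return STV in bpm.
#' @export
compute_stv <- function(fhr, epoch_s = 3.75, sample_rate = 4) {
  m <- as.integer(round(epoch_s * sample_rate))
  k <- length(fhr) %/% m
  if (k < 2)
    ctg_error("series too short for STV: need at least 2 full epochs",
              "ctg_length_error")
  means <- colMeans(matrix(fhr[seq_len(k * m)], nrow = m))
  mean(abs(diff(means)))
}

#' Long-term variability
#'
#' The FHR amplitude (max minus min) per whole minute, averaged over the
#' segment's full minutes; partial trailing minutes are dropped.
#'
#' @inheritParams compute_stv
#' @return LTV in bpm.
#' @export
compute_ltv <- function(fhr, sample_rate = 4) {
  m <- as.integer(round(60 * sample_rate))
  k <- length(fhr) %/% m
  if (k < 1)
    ctg_error("series too short for LTV: need at least 1 full minute",
              "ctg_length_error")
  x <- matrix(fhr[seq_len(k * m)], nrow = m)
  mean(apply(x, 2, function(col) max(col) - min(col)))
}

#' Joint deceleration-contraction features
#'
#' Six measures coupling decelerations to uterine activity: the duration
#' and deviation area of decelerations (and of late decelerations) falling
#' outside the union of contraction intervals, and the summed absolute time
#' difference between each deceleration peak and the nearest contraction
#' peak. All six are 0 when the segment has no contractions (for the
#' peak-time features) or no decelerations.
#'
#' @param dec_events,ctr_events `ctg_events` from one segment.
#' @param fhr,baseline the segment series, needed to integrate deviation
#'   area over the surviving (outside-contraction) samples.
#' @param sample_rate Hz.
#' @return named numeric vector of the 6 joint features.
#' @export
joint_dec_contraction <- function(dec_events, ctr_events, fhr, baseline,
                                  sample_rate = 4) {
  fs <- sample_rate
  n <- length(fhr)
  out <- c(dec_no_ctr_dur = 0, late_dec_no_ctr_dur = 0,
           dec_no_ctr_area = 0, late_dec_no_ctr_area = 0,
           dec_ctr_peak_timediff = 0, late_dec_ctr_peak_timediff = 0)
  if (nrow(dec_events) == 0) return(out)
  in_ctr <- rep(FALSE, n)
  if (nrow(ctr_events) > 0) {
    for (r in seq_len(nrow(ctr_events))) {
      i0 <- floor(ctr_events$start_s[r] * fs) + 1L
      i1 <- ceiling(ctr_events$end_s[r] * fs)
      in_ctr[max(1L, i0):min(n, i1)] <- TRUE
    }
  }
  dev <- baseline - fhr
  for (r in seq_len(nrow(dec_events))) {
    i0 <- floor(dec_events$start_s[r] * fs) + 1L
    i1 <- ceiling(dec_events$end_s[r] * fs)
    idx <- max(1L, i0):min(n, i1)
    keep <- idx[!in_ctr[idx]]
    dur <- length(keep) / fs
    area <- if (length(keep)) sum(pmax(dev[keep], 0)) / fs else 0
    out["dec_no_ctr_dur"] <- out["dec_no_ctr_dur"] + dur
    out["dec_no_ctr_area"] <- out["dec_no_ctr_area"] + area
    if (isTRUE(dec_events$is_late[r])) {
      out["late_dec_no_ctr_dur"] <- out["late_dec_no_ctr_dur"] + dur
      out["late_dec_no_ctr_area"] <- out["late_dec_no_ctr_area"] + area
    }
    if (nrow(ctr_events) > 0) {
      td <- min(abs(dec_events$peak_s[r] - ctr_events$peak_s))
      out["dec_ctr_peak_timediff"] <- out["dec_ctr_peak_timediff"] + td
      if (isTRUE(dec_events$is_late[r]))
        out["late_dec_ctr_peak_timediff"] <-
          out["late_dec_ctr_peak_timediff"] + td
    }
  }
  out
}

summarise_events <- function(ev) {
  if (nrow(ev) == 0)
    return(c(count = 0, total_dur = 0, area = 0, max_depth = 0))
  c(count = nrow(ev), total_dur = sum(ev$end_s - ev$start_s),
    area = sum(ev$area), max_depth = max(ev$max_depth))
}

#' Compute the 25-feature vector of a segment
#'
#' Gathers all features of one analysis segment: baseline statistics over
#' the segment's baseline series, acceleration / deceleration / contraction
#' morphology from the detected events, the joint deceleration-contraction
#' measures, and the two variability indices. Empty event lists yield zero
#' counts, durations, areas and depths.
#'
#' @param segment a `ctg_segment`.
#' @param baseline a `baseline_estimate` aligned to the segment (or a bare
#'   numeric baseline series).
#' @param accelerations,decelerations,contractions `ctg_events`; when
#'   `NULL` they are detected from the segment and baseline with default
#'   settings.
#' @return named numeric vector of length 25 (see [ctg_feature_names()]).
#' @export
compute_features <- function(segment, baseline, accelerations = NULL,
                             decelerations = NULL, contractions = NULL) {
  fs <- segment$sample_rate
  b <- if (inherits(baseline, "baseline_estimate")) baseline$baseline
       else as.numeric(baseline)
  if (length(b) != length(segment$fhr))
    ctg_error("baseline is not aligned to the segment", "ctg_alignment_error")
  if (is.null(accelerations))
    accelerations <- detect_accelerations(segment$fhr, b, sample_rate = fs)
  if (is.null(decelerations))
    decelerations <- detect_decelerations(segment$fhr, b, sample_rate = fs)
  if (is.null(contractions))
    contractions <- detect_contractions(segment$uc, sample_rate = fs)

  acc <- summarise_events(accelerations)
  dec <- summarise_events(decelerations)
  late <- summarise_events(decelerations[decelerations$is_late, , drop = FALSE])
  ctr <- summarise_events(contractions)
  joint <- joint_dec_contraction(decelerations, contractions,
                                 segment$fhr, b, sample_rate = fs)
  fv <- c(
    b_min = min(b), b_med = stats::median(b), b_max = max(b),
    acc_count = unname(acc["count"]), acc_total_dur = unname(acc["total_dur"]),
    acc_area = unname(acc["area"]), acc_max_depth = unname(acc["max_depth"]),
    dec_count = unname(dec["count"]), late_dec_count = unname(late["count"]),
    dec_total_dur = unname(dec["total_dur"]),
    late_dec_total_dur = unname(late["total_dur"]),
    dec_area = unname(dec["area"]), late_dec_area = unname(late["area"]),
    dec_max_depth = unname(dec["max_depth"]),
    ctr_count = unname(ctr["count"]), ctr_total_dur = unname(ctr["total_dur"]),
    ctr_area = unname(ctr["area"]),
    joint["dec_no_ctr_dur"], joint["late_dec_no_ctr_dur"],
    joint["dec_no_ctr_area"], joint["late_dec_no_ctr_area"],
    joint["dec_ctr_peak_timediff"], joint["late_dec_ctr_peak_timediff"],
    stv = compute_stv(segment$fhr, sample_rate = fs),
    ltv = compute_ltv(segment$fhr, sample_rate = fs))
  fv <- fv[ctg_feature_names()]
  stopifnot(!anyNA(fv))
  fv
}
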