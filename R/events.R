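# Events are plain data frames (class ctg_events) with one row per event:
# kind, start_s, end_s (half-open), peak_s, max_depth, area, is_late.

empty_events <- function() {
  structure(data.frame(kind = character(), start_s = numeric(),
                       end_s = numeric(), peak_s = numeric(),
                       max_depth = numeric(), area = numeric(),
                       is_late = logical(), stringsAsFactors = FALSE),
            class = c("ctg_events", "data.frame"))
}

# Shared run-based excursion detector.  dev is the signed deviation that
# must stay strictly positive throughout a candidate run.
detect_runs <- function(dev, value, fs, kind, min_duration_s, strict_duration,
                        max_crit, mean_crit) {
  runs <- mask_runs(dev > 0)
  if (nrow(runs) == 0) return(empty_events())
  rows <- lapply(seq_len(nrow(runs)), function(r) {
    i0 <- runs[r, 1]; i1 <- runs[r, 2]
    idx <- i0:i1
    dur <- length(idx) / fs
    dur_ok <- if (strict_duration) dur > min_duration_s else dur >= min_duration_s
    if (!dur_ok) return(NULL)
    d <- dev[idx]
    if (!is.null(max_crit) && max(d) <= max_crit) return(NULL)
    if (!is.null(mean_crit) && mean(d) <= mean_crit) return(NULL)
    pk <- idx[which.max(d)]
    data.frame(kind = kind,
               start_s = (i0 - 1) / fs, end_s = i1 / fs,
               peak_s = (pk - 1) / fs,
               max_depth = max(d), area = sum(d) / fs,
               is_late = if (kind == "deceleration") dur > 120 else FALSE,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty_events())
  out <- do.call(rbind, rows)
  class(out) <- c("ctg_events", "data.frame")
  out
}

#' Detect FHR accelerations
#'
#' Candidate periods are maximal runs where the FHR is strictly above the
#' baseline. A run is an acceleration when its maximum deviation exceeds
#' 15 bpm, its mean deviation exceeds 10 bpm, and it lasts at least
#' `min_duration_s` (the 15-s floor of the clinical guidelines; set to 0 to
#' rely on the amplitude criteria alone). Area is the deviation integrated
#' over the run in bpm.s; `max_depth` is the peak deviation.
#'
#' @param fhr,baseline aligned gap-free series (bpm).
#' @param min_duration_s minimum event duration in seconds (default 15).
#' @param sample_rate Hz.
#' @return a `ctg_events` data frame, events sorted by start time.
#' @export
detect_accelerations <- function(fhr, baseline, min_duration_s = 15,
                                 sample_rate = 4) {
  if (length(fhr) != length(baseline))
    ctg_error("fhr and baseline are not aligned", "ctg_alignment_error")
  detect_runs(fhr - baseline, fhr, sample_rate, "acceleration",
              min_duration_s, strict_duration = FALSE,
              max_crit = 15, mean_crit = 10)
}

#' Detect FHR decelerations
#'
#' Mirror image of [detect_accelerations()]: runs strictly below the
#' baseline, deviations measured as baseline - FHR. Decelerations lasting
#' more than two minutes are flagged `is_late`.
#'
#' @inheritParams detect_accelerations
#' @export
detect_decelerations <- function(fhr, baseline, min_duration_s = 15,
                                 sample_rate = 4) {
  if (length(fhr) != length(baseline))
    ctg_error("fhr and baseline are not aligned", "ctg_alignment_error")
  detect_runs(baseline - fhr, fhr, sample_rate, "deceleration",
              min_duration_s, strict_duration = FALSE,
              max_crit = 15, mean_crit = 10)
}

#' Detect uterine contractions
#'
#' A contraction is a maximal period during which the UC signal remains
#' above `threshold` (10 mm Hg) for more than `min_duration_s` (30 s).
#' The peak is the UC maximum of the run; area is integrated above the
#' threshold, in mm Hg.s.
#'
#' @param uc gap-free UC series (mm Hg).
#' @param threshold mm Hg (default 10).
#' @param min_duration_s seconds, exclusive (default 30).
#' @param sample_rate Hz.
#' @return a `ctg_events` data frame.
#' @export
detect_contractions <- function(uc, threshold = 10, min_duration_s = 30,
                                sample_rate = 4) {
  detect_runs(uc - threshold, uc, sample_rate, "contraction",
              min_duration_s, strict_duration = TRUE,
              max_crit = NULL, mean_crit = NULL)
}

#' Write detected events to CSV
#' @param events a `ctg_events` data frame.
#' @param path destination.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
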