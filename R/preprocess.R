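# Runs of TRUE in a logical vector, as (start, end) index pairs (inclusive).
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Fill one gap [i0, i1] of series x given anchor indices a0 = i0-1, a1 = i1+1.
# Hermite slopes come from the nearest observed neighbour outside each anchor
# (falling back to the across-gap secant at series boundaries of observation).
fill_gap <- function(x, i0, i1, method, observed) {
  a0 <- i0 - 1L; a1 <- i1 + 1L
  idx <- i0:i1
  if (method == "linear") {
    x[idx] <- x[a0] + (x[a1] - x[a0]) * (idx - a0) / (a1 - a0)
    return(x)
  }
  secant <- (x[a1] - x[a0]) / (a1 - a0)
  out0 <- if (a0 > 1 && observed[a0 - 1L]) (x[a0] - x[a0 - 1L]) else secant
  out1 <- if (a1 < length(x) && observed[a1 + 1L]) (x[a1 + 1L] - x[a1]) else secant
  m0 <- out0; m1 <- out1                      # slopes per sample
  h <- a1 - a0
  s <- (idx - a0) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  x[idx] <- h00 * x[a0] + h10 * h * m0 + h01 * x[a1] + h11 * h * m1
  x
}

#' Interpolate short signal dropouts
#'
#' Every maximal run of missing samples shorter than `max_gap_s` and bounded
#' by observed samples on both sides is filled and unmasked; longer runs and
#' runs touching either record boundary (no anchor on one side) are left
#' untouched. Observed samples are never modified. The default linear fill
#' matches routine CTG preprocessing; a cubic Hermite alternative (endpoint
#' slopes from the nearest outer observed neighbours) is available and
#' behaves nearly identically on real traces.
#'
#' @param rec a `ctg_record`.
#' @param max_gap_s maximum gap duration to fill, exclusive (default 600 s).
#' @param method `"linear"` or `"cubic_hermite"`.
#' @return a `ctg_record` with gaps filled and masks cleared.
#' @export
interpolate_gaps <- function(rec, max_gap_s = 600,
                             method = c("linear", "cubic_hermite")) {
  method <- match.arg(method)
  validate_ctg_record(rec)
  fs <- rec$sample_rate
  for (ch in c("fhr", "uc")) {
    mk <- paste0("missing_", ch)
    mask <- rec[[mk]]
    if (!any(mask)) next
    x <- rec[[ch]]
    runs <- mask_runs(mask)
    observed <- !mask
    for (r in seq_len(nrow(runs))) {
      i0 <- runs[r, 1]; i1 <- runs[r, 2]
      len_s <- (i1 - i0 + 1) / fs
      if (len_s >= max_gap_s) next             # "less than 10 min" is strict
      if (i0 == 1L || i1 == length(x)) next    # boundary gap: no anchor
      x <- fill_gap(x, i0, i1, method, observed)
      mask[i0:i1] <- FALSE
    }
    rec[[ch]] <- x
    rec[[mk]] <- mask
  }
  rec
}

#' Segment selection outcome when a case must be dropped
#'
#' @param reason `"no_window"` (no clean window of the required length
#'   exists) or `"too_early"` (the latest clean window starts too long
#'   before delivery).
#' @param case_id the affected case.
#' @return a `ctg_discard` object. Use [is_discard()] to branch on it.
#' @export
ctg_discard <- function(reason, case_id = NA_character_) {
  reason <- match.arg(reason, c("no_window", "too_early"))
  structure(list(reason = reason, case_id = case_id), class = "ctg_discard")
}

#' @rdname ctg_discard
#' @param x object to test.
#' @export
is_discard <- function(x) inherits(x, "ctg_discard")

#' @export
print.ctg_discard <- function(x, ...) {
  cat(sprintf("<ctg_discard> case %s: %s\n", x$case_id, x$reason))
  invisible(x)
}

#' Select the latest clean analysis segment
#'
#' Finds the latest window of `seg_len_s` seconds in which neither FHR nor
#' UC has a missing sample (after [interpolate_gaps()]). Windows may start
#' at any sample. The case is discarded when no such window exists, or when
#' the window found starts more than `max_start_s` seconds before delivery
#' (segment start relative to delivery = `end_offset` + time from segment
#' start to record end).
#'
#' @param rec a gap-interpolated `ctg_record`.
#' @param seg_len_s segment length in seconds (default 1800, i.e. 30 min).
#' @param max_start_s latest admissible segment start before delivery
#'   (default 5400 s, i.e. 90 min).
#' @return a `ctg_segment` (fields `fhr`, `uc`, `sample_rate`,
#'   `start_index`/`end_index` into the parent record, half-open, and
#'   `start_before_delivery` in seconds) or a [ctg_discard()].
#' @export
select_segment <- function(rec, seg_len_s = 1800, max_start_s = 5400) {
  validate_ctg_record(rec)
  fs <- rec$sample_rate
  L <- as.integer(round(seg_len_s * fs))
  n <- length(rec$fhr)
  if (n < L) return(ctg_discard("no_window", rec$case_id))
  ok <- !(rec$missing_fhr | rec$missing_uc)
  csum <- c(0, cumsum(ok))
  clean <- (csum[(L + 1):(n + 1)] - csum[1:(n - L + 1)]) == L
  if (!any(clean)) return(ctg_discard("no_window", rec$case_id))
  s <- max(which(clean))                        # latest clean start
  start_before_delivery <- rec$end_offset + (n - (s - 1)) / fs
  if (start_before_delivery > max_start_s)
    return(ctg_discard("too_early", rec$case_id))
  idx <- s:(s + L - 1L)
  structure(list(case_id = rec$case_id,
                 fhr = rec$fhr[idx], uc = rec$uc[idx],
                 sample_rate = fs,
                 start_index = s, end_index = s + L,
                 start_before_delivery = start_before_delivery,
                 meta = rec$meta),
            class = "ctg_segment")
}

#' @export
print.ctg_segment <- function(x, ...) {
  cat(sprintf(
    "<ctg_segment> case %s: %.1f min @ %g Hz, starts %.1f min before delivery\n",
    x$case_id, length(x$fhr) / x$sample_rate / 60, x$sample_rate,
    x$start_before_delivery / 60))
  invisible(x)
}
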