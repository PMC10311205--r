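#' Per-case clinical metadata
#'
#' @param ph umbilical arterial pH at birth, or `NA` if unknown. When
#'   present must lie in \[6.5, 7.6\].
#' @param delivery_mode one of `"vaginal"`, `"operative"`, `"cesarean"`,
#'   `"unknown"`.
#' @param apgar1,apgar5 Apgar scores at 1 and 5 minutes (integer 0--10 or
#'   `NA`).
#' @return a `case_meta` list.
#' @export
case_meta <- function(ph = NA_real_, delivery_mode = "unknown",
                      apgar1 = NA_integer_, apgar5 = NA_integer_) {
  delivery_mode <- match.arg(delivery_mode,
                             c("vaginal", "operative", "cesarean", "unknown"))
  if (!is.na(ph) && (ph < 6.5 || ph > 7.6))
    stop("ph out of plausible range [6.5, 7.6]: ", ph)
  for (a in list(apgar1, apgar5))
    if (!is.na(a) && (a < 0 || a > 10)) stop("apgar must be in [0, 10]")
  structure(list(ph = ph, delivery_mode = delivery_mode,
                 apgar1 = apgar1, apgar5 = apgar5),
            class = "case_meta")
}

#' Construct a CTG record
#'
#' A CTG record holds paired fetal heart rate (bpm) and uterine activity
#' (mm Hg) series on a shared uniform time axis, together with missing-value
#' masks and case metadata. Sample `k` (1-based) sits at time
#' `(k - 1) / sample_rate` seconds from record start; `end_offset` anchors
#' the last sample relative to delivery.
#'
#' Missing samples are encoded in the raw signals as exact 0 or -1 values;
#' when no masks are supplied they are derived from that convention.
#' Optionally (default on) FHR values outside the physiological range
#' \[30, 250\] bpm are also flagged missing, guarding the downstream filter
#' bank against nonphysiological spikes.
#'
#' @param case_id character identifier.
#' @param fhr numeric FHR series (bpm).
#' @param uc numeric uterine-activity series (mm Hg), same length as `fhr`.
#' @param sample_rate sampling rate in Hz (default 4).
#' @param end_offset seconds between the last sample and delivery (0 when
#'   unknown).
#' @param missing_fhr,missing_uc optional logical masks; derived from the
#'   0 / -1 convention when `NULL`.
#' @param meta a [case_meta()] object.
#' @param physiological_guard flag FHR outside \[30, 250\] bpm as missing
#'   when deriving masks (default `TRUE`).
#' @return an object of class `ctg_record`.
#' @export
ctg_record <- function(case_id, fhr, uc, sample_rate = 4, end_offset = 0,
                       missing_fhr = NULL, missing_uc = NULL,
                       meta = case_meta(), physiological_guard = TRUE) {
  fhr <- as.numeric(fhr); uc <- as.numeric(uc)
  if (is.null(missing_fhr)) {
    missing_fhr <- fhr == 0 | fhr == -1 | is.na(fhr)
    if (physiological_guard) missing_fhr <- missing_fhr | fhr < 30 | fhr > 250
  }
  # devices emit exact 0 for UC dropout, so 0 is missing for UC as well
  if (is.null(missing_uc)) missing_uc <- uc == 0 | uc == -1 | is.na(uc)
  rec <- structure(list(case_id = as.character(case_id), fhr = fhr, uc = uc,
                        sample_rate = sample_rate, end_offset = end_offset,
                        missing_fhr = as.logical(missing_fhr),
                        missing_uc = as.logical(missing_uc), meta = meta),
                   class = "ctg_record")
  validate_ctg_record(rec)
  rec
}

#' Validate the invariants of a CTG record
#'
#' Checks equal series/mask lengths, a positive sampling rate and a
#' nonnegative delivery offset; errors on violation, otherwise returns the
#' record invisibly.
#' @param rec a `ctg_record`.
#' @export
validate_ctg_record <- function(rec) {
  stopifnot(inherits(rec, "ctg_record"))
  n <- length(rec$fhr)
  if (length(rec$uc) != n)
    stop("fhr and uc must have equal length (", n, " vs ", length(rec$uc), ")")
  if (length(rec$missing_fhr) != n || length(rec$missing_uc) != n)
    stop("missing masks must match the series length")
  if (!is.numeric(rec$sample_rate) || rec$sample_rate <= 0)
    stop("sample_rate must be > 0")
  if (rec$end_offset < 0) stop("end_offset must be >= 0")
  invisible(rec)
}

#' @export
print.ctg_record <- function(x, ...) {
  n <- length(x$fhr)
  cat(sprintf("<ctg_record> case %s: %d samples @ %g Hz (%.1f min)\n",
              x$case_id, n, x$sample_rate, n / x$sample_rate / 60))
  cat(sprintf("  missing: FHR %.1f%%, UC %.1f%%; end offset %g s; pH %s\n",
              100 * mean(x$missing_fhr), 100 * mean(x$missing_uc),
              x$end_offset,
              if (is.na(x$meta$ph)) "unknown" else format(x$meta$ph)))
  invisible(x)
}

ctg_error <- function(msg, class) {
  stop(structure(class = c(class, "ctg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a CTG record from CSV
#'
#' Expects the dialect `time_s,fhr_bpm,uc_mmhg` (comma separated, '.'
#' decimal, UTF-8) with a strictly increasing, uniformly spaced time column.
#' Values equal to 0 or -1 are flagged missing, matching how dropout is
#' encoded in raw CTG exports.
#'
#' @param path CSV file path.
#' @param sample_rate expected rate in Hz; when `NULL` it is inferred from
#'   the time column, otherwise cross-checked against it.
#' @param case_id identifier for the record; defaults to the file name.
#' @param end_offset seconds between last sample and delivery.
#' @param meta a [case_meta()].
#' @param physiological_guard see [ctg_record()].
#' @return a `ctg_record`.
#' @export
read_ctg_csv <- function(path, sample_rate = NULL, case_id = NULL,
                         end_offset = 0, meta = case_meta(),
                         physiological_guard = TRUE) {
  if (!file.exists(path)) ctg_error(paste("no such file:", path), "ctg_io_error")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) ctg_error(paste("malformed CSV:",
                                                     conditionMessage(e)),
                                               "ctg_format_error"))
  if (nrow(df) == 0) ctg_error("empty record file", "ctg_empty_error")
  need <- c("time_s", "fhr_bpm", "uc_mmhg")
  if (!all(need %in% names(df)))
    ctg_error(paste("missing columns:",
                    paste(setdiff(need, names(df)), collapse = ", ")),
              "ctg_format_error")
  tm <- df$time_s
  if (nrow(df) > 1) {
    dt <- diff(tm)
    if (any(dt <= 0) || max(dt) - min(dt) > 1e-6)
      ctg_error("time axis not strictly increasing and uniform",
                "ctg_sampling_error")
    fs <- 1 / stats::median(dt)
  } else fs <- if (is.null(sample_rate)) 4 else sample_rate
  if (!is.null(sample_rate)) {
    if (abs(fs - sample_rate) > 1e-6 * sample_rate)
      ctg_error(sprintf("time step implies %g Hz, expected %g Hz",
                        fs, sample_rate), "ctg_sampling_error")
    fs <- sample_rate
  }
  if (is.null(case_id)) case_id <- sub("\\.csv$", "", basename(path))
  ctg_record(case_id, df$fhr_bpm, df$uc_mmhg, sample_rate = fs,
             end_offset = end_offset, meta = meta,
             physiological_guard = physiological_guard)
}

#' Write a CTG record to CSV
#'
#' Inverse of [read_ctg_csv()]: writes `time_s,fhr_bpm,uc_mmhg` rows with
#' the record's stored sample values (masked positions keep their raw 0/-1
#' encoding).
#' @param rec a `ctg_record`.
#' @param path destination path.
#' @export
write_ctg_csv <- function(rec, path) {
  validate_ctg_record(rec)
  n <- length(rec$fhr)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate,
                   fhr_bpm = rec$fhr, uc_mmhg = rec$uc)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal WFDB (format 16) support --------------------------------------
# Header: "record nsig fs nsamp" then one line per signal:
#   "file fmt gain(baseline)/units adc_res adc_zero init checksum blk desc".
# Signal file: interleaved int16 little-endian ADC counts;
# physical = (adc - baseline) / gain.

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain_spec <- f[3]
    gain <- as.numeric(sub("[(/].*$", "", gain_spec))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec)) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], fmt = f[2], gain = if (gain == 0) 200 else gain,
         baseline = baseline, desc = desc)
  })
  list(record = top[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read a two-channel WFDB record (FHR + UC)
#'
#' Minimal reader for the WFDB dialect used by open intrapartum CTG
#' distributions: a text header plus a format-16 (int16 little-endian,
#' interleaved) signal file with channels described as `"FHR"` and `"UC"`.
#' The same 0 / -1 missing-value convention as the CSV reader is applied to
#' the physical values.
#'
#' @param path record path with or without the `.hea` extension.
#' @inheritParams read_ctg_csv
#' @return a `ctg_record`.
#' @export
read_wfdb_record <- function(path, case_id = NULL, end_offset = 0,
                             meta = case_meta(), physiological_guard = TRUE) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) ctg_error(paste("no such header:", hea), "ctg_io_error")
  h <- parse_wfdb_header(hea)
  if (any(vapply(h$signals, function(s) s$fmt, "") != "16"))
    ctg_error("only WFDB format 16 is supported", "ctg_format_error")
  descs <- toupper(vapply(h$signals, function(s) s$desc, ""))
  i_fhr <- match("FHR", descs); i_uc <- match("UC", descs)
  if (is.na(i_fhr) || is.na(i_uc))
    ctg_error("record must contain channels named FHR and UC",
              "ctg_format_error")
  dat_path <- file.path(dirname(hea), h$signals[[1]]$file)
  if (!file.exists(dat_path))
    ctg_error(paste("no such signal file:", dat_path), "ctg_io_error")
  raw <- readBin(dat_path, what = "integer", size = 2, signed = TRUE,
                 endian = "little",
                 n = file.info(dat_path)$size / 2)
  if (length(raw) %% h$nsig != 0)
    ctg_error("signal file length not a multiple of channel count",
              "ctg_format_error")
  m <- matrix(raw, ncol = h$nsig, byrow = TRUE)
  phys <- function(i) (m[, i] - h$signals[[i]]$baseline) / h$signals[[i]]$gain
  if (is.null(case_id)) case_id <- h$record
  ctg_record(case_id, phys(i_fhr), phys(i_uc), sample_rate = h$fs,
             end_offset = end_offset, meta = meta,
             physiological_guard = physiological_guard)
}

#' Write a CTG record as a WFDB format-16 pair
#'
#' Fixture-grade writer producing a header + int16 signal file readable by
#' [read_wfdb_record()]. Physical values are quantised at `1/gain` units.
#'
#' @param rec a `ctg_record`.
#' @param path record base path (no extension).
#' @param gain ADC counts per physical unit (default 100, i.e. 0.01
#'   resolution).
#' @export
write_wfdb_record <- function(rec, path, gain = 100) {
  validate_ctg_record(rec)
  n <- length(rec$fhr)
  base <- basename(path)
  dat <- paste0(base, ".dat")
  hdr <- c(sprintf("%s 2 %g %d", base, rec$sample_rate, n),
           sprintf("%s 16 %g(0)/bpm 16 0 0 0 0 FHR", dat, gain),
           sprintf("%s 16 %g(0)/mmHg 16 0 0 0 0 UC", dat, gain))
  writeLines(hdr, paste0(path, ".hea"))
  adc <- as.integer(round(rbind(rec$fhr, rec$uc) * gain))
  writeBin(adc, file.path(dirname(path), dat), size = 2, endian = "little")
  invisible(path)
}
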