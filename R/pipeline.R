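#' Default run configuration
#'
#' Nested list of every tunable of the pipeline with its default. Unknown
#' keys in a user configuration are rejected by [merge_config()].
#' @return nested list.
#' @export
ctg_config <- function() {
  list(
    preprocess = list(max_gap_s = 600, segment_len_s = 1800,
                      max_start_before_delivery_s = 5400,
                      interpolation = "linear"),
    baseline = list(mode = "variable", T0_s = 1200,
                    bands_bpm = default_bands(), grid_stride = 4,
                    T_clamp_s = c(300, 3600)),
    events = list(min_accel_dur_s = 15, min_decel_dur_s = 15,
                  ctr_threshold_mmhg = 10, min_ctr_dur_s = 30),
    model = list(features = default_model_features(), lambda = 1e-4,
                 outcome_threshold = 7.05, k_folds = 5)
  )
}

#' Merge a user configuration over the defaults
#'
#' @param user nested list (e.g. from [yaml::read_yaml()]); keys absent
#'   from [ctg_config()] raise an error.
#' @param base defaults to merge onto.
#' @return the merged configuration.
#' @export
merge_config <- function(user, base = ctg_config()) {
  if (is.null(user)) return(base)
  for (k in names(user)) {
    if (!k %in% names(base))
      ctg_error(paste("unknown config key:", k), "ctg_config_error")
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]])) {
      base[[k]] <- merge_config(user[[k]], base[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full feature-extraction pipeline on one record
#'
#' Interpolates gaps, selects the latest clean segment, computes the
#' stability probabilities and the weighted-median baseline, detects
#' events, and assembles the 25-feature vector.
#'
#' @param rec a `ctg_record`.
#' @param stability_model a `stability_model`, or `NULL` to run with the
#'   uninformative constant `p_stab = 1`.
#' @param config a configuration from [ctg_config()] / [merge_config()].
#' @return a list with `features` (named vector), `segment`, `baseline`,
#'   `accelerations`, `decelerations`, `contractions` — or a
#'   [ctg_discard()] when no admissible segment exists.
#' @export
ctg_extract <- function(rec, stability_model = NULL, config = ctg_config()) {
  rec <- interpolate_gaps(rec, max_gap_s = config$preprocess$max_gap_s,
                          method = config$preprocess$interpolation)
  seg <- select_segment(rec, seg_len_s = config$preprocess$segment_len_s,
                        max_start_s = config$preprocess$max_start_before_delivery_s)
  if (is_discard(seg)) return(seg)
  fs <- seg$sample_rate
  p_stab <- predict_stability(stability_model, seg$fhr, sample_rate = fs)
  bl <- estimate_baseline(seg$fhr, p_stab, mode = config$baseline$mode,
                          T0_s = config$baseline$T0_s, sample_rate = fs,
                          grid_stride = config$baseline$grid_stride,
                          t_clamp_s = config$baseline$T_clamp_s)
  acc <- detect_accelerations(seg$fhr, bl$baseline,
                              min_duration_s = config$events$min_accel_dur_s,
                              sample_rate = fs)
  dec <- detect_decelerations(seg$fhr, bl$baseline,
                              min_duration_s = config$events$min_decel_dur_s,
                              sample_rate = fs)
  ctr <- detect_contractions(seg$uc,
                             threshold = config$events$ctr_threshold_mmhg,
                             min_duration_s = config$events$min_ctr_dur_s,
                             sample_rate = fs)
  fv <- compute_features(seg, bl, acc, dec, ctr)
  list(features = fv, segment = seg, baseline = bl,
       accelerations = acc, decelerations = dec, contractions = ctr)
}

#' Extract a feature table from many records
#'
#' Applies [ctg_extract()] to each record and stacks the feature vectors,
#' carrying case id, pH and the outcome label. Discarded cases are listed
#' separately with their machine-readable reason.
#'
#' @param records list of `ctg_record`s.
#' @param stability_model optional `stability_model`.
#' @param config pipeline configuration.
#' @param outcome_threshold pH cutoff defining the outcome column.
#' @return list with `features` (data frame, one row per retained case)
#'   and `discards` (data frame `case_id`, `reason`).
#' @export
extract_feature_table <- function(records, stability_model = NULL,
                                  config = ctg_config(),
                                  outcome_threshold = 7.05) {
  rows <- list(); disc <- list()
  for (rec in records) {
    res <- ctg_extract(rec, stability_model, config)
    if (is_discard(res)) {
      disc[[length(disc) + 1]] <- data.frame(case_id = res$case_id,
                                             reason = res$reason)
      next
    }
    ph <- rec$meta$ph
    rows[[length(rows) + 1]] <-
      cbind(data.frame(case_id = rec$case_id, ph = ph,
                       outcome = if (is.na(ph)) NA else ph < outcome_threshold),
            as.data.frame(t(res$features)))
  }
  list(features = if (length(rows)) do.call(rbind, rows) else NULL,
       discards = if (length(disc)) do.call(rbind, disc) else
         data.frame(case_id = character(), reason = character()))
}
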