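#' @title Canonical feature schema and end-to-end pipeline
#' @description
#' The canonical per-subject feature vector has 80 named columns in four
#' domains: 35 temporal, 20 spectral, 15 complexity and 10 higher-order
#' features. [ms_pipeline()] runs the whole analysis on a list of
#' recordings: preprocessing, epoching, rejection, pooled GFP-peak
#' extraction, K-means template learning, back-fitting, and per-subject
#' feature extraction into a feature table.
#' @name features
NULL

#' Canonical feature names by domain
#'
#' @param domains subset of `c("temporal", "spectral", "complexity",
#'   "higher_order")`.
#' @param K number of states.
#' @return Character vector of feature names (80 for all domains, K = 4).
#' @export
feature_names <- function(domains = c("temporal", "spectral", "complexity",
                                      "higher_order"), K = 4) {
  domains <- match.arg(domains, several.ok = TRUE)
  unlist(lapply(domains, function(d) switch(d,
    temporal = temporal_feature_names(K),
    spectral = spectral_feature_names(K),
    complexity = complexity_feature_names(),
    higher_order = higher_order_feature_names(K))), use.names = FALSE)
}

#' Map each canonical feature to its domain
#'
#' @param K number of states.
#' @return Named character vector: names are features, values domains.
#' @export
feature_domains <- function(K = 4) {
  doms <- c("temporal", "spectral", "complexity", "higher_order")
  out <- unlist(lapply(doms, function(d)
    setNames(rep(d, length(feature_names(d, K))), feature_names(d, K))))
  out
}

#' Extract the full 80-feature vector for one subject
#'
#' @param es the subject's [eeg_epochs()] (after rejection).
#' @param labels the subject's [ms_labels()] aligned to accepted epochs.
#' @param K number of states.
#' @param min_pooled_sec spectral pooled-duration threshold (seconds).
#' @return Named numeric vector with the 80 canonical features.
#' @export
subject_features <- function(es, labels, K = 4, min_pooled_sec = 1) {
  out <- c(temporal_vector(labels, K = K, fs = es$fs),
           suppressWarnings(
             spectral_vector(es, labels, K = K,
                             min_pooled_sec = min_pooled_sec)),
           complexity_vector(labels),
           higher_order_vector(labels, K = K))
  out[feature_names(K = K)]
}

#' Run the full microstate analysis pipeline on a cohort
#'
#' Steps, in order: cross-subject channel standardization; per-subject
#' preprocessing (zero-phase band-pass, notch, common average reference,
#' resampling); epoching with overlap; amplitude/variance epoch rejection;
#' GFP-peak topography extraction pooled across all subjects (group-blind);
#' K-means template learning; per-sample back-fitting; and extraction of
#' the 80 canonical features per subject.
#'
#' Polarity-invariant matching (`ignore_polarity = TRUE`) is the default
#' here: oscillatory sources reverse sign every half-cycle, so signed
#' matching splits each state between a template and its negative. The
#' signed variant remains available for strict method replication.
#'
#' @param recordings list of [eeg_recording()].
#' @param groups optional group label per recording (defaults to each
#'   recording's `group` field).
#' @param K number of microstates.
#' @param seed RNG seed for template learning.
#' @param band,notch,target_fs preprocessing parameters.
#' @param window,overlap epoching parameters (seconds, fraction).
#' @param amp_limit,var_z_limit rejection thresholds.
#' @param min_peak_distance GFP peak spacing in samples.
#' @param ignore_polarity polarity-invariant clustering and back-fitting.
#' @param min_pooled_sec spectral pooled-duration threshold (seconds).
#' @param preprocess set `FALSE` to skip filtering/CAR/resampling (inputs
#'   already preprocessed).
#' @param verbose print progress.
#' @return List with `features` (data.frame: subject, group + 80 columns),
#'   `templates`, `labels` (per subject), `epochs` (per subject) and
#'   `layout`.
#' @export
ms_pipeline <- function(recordings, groups = NULL, K = 4, seed = 42,
                        band = c(1, 45), notch = 50, target_fs = 128,
                        window = 2, overlap = 0.5, amp_limit = 100,
                        var_z_limit = 3, min_peak_distance = 2,
                        ignore_polarity = TRUE, min_pooled_sec = 1,
                        preprocess = TRUE, verbose = FALSE) {
  if (is.null(groups))
    groups <- vapply(recordings, function(r) r$group %||% NA_character_, "")
  std <- standardize_channels(recordings)
  recs <- std$recordings
  say <- function(...) if (verbose) message(sprintf(...))
  epochs <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    say("preprocessing subject %d/%d", i, length(recs))
    r <- recs[[i]]
    if (preprocess)
      r <- preprocess_recording(r, band = band, notch = notch,
                                target_fs = target_fs)
    es <- epoch_recording(r, window = window, overlap = overlap)
    epochs[[i]] <- reject_epochs(es, amp_limit, var_z_limit)
  }
  say("extracting GFP-peak maps")
  maps <- do.call(rbind, lapply(epochs, extract_peak_maps,
                                min_peak_distance = min_peak_distance))
  say("learning templates from %d peak maps", nrow(maps))
  templates <- learn_templates(maps, K = K, seed = seed,
                               ignore_polarity = ignore_polarity)
  templates$ch_names <- std$layout
  labels <- vector("list", length(recs))
  feats <- matrix(NA_real_, length(recs), length(feature_names(K = K)),
                  dimnames = list(NULL, feature_names(K = K)))
  for (i in seq_along(recs)) {
    say("back-fitting + features subject %d/%d", i, length(recs))
    labels[[i]] <- assign_labels(epochs[[i]], templates,
                                 ignore_polarity = ignore_polarity)
    feats[i, ] <- subject_features(epochs[[i]], labels[[i]], K = K,
                                   min_pooled_sec = min_pooled_sec)
  }
  subjects <- vapply(seq_along(recs), function(i)
    recs[[i]]$subject %||% sprintf("S%02d", i), "")
  features <- data.frame(subject = subjects, group = as.character(groups),
                         feats, check.names = FALSE)
  names(labels) <- names(epochs) <- subjects
  list(features = features, templates = templates, labels = labels,
       epochs = epochs, layout = std$layout)
}
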