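# Feature construction. Cross-task mode turns every trial's activation /
# resting interval pair into %ERD/ERS values on a fixed electrode x
# frequency grid (default 10 electrodes x 10 integer frequencies, 4-13 Hz).
# The ratio form cancels multiplicative slow drifts: any common gain on
# both intervals divides out. Within-task mode for the alternating-materials
# design uses raw alpha band power per electrode (that study predates the
# ratio lesson).

#' Percent event-related desynchronization / synchronization
#'
#' `(P_activation - P_reference) / P_reference * 100`. Negative values are
#' desynchronization (ERD, power loss under load), positive values
#' synchronization (ERS). Invariant under common rescaling of both powers.
#'
#' @param power_activation power in the activation interval (> 0 typical)
#' @param power_reference power in the reference/resting interval (> 0)
#' @export
erd_ers <- function(power_activation, power_reference) {
  if (any(power_reference <= 0))
    stopf("reference power must be positive")
  (power_activation - power_reference) / power_reference * 100
}

new_features <- function(x, info, labels = NULL) {
  stopifnot(nrow(x) == nrow(info))
  if (any(!is.finite(x))) stopf("non-finite feature values")
  structure(list(x = x, info = info, labels = labels), class = "wml_features")
}

#' @export
print.wml_features <- function(x, ...) {
  cat("<wml_features>", nrow(x$x), "trials x", ncol(x$x), "features\n")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.wml_features <- function(x) dim(x$x)

#' @export
as.matrix.wml_features <- function(x, ...) x$x

#' Cross-task %ERD/ERS feature matrix
#'
#' For every interval pair, a Burg AR spectrum is fitted separately to the
#' activation and the resting interval of each electrode, evaluated at the
#' requested integer frequencies, and combined into %ERD/ERS. One row per
#' trial; with defaults 10 electrodes x 10 frequencies = 100 columns, the
#' same feature definition for every task.
#'
#' @param recording an [eeg_recording()]
#' @param pairs an `interval_pairs` data frame ([extract_interval_pairs()])
#' @param electrodes electrode subset (default the 10-channel montage)
#' @param freqs evaluation frequencies in Hz
#' @param order Burg AR order
#' @return a `wml_features` object; trials whose spectra could not be
#'   estimated are dropped (count reported via message)
#' @export
crosstask_features <- function(recording, pairs, electrodes = DEFAULT_EEG,
                               freqs = 4:13, order = 16) {
  if (nrow(pairs) == 0L) stopf("no interval pairs supplied")
  missing_el <- setdiff(electrodes, recording$channels)
  if (length(missing_el))
    stopf("electrodes not in recording: %s", paste(missing_el, collapse = ", "))
  rate <- recording$rate
  feat_names <- as.vector(t(outer(electrodes, freqs, paste, sep = "_")))
  n <- nrow(pairs)
  x <- matrix(NA_real_, n, length(feat_names), dimnames = list(NULL, feat_names))
  ok <- logical(n)
  for (i in seq_len(n)) {
    row <- tryCatch({
      sa <- epoch_signal(recording, pairs$ia_start[i], pairs$ia_end[i], electrodes)
      sr <- epoch_signal(recording, pairs$ir_start[i], pairs$ir_end[i], electrodes)
      vals <- numeric(0)
      for (e in seq_along(electrodes)) {
        pa <- ar_psd(burg(sa[e, ], order), rate, freqs)$power
        pr <- ar_psd(burg(sr[e, ], order), rate, freqs)$power
        vals <- c(vals, erd_ers(pa, pr))
      }
      vals
    }, error = function(e) NULL)
    if (!is.null(row) && all(is.finite(row))) {
      x[i, ] <- row
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stopf("no trial yielded valid spectra")
  if (any(!ok)) message(sum(!ok), " trial(s) dropped during feature extraction")
  new_features(x[ok, , drop = FALSE], as.data.frame(pairs)[ok, , drop = FALSE])
}

#' Alpha band-power features for the alternating-materials design
#'
#' One row per 15-s epoch; columns are raw alpha (8-13 Hz) Burg band power
#' per electrode, labels are the material type. Only the alpha band is
#' available in this mode: the materials showed no theta differences, and
#' the mode predates the ratio-based features.
#'
#' @param recording an [eeg_recording()]
#' @param epochs a `wml_epochs` data frame ([segment_study_windows()])
#' @param electrodes electrode subset (default frontal + parietal)
#' @param band must be "alpha"
#' @param order Burg AR order
#' @return a `wml_features` object with material-type labels
#' @export
study1_features <- function(recording, epochs,
                            electrodes = c("F3", "Fz", "F4", "P3", "Pz", "P4"),
                            band = "alpha", order = 16) {
  if (nrow(epochs) == 0L) stopf("no epochs supplied")
  if (!identical(band, "alpha"))
    stopf("only alpha band power is supported in this mode")
  bf <- FREQ_BANDS$alpha
  n <- nrow(epochs)
  x <- matrix(NA_real_, n, length(electrodes),
              dimnames = list(NULL, paste0(electrodes, "_alpha")))
  for (i in seq_len(n)) {
    sl <- epoch_signal(recording, epochs$start_s[i], epochs$end_s[i], electrodes)
    for (e in seq_along(electrodes)) {
      x[i, e] <- band_power(ar_psd(burg(sl[e, ], order), recording$rate, bf),
                            "alpha")
    }
  }
  labels <- factor(ifelse(epochs$task_id == "study1_theorem", "theorem", "comic"),
                   levels = c("comic", "theorem"))
  new_features(x, as.data.frame(epochs), labels = labels)
}

#' Serialize a feature matrix to TSV (+ JSON provenance sidecar)
#'
#' @param features a `wml_features` object
#' @param path TSV path; provenance goes to `paste0(path, ".json")`
#' @export
write_features_tsv <- function(features, path) {
  df <- as.data.frame(features$x)
  if (!is.null(features$labels)) df$label <- as.character(features$labels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(features$info, paste0(path, ".json"), digits = NA)
  invisible(path)
}
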