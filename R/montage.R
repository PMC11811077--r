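# Recordings, electrode label canonicalisation and the 16-channel bipolar
# montage over the neonatal 10-20 electrode set.

#' The 12 neonatal 10-20 electrodes
#' @return character vector of canonical electrode names.
#' @export
neonatal_electrodes <- function() {
  c("Fp1", "Fp2", "T3", "T4", "C3", "C4", "P3", "P4", "O1", "O2", "Cz", "Pz")
}

# Accepted alternative names for the same physical sites (modern 10-10
# nomenclature). Anything else that fails a case-insensitive match against
# the 12-electrode set is not a montage electrode.
electrode_aliases <- function() c(T7 = "T3", T8 = "T4")

# Case-insensitive canonicalisation of one EDF label; NA when the label is
# not (an alias of) a montage electrode. Common "EEG Fp1-Ref" dialects are
# stripped first.
canonical_electrode <- function(label) {
  x <- trimws(label)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("[-_ ](REF|LE|AVG)$", "", x, ignore.case = TRUE)
  std <- neonatal_electrodes()
  hit <- match(toupper(x), toupper(std))
  if (!is.na(hit)) return(std[hit])
  ali <- electrode_aliases()
  hit <- match(toupper(x), toupper(names(ali)))
  if (!is.na(hit)) return(unname(ali[hit]))
  NA_character_
}

#' Construct an EEG recording
#'
#' A recording holds a channels-by-samples matrix of voltages in microvolts
#' together with its sampling rate, channel labels and per-subject metadata
#' (opaque subject identifier and PMA label in weeks).
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels channel labels, one per row of `data`.
#' @param subject_id opaque subject identifier.
#' @param pma_weeks postmenstrual age in weeks, or `NA` when unlabelled.
#' @param pma_range plausible PMA range; labels outside it are rejected.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(data, fs, labels, subject_id = "anon",
                      pma_weeks = NA_real_, pma_range = c(20, 46)) {
  data <- as.matrix(data)
  if (length(labels) != nrow(data)) {
    stop_value("got %d labels for %d data rows", length(labels), nrow(data))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop_value("fs must be a positive number")
  if (!is.na(pma_weeks) && (pma_weeks < pma_range[1] || pma_weeks > pma_range[2])) {
    stop_value("pma_weeks = %.2f outside plausible range [%g, %g]",
               pma_weeks, pma_range[1], pma_range[2])
  }
  structure(list(data = data, fs = as.numeric(fs), labels = as.character(labels),
                 subject_id = as.character(subject_id), pma_weeks = as.numeric(pma_weeks)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s | %d ch x %d samples | fs %g Hz | %.4g s | PMA %s wk\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs,
              if (is.na(x$pma_weeks)) "?" else sprintf("%.1f", x$pma_weeks)))
  invisible(x)
}

duration_s <- function(rec) ncol(rec$data) / rec$fs

#' The 16-channel bipolar montage
#'
#' Double-banana longitudinal leads plus symmetric bipolar references over
#' the 12 neonatal electrodes. Channel IDs 1--16 give a stable shorthand for
#' channel-subset bookkeeping during selection.
#'
#' @return data frame with columns `id`, `anode`, `cathode`, `name`.
#' @export
neonatal_montage <- function() {
  m <- data.frame(
    id = 1:16,
    anode   = c("C3", "C3", "C4", "Cz", "Fp1", "Fp1", "Fp1", "Fp2",
                "Fp2", "O1", "P3", "P3", "P4", "T3", "T3", "T4"),
    cathode = c("C4", "P3", "P4", "Pz", "C3", "Fp2", "T3", "C4",
                "T4", "O2", "O1", "P4", "O2", "O1", "T4", "O2"),
    stringsAsFactors = FALSE)
  m$name <- paste0(m$anode, "-", m$cathode)
  stopifnot(all(m$anode != m$cathode),
            all(c(m$anode, m$cathode) %in% neonatal_electrodes()))
  m
}

#' Read a referential EEG recording from EDF
#'
#' Reads a 16-bit EDF file, canonicalises electrode labels (case-insensitive,
#' with `T7`/`T8` accepted as `T3`/`T4`) and keeps the 12 montage electrodes.
#' Subject metadata is never guessed from the EDF header: pass `pma_weeks`
#' and `subject_id` directly or through a JSON sidecar written by
#' [write_sidecar()].
#'
#' @param path EDF file path.
#' @param subject_id,pma_weeks metadata; override sidecar values.
#' @param sidecar path to a JSON sidecar `{"subject_id": ..., "pma_weeks": ...}`.
#' @param units `"uV"` (default) or `"V"`; volt data are converted to
#'   microvolts since amplitude features are scale-dependent.
#' @param pma_range plausible PMA range enforced on load.
#' @return an [recording] with the 12 electrodes in canonical order.
#' @export
read_edf <- function(path, subject_id = NULL, pma_weeks = NULL, sidecar = NULL,
                     units = c("uV", "V"), pma_range = c(20, 46)) {
  units <- match.arg(units)
  if (!file.exists(path)) stop_classed("neofba_io_error", "no such file: %s", path)
  hdr <- read_edf_header(path)
  canon <- vapply(hdr$labels, canonical_electrode, "")
  need <- neonatal_electrodes()
  missing <- setdiff(need, canon)
  if (length(missing)) {
    stop_montage("EDF %s lacks electrode(s): %s", basename(path),
                 paste(missing, collapse = ", "))
  }
  if (!is.null(sidecar)) {
    sc <- if (is.character(sidecar)) jsonlite::read_json(sidecar) else sidecar
    subject_id <- subject_id %||% sc$subject_id
    pma_weeks <- pma_weeks %||% sc$pma_weeks
  }
  dat <- read_edf_data(path, hdr)
  sel <- match(need, canon)
  dat <- dat[sel, , drop = FALSE]
  if (units == "V") dat <- dat * 1e6
  recording(dat, fs = hdr$nsamp[sel[1]] / hdr$record_dur, labels = need,
            subject_id = subject_id %||% hdr$patient,
            pma_weeks = as.numeric(pma_weeks %||% NA_real_), pma_range = pma_range)
}

#' Write the JSON metadata sidecar for an EDF recording
#' @param subject_id,pma_weeks metadata values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(subject_id, pma_weeks, path) {
  jsonlite::write_json(list(subject_id = subject_id, pma_weeks = pma_weeks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Derive the bipolar montage from a referential recording
#'
#' Each bipolar channel is the anode-minus-cathode voltage difference;
#' channels are ordered by montage ID.
#'
#' @param rec a referential [recording] containing all montage electrodes.
#' @param montage montage table as from [neonatal_montage()].
#' @return a 16-channel [recording] labelled `"A-B"`.
#' @export
build_bipolar <- function(rec, montage = neonatal_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  ia <- match(montage$anode, rec$labels)
  ic <- match(montage$cathode, rec$labels)
  bad <- unique(c(montage$anode[is.na(ia)], montage$cathode[is.na(ic)]))
  if (length(bad)) stop_montage("recording lacks electrode(s): %s", paste(bad, collapse = ", "))
  out <- rec$data[ia, , drop = FALSE] - rec$data[ic, , drop = FALSE]
  ord <- order(montage$id)
  recording(out[ord, , drop = FALSE], fs = rec$fs, labels = montage$name[ord],
            subject_id = rec$subject_id, pma_weeks = rec$pma_weeks)
}
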