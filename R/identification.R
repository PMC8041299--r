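#' Mass accuracy in parts per million
#'
#' Absolute relative deviation of an observed m/z from its theoretical value,
#' expressed in ppm. Species-level identification accepts ppm error < 5.
#'
#' @param observed_mz Observed m/z in Da (> 0). Vectorized.
#' @param theoretical_mz Theoretical m/z in Da (> 0).
#' @return Non-negative ppm error.
#' @examples
#' ppm_error(806.5730, 806.5694)  # ~4.46, passes the < 5 filter
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(observed_mz <= 0) || any(theoretical_mz <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  abs(observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Isotope-pattern similarity
#'
#' Cosine similarity between an observed and a theoretical isotope envelope
#' (relative intensities, monoisotopic peak first), scaled to percent.
#' Identification accepts similarity > 80%. The cosine is the conventional
#' envelope comparison; it is 100 exactly when the envelopes are proportional.
#'
#' @param observed,theoretical Numeric vectors of equal length >= 2 with
#'   intensities in [0, 1] (maximum normalized to 1).
#' @return Similarity in [0, 100].
#' @export
isotope_similarity <- function(observed, theoretical) {
  if (length(observed) != length(theoretical)) {
    stop("envelope length mismatch: ", length(observed), " vs ",
         length(theoretical), call. = FALSE)
  }
  if (length(observed) < 2L) stop("envelopes need >= 2 peaks", call. = FALSE)
  if (any(observed < 0) || any(theoretical < 0)) {
    stop("envelope intensities must be non-negative", call. = FALSE)
  }
  no <- sqrt(sum(observed^2)); nt <- sqrt(sum(theoretical^2))
  if (no == 0 || nt == 0) stop("zero envelope", call. = FALSE)
  100 * sum(observed * theoretical) / (no * nt)
}

#' Build a class retention/m-z window table
#'
#' In supercritical fluid chromatography lipids elute by headgroup, so each
#' class occupies a narrow retention zone; a rectangular window in
#' (retention time) x (m/z) designates features of that class. Windows are
#' closed on both ends so boundary features are never silently dropped, and
#' must be pairwise non-overlapping.
#'
#' @param class_windows A data.frame with columns \code{class},
#'   \code{rt_min}, \code{rt_max}, \code{mz_min}, \code{mz_max}.
#' @return The validated table (class \code{class_window_set}).
#' @export
class_window_set <- function(class_windows) {
  req <- c("class", "rt_min", "rt_max", "mz_min", "mz_max")
  if (!all(req %in% names(class_windows))) {
    stop("window table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  w <- class_windows[, req]
  if (any(w$rt_min >= w$rt_max) || any(w$mz_min >= w$mz_max)) {
    stop("each window needs rt_min < rt_max and mz_min < mz_max",
         call. = FALSE)
  }
  n <- nrow(w)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      rt_overlap <- w$rt_min[i] <= w$rt_max[j] && w$rt_min[j] <= w$rt_max[i]
      mz_overlap <- w$mz_min[i] <= w$mz_max[j] && w$mz_min[j] <= w$mz_max[i]
      if (rt_overlap && mz_overlap) {
        stop("class windows overlap: '", w$class[i], "' and '", w$class[j],
             "'", call. = FALSE)
      }
    }
  }
  structure(w, class = c("class_window_set", "data.frame"))
}

#' Read a class window table from delimited text
#'
#' @param path Path to a tab- or comma-delimited file with columns
#'   \code{class}, \code{rt_min}, \code{rt_max}, \code{mz_min}, \code{mz_max}.
#' @param sep Field separator (default tab).
#' @return A validated \code{class_window_set}.
#' @export
read_class_windows <- function(path, sep = "\t") {
  class_window_set(utils::read.table(path, header = TRUE, sep = sep,
                                     stringsAsFactors = FALSE))
}

#' Assign a feature to a lipid class by its retention/m-z window
#'
#' @param retention_time Feature retention time, minutes.
#' @param observed_mz Feature m/z, Da.
#' @param windows A \code{class_window_set}.
#' @return The matching class, or \code{NA_character_} if the feature falls
#'   outside every window. Intervals are closed, so a feature exactly on a
#'   boundary is assigned.
#' @export
assign_class_by_window <- function(retention_time, observed_mz, windows) {
  stopifnot(inherits(windows, "class_window_set"))
  if (retention_time < 0 || observed_mz <= 0) {
    stop("feature needs retention_time >= 0 and observed_mz > 0",
         call. = FALSE)
  }
  hit <- windows$rt_min <= retention_time & retention_time <= windows$rt_max &
    windows$mz_min <= observed_mz & observed_mz <= windows$mz_max
  if (!any(hit)) return(NA_character_)
  windows$class[which(hit)[1L]]
}

#' Apply the species identification filters
#'
#' Combines the three downstream identification criteria: the feature must
#' fall in its class window, have mass accuracy better than \code{max_ppm}
#' and isotope-pattern similarity above \code{min_similarity}.
#'
#' @param retention_time,observed_mz Feature coordinates.
#' @param theoretical_mz Theoretical m/z of the candidate species.
#' @param observed_envelope,theoretical_envelope Isotope envelopes.
#' @param windows A \code{class_window_set}.
#' @param max_ppm Mass-accuracy threshold (default 5 ppm).
#' @param min_similarity Envelope-similarity threshold (default 80%).
#' @return A list with the assigned class (or NA), the ppm error, the
#'   similarity, and \code{identified} (TRUE when all three filters pass).
#' @export
identify_feature <- function(retention_time, observed_mz, theoretical_mz,
                             observed_envelope, theoretical_envelope,
                             windows, max_ppm = 5, min_similarity = 80) {
  cls <- assign_class_by_window(retention_time, observed_mz, windows)
  ppm <- ppm_error(observed_mz, theoretical_mz)
  sim <- isotope_similarity(observed_envelope, theoretical_envelope)
  list(class = cls, ppm = ppm, similarity = sim,
       identified = !is.na(cls) && ppm < max_ppm && sim > min_similarity)
}
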