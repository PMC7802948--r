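## M-mode diaphragm amplitude: per-inspiration baseline-to-peak distance on
## a position-vs-time trace, averaged over 3-5 breaths.

## Savitzky-Golay smoothing of the trace; falls back to the raw signal when
## the trace is too short for the window. Peak/onset values are read from
## the smoothed signal, which suppresses the positive bias that taking a
## max over noisy samples would otherwise add to every amplitude.
.smoothTrace <- function(x, window) {
  window <- as.integer(window)
  if (window < 5L || length(x) <= window) {
    return(x)
  }
  if (window %% 2L == 0L) window <- window + 1L
  as.numeric(signal::sgolayfilt(x, p = 3, n = window))
}

## indices of strict local maxima / minima of a vector
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(integer(0))
  }
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}
.localMinima <- function(x) .localMaxima(-x)

## topographic prominence of peak i among candidate peaks of x
.prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    ## nearest higher point on each side (or the trace end)
    left <- x[seq_len(p - 1L)]
    higherL <- which(left > x[p])
    lo <- if (length(higherL)) max(higherL) + 1L else 1L
    right <- x[(p + 1L):length(x)]
    higherR <- which(right > x[p])
    hi <- if (length(higherR)) p + min(higherR) - 1L else length(x)
    baseL <- min(x[lo:p])
    baseR <- min(x[p:hi])
    x[p] - max(baseL, baseR)
  }, numeric(1L))
}

#' Detect inspirations on an M-mode trace
#'
#' Finds inspiratory peaks as local maxima of the (lightly smoothed) trace
#' with topographic prominence of at least `minProminence`, separated by at
#' least `minSeparation`; each peak is paired with its onset, the last local
#' minimum preceding it (the pre-inspiratory baseline).
#'
#' @param trace an [MModeTrace-class].
#' @param minProminence minimum peak prominence in mm (default 0.2, well
#'   below a mouse diaphragm excursion and above trace noise).
#' @param minSeparation minimum peak separation in seconds (default 0.2,
#'   matching anesthetised-mouse breathing of roughly 2-4 Hz).
#' @param smoothWindow Savitzky-Golay window in samples (odd; 0 disables
#'   smoothing).
#' @return data.frame with columns `onset` and `peak` (sample indices), one
#'   row per detected inspiration, ordered in time; zero rows when no peak
#'   qualifies.
#' @export
detectInspirations <- function(trace, minProminence = 0.2,
                               minSeparation = 0.2, smoothWindow = 11L) {
  stopifnot(is(trace, "MModeTrace"))
  x <- .smoothTrace(tracePosition(trace), smoothWindow)
  peaks <- .localMaxima(x)
  if (length(peaks) == 0L) {
    return(data.frame(onset = integer(0), peak = integer(0)))
  }
  prom <- .prominence(x, peaks)
  peaks <- peaks[prom >= minProminence]
  if (length(peaks) == 0L) {
    return(data.frame(onset = integer(0), peak = integer(0)))
  }
  ## enforce separation greedily, keeping the taller of two close peaks
  minGap <- minSeparation * sampleRate(trace)
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= minGap)) kept <- c(kept, p)
  }
  peaks <- sort(kept)
  minima <- .localMinima(x)
  onset <- vapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    ## last local minimum before the peak that actually sits at the breath
    ## baseline (at least minProminence below the peak); small noise
    ## dimples on the inspiratory upslope do not qualify
    prev <- minima[minima < p & x[minima] <= x[p] - minProminence]
    if (length(prev)) {
      max(prev)
    } else {
      lo <- if (i > 1L) peaks[i - 1L] else 1L
      lo - 1L + which.min(x[lo:p])
    }
  }, integer(1L))
  data.frame(onset = as.integer(onset), peak = as.integer(peaks))
}

#' Per-breath amplitudes and their mean
#'
#' The amplitude of each inspiration is the baseline-to-peak distance
#' `position[peak] - position[onset]` in mm, read from the same smoothed
#' signal used for detection. When more than 5 breaths are available the
#' first 5 after the first full cycle are used (breaths 2-6, a deterministic
#' choice that also skips a possibly clipped first cycle); 3-5 breaths are
#' the conventional basis, and fewer than 3 triggers a warning.
#'
#' @param trace an [MModeTrace-class].
#' @param pairs data.frame from [detectInspirations()]; detected
#'   automatically when omitted.
#' @param baseline `"per_breath"` (pre-inspiratory local minimum; robust to
#'   slow drift) or `"global_median"` (trace median as a common baseline).
#' @param maxBreaths maximum breaths averaged (default 5).
#' @param smoothWindow Savitzky-Golay window; must match the detection
#'   setting for index alignment.
#' @param ... passed to [detectInspirations()] when `pairs` is omitted.
#' @return An [AmplitudeResult-class].
#' @examples
#' tr <- simulateMMode(mmodeTruth(amplitudeMm = 0.9, noiseSdMm = 0), 200)
#' breathAmplitudes(tr)
#' @export
breathAmplitudes <- function(trace, pairs = NULL,
                             baseline = c("per_breath", "global_median"),
                             maxBreaths = 5L, smoothWindow = 11L, ...) {
  stopifnot(is(trace, "MModeTrace"))
  baseline <- match.arg(baseline)
  if (is.null(pairs)) {
    pairs <- detectInspirations(trace, smoothWindow = smoothWindow, ...)
  }
  if (nrow(pairs) < 1L) {
    stop("no inspirations to measure")
  }
  if (nrow(pairs) > maxBreaths) {
    pairs <- pairs[seq(2L, 1L + maxBreaths), , drop = FALSE]
  }
  if (nrow(pairs) < 3L) {
    warning(sprintf(
      "only %d breath(s) available; 3-5 are conventional", nrow(pairs)
    ))
  }
  x <- .smoothTrace(tracePosition(trace), smoothWindow)
  amp <- switch(baseline,
    per_breath = x[pairs$peak] - x[pairs$onset],
    global_median = x[pairs$peak] - stats::median(x)
  )
  new("AmplitudeResult",
    perBreath = as.numeric(amp), meanAmplitude = mean(amp),
    nUsed = nrow(pairs)
  )
}

#' Body-weight normalised amplitude
#'
#' @param meanAmplitude mean diaphragm amplitude in mm.
#' @param bodyWeight body weight in g (> 0).
#' @return Amplitude per gram of body weight (mm/g).
#' @examples
#' normalizeAmplitude(0.68, 34) # 0.02 mm/g
#' @export
normalizeAmplitude <- function(meanAmplitude, bodyWeight) {
  if (any(!is.finite(bodyWeight)) || any(bodyWeight <= 0)) {
    stop("body weight must be positive")
  }
  meanAmplitude / bodyWeight
}

#' Read a digitised M-mode trace from CSV
#'
#' Expects columns `time_s` and `position_mm` (header row required).
#'
#' @param path CSV file path.
#' @return An [MModeTrace-class].
#' @export
readTrace <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "position_mm") %in% names(df))) {
    stop("trace CSV must have columns time_s and position_mm: ", path)
  }
  MModeTrace(df$time_s, df$position_mm)
}

#' Seeded replicate study of amplitude recovery
#'
#' For each seed, simulate a noisy breathing trace with known amplitude,
#' run the detector/estimator and record the recovery error.
#'
#' @param nSeeds number of seeded replicates.
#' @param amplitudeMm,noiseSdMm ground-truth amplitude and noise SD (mm).
#' @param sampleRate sampling rate (Hz).
#' @param seed base seed; replicate k uses `seed + k`.
#' @param ... further arguments to [mmodeTruth()].
#' @return data.frame with one row per replicate: seed, estimate, error.
#' @export
amplitudeRecoveryStudy <- function(nSeeds = 20L, amplitudeMm = 0.9,
                                   noiseSdMm = 0.05, sampleRate = 200,
                                   seed = 1L, ...) {
  rows <- lapply(seq_len(nSeeds), function(k) {
    tr <- simulateMMode(
      mmodeTruth(
        amplitudeMm = amplitudeMm, noiseSdMm = noiseSdMm,
        seed = seed + k, ...
      ),
      sampleRate = sampleRate
    )
    est <- meanAmplitude(breathAmplitudes(tr))
    data.frame(seed = seed + k, estimate = est, error = est - amplitudeMm)
  })
  do.call(rbind, rows)
}
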