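#' Apparent FRET efficiency from ALEX intensities
#'
#' E* = I_DA / (I_DD + I_DA), uncorrected for crosstalk or detection-factor
#' gamma. Frames with zero total donor-excitation signal yield `NA` and are
#' flagged by attribute rather than silently dropped.
#'
#' @param I_DD Donor emission upon donor excitation (per frame).
#' @param I_DA Acceptor emission upon donor excitation.
#' @return Numeric E* per frame; attribute `undefined` marks zero-denominator
#'   frames.
#' @export
compute_estar <- function(I_DD, I_DA) {
  stopifnot(length(I_DD) == length(I_DA))
  den <- I_DD + I_DA
  bad <- den == 0
  e <- ifelse(bad, NA_real_, I_DA / den)
  if (any(bad)) attr(e, "undefined") <- which(bad)
  e
}

#' Donor-acceptor stoichiometry from ALEX intensities
#'
#' S = (I_DD + I_DA) / (I_DD + I_DA + I_AA); near 1 for donor-only, near 0
#' for acceptor-only, intermediate for doubly labelled molecules.
#'
#' @param I_DD,I_DA Intensities upon donor excitation.
#' @param I_AA Acceptor emission upon acceptor excitation.
#' @return Numeric S per frame; attribute `undefined` marks zero-denominator
#'   frames.
#' @export
compute_stoichiometry <- function(I_DD, I_DA, I_AA) {
  stopifnot(length(I_DD) == length(I_DA), length(I_DA) == length(I_AA))
  den <- I_DD + I_DA + I_AA
  bad <- den == 0
  s <- ifelse(bad, NA_real_, (I_DD + I_DA) / den)
  if (any(bad)) attr(s, "undefined") <- which(bad)
  s
}

#' Construct an intensity trace object
#'
#' @param trace_id Identifier.
#' @param I_DD,I_DA,I_AA Equal-length per-frame intensity series.
#' @param frame_time Frame time in seconds.
#' @return Object of class `intensity_trace`.
#' @export
intensity_trace <- function(trace_id, I_DD, I_DA, I_AA, frame_time) {
  n <- length(I_DD)
  if (n < 1L || length(I_DA) != n || length(I_AA) != n)
    stop("intensity series must be equal length >= 1")
  if (any(!is.finite(c(I_DD, I_DA, I_AA)))) stop("intensities must be finite")
  structure(list(trace_id = as.character(trace_id),
                 I_DD = as.numeric(I_DD), I_DA = as.numeric(I_DA),
                 I_AA = as.numeric(I_AA), frame_time = frame_time),
            class = "intensity_trace")
}

# Robust noise floor: 3 x MAD of the last `n` frames (post-bleach baseline).
noise_floor <- function(series, n = 20L) {
  tailpart <- tail(series, n)
  3 * stats::mad(tailpart, center = stats::median(tailpart))
}

#' Detect photobleaching steps in an intensity series
#'
#' Windowed-median change-point surrogate for the manual screening usually
#' applied to TIRF traces: a frame is a bleach step when the forward median
#' over `window` frames falls below `drop_ratio` times the backward median and
#' the series stays at the noise floor afterwards. Two or more steps signal
#' multi-step bleaching.
#'
#' @param series Intensity series, length >= 2*window.
#' @param window Median window in frames.
#' @param drop_ratio Fractional drop defining a step, in (0, 1).
#' @return Integer vector of 0-based step frames (possibly empty).
#' @export
detect_bleach_steps <- function(series, window = 5L, drop_ratio = 0.5) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (drop_ratio <= 0 || drop_ratio >= 1) stop("drop_ratio must be in (0,1)")
  n <- length(series)
  if (n < 2L * window) stop("series too short for the chosen window")
  floor_level <- noise_floor(series)
  steps <- integer(0)
  t <- window + 1L
  while (t <= n - window + 1L) {
    back <- stats::median(series[(t - window):(t - 1L)])
    fwd <- stats::median(series[t:min(n, t + window - 1L)])
    if (back > floor_level && fwd < drop_ratio * back) {
      # refine: first frame at or below the midpoint of the two levels
      span <- t:min(n, t + 2L * window)
      mid <- (back + fwd) / 2
      hit <- span[series[span] <= mid][1]
      if (is.na(hit)) hit <- t
      steps <- c(steps, hit - 1L)        # 0-based step frame
      t <- hit + window                  # skip past the edge of this step
    } else {
      t <- t + 1L
    }
  }
  steps
}

#' Detect fluorophore blinking in an intensity series
#'
#' TRUE when the series drops to the noise floor and later recovers above
#' `drop_ratio` times its pre-drop level (transient dark state, as opposed to
#' an irreversible bleach).
#'
#' @inheritParams detect_bleach_steps
#' @return Logical scalar.
#' @export
detect_blinking <- function(series, window = 5L, drop_ratio = 0.5) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (drop_ratio <= 0 || drop_ratio >= 1) stop("drop_ratio must be in (0,1)")
  n <- length(series)
  if (n < 2L * window) stop("series too short for the chosen window")
  floor_level <- noise_floor(series)
  med <- vapply(seq_len(n - window + 1L),
                function(t) stats::median(series[t:(t + window - 1L)]), numeric(1))
  pre <- stats::median(series[seq_len(window)])
  if (pre <= floor_level) return(FALSE)
  dark <- which(med <= floor_level)
  if (length(dark) == 0L) return(FALSE)
  any(med[dark[1]:length(med)] > drop_ratio * pre)
}

#' Truncate an intensity trace at its first bleach event and return E*
#'
#' Only data points preceding any donor or acceptor photobleaching event are
#' retained.
#'
#' @param trace An `intensity_trace`.
#' @param first_bleach 0-based frame of the first bleach step, or `NULL` for
#'   none (full trace kept).
#' @return A `fret_trace` of E* values over frames `[0, first_bleach)`.
#' @export
truncate_at_bleach <- function(trace, first_bleach = NULL) {
  n <- length(trace$I_DD)
  if (is.null(first_bleach)) first_bleach <- n
  if (first_bleach < 1L || first_bleach > n)
    stop("first_bleach must leave at least one frame within the trace")
  idx <- seq_len(first_bleach)
  e <- compute_estar(trace$I_DD[idx], trace$I_DA[idx])
  fret_trace(trace$trace_id, as.numeric(e), trace$frame_time)
}

#' Classify a molecule by mean stoichiometry
#'
#' @param mean_estar Mean E* of the trace (unused by the rule; kept for
#'   reporting symmetry with E*-S plots).
#' @param mean_s Mean stoichiometry.
#' @param s_bounds `(low, high)` gates with 0 < low < high < 1; D-A species
#'   lie within the gates, donor-only above, acceptor-only below.
#' @return One of `"D-A"`, `"D-only"`, `"A-only"`.
#' @export
classify_species <- function(mean_estar, mean_s, s_bounds = c(0.3, 0.8)) {
  if (!(s_bounds[1] > 0 && s_bounds[1] < s_bounds[2] && s_bounds[2] < 1))
    stop("s_bounds must satisfy 0 < low < high < 1")
  if (mean_s > s_bounds[2]) "D-only"
  else if (mean_s < s_bounds[1]) "A-only"
  else "D-A"
}

#' Selection rules for intensity-trace screening
#'
#' @param early_bleach_frames Traces with any bleach step before this many
#'   initial frames are excluded (the conventional frames 1-50 gate; 0-based
#'   indices 0-49).
#' @param min_length Minimum kept-trace length in frames.
#' @param window,drop_ratio Change-point detector settings.
#' @param s_bounds Stoichiometry gates for D-A classification.
#' @return List of rule settings.
#' @export
selection_rules <- function(early_bleach_frames = 50L, min_length = 20L,
                            window = 5L, drop_ratio = 0.5,
                            s_bounds = c(0.3, 0.8)) {
  list(early_bleach_frames = as.integer(early_bleach_frames),
       min_length = as.integer(min_length), window = as.integer(window),
       drop_ratio = drop_ratio, s_bounds = s_bounds)
}

#' Screen intensity traces and convert survivors to E* traces
#'
#' Applies the standard smFRET trace-selection protocol: exclude traces with
#' multi-step donor or acceptor photobleaching, traces bleaching within the
#' first 50 frames, blinking traces, and donor-only / acceptor-only species;
#' truncate kept traces at the first bleach event. Donor bleaching is
#' detected on I_DD + I_DA, acceptor bleaching on I_AA.
#'
#' @param dataset List of `intensity_trace` objects.
#' @param rules A [selection_rules()] list.
#' @return List with `traces` (kept `fret_trace`s) and `report` (data.frame
#'   with one verdict per input trace: trace_id, kept, reason, truncate_frame).
#' @export
select_traces <- function(dataset, rules = selection_rules()) {
  verdicts <- vector("list", length(dataset))
  kept <- list()
  for (i in seq_along(dataset)) {
    tr <- dataset[[i]]
    n <- length(tr$I_DD)
    row <- data.frame(trace_id = tr$trace_id, kept = FALSE,
                      reason = NA_character_, truncate_frame = NA_integer_,
                      stringsAsFactors = FALSE)
    donor_sig <- tr$I_DD + tr$I_DA
    if (n < 2L * rules$window || n < rules$min_length) {
      row$reason <- "too-short"
      verdicts[[i]] <- row
      next
    }
    d_steps <- detect_bleach_steps(donor_sig, rules$window, rules$drop_ratio)
    a_steps <- detect_bleach_steps(tr$I_AA, rules$window, rules$drop_ratio)
    all_steps <- sort(c(d_steps, a_steps))
    if (length(d_steps) >= 2L || length(a_steps) >= 2L) {
      row$reason <- "multi-step-bleach"
    } else if (length(all_steps) > 0L && all_steps[1] < rules$early_bleach_frames) {
      row$reason <- "early-bleach"
    } else if (detect_blinking(donor_sig, rules$window, rules$drop_ratio) ||
               detect_blinking(tr$I_AA, rules$window, rules$drop_ratio)) {
      row$reason <- "blink"
    } else {
      cut <- if (length(all_steps) > 0L) all_steps[1] else n
      if (cut < rules$min_length) {
        row$reason <- "too-short"
      } else {
        idx <- seq_len(cut)
        s_mean <- mean(compute_stoichiometry(tr$I_DD[idx], tr$I_DA[idx],
                                             tr$I_AA[idx]), na.rm = TRUE)
        e_mean <- mean(compute_estar(tr$I_DD[idx], tr$I_DA[idx]), na.rm = TRUE)
        sp <- classify_species(e_mean, s_mean, rules$s_bounds)
        if (sp != "D-A") {
          row$reason <- "not-DA-species"
        } else {
          row$kept <- TRUE
          row$reason <- "kept"
          row$truncate_frame <- cut
          kept[[length(kept) + 1L]] <- truncate_at_bleach(tr, cut)
        }
      }
    }
    verdicts[[i]] <- row
  }
  list(traces = kept, report = do.call(rbind, verdicts))
}
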