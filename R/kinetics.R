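#' Count interstate transitions in a decoded path
#'
#' @param path A `state_path` (or `true_path`).
#' @return Number of frame pairs (t, t+1) with differing states.
#' @export
count_transitions <- function(path) {
  s <- path$states
  if (length(s) < 1L) stop("empty path")
  sum(diff(s) != 0L)
}

#' Classify a molecule as static or dynamic
#'
#' A molecule is dynamic when its decoded path shows more than three
#' interstate transitions within the observation span; three or fewer is
#' static.
#'
#' @param path A `state_path`.
#' @return `"dynamic"` or `"static"`.
#' @export
classify_dynamic <- function(path) {
  if (count_transitions(path) > 3L) "dynamic" else "static"
}

#' Flag candidate dynamic traces by donor/acceptor anti-correlation
#'
#' Optional pre-filter mirroring visual screening for anti-correlated DD and
#' DA channels; the binding static/dynamic call remains the transition-count
#' rule of [classify_dynamic()].
#'
#' @param trace An `intensity_trace`.
#' @param r_threshold Pearson correlation below which the trace is flagged.
#' @return Logical.
#' @export
flag_anticorrelated <- function(trace, r_threshold = -0.2) {
  if (sd(trace$I_DD) == 0 || sd(trace$I_DA) == 0) return(FALSE)
  stats::cor(trace$I_DD, trace$I_DA) < r_threshold
}

#' Convert a fitted model's transition matrix to rates
#'
#' Off-diagonal per-frame transition probabilities multiplied by the number
#' of frames per second; the package's rate convention throughout.
#'
#' @param model An `hmm_model` (or any list with `trans` and `frame_time`).
#' @return K x K matrix of rates in s^-1 with zero diagonal.
#' @export
rates_from_model <- function(model) {
  k <- model$trans / model$frame_time
  diag(k) <- 0
  k
}

#' Transition rates with group errors from dynamic traces
#'
#' Traces are randomly partitioned (seeded) into `n_groups` near-equal
#' groups; each group is fitted at fixed `K`; per-group rates are the fitted
#' per-frame transition probabilities divided by the frame time; the report
#' is the across-group mean with the across-group SD as error. Group states
#' are matched to the global ordering by ascending mean E*. Rates whose
#' expected transition count is below one in every group are reported `NA`
#' (too rare to estimate).
#'
#' @param dynamic_traces List of `fret_trace` objects (dynamic molecules).
#' @param K Number of states (fixed; from model selection on the full set).
#' @param frame_time Frame time in seconds.
#' @param n_groups Number of groups (default 3).
#' @param seed Seed for the random partition and the group fits.
#' @param ... Passed to [fit_hmm()].
#' @return List of class `kinetics_summary` with `k` (mean rates), `k_sd`,
#'   `dwell_means` (1 / summed exit rates), `n_groups`, `group_fits`,
#'   `frame_time`.
#' @export
transition_rates <- function(dynamic_traces, K, frame_time, n_groups = 3,
                             seed = 1, ...) {
  n <- length(dynamic_traces)
  if (n < n_groups) stop("need at least one trace per group")
  set.seed(trace_seed(seed, 0L))
  grp <- sample(rep_len(seq_len(n_groups), n))
  fits <- vector("list", n_groups)
  rate_arr <- array(NA_real_, c(K, K, n_groups))
  count_arr <- array(NA_real_, c(K, K, n_groups))
  for (g in seq_len(n_groups)) {
    fits[[g]] <- fit_hmm(dynamic_traces[grp == g], K, seed = trace_seed(seed, g), ...)
    kg <- rates_from_model(fits[[g]])
    rate_arr[, , g] <- kg
    # expected transition counts: per-frame probability x frames decoded in i
    occ_frames <- colSums(do.call(rbind, lapply(dynamic_traces[grp == g], function(tr) {
      g2 <- forward_backward(tr, fits[[g]])$gamma
      colSums(g2)
    })))
    count_arr[, , g] <- occ_frames * fits[[g]]$trans
  }
  k_mean <- apply(rate_arr, c(1, 2), mean)
  k_sd <- apply(rate_arr, c(1, 2), sd)
  too_rare <- apply(count_arr, c(1, 2), max) < 1
  diag(too_rare) <- TRUE
  k_mean[too_rare & row(k_mean) != col(k_mean)] <- NA_real_
  k_sd[too_rare & row(k_sd) != col(k_sd)] <- NA_real_
  diag(k_mean) <- 0; diag(k_sd) <- 0
  exit <- rowSums(k_mean, na.rm = TRUE)
  structure(list(k = k_mean, k_sd = k_sd,
                 dwell_means = ifelse(exit > 0, 1 / exit, Inf),
                 n_groups = n_groups, group_fits = fits,
                 frame_time = frame_time),
            class = "kinetics_summary")
}

#' Mean dwell time in a state from its exit rates
#'
#' The mean lifetime of state i is the reciprocal of the summed transition
#' rates out of that state, 1 / sum_j k_ij.
#'
#' @param rates K x K rate matrix in s^-1 (diagonal ignored; `NA` entries
#'   treated as zero).
#' @param state State index (1-based) or label.
#' @return Mean dwell in seconds; `Inf` (with a warning) when all exit rates
#'   are zero.
#' @export
mean_dwell <- function(rates, state) {
  r <- rates[state, ]
  r[state] <- 0
  total <- sum(r, na.rm = TRUE)
  if (total <= 0) {
    warning("all exit rates zero: infinite dwell")
    return(Inf)
  }
  1 / total
}

#' Extract dwell records from a decoded path
#'
#' Maximal constant-state runs; the first and last runs are flagged censored
#' (the molecule was already in the state at the start, or still in it at
#' bleach/end).
#'
#' @param path A `state_path`.
#' @return data.frame with columns trace_id, state (0-based), start_frame
#'   (0-based), frames, seconds, censored_start, censored_end.
#' @export
extract_dwells <- function(path) {
  s <- path$states
  if (length(s) < 1L) stop("empty path")
  r <- rle(s)
  n_runs <- length(r$lengths)
  starts <- cumsum(c(0L, r$lengths[-n_runs]))
  data.frame(trace_id = path$trace_id, state = r$values,
             start_frame = starts, frames = r$lengths,
             seconds = r$lengths * path$frame_time,
             censored_start = seq_len(n_runs) == 1L,
             censored_end = seq_len(n_runs) == n_runs,
             stringsAsFactors = FALSE)
}

#' Fraction of long dwells in a state
#'
#' @param dwells data.frame from [extract_dwells()] (rows from many traces
#'   may be concatenated with `rbind`).
#' @param state State index (0-based, as stored in dwell records).
#' @param threshold Duration threshold in seconds (default 5.0).
#' @param include_censored Count edge-censored dwells too? Default FALSE.
#' @return Fraction of counted state dwells with `seconds > threshold`.
#' @export
long_dwell_fraction <- function(dwells, state, threshold = 5.0,
                                include_censored = FALSE) {
  d <- dwells[dwells$state == state, , drop = FALSE]
  if (!include_censored)
    d <- d[!d$censored_start & !d$censored_end, , drop = FALSE]
  if (nrow(d) == 0L) stop("no counted dwells in state ", state)
  mean(d$seconds > threshold)
}

#' Fraction of dwells shorter than one camera frame
#'
#' Dwells in an exponential state with exit-rate sum `sum_j k_ij` that are
#' shorter than the output frame time are invisible at that acquisition
#' rate. Estimated by Monte-Carlo sampling of exponential dwell durations;
#' the analytic value `1 - exp(-frame_time_out * sum(k))` is returned
#' alongside.
#'
#' @param rates K x K rate matrix in s^-1.
#' @param state State index (1-based) or label.
#' @param frame_time_out Frame time of the slow acquisition in seconds.
#' @param n_samples Monte-Carlo sample count.
#' @param seed Seed for the draws.
#' @return List with `fraction` (Monte-Carlo), `analytic`, `n_samples`.
#' @export
missed_dwell_fraction <- function(rates, state, frame_time_out,
                                  n_samples = 1e5, seed = 1) {
  if (frame_time_out <= 0) stop("frame_time_out must be positive")
  r <- rates[state, ]
  r[state] <- 0
  total <- sum(r, na.rm = TRUE)
  if (total <= 0) return(list(fraction = 0, analytic = 0, n_samples = 0L))
  set.seed(trace_seed(seed, 0L))
  dwell <- rexp(n_samples, rate = total)
  list(fraction = mean(dwell < frame_time_out),
       analytic = 1 - exp(-frame_time_out * total),
       n_samples = as.integer(n_samples))
}

#' Per-state occupancy from decoded paths
#'
#' @param paths List of `state_path` objects (a single path is accepted).
#' @param K Number of states; inferred from the paths when missing.
#' @return Named fraction vector summing to 1.
#' @export
occupancy <- function(paths, K = NULL) {
  if (inherits(paths, "state_path") || inherits(paths, "true_path"))
    paths <- list(paths)
  s <- unlist(lapply(paths, function(p) p$states))
  if (length(s) == 0L) stop("no frames")
  if (is.null(K)) K <- max(s) + 1L
  tab <- tabulate(s + 1L, nbins = K)
  setNames(tab / sum(tab), paste0("state", seq_len(K) - 1L))
}

#' Static/dynamic census of a decoded dataset
#'
#' @param paths List of `state_path` objects.
#' @return List with `n_static`, `n_dynamic` and the per-trace verdicts.
#' @export
dynamic_census <- function(paths) {
  verdict <- vapply(paths, classify_dynamic, character(1))
  list(n_static = sum(verdict == "static"),
       n_dynamic = sum(verdict == "dynamic"),
       verdict = setNames(verdict, vapply(paths, function(p) p$trace_id,
                                          character(1))))
}
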