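#' Specify transition rates between conformational states
#'
#' @param k Square numeric matrix of off-diagonal first-order rates
#'   \eqn{k_{ij}} (s^-1) for transitions from state `i` to state `j`. The
#'   diagonal is ignored (forced to zero). Row/column names, if present, name
#'   the states in ascending order of mean E*.
#' @param state_labels Optional character vector of state names overriding the
#'   dimnames of `k`.
#' @return An object of class `rate_spec`.
#' @export
rate_spec <- function(k, state_labels = NULL) {
  k <- as.matrix(k)
  if (nrow(k) != ncol(k)) stop("rate matrix must be square")
  if (any(!is.finite(k))) stop("rates must be finite")
  diag(k) <- 0
  if (any(k < 0)) stop("rates must be non-negative")
  if (is.null(state_labels)) state_labels <- rownames(k)
  if (is.null(state_labels)) state_labels <- paste0("S", seq_len(nrow(k)))
  dimnames(k) <- list(state_labels, state_labels)
  structure(list(k = k, state_labels = state_labels), class = "rate_spec")
}

#' Specify the Gaussian emission model for simulated E* traces
#'
#' @param means Per-state mean apparent FRET efficiency E*, strictly
#'   increasing with state index.
#' @param noise_sd Standard deviation of the per-frame Gaussian noise added to
#'   the state mean (dimensionless E* units).
#' @return An object of class `emission_spec`.
#' @export
emission_spec <- function(means, noise_sd) {
  if (any(diff(means) <= 0)) stop("state means must be strictly increasing")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    stop("noise_sd must be a positive scalar")
  structure(list(means = as.numeric(means), noise_sd = noise_sd),
            class = "emission_spec")
}

#' Configure a trajectory simulation
#'
#' `frame_time` and `n_frames` describe the *output* traces. With
#' `bin_factor > 1` the underlying state path is simulated at the finer time
#' `frame_time / bin_factor` for `n_frames * bin_factor` frames, the noiseless
#' state-mean series is averaged in blocks of `bin_factor`, and Gaussian noise
#' of `emission_spec$noise_sd` is added to the binned series. This emulates
#' slow-camera acquisition of fast dynamics.
#'
#' @param rate_spec A [rate_spec].
#' @param emission_spec An [emission_spec]; one mean per state.
#' @param frame_time Output frame time in seconds.
#' @param n_traces,n_frames Number of traces and output frames per trace.
#' @param bin_factor Integer >= 1; frames averaged per output frame.
#' @param seed Integer root seed for the dataset.
#' @param initial `"stationary"` (default) or an explicit probability vector
#'   over states.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rate_spec, emission_spec, frame_time, n_traces, n_frames,
                       bin_factor = 1L, seed = 1L, initial = "stationary") {
  stopifnot(inherits(rate_spec, "rate_spec"), inherits(emission_spec, "emission_spec"))
  if (length(emission_spec$means) != nrow(rate_spec$k))
    stop("one emission mean per state required")
  if (frame_time <= 0) stop("frame_time must be positive")
  if (n_traces < 1 || n_frames < 1) stop("n_traces and n_frames must be >= 1")
  bin_factor <- as.integer(bin_factor)
  if (bin_factor < 1L) stop("bin_factor must be >= 1")
  if (is.numeric(initial)) {
    if (length(initial) != nrow(rate_spec$k) || any(initial < 0) ||
        abs(sum(initial) - 1) > 1e-9)
      stop("initial must be a probability vector over states")
  } else if (!identical(initial, "stationary")) {
    stop("initial must be \"stationary\" or a probability vector")
  }
  structure(list(rate_spec = rate_spec, emission_spec = emission_spec,
                 frame_time = frame_time, n_traces = as.integer(n_traces),
                 n_frames = as.integer(n_frames), bin_factor = bin_factor,
                 seed = as.integer(seed), initial = initial),
            class = "sim_config")
}

#' Per-frame transition probability matrix from first-order rates
#'
#' Uses the linear discretisation \eqn{p_{ij} = k_{ij} \Delta t} (off-diagonal)
#' with the diagonal absorbing the remainder, the same convention under which
#' fitted per-frame transition probabilities are converted back to rates by
#' multiplying with the number of frames per second. A matrix-exponential
#' alternative is available for sensitivity checks.
#'
#' @param rate_spec A [rate_spec].
#' @param frame_time Frame time \eqn{\Delta t} in seconds.
#' @param method `"linear"` (the package contract) or `"expm"`.
#' @return Row-stochastic K x K matrix with the rate_spec's state labels.
#' @export
#' @examples
#' build_transition_matrix(rnap_clamp_rates(), 0.02)
build_transition_matrix <- function(rate_spec, frame_time, method = c("linear", "expm")) {
  method <- match.arg(method)
  if (frame_time <= 0) stop("frame_time must be positive")
  k <- rate_spec$k
  if (method == "expm") {
    Q <- k
    diag(Q) <- -rowSums(k)
    return(expm_pade(Q * frame_time))
  }
  P <- k * frame_time
  off <- rowSums(P)
  if (any(off >= 1))
    stop("frame time too coarse: off-diagonal transition probability >= 1 in row(s) ",
         paste(which(off >= 1), collapse = ", "))
  diag(P) <- 1 - off
  P
}

# Scaling-and-squaring Pade approximant; K is tiny so cost is irrelevant.
expm_pade <- function(M) {
  n <- nrow(M)
  j <- max(0L, 1L + floor(log2(max(rowSums(abs(M)), 1e-300))))
  M <- M / 2^j
  X <- M
  c <- 1 / 2
  E <- diag(n) + c * M
  D <- diag(n) - c * M
  q <- 6L; p <- TRUE
  for (kk in 2:q) {
    c <- c * (q - kk + 1) / (kk * (2 * q - kk + 1))
    X <- M %*% X
    E <- E + c * X
    if (p) D <- D + c * X else D <- D - c * X
    p <- !p
  }
  E <- solve(D, E)
  for (kk in seq_len(j)) E <- E %*% E
  E
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P Row-stochastic transition matrix.
#' @return Probability vector pi with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  K <- nrow(P)
  A <- rbind(t(P) - diag(K), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- qr.solve(A, b)
  pi <- pmax(pi, 0)
  setNames(pi / sum(pi), rownames(P))
}

#' Simulate a discrete-time Markov state path
#'
#' Draws from the current RNG stream; wrap in [set.seed()] (or use
#' [simulate_dataset()]) for reproducibility.
#'
#' @param P Row-stochastic per-frame transition matrix.
#' @param initial Initial state probability vector.
#' @param n_frames Path length.
#' @param frame_time Frame time in seconds, attached to the result.
#' @return Object of class `true_path`: list with integer `states` (0-based)
#'   and `frame_time`.
#' @export
simulate_state_path <- function(P, initial, n_frames, frame_time) {
  if (abs(sum(initial) - 1) > 1e-9 || any(initial < 0))
    stop("initial must be a probability vector")
  if (any(abs(rowSums(P) - 1) > 1e-9)) stop("P must be row-stochastic")
  u <- runif(n_frames)
  structure(list(states = sim_path_core(P, initial, u), frame_time = frame_time),
            class = "true_path")
}

#' Emit a noisy E* trace from a state path
#'
#' E* per frame is the state mean plus zero-mean Gaussian noise; values are
#' deliberately not clipped to \[0, 1\], as in real apparent-FRET data.
#'
#' @param path A `true_path`.
#' @param emission_spec An [emission_spec].
#' @param trace_id Identifier attached to the trace.
#' @return Object of class `fret_trace`.
#' @export
emit_estar <- function(path, emission_spec, trace_id = "sim") {
  means <- emission_spec$means
  if (any(path$states < 0L | path$states >= length(means)))
    stop("path contains states outside the emission model")
  e <- means[path$states + 1L] + rnorm(length(path$states), 0, emission_spec$noise_sd)
  fret_trace(trace_id, e, path$frame_time)
}

#' Construct an E* trace object
#'
#' @param trace_id Identifier.
#' @param estar Numeric vector of per-frame apparent FRET efficiencies.
#' @param frame_time Frame time in seconds.
#' @return Object of class `fret_trace`.
#' @export
fret_trace <- function(trace_id, estar, frame_time) {
  if (length(estar) < 1L) stop("trace must contain at least one frame")
  if (frame_time <= 0) stop("frame_time must be positive")
  structure(list(trace_id = as.character(trace_id), estar = as.numeric(estar),
                 frame_time = frame_time), class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace %s: %d frames @ %g s, mean E* = %.3f>\n",
              x$trace_id, length(x$estar), x$frame_time, mean(x$estar)))
  invisible(x)
}

#' Bin a series by block averaging
#'
#' Output element m is the arithmetic mean of input frames
#' `[m*factor, (m+1)*factor)`; remainder frames are dropped.
#'
#' @param values Numeric series.
#' @param factor Integer >= 1.
#' @return Numeric series of length `floor(length(values) / factor)`.
#' @export
bin_trace <- function(values, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (length(values) < 1L) stop("empty input")
  n_out <- length(values) %/% factor
  if (n_out == 0L) return(numeric(0))
  colMeans(matrix(values[seq_len(n_out * factor)], nrow = factor))
}

# Deterministic per-trace seed fan-out from the dataset root seed.
trace_seed <- function(seed, index) {
  (as.double(seed) * 48271 + index * 16807) %% 2147483647
}

#' Simulate a dataset of FRET traces with known ground truth
#'
#' With `bin_factor = 1`, per-frame Gaussian noise is added directly to the
#' state-mean series. With `bin_factor > 1`, the state path is simulated at
#' the fine frame time, the noiseless state-mean series is block-averaged, and
#' noise is then added to the binned series (see [sim_config()]); ground-truth
#' paths are retained at the fine resolution.
#'
#' @param config A [sim_config].
#' @return Object of class `fret_dataset`: list with `traces` (list of
#'   `fret_trace`), `paths` (list of `true_path`, fine resolution), and
#'   `config`.
#' @export
#' @examples
#' cfg <- sim_config(rnap_clamp_rates(), emission_spec(c(0.20, 0.30, 0.42), 0.07),
#'                   frame_time = 0.02, n_traces = 3, n_frames = 100, seed = 7)
#' ds <- simulate_dataset(cfg)
#' length(ds$traces)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bf <- config$bin_factor
  dt_fine <- config$frame_time / bf
  n_fine <- config$n_frames * bf
  P <- build_transition_matrix(config$rate_spec, dt_fine)
  init <- if (identical(config$initial, "stationary"))
    stationary_distribution(P) else config$initial
  means <- config$emission_spec$means
  sdn <- config$emission_spec$noise_sd

  traces <- vector("list", config$n_traces)
  paths <- vector("list", config$n_traces)
  for (i in seq_len(config$n_traces)) {
    set.seed(trace_seed(config$seed, i))
    path <- simulate_state_path(P, init, n_fine, dt_fine)
    paths[[i]] <- path
    id <- sprintf("sim%04d", i)
    if (bf == 1L) {
      traces[[i]] <- emit_estar(path, config$emission_spec, trace_id = id)
    } else {
      level <- bin_trace(means[path$states + 1L], bf)
      e <- level + rnorm(length(level), 0, sdn)
      traces[[i]] <- fret_trace(id, e, config$frame_time)
    }
  }
  structure(list(traces = traces, paths = paths, config = config),
            class = "fret_dataset")
}

#' @export
print.fret_dataset <- function(x, ...) {
  cat(sprintf("<fret_dataset: %d traces x %d frames @ %g s (bin_factor %d, seed %d)>\n",
              length(x$traces), x$config$n_frames, x$config$frame_time,
              x$config$bin_factor, x$config$seed))
  invisible(x)
}

#' Estimate the E* noise SD from static traces
#'
#' The per-frame Gaussian noise level used in simulations is measured as the
#' mean of per-trace sample standard deviations over traces classified static.
#'
#' @param static_traces List of `fret_trace` objects (each length >= 2, or a
#'   constant single-frame trace contributes 0).
#' @return Scalar noise SD (dimensionless).
#' @export
estimate_noise_sd <- function(static_traces) {
  if (length(static_traces) == 0L) stop("no traces supplied")
  sds <- vapply(static_traces, function(tr) {
    if (length(tr$estar) < 2L) return(0)
    sd(tr$estar)
  }, numeric(1))
  mean(sds)
}
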