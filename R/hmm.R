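#' Conjugate prior settings for the variational-Bayes HMM
#'
#' Weakly informative, scale-free defaults: emission means centred on pooled
#' data quantiles with one pseudo-frame of strength; Gamma prior on the
#' emission precision matched to the pooled variance; Dirichlet transition
#' rows with self-transition pseudo-count 1 and off-diagonal 0.1; flat
#' Dirichlet over the initial state.
#'
#' @param mean_strength Pseudo-frames behind each prior emission mean.
#' @param precision_shape Gamma shape for the emission precision.
#' @param self_count,off_count Dirichlet pseudo-counts for transition rows.
#' @param init_count Dirichlet pseudo-count for the initial distribution.
#' @return List of prior settings consumed by [fit_hmm()].
#' @export
hmm_priors <- function(mean_strength = 1, precision_shape = 1,
                       self_count = 1, off_count = 0.1, init_count = 1) {
  list(mean_strength = mean_strength, precision_shape = precision_shape,
       self_count = self_count, off_count = off_count, init_count = init_count)
}

# Materialise prior hyperparameters for K states from the pooled sample.
build_prior <- function(K, x_pooled, priors) {
  v <- max(var(x_pooled), 1e-8)
  list(m0 = as.numeric(quantile(x_pooled, probs = (2 * seq_len(K) - 1) / (2 * K))),
       beta0 = rep(priors$mean_strength, K),
       a0 = rep(priors$precision_shape, K),
       b0 = rep(priors$precision_shape * v, K),
       alpha_trans0 = matrix(priors$off_count, K, K) +
         diag(priors$self_count - priors$off_count, K),
       alpha_init0 = rep(priors$init_count, K))
}

kl_dirichlet <- function(aq, ap) {
  (lgamma(sum(aq)) - sum(lgamma(aq))) - (lgamma(sum(ap)) - sum(lgamma(ap))) +
    sum((aq - ap) * (digamma(aq) - digamma(sum(aq))))
}

kl_normal_gamma <- function(m, beta, a, b, m0, beta0, a0, b0) {
  kl_gamma <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  kl_norm <- 0.5 * (log(beta / beta0) + beta0 / beta +
                      beta0 * (a / b) * (m - m0)^2 - 1)
  sum(kl_gamma + kl_norm)
}

# Expected log emission densities under q(mu, lambda): T x K matrix.
expected_log_emission <- function(x, m, beta, a, b) {
  elog_lambda <- digamma(a) - log(b)
  out <- matrix(0, length(x), length(m))
  for (k in seq_along(m)) {
    out[, k] <- 0.5 * elog_lambda[k] - 0.5 * log(2 * pi) - 0.5 / beta[k] -
      0.5 * (a[k] / b[k]) * (x - m[k])^2
  }
  out
}

#' Fit a pooled variational-Bayes hidden Markov model to E* traces
#'
#' All traces are treated as independent realisations of one K-state model
#' with Gaussian emissions (shared means, SDs, transition matrix and initial
#' distribution). Inference is variational-Bayes EM with conjugate priors
#' (Normal-Gamma emissions, Dirichlet transition rows), the standard
#' machinery behind lower-bound-based smFRET state counting. The returned
#' fit quality `L` is the total evidence lower bound divided by the number of
#' traces ("lower bound per series").
#'
#' @param traces List of `fret_trace` objects sharing one frame time.
#' @param K Number of states (>= 1).
#' @param priors A [hmm_priors()] list.
#' @param n_restarts Independent initialisations; the fit with the highest
#'   lower bound is returned.
#' @param tol Convergence threshold on the per-frame change in the lower
#'   bound.
#' @param max_iter Iteration cap per restart.
#' @param seed Integer seed controlling initialisation jitter.
#' @return Object of class `hmm_model` with fields `K`, `means`, `sds`,
#'   `trans`, `init`, `L`, `frame_time`, posterior hyperparameters
#'   (`posterior`), the per-iteration lower-bound trace (`elbo_trace`), and a
#'   per-state `collapsed` flag (expected occupancy < 1 frame). States are
#'   ordered by ascending mean E*.
#' @export
fit_hmm <- function(traces, K, priors = hmm_priors(), n_restarts = 3,
                    tol = 1e-8, max_iter = 500, seed = 1) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (length(traces) == 0L) stop("no traces supplied")
  xs <- lapply(traces, function(tr) tr$estar)
  frame_time <- traces[[1]]$frame_time
  n_frames_total <- sum(lengths(xs))
  if (n_frames_total < 10L * K) stop("need at least 10 frames per state")
  prior <- build_prior(K, unlist(xs), priors)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(trace_seed(seed, r))
    fit <- vbem_once(xs, K, prior, tol, max_iter)
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }
  finalize_hmm(best, K, frame_time, length(traces))
}

# One VBEM run from a jittered quantile initialisation.
vbem_once <- function(xs, K, prior, tol, max_iter) {
  x_all <- unlist(xs)
  n_total <- length(x_all)
  spread <- diff(range(x_all))
  m_init <- sort(prior$m0 + rnorm(K, 0, 0.05 * max(spread, 1e-6)))

  # hard assignment to nearest initial mean -> initial sufficient statistics
  stats <- hard_assign_stats(xs, m_init)
  post <- m_step(stats, prior)

  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  for (it in seq_len(max_iter)) {
    es <- e_step(xs, post)
    elbo <- es$logZ - kl_terms(post, prior)
    elbo_trace <- c(elbo_trace, elbo)
    post <- m_step(es$stats, prior)
    if (is.finite(elbo_prev) && abs(elbo - elbo_prev) / n_total < tol) break
    elbo_prev <- elbo
  }
  list(post = post, elbo = elbo, elbo_trace = elbo_trace, n_iter = it,
       stats = es$stats)
}

hard_assign_stats <- function(xs, means) {
  K <- length(means)
  N <- numeric(K); sx <- numeric(K); sxx <- numeric(K)
  trans <- matrix(0, K, K); init <- numeric(K)
  for (x in xs) {
    z <- max.col(-abs(outer(x, means, "-")), ties.method = "first")
    for (k in seq_len(K)) {
      sel <- z == k
      N[k] <- N[k] + sum(sel)
      sx[k] <- sx[k] + sum(x[sel])
      sxx[k] <- sxx[k] + sum(x[sel]^2)
    }
    init[z[1]] <- init[z[1]] + 1
    if (length(z) > 1L) {
      for (t in 2:length(z)) trans[z[t - 1L], z[t]] <- trans[z[t - 1L], z[t]] + 1
    }
  }
  list(N = N, sx = sx, sxx = sxx, trans = trans, init = init)
}

m_step <- function(stats, prior) {
  N <- stats$N
  xbar <- ifelse(N > 0, stats$sx / pmax(N, 1e-12), prior$m0)
  S <- ifelse(N > 0, stats$sxx / pmax(N, 1e-12) - xbar^2, 0)
  S <- pmax(S, 0)
  beta <- prior$beta0 + N
  m <- (prior$beta0 * prior$m0 + N * xbar) / beta
  a <- prior$a0 + N / 2
  b <- prior$b0 + 0.5 * (N * S + prior$beta0 * N * (xbar - prior$m0)^2 / beta)
  list(m = m, beta = beta, a = a, b = b,
       alpha_trans = prior$alpha_trans0 + stats$trans,
       alpha_init = prior$alpha_init0 + stats$init)
}

e_step <- function(xs, post) {
  K <- length(post$m)
  elog_A <- digamma(post$alpha_trans) - digamma(rowSums(post$alpha_trans))
  elog_pi <- digamma(post$alpha_init) - digamma(sum(post$alpha_init))
  N <- numeric(K); sx <- numeric(K); sxx <- numeric(K)
  trans <- matrix(0, K, K); init <- numeric(K)
  logZ <- 0
  for (x in xs) {
    logB <- expected_log_emission(x, post$m, post$beta, post$a, post$b)
    fb <- fb_core(logB, elog_A, elog_pi)
    g <- fb$gamma
    logZ <- logZ + fb$logZ
    N <- N + colSums(g)
    sx <- sx + as.numeric(crossprod(g, x))
    sxx <- sxx + as.numeric(crossprod(g, x^2))
    trans <- trans + fb$xi
    init <- init + g[1, ]
  }
  list(stats = list(N = N, sx = sx, sxx = sxx, trans = trans, init = init),
       logZ = logZ)
}

kl_terms <- function(post, prior) {
  K <- length(post$m)
  kl <- kl_normal_gamma(post$m, post$beta, post$a, post$b,
                        prior$m0, prior$beta0, prior$a0, prior$b0)
  kl <- kl + kl_dirichlet(post$alpha_init, prior$alpha_init0)
  for (i in seq_len(K))
    kl <- kl + kl_dirichlet(post$alpha_trans[i, ], prior$alpha_trans0[i, ])
  kl
}

finalize_hmm <- function(fit, K, frame_time, n_traces) {
  post <- fit$post
  ord <- order(post$m)
  trans <- post$alpha_trans[ord, ord, drop = FALSE]
  trans <- trans / rowSums(trans)
  init <- post$alpha_init[ord] / sum(post$alpha_init)
  structure(list(
    K = K,
    means = post$m[ord],
    sds = sqrt(post$b[ord] / post$a[ord]),
    trans = trans,
    init = init,
    L = fit$elbo / n_traces,
    frame_time = frame_time,
    posterior = lapply(list(m = post$m, beta = post$beta, a = post$a,
                            b = post$b), function(v) v[ord]),
    elbo_trace = fit$elbo_trace,
    n_iter = fit$n_iter,
    collapsed = fit$stats$N[ord] < 1
  ), class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model: K = %d, L = %.2f per series, %d iterations>\n",
              x$K, x$L, x$n_iter))
  cat("  means:", paste(sprintf("%.3f", x$means), collapse = " "), "\n")
  cat("  sds:  ", paste(sprintf("%.3f", x$sds), collapse = " "), "\n")
  if (any(x$collapsed)) cat("  WARNING: collapsed state(s):",
                            which(x$collapsed), "\n")
  invisible(x)
}

#' Select the number of states by the lower-bound increment rule
#'
#' Fits models over `k_range` and chooses the smallest K whose increment in
#' lower bound per series when moving to K+1 falls below `delta_threshold`
#' (no significant improvement from an extra state); if every increment is
#' large, the maximum of the range is returned.
#'
#' @param traces List of `fret_trace` objects.
#' @param k_range Ascending integer vector of candidate state counts
#'   (minimum >= 2).
#' @param delta_threshold Lower-bound increment below which an extra state is
#'   judged unsupported.
#' @param ... Passed to [fit_hmm()].
#' @return List with `K`, `L` (named per-K lower bounds) and `fits` (all
#'   per-K models, for audit).
#' @export
select_model <- function(traces, k_range = 2:6, delta_threshold = 1.0, ...) {
  k_range <- as.integer(k_range)
  if (is.unsorted(k_range) || min(k_range) < 2L)
    stop("k_range must be ascending with minimum >= 2")
  fits <- lapply(k_range, function(K) fit_hmm(traces, K, ...))
  L <- vapply(fits, function(f) f$L, numeric(1))
  names(L) <- names(fits) <- paste0("K", k_range)
  K_star <- k_range[length(k_range)]
  if (length(k_range) > 1L) {
    inc <- diff(L)
    hit <- which(inc < delta_threshold)
    if (length(hit) > 0L) K_star <- k_range[hit[1]]
  }
  list(K = K_star, L = L, fits = fits)
}

#' Exact posterior state probabilities for one trace under a fitted model
#'
#' Forward-backward recursions in scaled space with the model's point
#' parameters (posterior means), returning per-frame responsibilities, summed
#' transition responsibilities and the log-evidence of the trace.
#'
#' @param trace A `fret_trace`.
#' @param model An `hmm_model`.
#' @return List with `gamma` (T x K), `xi` (K x K, summed over frame pairs)
#'   and `loglik`.
#' @export
forward_backward <- function(trace, model) {
  logB <- log_emission(trace$estar, model)
  fb <- fb_core(logB, log(model$trans), log(model$init))
  list(gamma = fb$gamma, xi = fb$xi, loglik = fb$logZ)
}

log_emission <- function(x, model) {
  out <- vapply(seq_len(model$K),
                function(k) dnorm(x, model$means[k], model$sds[k], log = TRUE),
                numeric(length(x)))
  if (!all(is.finite(out))) stop("non-finite emission density")
  matrix(out, ncol = model$K)
}

#' Most probable state path for one trace
#'
#' Viterbi decoding under the model's point parameters; ties are broken
#' toward the lower (lower-E*) state index.
#'
#' @param trace A `fret_trace`.
#' @param model An `hmm_model`.
#' @return Object of class `state_path`: list with `trace_id`, integer
#'   `states` (0-based, mean-ordered) and `frame_time`.
#' @export
viterbi <- function(trace, model) {
  logB <- log_emission(trace$estar, model)
  states <- viterbi_core(logB, log(model$trans), log(model$init))
  structure(list(trace_id = trace$trace_id, states = states,
                 frame_time = model$frame_time), class = "state_path")
}

#' Decode every trace in a dataset
#'
#' @param model An `hmm_model`.
#' @param traces List of `fret_trace` objects.
#' @return List of `state_path` objects.
#' @export
decode_paths <- function(model, traces) lapply(traces, viterbi, model = model)
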