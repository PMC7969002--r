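# Independent oracles used by the HMM tests: exhaustive enumeration over all
# K^T state paths. Only feasible for tiny instances; that is the point.

enum_all_paths <- function(T_len, K) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
}

# Log-evidence and jointly most probable path by brute force.
enum_hmm <- function(x, means, sds, A, init) {
  paths <- enum_all_paths(length(x), length(means))
  lp <- apply(paths, 1, function(z) {
    p <- log(init[z[1]]) + sum(dnorm(x, means[z], sds[z], log = TRUE))
    if (length(z) > 1L)
      p <- p + sum(log(A[cbind(z[-length(z)], z[-1])]))
    p
  })
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best_path = as.integer(paths[which.max(lp), ]) - 1L)
}

# Random small HMM instance (valid model + trace) for property tests.
random_hmm_instance <- function(T_len, K) {
  means <- sort(runif(K, 0, 1))
  sds <- runif(K, 0.05, 0.2)
  A <- matrix(rexp(K * K) + 0.1, K, K)
  A <- A / rowSums(A)
  init <- rexp(K) + 0.1
  init <- init / sum(init)
  x <- rnorm(T_len, sample(means, T_len, replace = TRUE), 0.1)
  model <- structure(list(K = K, means = means, sds = sds, trans = A,
                          init = init, frame_time = 0.02),
                     class = "hmm_model")
  list(x = x, model = model)
}

# Reference three-state kinetics shared across tests (20-ms conditions).
ref_rates <- function() rnap_clamp_rates()
ref_emission <- function(sd = 0.070) emission_spec(c(0.20, 0.30, 0.42), sd)
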