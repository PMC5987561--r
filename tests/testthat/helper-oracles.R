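# Independent oracles and small fixture builders used across the test files.

# character-by-character GATC scan, independent of the Biostrings-based
# implementation: returns 0-based cut coordinates (motif start + 2)
oracle_gatc_cuts <- function(seqstr) {
  b <- strsplit(seqstr, "")[[1]]
  cuts <- integer(0)
  if (length(b) >= 4L)
    for (i in seq_len(length(b) - 3L))
      if (b[i] == "G" && b[i + 1L] == "A" && b[i + 2L] == "T" &&
          b[i + 3L] == "C")
        cuts <- c(cuts, i + 1L)  # 1-based motif pos i -> 0-based cut i+1
  cuts
}

# exhaustive path enumeration over all 3^n state paths of a heterogeneous
# chain: joint log-probabilities of every path, plus derived quantities
oracle_enumerate <- function(values, d, params) {
  n <- length(values)
  stopifnot(n <= 10L)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  ld <- sapply(1:3, function(j)
    dnorm(values, params$mu[j], params$sigma[j], log = TRUE))
  ld <- matrix(ld, nrow = n)
  lA <- lapply(d, function(dd) log(transition_matrix(dd, params)))
  logp <- apply(paths, 1L, function(s) {
    lp <- log(params$pi[s[1L]]) + ld[1L, s[1L]]
    if (n > 1L)
      for (t in 2:n) lp <- lp + lA[[t - 1L]][s[t - 1L], s[t]] + ld[t, s[t]]
    lp
  })
  m <- max(logp)
  loglik <- m + log(sum(exp(logp - m)))
  post <- sapply(1:3, function(j)
    vapply(seq_len(n), function(t)
      exp(log(sum(exp(logp[paths[, t] == j] - m))) + m - loglik),
      numeric(1)))
  best <- which.max(logp)
  list(loglik = loglik, best_path = paths[best, ],
       best_logprob = logp[best], posterior = matrix(post, nrow = n))
}

# log-probability of one specific state path (1-based states)
oracle_path_logprob <- function(values, d, params, path) {
  n <- length(values)
  lp <- log(params$pi[path[1L]]) +
    dnorm(values[1L], params$mu[path[1L]], params$sigma[path[1L]], log = TRUE)
  if (n > 1L)
    for (t in 2:n) {
      A <- transition_matrix(d[t - 1L], params)
      lp <- lp + log(A[path[t - 1L], path[t]]) +
        dnorm(values[t], params$mu[path[t]], params$sigma[path[t]],
              log = TRUE)
    }
  lp
}

# random, valid HMM parameters
rand_params <- function() {
  mu <- sort(rnorm(3, 0, 2))
  mu <- mu + c(-0.1, 0, 0.1) * cumsum(rep(1, 3))  # keep strictly apart
  pi <- runif(3, 0.1, 1)
  hmm_params(mu = mu, sigma = runif(3, 0.3, 1.5), pi = pi / sum(pi),
             p0 = runif(1, 0.2, 0.99), L = runif(1, 200, 5000))
}

# a toy single-chromosome fragment table with given lengths
toy_fragments <- function(lengths, chrom = "chr1") {
  end <- cumsum(lengths)
  start <- end - lengths
  data.frame(chrom = rep(chrom, length(lengths)), start = start, end = end,
             id = seq_along(lengths), length = lengths,
             end_flank = seq_along(lengths) %in% c(1L, length(lengths)))
}

toy_profile <- function(values, ids = seq_along(values), masked = NULL) {
  if (is.null(masked)) masked <- rep(FALSE, length(values))
  data.frame(id = ids, value = values, masked = masked)
}

# a state call over given ids from integer states 0/1/2 (NA allowed)
toy_call <- function(states, ids = seq_along(states)) {
  lv <- state_labels()
  data.frame(id = ids,
             state = factor(ifelse(is.na(states), NA_character_,
                                   lv[states + 1L]), levels = lv))
}

# random state call for property tests; na_prob masks fragments
rand_call <- function(n, na_prob = 0.1) {
  s <- sample(0:2, n, replace = TRUE)
  s[runif(n) < na_prob] <- NA
  toy_call(s)
}
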