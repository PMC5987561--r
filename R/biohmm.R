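#' Parameters of the three-state heterogeneous HMM
#'
#' @param mu Emission means (log2 units), strictly ascending; state 0 =
#'   depleted, 1 = intermediate, 2 = enriched.
#' @param sigma Emission standard deviations (one per state).
#' @param pi Stationary/initial distribution over the three states.
#' @param p0 Self-transition probability at zero distance, in `[0, 1]`.
#' @param L Decay length in bases (> 0) over which transition probabilities
#'   relax to the stationary distribution.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(mu, sigma, pi, p0, L) {
  stopifnot(length(mu) == 3L, length(sigma) == 3L, length(pi) == 3L)
  if (any(diff(mu) <= 0))
    stop("mu must be strictly ascending (depleted < intermediate < enriched)",
         call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be probabilities summing to 1", call. = FALSE)
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]", call. = FALSE)
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 pi = as.numeric(pi), p0 = p0, L = L),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Heterogeneous 3-state HMM parameters\n")
  m <- rbind(mu = x$mu, sigma = x$sigma, pi = x$pi)
  colnames(m) <- state_labels()
  print(round(m, 4))
  cat(sprintf("p0 = %.4f, L = %.1f bp\n", x$p0, x$L))
  invisible(x)
}

#' Distance-dependent transition matrix
#'
#' The heterogeneous chain relaxes exponentially toward its stationary
#' distribution with the physical distance `d` between adjacent fragments:
#' `A(d)[j, j] = pi_j + (p0 - pi_j) * exp(-d / L)` and off-diagonal mass is
#' distributed proportionally to the stationary weights,
#' `A(d)[j, k] = (1 - A(d)[j, j]) * pi_k / (1 - pi_j)`. At `d = 0` the
#' self-transition probability is `p0`; as `d -> Inf` every row tends to
#' `pi`, so distant fragments are nearly independent while nearby fragments
#' share states.
#'
#' @param d Distance in bases (>= 0).
#' @param params An [hmm_params()] object.
#' @return A 3x3 row-stochastic matrix (rows = state at the previous
#'   fragment).
#' @examples
#' p <- hmm_params(c(-1.5, 0, 1.5), rep(0.5, 3), rep(1/3, 3), 0.9, 2000)
#' transition_matrix(0, p)
#' transition_matrix(1e9, p)   # rows approach pi
#' @export
transition_matrix <- function(d, params) {
  if (!is.finite(d) && !(is.infinite(d) && d > 0))
    stop("domain error: d must be a non-negative number", call. = FALSE)
  if (d < 0) stop("domain error: d must be >= 0", call. = FALSE)
  w <- exp(-d / params$L)
  pi <- params$pi
  A <- matrix(0, 3L, 3L, dimnames = list(state_labels(), state_labels()))
  for (j in 1:3) {
    A[j, j] <- pi[j] + (params$p0 - pi[j]) * w
    if (pi[j] < 1) A[j, -j] <- (1 - A[j, j]) * pi[-j] / (1 - pi[j])
  }
  A
}

# K x K x (n-1) array of log transition matrices for a distance vector,
# vectorised over distances
log_trans_array <- function(d, params) {
  n1 <- length(d)
  pi <- params$pi
  w <- exp(-d / params$L)
  arr <- array(0, dim = c(3L, 3L, n1))
  for (j in 1:3) {
    diag_j <- pi[j] + (params$p0 - pi[j]) * w
    arr[j, j, ] <- log(diag_j)
    for (k in setdiff(1:3, j))
      arr[j, k, ] <- log1p(-diag_j) + log(pi[k]) - log1p(-pi[j])
  }
  arr
}

# align a profile to the fragment table and split the unmasked fragments
# into per-chromosome chains with midpoint-to-midpoint distances
build_chains <- function(profile, fragments) {
  if (!setequal(profile$id, fragments$id))
    stop("profile and fragments are on different fragment universes",
         call. = FALSE)
  profile <- profile[match(fragments$id, profile$id), ]
  masked <- if ("masked" %in% names(profile)) profile$masked
            else rep(FALSE, nrow(profile))
  masked <- masked | is.na(profile$value)
  if (any(!masked & !is.finite(profile$value)))
    stop("input error: non-finite values in profile", call. = FALSE)
  keep <- which(!masked)
  chains <- lapply(split(keep, factor(fragments$chrom[keep],
                                      levels = unique(fragments$chrom))),
                   function(i) {
    if (length(i) == 0L) return(NULL)
    mid <- (fragments$start[i] + fragments$end[i]) / 2
    list(idx = i, id = fragments$id[i], value = profile$value[i],
         d = if (length(i) > 1L) diff(mid) else numeric(0))
  })
  chains <- Filter(Negate(is.null), chains)
  list(chains = chains, masked = masked, profile = profile,
       fragments = fragments)
}

log_emission <- function(value, params) {
  matrix(vapply(1:3, function(j) dnorm(value, params$mu[j], params$sigma[j],
                                       log = TRUE),
                numeric(length(value))),
         nrow = length(value), ncol = 3L)
}

# expected complete-data log-likelihood terms that involve (pi, p0, L):
# initial-state occupancies plus expected transition counts
q_transition <- function(pi, p0, L, gamma1, xi_flat, d_all) {
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8 || p0 < 0 || p0 > 1 || L <= 0)
    return(-Inf)
  q <- sum(gamma1 * log(pi))
  if (length(d_all) > 0L) {
    w <- exp(-d_all / L)
    for (j in 1:3) {
      diag_j <- pi[j] + (p0 - pi[j]) * w
      diag_j <- pmin(pmax(diag_j, 1e-300), 1)
      q <- q + sum(xi_flat[j, j, ] * log(diag_j))
      off <- log1p(-pmin(diag_j, 1 - 1e-300)) - log1p(-pi[j])
      for (k in setdiff(1:3, j))
        q <- q + sum(xi_flat[j, k, ] * (off + log(pi[k])))
    }
  }
  q
}

#' Fit the three-state heterogeneous HMM to a binding profile
#'
#' Segments a Dam-normalised log2 profile over unevenly spaced GATC fragments
#' into depleted, intermediate and enriched binding states. Emissions are
#' Gaussian per state; transitions depend on the midpoint-to-midpoint
#' distance between consecutive unmasked fragments through
#' [transition_matrix()], so the chain is heterogeneous: nearby fragments are
#' correlated, distant fragments nearly independent. Chromosomes are treated
#' as independent chains sharing one parameter set. Masked fragments are
#' skipped and the distance between their unmasked neighbours is used
#' (gap-aware), not imputed.
#'
#' Fitting is by Baum-Welch in log space. Emission means and sds have exact
#' M-steps (sds floored at `sqrt(var_floor)`); the transition parameters
#' `pi`, `p0` and `L` are updated by bounded numeric maximisation of the
#' expected complete-data log-likelihood, accepting a candidate only if it
#' improves it (generalised EM), so the log-likelihood trace is
#' non-decreasing. States are relabelled in ascending order of fitted mean
#' before return, so state identity never depends on initialisation.
#'
#' @param profile Profile data frame (`id`, `value`, optional `masked`), e.g.
#'   from [average_replicates()].
#' @param fragments Fragment table from [find_gatc_fragments()].
#' @param init Optional [hmm_params()] used as starting point. By default
#'   `mu` starts at the 10th/50th/90th percentiles of the profile, `sigma` at
#'   half the profile sd, `pi` uniform, `p0 = 0.9` and `L` at the median
#'   inter-fragment distance.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param var_floor Lower bound on emission variances (log2 units squared),
#'   preventing emission collapse.
#' @return An object of class `biohmm` with components `params`
#'   ([hmm_params()]), `state_call` (per-fragment decoded states, `NA` where
#'   masked), `posterior` (fragments x 3 matrix of state posteriors),
#'   `loglik_trace`, `converged`, `degenerate` (two fitted means closer than
#'   1e-3), and the aligned input data. Methods: `print`, `summary`, `coef`,
#'   `logLik`, [predict.biohmm()], [plot.biohmm()], [simulate.biohmm()],
#'   `residuals`, `fitted`.
#' @examples
#' cfg <- sim_config(seed = 7, n_chroms = 1, chrom_length = 5e4)
#' frag <- find_gatc_fragments(simulate_genome(cfg))
#' s <- simulate_states(frag, cfg)
#' fit <- biohmm(simulate_profile(frag, s, cfg), frag)
#' fit
#' @export
biohmm <- function(profile, fragments, init = NULL, tol = 1e-6,
                   max_iter = 500L, var_floor = 1e-3) {
  built <- build_chains(profile, fragments)
  chains <- built$chains
  v_all <- unlist(lapply(chains, `[[`, "value"))
  if (length(v_all) < 30L)
    stop("at least 30 unmasked fragments are required", call. = FALSE)
  d_all <- unlist(lapply(chains, `[[`, "d"))

  if (is.null(init)) {
    mu0 <- as.numeric(quantile(v_all, c(0.1, 0.5, 0.9), names = FALSE))
    if (any(diff(mu0) <= 0))              # flat profile: spread artificially
      mu0 <- mu0 + c(-1, 0, 1) * max(1e-3, sd(v_all), na.rm = TRUE)
    s0 <- max(sd(v_all) / 2, sqrt(var_floor))
    init <- hmm_params(mu0, rep(s0, 3), rep(1/3, 3), 0.9,
                       max(median(d_all), 1))
  }
  params <- init
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    e <- e_step(chains, params)
    trace <- c(trace, e$loglik)
    if (iter > 1L) {
      delta <- trace[iter] - trace[iter - 1L]
      if (abs(delta) / (abs(trace[iter - 1L]) + 1e-12) < tol) {
        converged <- TRUE
        break
      }
    }
    params <- m_step(e, v_all, d_all, params, var_floor)
  }

  # enforce ascending-mean labelling
  ord <- order(params$mu)
  relabel <- any(ord != 1:3)
  if (relabel) {
    params <- hmm_params(params$mu[ord],
                         params$sigma[ord],
                         params$pi[ord], params$p0, params$L)
    e <- e_step(chains, params)
  }
  gamma <- do.call(rbind, e$gamma)

  path <- viterbi_path(chains, params)
  n_frag <- nrow(built$fragments)
  state_int <- rep(NA_integer_, n_frag)
  post <- matrix(NA_real_, n_frag, 3L,
                 dimnames = list(built$fragments$id, state_labels()))
  idx <- unlist(lapply(chains, `[[`, "idx"))
  state_int[idx] <- path - 1L
  post[idx, ] <- gamma

  degenerate <- min(diff(sort(params$mu))) < 1e-3
  structure(list(
    params = params,
    state_call = data.frame(built$fragments[, c("chrom", "start", "end", "id")],
                            state = state_factor_na(state_int)),
    posterior = post,
    loglik_trace = trace,
    converged = converged,
    degenerate = degenerate,
    n_fragments = n_frag,
    n_unmasked = length(v_all),
    data = list(profile = built$profile, fragments = built$fragments),
    call = match.call()
  ), class = "biohmm")
}

state_factor_na <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- state_labels()[x[ok] + 1L]
  factor(out, levels = state_labels())
}

e_step <- function(chains, params) {
  gamma <- vector("list", length(chains))
  xi <- vector("list", length(chains))
  gamma1 <- numeric(3)
  loglik <- 0
  logpi <- log(params$pi)
  for (c_i in seq_along(chains)) {
    ch <- chains[[c_i]]
    ld <- log_emission(ch$value, params)
    la <- log_trans_array(ch$d, params)
    fb <- hmm_forward_backward_cpp(ld, as.numeric(la), logpi)
    gamma[[c_i]] <- fb$gamma
    xi[[c_i]] <- fb$xi
    gamma1 <- gamma1 + fb$gamma[1L, ]
    loglik <- loglik + fb$loglik
  }
  list(gamma = gamma, xi = xi, gamma1 = gamma1, loglik = loglik)
}

m_step <- function(e, v_all, d_all, params, var_floor) {
  gamma <- do.call(rbind, e$gamma)
  wsum <- colSums(gamma)
  mu <- colSums(gamma * v_all) / wsum
  sigma2 <- vapply(1:3, function(j)
    sum(gamma[, j] * (v_all - mu[j])^2) / wsum[j], numeric(1))
  sigma <- sqrt(pmax(sigma2, var_floor))

  # pool expected transition counts; all chains share the distance law
  xi_all <- e$xi[lengths(e$xi) > 0L]
  if (length(xi_all) > 0L) {
    xi_flat <- array(unlist(xi_all), dim = c(3L, 3L, length(d_all)))
  } else xi_flat <- array(0, dim = c(3L, 3L, 0L))

  pi <- params$pi
  p0 <- params$p0
  L <- params$L
  q_cur <- q_transition(pi, p0, L, e$gamma1, xi_flat, d_all)

  # occupancy-based candidate for pi, accepted only if it improves Q
  pi_cand <- wsum / sum(wsum)
  pi_cand <- pmax(pi_cand, 1e-8)
  pi_cand <- pi_cand / sum(pi_cand)
  q_cand <- q_transition(pi_cand, p0, L, e$gamma1, xi_flat, d_all)
  if (q_cand > q_cur) {
    pi <- pi_cand
    q_cur <- q_cand
  }

  if (length(d_all) > 0L) {
    op <- optimize(function(p) q_transition(pi, p, L, e$gamma1, xi_flat, d_all),
                   interval = c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-6)
    if (op$objective > q_cur) {
      p0 <- op$maximum
      q_cur <- op$objective
    }
    ol <- optimize(function(lg) q_transition(pi, p0, exp(lg), e$gamma1,
                                             xi_flat, d_all),
                   interval = c(0, log(100 * max(d_all, 1))),
                   maximum = TRUE, tol = 1e-6)
    if (ol$objective > q_cur) L <- exp(ol$maximum)
  }

  # joint relabeling by ascending mean is likelihood-invariant (emissions and
  # the stationary-weighted kernel permute together), so components can be
  # kept in ascending order at every iteration
  ord <- order(mu)
  mu <- enforce_separation(mu[ord])
  hmm_params(mu, sigma[ord], pi[ord], p0, L)
}

# hmm_params requires strictly ascending means; nudge exact ties apart by a
# negligible amount (the fit is flagged degenerate downstream)
enforce_separation <- function(mu) {
  for (j in 2:3)
    if (mu[j] <= mu[j - 1L]) mu[j] <- mu[j - 1L] + 1e-9
  mu
}

viterbi_path <- function(chains, params) {
  logpi <- log(params$pi)
  unlist(lapply(chains, function(ch) {
    ld <- log_emission(ch$value, params)
    la <- log_trans_array(ch$d, params)
    hmm_viterbi_cpp(ld, as.numeric(la), logpi)$path
  }))
}

#' Viterbi decoding of a profile under given HMM parameters
#'
#' Computes the single most probable state path under the heterogeneous
#' chain, per chromosome. Ties are broken toward the lower state index, i.e.
#' conservatively toward 'depleted'.
#'
#' @inheritParams biohmm
#' @param params An [hmm_params()] object.
#' @return A state-call data frame (`chrom`, `start`, `end`, `id`, `state`)
#'   with `state` a factor in depleted/intermediate/enriched and `NA` for
#'   masked fragments.
#' @export
viterbi_decode <- function(profile, fragments, params) {
  built <- build_chains(profile, fragments)
  path <- viterbi_path(built$chains, params)
  state_int <- rep(NA_integer_, nrow(built$fragments))
  state_int[unlist(lapply(built$chains, `[[`, "idx"))] <- path - 1L
  data.frame(built$fragments[, c("chrom", "start", "end", "id")],
             state = state_factor_na(state_int))
}

#' Log-likelihood of a profile under given HMM parameters
#'
#' Forward-algorithm log-likelihood of the unmasked profile values under the
#' heterogeneous chain, summed over per-chromosome chains.
#'
#' @inheritParams viterbi_decode
#' @return A single number.
#' @export
biohmm_loglik <- function(profile, fragments, params) {
  built <- build_chains(profile, fragments)
  e_step(built$chains, params)$loglik
}

#' Posterior state probabilities of a profile under given HMM parameters
#'
#' Forward-backward smoothing with the same heterogeneous transitions as
#' [viterbi_decode()]; each unmasked fragment's posterior sums to 1.
#'
#' @inheritParams viterbi_decode
#' @return Numeric matrix (fragments x 3, columns depleted / intermediate /
#'   enriched, rownames = fragment ids); rows are `NA` for masked fragments.
#' @export
posterior_decode <- function(profile, fragments, params) {
  built <- build_chains(profile, fragments)
  e <- e_step(built$chains, params)
  post <- matrix(NA_real_, nrow(built$fragments), 3L,
                 dimnames = list(built$fragments$id, state_labels()))
  post[unlist(lapply(built$chains, `[[`, "idx")), ] <- do.call(rbind, e$gamma)
  post
}
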