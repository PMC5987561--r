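test_that("the transition kernel interpolates between identity and the
           stationary distribution", {
  p <- hmm_params(c(-1.5, 0, 1.5), rep(0.5, 3), rep(1/3, 3), p0 = 1,
                  L = 2000)
  expect_equal(unname(transition_matrix(0, p)), diag(3))

  p2 <- hmm_params(c(-1.5, 0, 1.5), rep(0.5, 3), c(0.5, 0.3, 0.2),
                   p0 = 0.9, L = 2000)
  A_far <- transition_matrix(1e12, p2)
  for (j in 1:3) expect_equal(unname(A_far[j, ]), p2$pi, tolerance = 1e-12)

  # d = L, p0 = 0.9, uniform pi: diagonal = 1/3 + (0.9 - 1/3) e^{-1}
  p3 <- hmm_params(c(-1, 0, 1), rep(0.5, 3), rep(1/3, 3), p0 = 0.9, L = 500)
  A <- transition_matrix(500, p3)
  expect_equal(unname(diag(A)), rep(0.5417988, 3), tolerance = 1e-6)

  expect_error(transition_matrix(-1, p3), "domain error")
})

test_that("transition rows are stochastic for random distances and
           parameters", {
  set.seed(20)
  for (i in 1:50) {
    p <- rand_params()
    A <- transition_matrix(rexp(1, 1/1000), p)
    expect_equal(unname(rowSums(A)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(A >= 0))
  }
})

test_that("Viterbi, forward likelihood and posteriors match exhaustive
           path enumeration", {
  set.seed(21)
  for (n in c(1L, 2L, 5L, 8L, 10L)) {
    for (rep in 1:3) {
      p <- rand_params()
      lens <- sample(50:500, n, replace = TRUE)
      frag <- toy_fragments(lens)
      v <- rnorm(n, sample(p$mu, n, replace = TRUE), p$sigma[1])
      prof <- toy_profile(v)
      d <- diff((frag$start + frag$end) / 2)
      oracle <- oracle_enumerate(v, d, p)

      call <- viterbi_decode(prof, frag, p)
      path <- as.integer(call$state)
      expect_equal(path, unname(oracle$best_path))
      expect_equal(oracle_path_logprob(v, d, p, path), oracle$best_logprob,
                   tolerance = 1e-8)

      expect_equal(biohmm_loglik(prof, frag, p), oracle$loglik,
                   tolerance = 1e-8)

      post <- posterior_decode(prof, frag, p)
      expect_equal(unname(post), oracle$posterior, tolerance = 1e-8)
      expect_equal(unname(rowSums(post)), rep(1, n), tolerance = 1e-8)
    }
  }
})

test_that("a single fragment is decoded by the stationary-weighted emission
           density", {
  p <- hmm_params(c(-2, 0, 2), c(0.5, 0.5, 0.5), c(0.2, 0.5, 0.3), 0.9, 1000)
  frag <- toy_fragments(100L)
  for (v in c(-2.5, 0.1, 1.4)) {
    call <- viterbi_decode(toy_profile(v), frag, p)
    expected <- which.max(log(p$pi) + dnorm(v, p$mu, p$sigma, log = TRUE))
    expect_equal(as.integer(call$state), expected)
  }
})

test_that("identical chromosomes decode to identical paths", {
  set.seed(22)
  p <- rand_params()
  v <- rnorm(40, 0, 1.5)
  frag <- rbind(toy_fragments(rep(200L, 40), "chr1"),
                toy_fragments(rep(200L, 40), "chr2"))
  frag$id <- seq_len(80L)
  call <- viterbi_decode(toy_profile(c(v, v)), frag, p)
  expect_equal(as.integer(call$state[1:40]), as.integer(call$state[41:80]))
})

test_that("uniform stationary weights with equal means give uniform
           posteriors", {
  p <- hmm_params(c(0 - 1e-9, 0, 1e-9) * 1e6, rep(1, 3), rep(1/3, 3),
                  p0 = 1/3, L = 1000)
  # means differ only by 1e-3 in total; emissions effectively identical
  p$mu <- c(-1e-9, 0, 1e-9)
  post <- posterior_decode(toy_profile(rnorm(10)), toy_fragments(rep(100L, 10)),
                           p)
  expect_equal(unname(post), matrix(1/3, 10, 3), tolerance = 1e-6)
})

test_that("EM increases the likelihood monotonically and converges on
           simulated data", {
  cfg <- sim_config(seed = 31, n_chroms = 2, chrom_length = 6e4)
  frag <- find_gatc_fragments(simulate_genome(cfg))
  s <- simulate_states(frag, cfg)
  prof <- simulate_profile(frag, s, cfg)
  fit <- biohmm(prof, frag)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, nrow(frag)),
               tolerance = 1e-8)
  # states are labelled ascending in mean
  expect_true(all(diff(fit$params$mu) > 0))
})

test_that("a constant profile hits the variance floor and is flagged
           degenerate", {
  frag <- toy_fragments(rep(100L, 50))
  fit <- suppressWarnings(biohmm(toy_profile(rep(0.7, 50)), frag,
                                 max_iter = 50))
  expect_true(fit$degenerate)
  expect_true(all(fit$params$sigma >= sqrt(1e-3) - 1e-12))
})

test_that("the fitted labels do not depend on the initialisation", {
  cfg <- sim_config(seed = 33, n_chroms = 1, chrom_length = 1e5)
  frag <- find_gatc_fragments(simulate_genome(cfg))
  s <- simulate_states(frag, cfg)
  prof <- simulate_profile(frag, s, cfg)
  fit1 <- biohmm(prof, frag)
  init <- hmm_params(c(-4, 2, 3.5), c(1, 0.2, 2), c(0.1, 0.1, 0.8),
                     p0 = 0.5, L = 50)
  fit2 <- biohmm(prof, frag, init = init)
  expect_true(all(diff(fit2$params$mu) > 0))
  expect_equal(fit1$params$mu, fit2$params$mu, tolerance = 0.15)
  agree <- mean(fit1$state_call$state == fit2$state_call$state,
                na.rm = TRUE)
  expect_gt(agree, 0.95)
})

test_that("masked fragments are skipped gap-aware and never decoded", {
  set.seed(24)
  cfg <- sim_config(seed = 24, n_chroms = 1, chrom_length = 5e4)
  frag <- find_gatc_fragments(simulate_genome(cfg))
  s <- simulate_states(frag, cfg)
  prof <- simulate_profile(frag, s, cfg)
  prof$masked[seq(5, nrow(frag), by = 7)] <- TRUE
  prof$value[prof$masked] <- NA
  fit <- biohmm(prof, frag)
  expect_true(all(is.na(fit$state_call$state[prof$masked])))
  expect_true(all(!is.na(fit$state_call$state[!prof$masked])))
})

test_that("posterior argmax and Viterbi agree on nearly all fragments at
           high signal", {
  cfg <- sim_config(seed = 25, n_chroms = 1, chrom_length = 2e5)
  frag <- find_gatc_fragments(simulate_genome(cfg))
  s <- simulate_states(frag, cfg)
  prof <- simulate_profile(frag, s, cfg)
  fit <- biohmm(prof, frag)
  vit <- as.integer(fit$state_call$state)
  pmax_state <- max.col(fit$posterior, ties.method = "first")
  expect_gt(mean(vit == pmax_state), 0.9)
})

test_that("biohmm methods expose the fit coherently", {
  cfg <- sim_config(seed = 26, n_chroms = 1, chrom_length = 4e4)
  frag <- find_gatc_fragments(simulate_genome(cfg))
  s <- simulate_states(frag, cfg)
  fit <- biohmm(simulate_profile(frag, s, cfg), frag)

  co <- coef(fit)
  expect_named(co, c(paste0("mu.", state_labels()),
                     paste0("sigma.", state_labels()),
                     paste0("pi.", state_labels()), "p0", "L"))
  expect_equal(unname(co[["L"]]), fit$params$L)
  expect_s3_class(predict(fit), "data.frame")
  expect_equal(predict(fit), fit$state_call)
  expect_equal(dim(predict(fit, type = "posterior")), c(nrow(frag), 3L))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), tail(fit$loglik_trace, 1))
  expect_equal(attr(ll, "df"), 10L)
  r <- residuals(fit)
  f <- fitted(fit)
  expect_equal(unname(r + f), fit$data$profile$value)
  expect_output(print(fit), "Heterogeneous 3-state HMM")
  expect_output(print(summary(fit)), "posterior")

  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2L)
  expect_equal(nrow(sim[[1]]$profile), nrow(frag))
  sim2 <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(sim[[1]]$profile$value, sim2[[1]]$profile$value)

  # decoding new data under the fitted parameters
  prof2 <- simulate_profile(frag, s, sim_config(seed = 27, n_chroms = 1,
                                                chrom_length = 4e4))
  call2 <- predict(fit, profile = prof2)
  expect_equal(nrow(call2), nrow(frag))
})

test_that("too few fragments or non-finite values are refused", {
  frag <- toy_fragments(rep(100L, 10))
  expect_error(biohmm(toy_profile(rnorm(10)), frag), "at least 30")
  frag2 <- toy_fragments(rep(100L, 40))
  v <- rnorm(40); v[3] <- Inf
  expect_error(biohmm(toy_profile(v), frag2), "non-finite")
})
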