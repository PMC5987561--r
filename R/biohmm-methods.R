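#' @export
print.biohmm <- function(x, ...) {
  cat("Three-state heterogeneous HMM fit (DamID binding states)\n")
  cat(sprintf("  fragments: %d (%d unmasked), chromosomes: %d\n",
              x$n_fragments, x$n_unmasked,
              length(unique(x$state_call$chrom))))
  cat(sprintf("  log-likelihood: %.3f after %d EM iteration(s)%s%s\n",
              tail(x$loglik_trace, 1L), length(x$loglik_trace),
              if (x$converged) " (converged)" else " (not converged)",
              if (x$degenerate) " [degenerate]" else ""))
  print(x$params)
  tab <- table(x$state_call$state)
  cat("  state calls:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Summary of a fitted heterogeneous HMM
#'
#' @param object A [biohmm()] fit.
#' @param ... Unused.
#' @return A list of class `summary.biohmm` with the parameter table, state
#'   counts and proportions, mean posterior confidence of the decoded path,
#'   and convergence information.
#' @export
summary.biohmm <- function(object, ...) {
  st <- object$state_call$state
  tab <- table(st)
  dec <- !is.na(st)
  conf <- mean(object$posterior[cbind(which(dec),
                                      as.integer(st[dec]))])
  out <- list(params = object$params,
              state_counts = tab,
              state_prop = prop.table(tab),
              mean_posterior_confidence = conf,
              loglik = tail(object$loglik_trace, 1L),
              iterations = length(object$loglik_trace),
              converged = object$converged,
              degenerate = object$degenerate,
              n_fragments = object$n_fragments,
              n_unmasked = object$n_unmasked)
  class(out) <- "summary.biohmm"
  out
}

#' @export
print.summary.biohmm <- function(x, ...) {
  print(x$params)
  cat(sprintf("Fragments: %d (%d unmasked)\n", x$n_fragments, x$n_unmasked))
  m <- rbind(count = as.integer(x$state_counts),
             proportion = round(as.numeric(x$state_prop), 4))
  colnames(m) <- names(x$state_counts)
  print(m)
  cat(sprintf("Mean posterior probability of decoded state: %.4f\n",
              x$mean_posterior_confidence))
  cat(sprintf("Log-likelihood %.3f in %d iterations (%s)\n", x$loglik,
              x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.biohmm <- function(object, ...) {
  p <- object$params
  c(setNames(p$mu, paste0("mu.", state_labels())),
    setNames(p$sigma, paste0("sigma.", state_labels())),
    setNames(p$pi, paste0("pi.", state_labels())),
    p0 = p$p0, L = p$L)
}

#' @export
logLik.biohmm <- function(object, ...) {
  structure(tail(object$loglik_trace, 1L),
            df = 10L,  # 3 mu + 3 sigma + 2 free pi + p0 + L
            nobs = object$n_unmasked, class = "logLik")
}

#' Decode binding states from a fitted heterogeneous HMM
#'
#' With no new data, returns the decoding of the training profile; with
#' `profile`/`fragments` supplied, decodes the new profile under the fitted
#' parameters.
#'
#' @param object A [biohmm()] fit.
#' @param profile,fragments Optional new data (see [biohmm()]).
#' @param type `"states"` for the Viterbi state call, `"posterior"` for the
#'   forward-backward posterior matrix.
#' @param ... Unused.
#' @return A state-call data frame or a posterior matrix.
#' @export
predict.biohmm <- function(object, profile = NULL, fragments = NULL,
                           type = c("states", "posterior"), ...) {
  type <- match.arg(type)
  if (is.null(profile)) {
    if (type == "states") return(object$state_call)
    return(object$posterior)
  }
  if (is.null(fragments)) fragments <- object$data$fragments
  if (type == "states") viterbi_decode(profile, fragments, object$params)
  else posterior_decode(profile, fragments, object$params)
}

#' @export
fitted.biohmm <- function(object, ...) {
  st <- as.integer(object$state_call$state)
  out <- rep(NA_real_, object$n_fragments)
  ok <- !is.na(st)
  out[ok] <- object$params$mu[st[ok]]
  setNames(out, object$state_call$id)
}

#' @export
residuals.biohmm <- function(object, ...) {
  v <- object$data$profile$value
  v - fitted(object)
}

#' Plot a segmented binding profile
#'
#' Draws the profile values along one chromosome, coloured by decoded state,
#' with the fitted state means as horizontal guides.
#'
#' @param x A [biohmm()] fit.
#' @param chrom Chromosome to draw (default: the first).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.biohmm <- function(x, chrom = NULL, ...) {
  sc <- x$state_call
  if (is.null(chrom)) chrom <- sc$chrom[1L]
  i <- which(sc$chrom == chrom)
  v <- x$data$profile$value[i]
  mid <- (sc$start[i] + sc$end[i]) / 2
  col <- c(depleted = "#4575b4", intermediate = "grey50",
           enriched = "#d73027")[as.character(sc$state[i])]
  col[is.na(col)] <- "grey85"
  graphics::plot(mid, v, col = col, pch = 16, cex = 0.5,
                 xlab = sprintf("position on %s (bp)", chrom),
                 ylab = "log2 Dam-normalised intensity", ...)
  graphics::abline(h = x$params$mu, lty = 3, col = "grey40")
  invisible(x)
}

#' Simulate profiles from a fitted heterogeneous HMM
#'
#' Draws new hidden state paths from the fitted distance-dependent chain over
#' the training fragment layout and Gaussian emissions from the fitted state
#' means and sds. Useful for parametric-bootstrap checks.
#'
#' @param object A [biohmm()] fit.
#' @param nsim Number of simulated profiles.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of length `nsim`; each element has `states` (0/1/2 per
#'   unmasked fragment) and `profile` (a profile data frame on the training
#'   fragment universe).
#' @export
simulate.biohmm <- function(object, nsim = 1, seed = NULL, ...) {
  runner <- function() {
    frag <- object$data$fragments
    masked <- is.na(object$state_call$state)
    p <- object$params
    lapply(seq_len(nsim), function(s) {
      states <- rep(NA_integer_, nrow(frag))
      for (ch in unique(frag$chrom)) {
        i <- which(frag$chrom == ch & !masked)
        if (length(i) == 0L) next
        mid <- (frag$start[i] + frag$end[i]) / 2
        st <- integer(length(i))
        st[1L] <- sample.int(3L, 1L, prob = p$pi)
        if (length(i) > 1L)
          for (t in 2L:length(i)) {
            A <- transition_matrix(mid[t] - mid[t - 1L], p)
            st[t] <- sample.int(3L, 1L, prob = A[st[t - 1L], ])
          }
        states[i] <- st - 1L
      }
      ok <- !is.na(states)
      value <- rep(NA_real_, length(states))
      value[ok] <- rnorm(sum(ok), p$mu[states[ok] + 1L],
                         p$sigma[states[ok] + 1L])
      list(states = states,
           profile = new_profile(frag$id, value, !ok,
                                 provenance = list(source = "simulate.biohmm")))
    })
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}
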