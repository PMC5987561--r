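#' Configuration for the synthetic DamID-seq data generator
#'
#' Bundles every knob of the generator with validated defaults. The generator
#' emulates the statistical structure the downstream analysis assumes: uneven
#' GATC fragment lengths, a distance-dependent three-state hidden chain,
#' state-dependent log2(Dam-fusion/Dam) emissions, overdispersed counts, two
#' replicates per condition, and a differential-expression table with up- and
#' down-regulated genes.
#'
#' @param seed Integer seed; every generator operation is deterministic given
#'   this seed (each operation uses its own derived sub-seed, so generated
#'   pieces are reproducible individually and jointly).
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bases.
#' @param gatc_rate Expected GATC motifs per kb. The background sequence is
#'   generated free of spontaneous GATCs and motifs are planted as a Poisson
#'   process, so this is the total motif rate. The genome-wide GATC frequency
#'   of a uniform-composition genome is about 4/kb, the default.
#' @param state_means Emission means (log2 units) of the depleted,
#'   intermediate and enriched states; strictly ascending.
#' @param state_sd Emission standard deviation (log2 units) around the state
#'   mean, common to all states.
#' @param stationary Stationary distribution of the hidden chain
#'   (depleted, intermediate, enriched); must sum to 1. The default weights
#'   the depleted state most heavily, as for a Polycomb-type factor that
#'   occupies a minority of the genome.
#' @param decay_length Distance scale L (bases) of the transition kernel:
#'   fragments much closer than L share states, fragments much farther apart
#'   are nearly independent.
#' @param p0 Self-transition probability of the hidden chain at zero
#'   distance.
#' @param dam_mean_per_kb Expected Dam-only reads per kb of fragment length
#'   (library depth).
#' @param dispersion Negative-binomial size parameter of the counts; the
#'   Poisson limit is `dispersion = Inf`.
#' @param n_replicates Replicates per condition.
#' @param flip_prob Probability that a constant-state run of the reference
#'   condition is resampled to a different state in the test condition,
#'   creating blocky gain/loss regions with known truth.
#' @param n_genes Number of genes in the simulated DE table.
#' @param frac_up,frac_down Proportions of genes that are significantly up-
#'   resp. down-regulated (`frac_up + frac_down <= 1`).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_chroms = 1, chrom_length = 1e4)
#' cfg$gatc_rate
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e5,
                       gatc_rate = 4,
                       state_means = c(-1.5, 0, 1.5),
                       state_sd = 0.5,
                       stationary = c(0.55, 0.25, 0.20),
                       decay_length = 2000,
                       p0 = 0.9,
                       dam_mean_per_kb = 300,
                       dispersion = 20,
                       n_replicates = 2L,
                       flip_prob = 0.1,
                       n_genes = 200L,
                       frac_up = 0.15,
                       frac_down = 0.15) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, gatc_rate = gatc_rate,
              state_means = state_means, state_sd = state_sd,
              stationary = stationary, decay_length = decay_length, p0 = p0,
              dam_mean_per_kb = dam_mean_per_kb, dispersion = dispersion,
              n_replicates = as.integer(n_replicates), flip_prob = flip_prob,
              n_genes = as.integer(n_genes), frac_up = frac_up,
              frac_down = frac_down)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$state_means) == 3L, length(cfg$stationary) == 3L)
  if (cfg$n_chroms < 1L)
    stop("configuration error: n_chroms must be >= 1", call. = FALSE)
  if (!is.finite(cfg$chrom_length) || cfg$chrom_length <= 0)
    stop("configuration error: chrom_length must be positive", call. = FALSE)
  if (cfg$gatc_rate < 0)
    stop("configuration error: gatc_rate must be >= 0", call. = FALSE)
  if (any(diff(cfg$state_means) <= 0))
    stop("configuration error: state_means must be strictly ascending",
         call. = FALSE)
  if (cfg$state_sd <= 0)
    stop("configuration error: state_sd must be > 0", call. = FALSE)
  if (any(cfg$stationary < 0) || abs(sum(cfg$stationary) - 1) > 1e-9)
    stop("configuration error: stationary must be probabilities summing to 1",
         call. = FALSE)
  if (cfg$decay_length <= 0)
    stop("configuration error: decay_length must be > 0", call. = FALSE)
  if (cfg$p0 < 0 || cfg$p0 > 1)
    stop("configuration error: p0 must lie in [0, 1]", call. = FALSE)
  if (cfg$dam_mean_per_kb <= 0)
    stop("configuration error: dam_mean_per_kb must be > 0", call. = FALSE)
  if (cfg$dispersion <= 0)
    stop("configuration error: dispersion must be > 0", call. = FALSE)
  if (cfg$n_replicates < 1L)
    stop("configuration error: n_replicates must be >= 1", call. = FALSE)
  if (cfg$flip_prob < 0 || cfg$flip_prob > 1)
    stop("configuration error: flip_prob must lie in [0, 1]", call. = FALSE)
  if (cfg$frac_up < 0 || cfg$frac_down < 0 ||
      cfg$frac_up + cfg$frac_down > 1)
    stop("configuration error: frac_up + frac_down must not exceed 1",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic DamID-seq configuration\n")
  cat(sprintf("  genome: %d chromosome(s) x %g bases, GATC rate %g/kb\n",
              x$n_chroms, x$chrom_length, x$gatc_rate))
  cat(sprintf("  states: means (%s), sd %g, stationary (%s)\n",
              paste(x$state_means, collapse = ", "), x$state_sd,
              paste(x$stationary, collapse = ", ")))
  cat(sprintf("  chain:  p0 %g, decay length %g bp\n", x$p0, x$decay_length))
  cat(sprintf("  counts: %g Dam reads/kb, NB dispersion %g, %d replicate(s)\n",
              x$dam_mean_per_kb, x$dispersion, x$n_replicates))
  cat(sprintf("  genes:  %d (up %g, down %g), seed %d\n",
              x$n_genes, x$frac_up, x$frac_down, x$seed))
  invisible(x)
}
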