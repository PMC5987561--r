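#' Simulate a genome with GATC motifs planted at a known rate
#'
#' Generates one random A/C/G/T sequence per chromosome. The background is
#' made free of spontaneous GATC motifs (any that arise by chance are
#' disrupted), then motifs are planted as a Poisson process at `gatc_rate`
#' motifs per kb, so the realised motif count per chromosome is
#' Poisson-distributed with mean `gatc_rate * chrom_length / 1000` and
#' `gatc_rate` is the total motif rate of the emitted sequence.
#'
#' @param cfg A [sim_config()].
#' @return A [Biostrings::DNAStringSet] named `chr1`, `chr2`, ...
#' @examples
#' g <- simulate_genome(sim_config(seed = 1, n_chroms = 1, chrom_length = 1e4))
#' Biostrings::vcountPattern("GATC", g)
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  len <- as.integer(cfg$chrom_length)
  if (len <= 0)
    stop("configuration error: non-positive chromosome length", call. = FALSE)
  seqs <- with_seed(sub_seed(cfg$seed, 0), {
    lapply(seq_len(cfg$n_chroms), function(i) {
      b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # disrupt spontaneous GATCs so gatc_rate is the total motif rate
      repeat {
        hit <- find_motif_positions(b)
        if (length(hit) == 0L) break
        b[hit + 2L] <- sample(c("A", "C", "G"), length(hit), replace = TRUE)
      }
      n_mot <- rpois(1L, cfg$gatc_rate * len / 1000)
      if (n_mot > 0L && len >= 4L) {
        pos <- sample.int(len - 3L, n_mot, replace = TRUE)
        for (p in pos) b[p:(p + 3L)] <- c("G", "A", "T", "C")
      }
      paste(b, collapse = "")
    })
  })
  names(seqs) <- paste0("chr", seq_len(cfg$n_chroms))
  Biostrings::DNAStringSet(unlist(seqs))
}

# 1-based start positions of GATC in a character vector of single bases;
# GATC cannot overlap itself so a vectorised shift-scan is exact
find_motif_positions <- function(b) {
  n <- length(b)
  if (n < 4L) return(integer(0))
  idx <- seq_len(n - 3L)
  idx[b[idx] == "G" & b[idx + 1L] == "A" & b[idx + 2L] == "T" &
        b[idx + 3L] == "C"]
}

#' Simulate hidden binding states along a fragment map
#'
#' Realises the same distance-dependent three-state chain the heterogeneous
#' HMM assumes: the first fragment of each chromosome is drawn from the
#' stationary distribution and each subsequent fragment from
#' [transition_matrix()] evaluated at the midpoint-to-midpoint distance to its
#' predecessor.
#'
#' @param fragments Fragment table from [find_gatc_fragments()], sorted by
#'   (chrom, start).
#' @param cfg A [sim_config()].
#' @return Integer vector of true states (0 = depleted, 1 = intermediate,
#'   2 = enriched), aligned to `fragments`.
#' @export
simulate_states <- function(fragments, cfg) {
  validate_sim_config(cfg)
  check_fragments_sorted(fragments)
  params <- hmm_params(mu = cfg$state_means, sigma = rep(cfg$state_sd, 3),
                       pi = cfg$stationary, p0 = cfg$p0,
                       L = cfg$decay_length)
  with_seed(sub_seed(cfg$seed, 1), {
    states <- integer(nrow(fragments))
    for (ch in unique(fragments$chrom)) {
      i <- which(fragments$chrom == ch)
      mid <- (fragments$start[i] + fragments$end[i]) / 2
      s <- integer(length(i))
      s[1L] <- sample.int(3L, 1L, prob = cfg$stationary)
      if (length(i) > 1L) {
        for (t in 2L:length(i)) {
          A <- transition_matrix(mid[t] - mid[t - 1L], params)
          s[t] <- sample.int(3L, 1L, prob = A[s[t - 1L], ])
        }
      }
      states[i] <- s - 1L
    }
    states
  })
}

check_fragments_sorted <- function(fragments) {
  ord <- order(match(fragments$chrom, unique(fragments$chrom)),
               fragments$start)
  if (!identical(ord, seq_len(nrow(fragments))))
    stop("ordering error: fragments must be sorted by (chrom, start)",
         call. = FALSE)
  invisible(fragments)
}

#' Simulate the Gaussian emission layer of a binding profile
#'
#' Draws a per-fragment log2 binding intensity from the state-dependent
#' emission model, `N(state_means[s], state_sd)`. This is the latent
#' Dam-normalised profile that the count layer ([simulate_counts()]) is built
#' on top of, and the natural input for parameter-recovery experiments.
#'
#' @inheritParams simulate_states
#' @param states Integer vector of true states (0/1/2) from
#'   [simulate_states()].
#' @return A profile data frame (`id`, `value`, `masked`) as produced by
#'   [average_replicates()], with nothing masked.
#' @export
simulate_profile <- function(fragments, states, cfg) {
  validate_sim_config(cfg)
  stopifnot(length(states) == nrow(fragments))
  value <- with_seed(sub_seed(cfg$seed, 2),
                     rnorm(length(states), cfg$state_means[states + 1L],
                           cfg$state_sd))
  new_profile(fragments$id, value, rep(FALSE, length(value)),
              provenance = list(source = "simulate_profile"))
}

#' Simulate Dam and Dam-fusion read counts per fragment
#'
#' Counts are negative binomial (size = `dispersion`; Poisson is the
#' `dispersion -> Inf` limit). The Dam-only mean is
#' `dam_mean_per_kb * length / 1000`; the Dam-fusion (Pc) mean is the Dam mean
#' multiplied by `2^state_means[state]`. Replicates are i.i.d.
#'
#' @inheritParams simulate_profile
#' @param condition Label stored in the output tables (used to derive the
#'   replicate sub-seeds, so different conditions get independent counts).
#' @return A list with elements `dam` and `pc`, each a list (one element per
#'   replicate) of fragment-count tables (`id`, `count`) carrying `sample` and
#'   `replicate` attributes.
#' @export
simulate_counts <- function(fragments, states, cfg, condition = "A") {
  validate_sim_config(cfg)
  stopifnot(length(states) == nrow(fragments))
  n <- nrow(fragments)
  cond_off <- 1000L * (utf8ToInt(substr(paste0(condition, "A"), 1L, 1L)) %% 64L)
  dam_mu <- cfg$dam_mean_per_kb * fragments$length / 1000
  pc_mu <- dam_mu * 2^cfg$state_means[states + 1L]
  draw <- function(mu, seed) {
    if (n == 0L) return(integer(0))
    with_seed(seed, {
      if (is.infinite(cfg$dispersion)) rpois(n, mu)
      else rnbinom(n, mu = mu, size = cfg$dispersion)
    })
  }
  one_sample <- function(sample, mu, off) {
    lapply(seq_len(cfg$n_replicates), function(r) {
      cnt <- fragment_counts(fragments$id,
                             draw(mu, sub_seed(cfg$seed, 10L + cond_off + off + r)),
                             sample = paste0(condition, "_", sample),
                             replicate = r)
      cnt
    })
  }
  list(dam = one_sample("dam", dam_mu, 0L),
       pc = one_sample("pc", pc_mu, 100L))
}

# constructor for a per-fragment count table
fragment_counts <- function(id, count, sample = NA_character_,
                            replicate = NA_integer_) {
  stopifnot(length(id) == length(count), all(count >= 0))
  out <- data.frame(id = id, count = as.integer(count))
  attr(out, "sample") <- sample
  attr(out, "replicate") <- replicate
  out
}

#' Simulate a differential-expression table with genes placed on the genome
#'
#' Allocates exactly `round(frac_up * n_genes)` significantly up-regulated and
#' `round(frac_down * n_genes)` significantly down-regulated genes
#' (adjusted p < 0.05); the remainder get adjusted p >= 0.05. TSSs are placed
#' uniformly, by default at least one window-width from chromosome ends so
#' that TSS windows are not clipped; strands are random.
#'
#' @param cfg A [sim_config()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param margin Minimum distance of a TSS from either chromosome end.
#' @return Data frame with columns `gene`, `chrom`, `tss`, `strand`,
#'   `log2fc`, `padj`.
#' @export
simulate_de_table <- function(cfg, chrom_sizes, margin = 4000) {
  validate_sim_config(cfg)
  if (cfg$frac_up + cfg$frac_down > 1)
    stop("configuration error: frac_up + frac_down must not exceed 1",
         call. = FALSE)
  n <- cfg$n_genes
  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  usable <- pmax(chrom_sizes - 2 * margin, 0)  # keeps chromosome names
  if (all(usable <= 0))
    stop("configuration error: chromosomes too short for TSS margin",
         call. = FALSE)
  with_seed(sub_seed(cfg$seed, 3), {
    chrom <- sample(names(chrom_sizes), n, replace = TRUE,
                    prob = usable / sum(usable))
    tss <- floor(margin + runif(n) * usable[chrom])
    strand <- sample(c("+", "-"), n, replace = TRUE)
    cls <- sample(rep(c("up", "down", "ns"), c(n_up, n_down, n - n_up - n_down)))
    log2fc <- numeric(n)
    padj <- numeric(n)
    log2fc[cls == "up"] <- runif(sum(cls == "up"), 0.5, 3)
    log2fc[cls == "down"] <- -runif(sum(cls == "down"), 0.5, 3)
    log2fc[cls == "ns"] <- runif(sum(cls == "ns"), -0.4, 0.4)
    padj[cls != "ns"] <- runif(sum(cls != "ns"), 0, 0.049)
    padj[cls == "ns"] <- runif(sum(cls == "ns"), 0.05, 1)
    data.frame(gene = sprintf("g%04d", seq_len(n)), chrom = chrom,
               tss = as.integer(tss), strand = strand,
               log2fc = log2fc, padj = padj, row.names = NULL)
  })
}

#' Simulate a complete two-condition DamID-seq study
#'
#' Orchestrates the generator: genome, fragment index, hidden states for a
#' reference condition (`wt`), a perturbed test condition (`mut`) in which
#' whole constant-state runs are resampled with probability `flip_prob`,
#' Dam/Dam-fusion counts for every replicate of both conditions, and a DE
#' table. The true states are returned so downstream recovery can be scored.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome`, `fragments`, `states` (list `wt`, `mut` of
#'   true 0/1/2 states), `counts` (list `wt`, `mut` as from
#'   [simulate_counts()]), `de` (DE table) and `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  genome <- simulate_genome(cfg)
  fragments <- find_gatc_fragments(genome)
  states_wt <- simulate_states(fragments, cfg)
  states_mut <- perturb_states(fragments, states_wt, cfg)
  list(genome = genome,
       fragments = fragments,
       states = list(wt = states_wt, mut = states_mut),
       counts = list(wt = simulate_counts(fragments, states_wt, cfg, "wt"),
                     mut = simulate_counts(fragments, states_mut, cfg, "mut")),
       de = simulate_de_table(cfg, setNames(Biostrings::width(genome),
                                            names(genome))),
       cfg = cfg)
}

# resample whole constant-state runs to a different state with prob flip_prob
perturb_states <- function(fragments, states, cfg) {
  with_seed(sub_seed(cfg$seed, 4), {
    out <- states
    key <- paste(fragments$chrom, states)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (runif(1) < cfg$flip_prob) {
        old <- states[starts[k]]
        out[starts[k]:ends[k]] <- sample(setdiff(0:2, old), 1L)
      }
    }
    out
  })
}
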