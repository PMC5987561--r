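test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(state_means = c(0, 0, 1)), "ascending")
  expect_error(sim_config(stationary = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(sim_config(chrom_length = 0), "chrom_length")
  expect_error(sim_config(state_sd = 0), "state_sd")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(frac_up = 0.7, frac_down = 0.5), "frac_up")
})

test_that("simulated genomes carry GATC motifs at the configured rate and are
           reproducible", {
  cfg <- sim_config(seed = 1, n_chroms = 1, chrom_length = 1e5, gatc_rate = 4)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  n_mot <- Biostrings::vcountPattern("GATC", g1)[1]
  # Poisson(400): allow 4.5 sd of sampling error around the expectation
  expect_gt(n_mot, 400 - 4.5 * sqrt(400))
  expect_lt(n_mot, 400 + 4.5 * sqrt(400))
})

test_that("a zero GATC rate yields exactly one fragment per chromosome", {
  cfg <- sim_config(seed = 42, n_chroms = 2, chrom_length = 2e4,
                    gatc_rate = 0)
  frag <- find_gatc_fragments(simulate_genome(cfg))
  expect_equal(nrow(frag), 2L)
  expect_equal(frag$length, c(2e4, 2e4))
})

test_that("hidden states follow the distance-dependent chain", {
  # persistent limit: with p0 = 1 and L far above any spacing the diagonal
  # of the kernel is ~1, so the whole chromosome shares one state
  cfg_inf <- sim_config(seed = 5, n_chroms = 2, chrom_length = 5e4,
                        decay_length = 1e12, p0 = 1)
  frag <- find_gatc_fragments(simulate_genome(cfg_inf))
  s <- simulate_states(frag, cfg_inf)
  for (ch in unique(frag$chrom))
    expect_length(unique(s[frag$chrom == ch]), 1L)

  # determinism
  expect_identical(s, simulate_states(frag, cfg_inf))

  # unsorted fragments are rejected
  expect_error(simulate_states(frag[rev(seq_len(nrow(frag))), ], cfg_inf),
               "ordering error")
})

test_that("with negligible decay length the state frequencies match the
           stationary distribution", {
  cfg <- sim_config(seed = 11, n_chroms = 1, chrom_length = 2.6e6,
                    decay_length = 1e-6)
  frag <- find_gatc_fragments(simulate_genome(cfg))
  expect_gte(nrow(frag), 1e4)
  s <- simulate_states(frag, cfg)
  tab <- table(factor(s, levels = 0:2))
  p <- suppressWarnings(stats::chisq.test(tab, p = cfg$stationary))$p.value
  expect_gt(p, 0.01)
})

test_that("count emissions reproduce the state-dependent log2 ratio", {
  cfg <- sim_config(seed = 2)
  frag <- toy_fragments(rep(250L, 6000L))
  states <- rep(2L, 6000L)   # all enriched
  cnt <- simulate_counts(frag, states, cfg)
  lr <- log2((cnt$pc[[1]]$count + 1) / (cnt$dam[[1]]$count + 1))
  expect_lt(abs(mean(lr) - 1.5), 0.1)

  # determinism
  cnt2 <- simulate_counts(frag, states, cfg)
  expect_identical(cnt$dam[[1]]$count, cnt2$dam[[1]]$count)

  # replicates are independent draws
  expect_false(identical(cnt$dam[[1]]$count, cnt$dam[[2]]$count))
})

test_that("infinite dispersion gives Poisson counts (variance equals mean)", {
  cfg <- sim_config(seed = 9, dispersion = Inf)
  frag <- toy_fragments(rep(500L, 5000L))
  cnt <- simulate_counts(frag, rep(1L, 5000L), cfg)
  x <- cnt$dam[[1]]$count
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
})

test_that("empty fragment lists give empty count tables", {
  cfg <- sim_config(seed = 1)
  frag <- toy_fragments(integer(0))
  cnt <- simulate_counts(frag, integer(0), cfg)
  expect_equal(nrow(cnt$dam[[1]]), 0L)
  expect_equal(nrow(cnt$pc[[1]]), 0L)
})

test_that("the DE table allocates significant genes exactly and
           deterministically", {
  cfg <- sim_config(seed = 3, n_genes = 100, frac_up = 0.1, frac_down = 0.2)
  sizes <- c(chr1 = 1e5, chr2 = 1e5)
  de <- simulate_de_table(cfg, sizes)
  expect_equal(sum(de$log2fc > 0 & de$padj < 0.05), 10L)
  expect_equal(sum(de$log2fc < 0 & de$padj < 0.05), 20L)
  expect_true(all(de$padj[abs(de$log2fc) < 0.5] >= 0.05))
  expect_identical(de, simulate_de_table(cfg, sizes))
  # TSS placement respects the margin
  expect_true(all(de$tss >= 4000 & de$tss < 1e5 - 4000))

  none <- simulate_de_table(sim_config(seed = 3, n_genes = 50, frac_up = 0,
                                       frac_down = 0), sizes)
  expect_equal(sum(none$padj < 0.05), 0L)
})

test_that("the emission-profile layer is Gaussian around the state means", {
  cfg <- sim_config(seed = 8)
  frag <- toy_fragments(rep(200L, 4000L))
  states <- rep(0:2, length.out = 4000L)
  p <- simulate_profile(frag, states, cfg)
  for (k in 0:2)
    expect_lt(abs(mean(p$value[states == k]) - cfg$state_means[k + 1]), 0.05)
  expect_lt(abs(sd(p$value[states == 1]) - cfg$state_sd), 0.05)
})

test_that("a simulated two-condition dataset is internally consistent", {
  cfg <- sim_config(seed = 13, n_chroms = 1, chrom_length = 4e4, n_genes = 20)
  d <- simulate_dataset(cfg)
  expect_identical(names(d$counts), c("wt", "mut"))
  expect_length(d$states$wt, nrow(d$fragments))
  expect_length(d$counts$wt$dam, cfg$n_replicates)
  # the perturbation changes some but not all states
  expect_true(any(d$states$wt != d$states$mut))
  expect_true(mean(d$states$wt != d$states$mut) < 0.5)
  # conditions get independent count draws
  expect_false(identical(d$counts$wt$dam[[1]]$count,
                         d$counts$mut$dam[[1]]$count))
})
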