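test_that("TSS windows extend 2.5 kb upstream and 1.5 kb downstream,
           strand-aware and clipped", {
  sizes <- c(chr1 = 50000)
  w_plus <- build_tss_windows(
    data.frame(gene = "g1", chrom = "chr1", tss = 10000, strand = "+"),
    sizes)
  expect_equal(c(w_plus$start, w_plus$end), c(7500, 11500))

  w_minus <- build_tss_windows(
    data.frame(gene = "g1", chrom = "chr1", tss = 10000, strand = "-"),
    sizes)
  expect_equal(c(w_minus$start, w_minus$end), c(8500, 12500))

  w_clip <- build_tss_windows(
    data.frame(gene = "g1", chrom = "chr1", tss = 1000, strand = "+"),
    sizes)
  expect_equal(c(w_clip$start, w_clip$end), c(0, 2500))

  expect_error(build_tss_windows(
    data.frame(gene = "g1", chrom = "chr1", tss = 1000, strand = "."),
    sizes), "unknown strand")

  # the downstream bound is a parameter
  w_alt <- build_tss_windows(
    data.frame(gene = "g1", chrom = "chr1", tss = 10000, strand = "+"),
    sizes, downstream = 1000)
  expect_equal(w_alt$end, 11000)
})

test_that("reflecting the genome maps plus-strand windows onto minus-strand
           windows", {
  S <- 80000
  set.seed(50)
  tss <- sample(10000:70000, 20)
  w_plus <- build_tss_windows(
    data.frame(gene = paste0("g", 1:20), chrom = "c", tss = tss,
               strand = "+"), c(c = S))
  w_ref <- build_tss_windows(
    data.frame(gene = paste0("g", 1:20), chrom = "c", tss = S - tss,
               strand = "-"), c(c = S))
  expect_equal(w_ref$start, S - w_plus$end)
  expect_equal(w_ref$end, S - w_plus$start)
})

test_that("taGATCf mapping needs only a single base of overlap", {
  win <- data.frame(gene = "g1", chrom = "chr1", start = 7500, end = 11500,
                    strand = "+", tss = 10000)
  frag <- toy_fragments(c(7400L, 200L, 3900L, 500L))  # [0,7400),[7400,7600),...
  assoc <- map_tagatcf(win, frag)
  expect_true(all(c(2L, 3L) %in% assoc$id))   # 100 bp and full overlap
  expect_false(1L %in% assoc$id)              # abuts at 7400/7500? no: [0,7400) vs [7500,...) disjoint
  expect_false(4L %in% assoc$id)              # [11500,12000) abuts half-open

  # a fragment spanning two genes' windows serves both
  win2 <- rbind(win, data.frame(gene = "g2", chrom = "chr1", start = 11000,
                                end = 15000, strand = "+", tss = 13500))
  frag2 <- toy_fragments(c(10900L, 300L, 4000L))  # [10900,11200) spans both
  assoc2 <- map_tagatcf(win2, frag2)
  expect_equal(sort(assoc2$gene[assoc2$id == 2L]), c("g1", "g2"))

  # genes without fragments get no rows
  assoc3 <- map_tagatcf(win, toy_fragments(integer(0)))
  expect_equal(nrow(assoc3), 0L)
})

test_that("region classification follows the gain/loss/mixed rules", {
  expect_equal(classify_region(c("gain", "no_change", "no_change")), "gain")
  expect_equal(classify_region(c("loss", "no_change")), "loss")
  expect_equal(classify_region(c("gain", "loss")), "mixed")
  expect_equal(classify_region("no_change"), "no_change")
  expect_equal(classify_region(character(0)), "no_data")
})

test_that("classification equals brute-force enumeration over all label
           multisets up to size 6", {
  labels <- c("gain", "loss", "no_change")
  for (size in 1:6) {
    combos <- expand.grid(rep(list(labels), size), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      ls <- unlist(combos[i, ], use.names = FALSE)
      present <- setdiff(unique(ls), "no_change")
      expected <- if (length(present) == 2L) "mixed"
                  else if (length(present) == 1L) present
                  else "no_change"
      expect_equal(classify_region(ls), expected)
    }
  }
})

test_that("group assignment implements the direction-by-class table", {
  expected <- rbind(
    c("gain", "up", "I"), c("gain", "down", "II"),
    c("loss", "up", "III"), c("loss", "down", "IV"),
    c("mixed", "down", "m1"), c("mixed", "up", "m2"),
    c("no_change", "up", "none"), c("no_change", "down", "none"),
    c("no_data", "up", "none"), c("no_data", "down", "none"))
  for (i in seq_len(nrow(expected)))
    expect_equal(assign_group(expected[i, 1], expected[i, 2]),
                 expected[i, 3])
  expect_error(assign_group("gain", "sideways"))
})

test_that("every retained DE gene lands in exactly one group", {
  set.seed(51)
  cfg <- sim_config(seed = 51, n_chroms = 2, chrom_length = 8e4,
                    n_genes = 60)
  d <- simulate_dataset(cfg)
  sizes <- setNames(Biostrings::width(d$genome), names(d$genome))
  trans <- compare_states(toy_call(d$states$wt, d$fragments$id),
                          toy_call(d$states$mut, d$fragments$id))
  res <- assign_groups(d$de, d$fragments, trans, sizes)
  expect_equal(nrow(res), sum(d$de$padj < 0.05))
  expect_false(any(duplicated(res$gene)))
  expect_true(all(res$group %in% c("I", "II", "III", "IV", "m1", "m2",
                                   "none")))
  # the group is reproducible from the row's own class and direction
  expect_equal(res$group,
               unname(mapply(assign_group, res$region_class, res$direction)))
  # direction matches the DE table
  de_keep <- d$de[d$de$padj < 0.05, ]
  expect_equal(res$direction, ifelse(de_keep$log2fc > 0, "up", "down"))
})

test_that("genes with no significant DE are dropped and an empty DE table
           yields no groups", {
  frag <- toy_fragments(rep(1000L, 20))
  trans <- compare_states(toy_call(rep(1L, 20)), toy_call(rep(1L, 20)))
  de <- data.frame(gene = "g1", chrom = "chr1", tss = 5000, strand = "+",
                   log2fc = 2, padj = 0.5)
  res <- assign_groups(de, frag, trans, c(chr1 = 20000))
  expect_equal(nrow(res), 0L)
})
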