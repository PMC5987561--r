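#' Build TSS regulatory windows
#'
#' The presumptive regulatory region of a gene spans 2.5 kb upstream to
#' 1.5 kb downstream of its TSS: `[TSS - upstream, TSS + downstream)` on the
#' plus strand, strand-reflected (`[TSS - downstream, TSS + upstream)`) on
#' the minus strand, clipped to chromosome bounds.
#'
#' @param genes Data frame with columns `gene`, `chrom`, `tss`, `strand`
#'   (`+`/`-`). One row per TSS; genes with several TSSs get one window each.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param upstream,downstream Window extent in bases (defaults 2500/1500).
#' @return Data frame (`gene`, `chrom`, `start`, `end`, `strand`, `tss`).
#' @examples
#' build_tss_windows(
#'   data.frame(gene = "g1", chrom = "chr1", tss = 10000, strand = "+"),
#'   c(chr1 = 50000))
#' @export
build_tss_windows <- function(genes, chrom_sizes, upstream = 2500,
                              downstream = 1500) {
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad) > 0L)
    stop(sprintf("record error: unknown strand '%s' for gene %s",
                 genes$strand[bad[1L]], genes$gene[bad[1L]]), call. = FALSE)
  missing_chr <- setdiff(genes$chrom, names(chrom_sizes))
  if (length(missing_chr) > 0L)
    stop(sprintf("record error: unknown chromosome '%s'", missing_chr[1L]),
         call. = FALSE)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  size <- chrom_sizes[genes$chrom]
  data.frame(gene = genes$gene, chrom = genes$chrom,
             start = pmax(0, start), end = pmin(size, end),
             strand = genes$strand, tss = genes$tss, row.names = NULL)
}

#' Map transcription-associated GATC fragments (taGATCf) to TSS windows
#'
#' A fragment is associated with a regulatory region iff their intervals
#' overlap by at least one base -- no minimum-overlap requirement. A fragment
#' may serve several genes; genes whose window overlaps no fragment simply
#' get no rows.
#'
#' @param windows Regulatory windows from [build_tss_windows()].
#' @param fragments Fragment table from [find_gatc_fragments()].
#' @return Data frame (`gene`, `id`) of gene-fragment associations.
#' @export
map_tagatcf <- function(windows, fragments) {
  if (nrow(windows) == 0L || nrow(fragments) == 0L)
    return(data.frame(gene = character(0), id = integer(0)))
  gr_win <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end))
  gr_frag <- GenomicRanges::GRanges(
    fragments$chrom, IRanges::IRanges(fragments$start + 1L, fragments$end))
  hits <- GenomicRanges::findOverlaps(gr_win, gr_frag, minoverlap = 1L)
  out <- data.frame(gene = windows$gene[S4Vectors::queryHits(hits)],
                    id = fragments$id[S4Vectors::subjectHits(hits)])
  unique(out)  # a gene with several TSSs keeps each fragment once
}

#' Classify a regulatory region from its taGATCf transition labels
#'
#' A region is `gain` iff at least one associated fragment gained binding and
#' none lost it; `loss` iff at least one lost and none gained; `mixed` iff
#' both gains and losses occur; `no_change` otherwise. An empty label set
#' yields `no_data` (excluded downstream).
#'
#' @param labels Character or factor vector of transition labels
#'   (gain/loss/no_change) of one gene's taGATCf.
#' @return One of `"gain"`, `"loss"`, `"mixed"`, `"no_change"`, `"no_data"`.
#' @export
classify_region <- function(labels) {
  labels <- as.character(labels)
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) return("no_data")
  has_gain <- any(labels == "gain")
  has_loss <- any(labels == "loss")
  if (has_gain && has_loss) "mixed"
  else if (has_gain) "gain"
  else if (has_loss) "loss"
  else "no_change"
}

#' Assign a gene to a Polycomb-target group
#'
#' Joint classification by RNA direction and regulatory-region transition:
#' (up, gain) = I; (down, gain) = II; (up, loss) = III; (down, loss) = IV;
#' (down, mixed) = m1; (up, mixed) = m2; any region with `no_change` (or no
#' data) maps to `none`.
#'
#' @param region_class Region class from [classify_region()].
#' @param direction `"up"` or `"down"` (DE direction of the gene).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"m1"`, `"m2"`, `"none"`.
#' @export
assign_group <- function(region_class, direction) {
  stopifnot(direction %in% c("up", "down"))
  switch(region_class,
         gain = if (direction == "up") "I" else "II",
         loss = if (direction == "up") "III" else "IV",
         mixed = if (direction == "up") "m2" else "m1",
         "none")
}

#' Integrate transition calls with differential expression into groups
#'
#' Full driver for the regulatory integration: filters the DE table to
#' significant genes (adjusted p < `padj_cutoff`), builds TSS windows, maps
#' taGATCf, classifies each gene's region from its fragments' transition
#' labels (a gene with several TSSs is classified from the union of their
#' fragments) and assigns groups I-IV/m1/m2.
#'
#' @param de DE table with columns `gene`, `chrom`, `tss`, `strand`,
#'   `log2fc`, `padj`.
#' @param fragments Fragment table.
#' @param transitions Output of [compare_states()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param upstream,downstream Window extent (see [build_tss_windows()]).
#' @param padj_cutoff Significance cutoff on adjusted p (default 0.05).
#' @return Data frame (one row per retained gene): `gene`, `direction`,
#'   `region_class`, `group`, `n_tagatcf`, `tagatcf_ids`
#'   (comma-separated fragment ids).
#' @export
assign_groups <- function(de, fragments, transitions, chrom_sizes,
                          upstream = 2500, downstream = 1500,
                          padj_cutoff = 0.05) {
  keep <- de$padj < padj_cutoff
  de <- de[keep, , drop = FALSE]
  if (nrow(de) == 0L)
    return(data.frame(gene = character(0), direction = character(0),
                      region_class = character(0), group = character(0),
                      n_tagatcf = integer(0), tagatcf_ids = character(0)))
  windows <- build_tss_windows(de, chrom_sizes, upstream, downstream)
  assoc <- map_tagatcf(windows, fragments)
  lab <- transitions$label[match(assoc$id, transitions$id)]
  lab_by_gene <- split(lab, factor(assoc$gene, levels = unique(de$gene)))
  ids_by_gene <- split(assoc$id, factor(assoc$gene, levels = unique(de$gene)))
  direction <- ifelse(de$log2fc > 0, "up", "down")
  region_class <- vapply(de$gene, function(g)
    classify_region(lab_by_gene[[g]]), character(1))
  group <- mapply(assign_group, region_class, direction)
  data.frame(gene = de$gene, direction = direction,
             region_class = region_class, group = group,
             n_tagatcf = vapply(de$gene, function(g) {
               ids <- ids_by_gene[[g]]
               length(unique(ids[!is.na(lab_by_gene[[g]])]))
             }, integer(1)),
             tagatcf_ids = vapply(de$gene, function(g)
               paste(sort(unique(ids_by_gene[[g]])), collapse = ","),
               character(1)),
             row.names = NULL)
}
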