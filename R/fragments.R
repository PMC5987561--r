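#' Build the GATC fragment index of a genome
#'
#' Locates every GATC motif and places a cut coordinate at `motif_start + 2`,
#' the blunt GA^TC cut of DpnI. Fragments are the consecutive intervals
#' between cuts, including the two chromosome-end flanks, so fragments on a
#' chromosome are disjoint, adjacent and cover `[0, chrom_length)`.
#' Coordinates are 0-based half-open; ids are assigned in (chrom, start)
#' order, chromosomes in their input order. `N` bases never match the motif.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector of
#'   sequences).
#' @return Data frame with columns `chrom`, `start`, `end`, `id`, `length`
#'   and `end_flank` (`TRUE` for the two flanks of each chromosome, which are
#'   not bounded by cuts on both sides).
#' @examples
#' find_gatc_fragments(c(chrA = "AAGATCAA"))
#' @export
find_gatc_fragments <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must carry unique names", call. = FALSE)
  res <- lapply(seq_along(genome), function(i) {
    len <- Biostrings::width(genome)[i]
    if (len == 0L) {
      warning(sprintf("empty sequence for chromosome '%s'; no fragments",
                      names(genome)[i]), call. = FALSE)
      return(NULL)
    }
    m <- Biostrings::matchPattern("GATC", genome[[i]], fixed = TRUE)
    cuts <- IRanges::start(m) + 1L            # 0-based motif start + 2
    cuts <- cuts[cuts > 0L & cuts < len]
    bounds <- c(0L, cuts, len)
    k <- length(bounds) - 1L
    data.frame(chrom = names(genome)[i],
               start = bounds[-length(bounds)],
               end = bounds[-1L],
               end_flank = seq_len(k) %in% c(1L, k))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = integer(0), length = integer(0),
                      end_flank = logical(0)))
  out$id <- seq_len(nrow(out))
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "id", "length", "end_flank")]
}

#' Assign reads to GATC fragments under strict containment
#'
#' A read increments a fragment's count iff the read interval is fully
#' contained in that fragment (the strict overlap-resolution mode). Reads
#' spanning a cut site, or falling on a chromosome absent from the fragment
#' index, are discarded and tallied.
#'
#' @param reads Data frame of read intervals with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param fragments Fragment table from [find_gatc_fragments()].
#' @return A fragment-count table (`id`, `count`, every fragment present
#'   exactly once) with attribute `discarded` giving the number of reads not
#'   assigned. `sum(count) + discarded == nrow(reads)`.
#' @export
assign_reads_strict <- function(reads, fragments) {
  bad <- which(reads$start >= reads$end)
  if (length(bad) > 0L)
    stop(sprintf("malformed record at line %d: start >= end (%d >= %d)",
                 bad[1L], reads$start[bad[1L]], reads$end[bad[1L]]),
         call. = FALSE)
  counts <- integer(nrow(fragments))
  n_assigned <- 0L
  if (nrow(reads) > 0L && nrow(fragments) > 0L) {
    shared <- reads$chrom %in% fragments$chrom
    if (any(shared)) {
      rd <- reads[shared, , drop = FALSE]
      gr_reads <- GenomicRanges::GRanges(
        rd$chrom, IRanges::IRanges(rd$start + 1L, rd$end))
      gr_frag <- GenomicRanges::GRanges(
        fragments$chrom, IRanges::IRanges(fragments$start + 1L,
                                          fragments$end))
      hits <- GenomicRanges::findOverlaps(gr_reads, gr_frag, type = "within")
      # fragments are disjoint, so each read hits at most one fragment
      tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(fragments))
      counts <- as.integer(tab)
      n_assigned <- length(hits)
    }
  }
  out <- fragment_counts(fragments$id, counts)
  attr(out, "discarded") <- nrow(reads) - n_assigned
  out
}
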