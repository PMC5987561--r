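# All coordinates are 0-based half-open internally; conversion to the 1-based
# conventions of WIG happens only in these readers/writers.

#' Write a genome to FASTA
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

write_tsv <- function(df, path, col.names = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}

#' Write the fragment index as BED4
#'
#' Columns: chrom, start, end, id (0-based half-open, no header).
#' @param fragments Fragment table from [find_gatc_fragments()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  write_tsv(fragments[, c("chrom", "start", "end", "id")], path,
            col.names = FALSE)
}

#' Read a fragment index from BED4
#'
#' Recomputes `length` and `end_flank` (first/last fragment per chromosome).
#' @param path BED4 file (chrom, start, end, id).
#' @return A fragment table as from [find_gatc_fragments()].
#' @export
read_fragments_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "id"),
                   colClasses = c("character", "integer", "integer",
                                  "integer"))
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), ]
  df$length <- df$end - df$start
  df$end_flank <- stats::ave(df$start, df$chrom, FUN = function(x)
    seq_along(x) %in% c(1L, length(x))) > 0
  rownames(df) <- NULL
  df
}

#' Write per-fragment counts as TSV (chrom, start, end, count)
#' @param counts Fragment-count table (`id`, `count`).
#' @param fragments Fragment table supplying coordinates.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, fragments, path) {
  i <- match(counts$id, fragments$id)
  write_tsv(data.frame(chrom = fragments$chrom[i],
                       start = fragments$start[i], end = fragments$end[i],
                       count = counts$count), path)
}

#' Read per-fragment counts from TSV (chrom, start, end, count)
#'
#' @param path TSV with header columns chrom, start, end, count.
#' @param fragments Optional fragment table; when given, rows are matched to
#'   fragments by exact coordinates and a fragment-count table (`id`,
#'   `count`) is returned.
#' @return Fragment-count table if `fragments` is given, else the raw data
#'   frame.
#' @export
read_counts_tsv <- function(path, fragments = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (is.null(fragments)) return(df)
  key <- paste(df$chrom, df$start, df$end)
  fkey <- paste(fragments$chrom, fragments$start, fragments$end)
  i <- match(fkey, key)
  if (any(is.na(i)))
    stop("counts file does not cover the fragment universe", call. = FALSE)
  fragment_counts(fragments$id, df$count[i])
}

#' Write a normalised profile as TSV (chrom, start, end, value, masked)
#' @param profile Profile data frame (`id`, `value`, `masked`).
#' @param fragments Fragment table supplying coordinates.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, fragments, path) {
  i <- match(profile$id, fragments$id)
  write_tsv(data.frame(chrom = fragments$chrom[i],
                       start = fragments$start[i], end = fragments$end[i],
                       value = profile$value, masked = profile$masked), path)
}

#' Read a normalised profile from TSV
#' @param path TSV written by [write_profile_tsv()].
#' @param fragments Fragment table to align ids by coordinates.
#' @return A profile data frame (`id`, `value`, `masked`).
#' @export
read_profile_tsv <- function(path, fragments) {
  df <- read.table(path, sep = "\t", header = TRUE)
  key <- paste(df$chrom, df$start, df$end)
  fkey <- paste(fragments$chrom, fragments$start, fragments$end)
  i <- match(fkey, key)
  if (any(is.na(i)))
    stop("profile file does not cover the fragment universe", call. = FALSE)
  new_profile(fragments$id, df$value[i], as.logical(df$masked[i]))
}

#' Write genes as BED6 (TSS-anchored)
#'
#' Each gene is written as the 1-base interval containing its TSS with the
#' gene id as name, so `start` is the TSS on either strand.
#' @param de DE/gene table with columns `gene`, `chrom`, `tss`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(de, path) {
  write_tsv(data.frame(de$chrom, de$tss, de$tss + 1L, de$gene, 0L,
                       de$strand), path, col.names = FALSE)
}

#' Read genes from TSS-anchored BED6
#' @param path BED6 file written by [write_genes_bed()].
#' @return Data frame (`gene`, `chrom`, `tss`, `strand`).
#' @export
read_genes_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "gene", "score",
                                 "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character"))
  data.frame(gene = df$gene, chrom = df$chrom, tss = df$start,
             strand = df$strand)
}

#' Write a differential-expression table as TSV
#' @param de DE table (`gene`, `chrom`, `tss`, `strand`, `log2fc`, `padj`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) write_tsv(de, path)

#' Read a differential-expression table from TSV
#'
#' Requires columns `gene`, `log2fc`, `padj`; carries through any further
#' columns (`chrom`, `tss`, `strand`, ...).
#' @param path TSV file.
#' @return Data frame.
#' @export
read_de_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(df)))
    stop("DE table must have columns gene, log2fc, padj", call. = FALSE)
  df
}

#' Write binding-state calls in the state-WIG dialect
#'
#' Serialises a state call as WIG with the fixed encoding enriched = 1,
#' intermediate = 0, depleted = -1, one variableStep span per run of
#' equal-length fragments, coordinates 1-based per WIG convention. Masked
#' fragments (state `NA`) are omitted. Output is deterministic
#' (chromosome-then-start order, no timestamp), so rewriting the same call
#' is byte-identical.
#'
#' @param call State-call data frame (`id`, `state`).
#' @param fragments Fragment table aligned to the call.
#' @param path Output file.
#' @param name Track name written in the header.
#' @return `path`, invisibly.
#' @export
write_state_wig <- function(call, fragments, path, name = "hmm_states") {
  i <- match(call$id, fragments$id)
  if (any(is.na(i)))
    stop("alignment error: call and fragments do not share ids",
         call. = FALSE)
  df <- data.frame(chrom = fragments$chrom[i], start = fragments$start[i],
                   end = fragments$end[i], state = call$state)
  df <- df[!is.na(df$state), , drop = FALSE]
  df <- df[order(match(df$chrom, unique(fragments$chrom)), df$start), ,
           drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=%s", name), con)
  if (nrow(df) == 0L) return(invisible(path))
  code <- STATE_WIG_CODES[as.character(df$state)]
  span <- df$end - df$start
  lines <- character(0)
  for (ch in unique(df$chrom)) {
    j <- which(df$chrom == ch)
    # a new variableStep declaration whenever the span changes
    brk <- c(TRUE, diff(span[j]) != 0)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      k <- j[grp == g]
      lines <- c(lines,
                 sprintf("variableStep chrom=%s span=%d", ch, span[k[1L]]),
                 sprintf("%d %d", df$start[k] + 1L, code[k]))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read binding-state calls from the state-WIG dialect
#'
#' Accepts variableStep and fixedStep tracks whose values are the state codes
#' 1 (enriched), 0 (intermediate) and -1 (depleted); any other value is a
#' format error. Spans are converted from 1-based WIG coordinates to 0-based
#' half-open intervals; overlapping spans are rejected.
#'
#' @param path WIG file.
#' @return List with `fragments` (chrom, start, end, id) and `call`
#'   (state-call data frame `chrom`, `start`, `end`, `id`, `state`).
#' @export
read_state_wig <- function(path) {
  lines <- readLines(path)
  chrom <- character(0); start <- integer(0); end <- integer(0)
  state <- integer(0)
  mode <- NA_character_
  cur_chrom <- NA_character_; cur_span <- 1L
  fixed_pos <- NA_integer_; fixed_step <- 1L
  get_field <- function(parts, key, default = NA_character_) {
    hit <- grep(paste0("^", key, "="), parts, value = TRUE)
    if (length(hit) == 0L) return(default)
    sub(paste0("^", key, "="), "", hit[1L])
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#") || startsWith(line, "track"))
      next
    parts <- strsplit(line, "[ \t]+")[[1L]]
    if (parts[1L] == "variableStep" || parts[1L] == "fixedStep") {
      mode <- parts[1L]
      cur_chrom <- get_field(parts, "chrom")
      if (is.na(cur_chrom))
        stop(sprintf("format error at line %d: missing chrom", ln),
             call. = FALSE)
      cur_span <- as.integer(get_field(parts, "span", "1"))
      if (mode == "fixedStep") {
        fixed_pos <- as.integer(get_field(parts, "start"))
        fixed_step <- as.integer(get_field(parts, "step", "1"))
        if (is.na(fixed_pos))
          stop(sprintf("format error at line %d: fixedStep without start",
                       ln), call. = FALSE)
      }
      next
    }
    if (is.na(mode))
      stop(sprintf("format error at line %d: data before step declaration",
                   ln), call. = FALSE)
    if (mode == "variableStep") {
      if (length(parts) != 2L)
        stop(sprintf("format error at line %d: expected 'pos value'", ln),
             call. = FALSE)
      pos <- suppressWarnings(as.integer(parts[1L]))
      val <- suppressWarnings(as.numeric(parts[2L]))
    } else {
      pos <- fixed_pos
      fixed_pos <- fixed_pos + fixed_step
      val <- suppressWarnings(as.numeric(parts[1L]))
    }
    if (is.na(pos) || is.na(val))
      stop(sprintf("format error at line %d: unparseable record", ln),
           call. = FALSE)
    if (!val %in% c(-1, 0, 1))
      stop(sprintf("format error at line %d: value %s not in {-1, 0, 1}",
                   ln, parts[length(parts)]), call. = FALSE)
    chrom <- c(chrom, cur_chrom)
    start <- c(start, pos - 1L)          # WIG is 1-based
    end <- c(end, pos - 1L + cur_span)
    state <- c(state, as.integer(val))
  }
  ord <- order(match(chrom, unique(chrom)), start)
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
  state <- state[ord]
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    if (length(j) > 1L && any(start[j][-1L] < end[j][-length(j)]))
      stop(sprintf("format error: overlapping spans on %s", ch),
           call. = FALSE)
  }
  labels <- names(STATE_WIG_CODES)[match(state, STATE_WIG_CODES)]
  fragments <- data.frame(chrom = chrom, start = start, end = end,
                          id = seq_along(chrom))
  list(fragments = fragments,
       call = data.frame(fragments,
                         state = factor(labels, levels = state_labels())))
}

#' Write binding-state calls as BED with state names
#' @param call State-call data frame (`id`, `state`).
#' @param fragments Fragment table aligned to the call.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_state_bed <- function(call, fragments, path) {
  i <- match(call$id, fragments$id)
  keep <- !is.na(call$state)
  write_tsv(data.frame(fragments$chrom[i], fragments$start[i],
                       fragments$end[i],
                       as.character(call$state))[keep, ],
            path, col.names = FALSE)
}

#' Write a transition call as TSV
#' @param transitions Output of [compare_states()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transitions_tsv <- function(transitions, path) {
  write_tsv(transitions, path)
}

#' Read BED intervals (reads) for strict assignment
#' @param path BED file with at least chrom, start, end.
#' @return Data frame (`chrom`, `start`, `end`).
#' @export
read_reads_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE)
  data.frame(chrom = as.character(df[[1L]]), start = as.integer(df[[2L]]),
             end = as.integer(df[[3L]]))
}
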