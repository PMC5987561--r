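#' Dam-normalised log2 ratio for one replicate
#'
#' Computes the per-fragment log2 binding intensity of a Dam-fusion sample
#' over its paired Dam-only control,
#' `log2((pc_rpm + c) / (dam_rpm + c))`, where each sample is first scaled to
#' reads per million and `c` is a pseudocount in RPM units. The pseudocount
#' keeps every value finite; RPM scaling makes the result invariant to
#' sequencing depth.
#'
#' @param pc,dam Fragment-count tables (`id`, `count`) for the Dam-fusion and
#'   Dam-only samples, on the same fragment universe.
#' @param pseudocount Pseudocount `c` in RPM units (> 0).
#' @param scale `"rpm"` (default) scales each library to reads per million;
#'   `"none"` uses raw counts (useful when libraries are depth-matched by
#'   construction).
#' @return Data frame (`id`, `value`) of finite log2 ratios.
#' @export
normalize_replicate <- function(pc, dam, pseudocount = 0.5,
                                scale = c("rpm", "none")) {
  scale <- match.arg(scale)
  if (pseudocount <= 0)
    stop("pseudocount must be > 0", call. = FALSE)
  if (!setequal(pc$id, dam$id))
    stop("pc and dam counts are on different fragment universes",
         call. = FALSE)
  dam <- dam[match(pc$id, dam$id), ]
  n_pc <- sum(pc$count)
  n_dam <- sum(dam$count)
  if (n_pc == 0 || n_dam == 0)
    stop("empty-library error: a sample has zero total counts", call. = FALSE)
  if (scale == "rpm") {
    pc_s <- pc$count / n_pc * 1e6
    dam_s <- dam$count / n_dam * 1e6
  } else {
    pc_s <- pc$count
    dam_s <- dam$count
  }
  data.frame(id = pc$id,
             value = log2((pc_s + pseudocount) / (dam_s + pseudocount)))
}

#' Mask fragments with highly discordant replicate values
#'
#' Flags fragments whose between-replicate difference is a robust outlier:
#' with `d = rep1 - rep2`, a fragment is masked iff
#' `|d - median(d)| > k * mad(d)` (MAD scaled to estimate the sd). This is an
#' explicit, single-knob substitute for replicate-discordance filtering.
#'
#' @param rep1,rep2 Numeric vectors of per-fragment values for the two
#'   replicates, aligned to the same fragment universe.
#' @param k Robust z-score cutoff (> 0); default 3.
#' @return Logical mask, `TRUE` = excluded.
#' @export
exclude_discordant <- function(rep1, rep2, k = 3) {
  stopifnot(length(rep1) == length(rep2))
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  d <- rep1 - rep2
  s <- mad(d)
  mask <- abs(d - median(d)) > k * s
  mask[is.na(mask)] <- TRUE
  if (sum(!mask) < 10L)
    stop("too-few-fragments error: fewer than 10 unmasked fragments remain",
         call. = FALSE)
  mask
}

#' Average replicate values into a normalised profile
#'
#' Unmasked fragments carry the arithmetic mean of their replicate values;
#' masked fragments carry no value.
#'
#' @param values A numeric vector (single replicate), matrix (fragments x
#'   replicates) or list of per-replicate numeric vectors.
#' @param mask Logical exclusion mask (default: nothing masked).
#' @param ids Fragment ids (default `seq_len(n)`).
#' @param provenance Optional list recording sample ids and pseudocount.
#' @return A profile data frame (`id`, `value`, `masked`) of class
#'   `damid_profile`; `value` is `NA` exactly where `masked` is `TRUE`.
#' @export
average_replicates <- function(values, mask = NULL, ids = NULL,
                               provenance = list()) {
  if (is.list(values) && !is.data.frame(values))
    values <- do.call(cbind, values)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  n <- nrow(values)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(length(mask) == n, length(ids) == n)
  value <- rowMeans(values)
  mask <- mask | !is.finite(value)
  new_profile(ids, value, mask, provenance)
}

# profile constructor: value is NA wherever masked
new_profile <- function(id, value, masked, provenance = list()) {
  value[masked] <- NA_real_
  if (any(!masked & !is.finite(value)))
    stop("profile values must be finite where unmasked", call. = FALSE)
  out <- data.frame(id = id, value = value, masked = masked)
  attr(out, "provenance") <- provenance
  class(out) <- c("damid_profile", "data.frame")
  out
}

#' Build an averaged, masked profile from replicate count tables
#'
#' Convenience wrapper chaining [normalize_replicate()] per replicate,
#' replicate-discordance masking ([exclude_discordant()], applied when there
#' are exactly two replicates), masking of fragments with zero Dam counts in
#' every replicate (unobserved), and [average_replicates()].
#'
#' @param pc_reps,dam_reps Lists of fragment-count tables, one per replicate.
#' @param pseudocount,scale Passed to [normalize_replicate()].
#' @param k Discordance cutoff; `Inf` disables the discordance mask.
#' @return A `damid_profile` data frame.
#' @export
build_profile <- function(pc_reps, dam_reps, pseudocount = 0.5, k = 3,
                          scale = "rpm") {
  stopifnot(length(pc_reps) == length(dam_reps), length(pc_reps) >= 1L)
  vals <- mapply(function(pc, dam) {
    normalize_replicate(pc, dam, pseudocount, scale)$value
  }, pc_reps, dam_reps)
  ids <- pc_reps[[1L]]$id
  dam_zero <- Reduce(`&`, lapply(dam_reps, function(d)
    d$count[match(ids, d$id)] == 0L))
  mask <- dam_zero
  if (length(pc_reps) == 2L && is.finite(k))
    mask <- mask | exclude_discordant(vals[, 1L], vals[, 2L], k)
  average_replicates(vals, mask, ids,
                     provenance = list(pseudocount = pseudocount,
                                       discordance_k = k, scale = scale,
                                       n_replicates = length(pc_reps)))
}
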