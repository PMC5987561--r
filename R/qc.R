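#' Pearson correlation matrix of binding profiles
#'
#' Pairwise Pearson correlation over the jointly unmasked fragments of a set
#' of profiles on a shared fragment universe.
#'
#' @param profiles Named list of profile data frames (`id`, `value`,
#'   optional `masked`) aligned to identical fragment ids.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(profiles) {
  if (length(profiles) < 2L)
    stop("at least 2 profiles are required", call. = FALSE)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  ids <- profiles[[1L]]$id
  mat <- vapply(profiles, function(p) {
    if (!setequal(p$id, ids))
      stop("profiles are not aligned to identical fragment ids",
           call. = FALSE)
    p$value[match(ids, p$id)]
  }, numeric(length(ids)))
  keep <- complete.cases(mat)
  if (sum(keep) < 3L)
    stop("fewer than 3 jointly unmasked fragments", call. = FALSE)
  mat <- mat[keep, , drop = FALSE]
  sds <- apply(mat, 2L, sd)
  if (any(sds == 0))
    stop(sprintf("undefined-correlation error: zero variance in profile '%s'",
                 names(profiles)[which(sds == 0)[1L]]), call. = FALSE)
  r <- cor(mat)
  diag(r) <- 1
  r
}

#' Hierarchical clustering of binding profiles
#'
#' Agglomerative clustering of profiles with distance `1 - r` (one minus the
#' Pearson correlation) and average linkage. Deterministic; identical
#' profiles merge at height 0.
#'
#' @param mat Correlation matrix from [pearson_matrix()].
#' @param method Linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An [stats::hclust()] object.
#' @export
cluster_profiles <- function(mat, method = "average") {
  hclust(as.dist(1 - mat), method = method)
}

#' Export a profile dendrogram as Newick
#'
#' @param hc An [stats::hclust()] object from [cluster_profiles()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Lag-k autocorrelation of a binding profile over neighbouring fragments
#'
#' Pearson correlation between the values of unmasked fragments `i` and
#' `i + k`, where the lag counts *fragment index* among consecutive unmasked
#' fragments (adjacency of neighbouring GATC fragments), not base pairs.
#' Pairs never span a chromosome boundary; pairs are pooled across
#' chromosomes before the correlation is computed. Chromosomes with fewer
#' than `k + 2` unmasked fragments do not contribute.
#'
#' @param profile Profile data frame (`id`, `value`, optional `masked`).
#' @param fragments Fragment table in genome order.
#' @param lag Non-negative integer lag `k` (default 2).
#' @return Correlation in `[-1, 1]`; `lag = 0` gives 1 for any non-constant
#'   profile.
#' @export
lag_autocorrelation <- function(profile, fragments, lag = 2L) {
  stopifnot(lag >= 0L)
  built <- build_chains(profile, fragments)
  xs <- ys <- numeric(0)
  for (ch in built$chains) {
    v <- ch$value
    if (length(v) < lag + 2L) next
    if (lag == 0L) {
      xs <- c(xs, v); ys <- c(ys, v)
    } else {
      n <- length(v)
      xs <- c(xs, v[seq_len(n - lag)])
      ys <- c(ys, v[seq_len(n - lag) + lag])
    }
  }
  if (length(xs) < 2L)
    stop("undefined error: no valid fragment pairs at this lag",
         call. = FALSE)
  if (sd(xs) == 0 || sd(ys) == 0)
    stop("undefined-correlation error: constant profile", call. = FALSE)
  cor(xs, ys)
}

#' Fragment-size distributions per binding state
#'
#' Groups fragment lengths by decoded binding state and summarises each
#' state's distribution.
#'
#' @param call State-call data frame (`id`, `state`).
#' @param fragments Fragment table aligned to the call.
#' @return List with `summary` (data frame: `state`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`) and `sizes` (named list of the per-state length
#'   vectors). States with zero fragments get a summary row with count 0.
#' @export
state_fragment_sizes <- function(call, fragments) {
  len <- fragments$length[match(call$id, fragments$id)]
  if (any(is.na(len)))
    stop("state call is not aligned to the fragment table", call. = FALSE)
  sizes <- lapply(setNames(nm = state_labels()), function(s)
    len[!is.na(call$state) & call$state == s])
  summ <- do.call(rbind, lapply(state_labels(), function(s) {
    x <- sizes[[s]]
    if (length(x) == 0L)
      return(data.frame(state = s, n = 0L, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_))
    q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(state = s, n = length(x), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  }))
  rownames(summ) <- NULL
  list(summary = summ, sizes = sizes)
}
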