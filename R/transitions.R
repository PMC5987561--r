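# transition labels in fixed order
TRANSITION_LABELS <- c("gain", "loss", "no_change")

state_rank <- function(state) as.integer(state) - 1L  # depleted=0 ... enriched=2

# align two state calls on their joint unmasked fragment universe
align_calls <- function(a, b) {
  shared <- intersect(a$id, b$id)
  if (length(shared) == 0L)
    stop("alignment error: state calls share no fragments", call. = FALSE)
  a <- a[match(shared, a$id), ]
  b <- b[match(shared, b$id), ]
  keep <- !is.na(a$state) & !is.na(b$state)
  list(a = a[keep, ], b = b[keep, ])
}

#' Compare binding-state calls between two conditions
#'
#' Classifies every fragment of the joint unmasked universe as `gain`, `loss`
#' or `no_change` from condition A (reference) to condition B (test).
#' Fragments without a state call in either condition are excluded from the
#' comparison for both conditions.
#'
#' In `full` mode states are ranked depleted < intermediate < enriched and a
#' fragment is a `gain` iff its rank increases, a `loss` iff it decreases.
#' In `enriched_only` mode only transitions in and out of the `enriched`
#' state count: `gain` iff B is enriched and A is not, `loss` iff A is
#' enriched and B is not.
#'
#' @param a,b State-call data frames (`id`, `state`, optionally coordinates)
#'   for the reference and test condition, e.g. from [biohmm()] or
#'   [read_state_wig()].
#' @param mode `"full"` (rank-based) or `"enriched_only"`.
#' @return Data frame (`id`, `label`) with `label` a factor in
#'   gain/loss/no_change, carrying attributes `mode` and the per-condition
#'   states as columns `state_a`, `state_b`.
#' @export
compare_states <- function(a, b, mode = c("full", "enriched_only")) {
  mode <- match.arg(mode)
  al <- align_calls(a, b)
  ra <- state_rank(al$a$state)
  rb <- state_rank(al$b$state)
  if (mode == "full") {
    label <- ifelse(rb > ra, "gain", ifelse(rb < ra, "loss", "no_change"))
  } else {
    label <- ifelse(rb == 2L & ra != 2L, "gain",
                    ifelse(ra == 2L & rb != 2L, "loss", "no_change"))
  }
  out <- data.frame(id = al$a$id,
                    label = factor(label, levels = TRANSITION_LABELS),
                    state_a = al$a$state, state_b = al$b$state)
  if (all(c("chrom", "start", "end") %in% names(al$a)))
    out <- cbind(al$a[, c("chrom", "start", "end")], out)
  attr(out, "mode") <- mode
  rownames(out) <- NULL
  out
}

#' Summarise transition calls per chromosome or genome-wide
#'
#' @param transitions Output of [compare_states()].
#' @param fragments Fragment table (used to attach chromosomes when the
#'   transition table does not carry them); may be `NULL` if it does.
#' @param by `"genome"` for a single row, `"chromosome"` for one row per
#'   chromosome.
#' @return Data frame with columns `group`, `n`, `pct_gain`, `pct_loss`,
#'   `pct_no_change`; percentages sum to 100 per row.
#' @export
summarize_transitions <- function(transitions, fragments = NULL,
                                  by = c("genome", "chromosome")) {
  by <- match.arg(by)
  if (nrow(transitions) == 0L)
    stop("empty transition call", call. = FALSE)
  if (!"chrom" %in% names(transitions)) {
    if (is.null(fragments))
      stop("fragments required when transitions carry no chromosome",
           call. = FALSE)
    transitions$chrom <- fragments$chrom[match(transitions$id, fragments$id)]
  }
  grp <- if (by == "genome") rep("genome", nrow(transitions))
         else transitions$chrom
  tab <- table(grp, transitions$label)
  n <- rowSums(tab)
  data.frame(group = rownames(tab), n = as.integer(n),
             pct_gain = 100 * tab[, "gain"] / n,
             pct_loss = 100 * tab[, "loss"] / n,
             pct_no_change = 100 * tab[, "no_change"] / n,
             row.names = NULL)
}

#' Turnover of bound states between two conditions
#'
#' "Bound" pools the intermediate and enriched states. `pct_lost` is the
#' percentage of fragments bound in the reference condition that are depleted
#' in the test condition; `pct_de_novo` is the percentage of fragments bound
#' in the test condition that were depleted in the reference, i.e. binding
#' arising de novo.
#'
#' @inheritParams compare_states
#' @return List with elements `pct_lost`, `pct_de_novo`, `n_bound_a`,
#'   `n_bound_b`.
#' @export
bound_state_turnover <- function(a, b) {
  al <- align_calls(a, b)
  ra <- state_rank(al$a$state)
  rb <- state_rank(al$b$state)
  bound_a <- ra >= 1L
  bound_b <- rb >= 1L
  if (sum(bound_a) == 0L || sum(bound_b) == 0L)
    stop("undefined-rate error: no bound fragments in a denominator",
         call. = FALSE)
  list(pct_lost = 100 * sum(bound_a & rb == 0L) / sum(bound_a),
       pct_de_novo = 100 * sum(bound_b & ra == 0L) / sum(bound_b),
       n_bound_a = sum(bound_a), n_bound_b = sum(bound_b))
}

#' Cross-tabulate two transition comparisons
#'
#' Counts fragments by their transition label in two different comparisons
#' (e.g. tumour-vs-WT against late-vs-early development) over the shared
#' fragment universe. Marginals equal the per-comparison summaries.
#'
#' @param t1,t2 Outputs of [compare_states()].
#' @return A 3x3 contingency table (rows = `t1` labels, columns = `t2`
#'   labels).
#' @export
cross_tabulate_transitions <- function(t1, t2) {
  shared <- intersect(t1$id, t2$id)
  if (length(shared) == 0L)
    stop("alignment error: comparisons share no fragments", call. = FALSE)
  l1 <- t1$label[match(shared, t1$id)]
  l2 <- t2$label[match(shared, t2$id)]
  table(comparison1 = factor(l1, levels = TRANSITION_LABELS),
        comparison2 = factor(l2, levels = TRANSITION_LABELS))
}
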