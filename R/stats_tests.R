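#' Kruskal-Wallis test with greedy step-down homogeneous subsets
#'
#' Computes the tie-corrected Kruskal-Wallis H over all groups, then forms
#' homogeneous subsets: groups are ordered by mean pooled rank and a subset
#' is greedily extended while the Kruskal-Wallis test restricted to the
#' subset stays non-significant at `alpha`; when adding the next group
#' would make it significant the subset is closed and a new one starts.
#' Every group receives exactly one subset label (1..k); groups that do not
#' share a label differ significantly.
#'
#' @param groups named list: group label -> numeric vector of observations
#'   (e.g. HMM bit scores per subfamily).
#' @param alpha significance level for the step-down procedure
#'   (default 0.05).
#' @return list with `H`, `df`, `p.value` (overall test) and `subsets`, a
#'   data.frame with `group`, `n`, `mean_rank`, `subset`.
#' @export
kruskal_wallis_stepdown <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop_input("kruskal_wallis_stepdown(): need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 1))
    stop_input("kruskal_wallis_stepdown(): every group needs >= 1 observation")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  mean_rank <- tapply(r, g, mean)
  ord <- names(sort(mean_rank))
  subset_of <- stats::setNames(integer(length(ord)), ord)
  lab <- 0L
  i <- 1L
  while (i <= length(ord)) {
    lab <- lab + 1L
    j <- i
    while (j < length(ord)) {
      sub <- groups[ord[i:(j + 1L)]]
      xs <- unlist(sub, use.names = FALSE)
      gs <- factor(rep(names(sub), vapply(sub, length, integer(1))))
      p <- suppressWarnings(stats::kruskal.test(xs, gs)$p.value)
      if (is.na(p) || p > alpha) j <- j + 1L else break
    }
    subset_of[ord[i:j]] <- lab
    i <- j + 1L
  }
  subsets <- data.frame(group = ord,
                        n = vapply(groups[ord], length, integer(1)),
                        mean_rank = as.numeric(mean_rank[ord]),
                        subset = as.integer(subset_of[ord]),
                        stringsAsFactors = FALSE)
  rownames(subsets) <- NULL
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value, subsets = subsets)
}

# Number of ways to choose control positions out of N so that, after
# dropping h from each tail, the remaining g = nC - 2h ranks span at most s
# positions. Summation over the positions (a, b) of the (h+1)-th and
# (nC-h)-th control order statistics.
moses_count_span_le <- function(s, N, nC, h) {
  g <- nC - 2L * h
  if (g < 2) stop_input("moses test needs nC - 2*trim_h >= 2")
  total <- 0
  for (a in 1:(N - 1)) {
    bmax <- min(N, a + s - 1L)
    if (bmax <= a) next
    for (b in (a + 1):bmax) {
      if (b - a - 1 < g - 2) next
      total <- total + choose(a - 1, h) * choose(b - a - 1, g - 2) *
        choose(N - b, h)
    }
  }
  total
}

#' Moses test of extreme reactions
#'
#' Pools both samples, ranks them, trims the `trim_h` most extreme control
#' observations from each tail, and uses the span of the remaining control
#' ranks as the statistic. Small spans indicate that the experimental
#' sample reacts in both extremes. The p-value `P(span <= observed)` is
#' exact, computed from the combinatorial null distribution of the span
#' under random assignment of ranks.
#'
#' @param control,experimental numeric vectors; both must have at least
#'   `2 + 2 * trim_h` observations.
#' @param trim_h number of extreme control observations trimmed from each
#'   tail before the span is measured (default 1).
#' @return list with `span`, `trimmed` (= trim_h), `p.value`, `n_control`,
#'   `n_experimental`.
#' @export
moses_test <- function(control, experimental, trim_h = 1) {
  nC <- length(control); nE <- length(experimental)
  if (nC < 2 + 2 * trim_h || nE < 2 + 2 * trim_h)
    stop_input("moses_test(): both samples need >= 2 + 2*trim_h observations")
  N <- nC + nE
  pooled <- c(control, experimental)
  # rank by pooled order; ties broken by input order (control first) so the
  # span is always computed on a permutation of 1..N
  pos <- order(order(pooled))
  cpos <- sort(pos[seq_len(nC)])
  keep <- cpos[(trim_h + 1L):(nC - trim_h)]
  span <- max(keep) - min(keep) + 1L
  p <- moses_count_span_le(span, N, nC, trim_h) / choose(N, nC)
  list(span = as.integer(span), trimmed = as.integer(trim_h),
       p.value = min(1, p), n_control = nC, n_experimental = nE)
}

#' Pearson chi-square for family-vs-genome response proportions
#'
#' Compares the proportion of responsive genes inside a gene family with
#' the proportion across the genome using a 2x2 Pearson chi-square
#' (df = 1), without continuity correction by default.
#'
#' @param family_responsive,family_total counts for the family.
#' @param genome_responsive,genome_total counts for the genome.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `statistic`, `df`, `p.value`, `proportions`.
#' @export
family_vs_genome_chisq <- function(family_responsive, family_total,
                                   genome_responsive, genome_total,
                                   correct = FALSE) {
  if (family_responsive > family_total || genome_responsive > genome_total ||
      min(family_responsive, genome_responsive) < 0)
    stop_input("family_vs_genome_chisq(): need totals >= counts >= 0")
  tab <- rbind(family = c(family_responsive, family_total - family_responsive),
               genome = c(genome_responsive, genome_total - genome_responsive))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0))
    stop_input("family_vs_genome_chisq(): zero expected cell; use an exact test")
  d <- abs(tab - E)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  list(statistic = stat, df = 1,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       proportions = c(family = family_responsive / family_total,
                       genome = genome_responsive / genome_total))
}
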