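#' Mid-rank a score vector
#'
#' Ranks with rank 1 for the smallest score and mean ranks (mid-ranks) for
#' ties, so the ranks of `n` scores always sum to `n(n+1)/2`. A judge with
#' zero variance (all scores equal) ranks every item `(n+1)/2`.
#'
#' @param scores Numeric vector.
#' @return Numeric vector of ranks.
#' @examples
#' rank_with_ties(c(0, 0, 5)) # 1.5 1.5 3
#' @export
rank_with_ties <- function(scores) {
  rank(scores, ties.method = "average")
}

#' Tie-corrected Kendall's coefficient of concordance
#'
#' Agreement among `m` judges each scoring the same `n` items, on `[0, 1]`.
#' With `R_i` the sum of item `i`'s ranks across judges and
#' `S = sum((R_i - mean(R))^2)`,
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_j T_j},}
#' where `T_j = sum(t^3 - t)` over judge `j`'s tie groups of size `t`. The
#' tie correction lets fully tied judges (for instance receivers that never
#' observed anything and score every signaler 0) enter the statistic
#' instead of breaking it. `W = 1` exactly when all judges rank the items
#' identically (ties included); a completely degenerate table -- every
#' judge fully tied on every item -- has a zero denominator and returns 0
#' with a warning.
#'
#' @param table Numeric matrix of scores, judges in rows (`m >= 2`), items
#'   in columns (`n >= 2`).
#' @return Kendall's W in `[0, 1]`.
#' @examples
#' kendalls_w(rbind(c(10, 20, 30), c(5, 5, 5))) # 0.5
#' @export
kendalls_w <- function(table) {
  table <- as.matrix(table)
  m <- nrow(table)
  n <- ncol(table)
  if (m < 2 || n < 2)
    stop("need at least 2 judges and 2 items", call. = FALSE)
  ranks <- t(apply(table, 1, rank_with_ties))
  R <- colSums(ranks)
  S <- sum((R - mean(R))^2)
  tie_term <- sum(apply(ranks, 1, function(r) {
    t <- tabulate(match(r, unique(r)))
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * tie_term
  if (denom <= 0) {
    warning("all judges fully tied on all items; W undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  12 * S / denom
}

#' Concordance between true efforts and receiver estimates
#'
#' Builds the run's rating table (the true effort vector plus every
#' receiver's estimate vector, each treated as a judge) and returns its
#' tie-corrected Kendall's W. With the default 20 receivers this is a
#' 21-judge statistic.
#'
#' @param result A `run_result` from [run_sim()].
#' @return Kendall's W in `[0, 1]`.
#' @seealso [mean_rank_correlation()] for the pairwise diagnostic.
#' @export
run_concordance <- function(result) {
  kendalls_w(rating_table(result))
}

#' Mean receiver--truth rank correlation (diagnostic)
#'
#' Secondary, pairwise reading of ranking accuracy: the mean Spearman
#' correlation between each receiver's estimates and the true efforts.
#' Receivers with zero variance contribute `NA` and are dropped; if every
#' receiver is degenerate the result is `NA`. The headline statistic is
#' [run_concordance()], which keeps those receivers via the tie
#' correction.
#'
#' @param result A `run_result`.
#' @return Mean Spearman rho, or `NA` if undefined for every receiver.
#' @export
mean_rank_correlation <- function(result) {
  stopifnot(inherits(result, "run_result"))
  rho <- apply(result$estimates, 1, function(e) {
    if (stats::sd(e) == 0 || stats::sd(result$true_efforts) == 0) return(NA_real_)
    stats::cor(e, result$true_efforts, method = "spearman")
  })
  if (all(is.na(rho))) NA_real_ else mean(rho, na.rm = TRUE)
}
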