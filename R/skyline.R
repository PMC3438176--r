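#' Classic skyline plot from an ultrametric genealogy
#'
#' Deterministic stepwise estimate of female effective population size from
#' the coalescent interval lengths of a genealogy: during the interval I_k in
#' which k lineages exist, Nef_k = I_k (in generations) * k(k-1)/2. This is
#' the classic (non-Bayesian) skyline; it operates on a single genealogy with
#' node times in years.
#'
#' @param tree an `ape::phylo`, ultrametric, branch lengths in years.
#' @param generation_time years per generation (default 25).
#' @param tol relative tolerance for the ultrametricity check.
#' @return A `data.frame` of steps ordered oldest to youngest: `t_old`,
#'   `t_young` (years BP), `k` (lineages), `interval_years`, `nef`.
#' @export
classic_skyline <- function(tree, generation_time = 25, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("need an ape phylo")
  if (!ape::is.ultrametric(tree, tol = max(tol * max(ape::node.depth.edgelength(tree)), tol)))
    stop("genealogy is not ultrametric")
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least two tips")
  bt <- sort(unname(ape::branching.times(tree)))  # years BP of coalescences
  times <- c(0, bt)
  k <- seq(n, 2L)                                  # lineages in each interval
  interval <- diff(times)
  nef <- (interval / generation_time) * k * (k - 1) / 2
  out <- data.frame(
    t_old = times[-1][length(k):1],
    t_young = times[-length(times)][length(k):1],
    k = k[length(k):1],
    interval_years = interval[length(k):1],
    nef = nef[length(k):1]
  )
  rownames(out) <- NULL
  out
}

#' Time-weighted harmonic mean of a skyline
#'
#' For a constant-size population this recovers Nef (up to coalescent noise).
#' Zero-length intervals are ignored.
#'
#' @param steps output of [classic_skyline()].
#' @export
skyline_harmonic_nef <- function(steps) {
  keep <- steps$interval_years > 0 & steps$nef > 0
  sum(steps$interval_years[keep]) /
    sum(steps$interval_years[keep] / steps$nef[keep])
}

#' Ratio of recent to ancient skyline size
#'
#' Splits the coalescent intervals into terciles (youngest third vs oldest
#' third by interval count) and returns the ratio of their time-weighted
#' harmonic mean Nef values. Values well above 1 indicate recent growth; a
#' constant-size genealogy fluctuates around 1.
#'
#' @param steps output of [classic_skyline()].
#' @param fraction fraction of intervals in each epoch (default 1/3).
#' @export
skyline_epoch_ratio <- function(steps, fraction = 1 / 3) {
  steps <- steps[order(steps$t_young), , drop = FALSE]  # youngest first
  m <- nrow(steps)
  take <- max(1L, ceiling(m * fraction))
  young <- steps[seq_len(take), , drop = FALSE]
  old <- steps[seq.int(m - take + 1L, m), , drop = FALSE]
  skyline_harmonic_nef(young) / skyline_harmonic_nef(old)
}
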