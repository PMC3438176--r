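#' Clock calibrations
#'
#' A calibration converts mutational distance to years. Rate-based
#' calibrations carry a substitution rate in mutations/site/Myr and need a
#' region length; per-mutation calibrations carry a constant in years per
#' mutation.
#'
#' @param name calibration name.
#' @param mode `"rate"` or `"per-mutation"`.
#' @param rate mutations/site/Myr (rate mode) or years/mutation
#'   (per-mutation mode).
#' @param region_length bp of sequence the rate applies to (rate mode only).
#' @export
clock_calibration <- function(name, mode = c("rate", "per-mutation"),
                              rate, region_length = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  if (mode == "rate" && is.null(region_length))
    stop("rate-based calibrations need region_length")
  structure(list(name = name, mode = mode, rate = rate,
                 region_length = region_length),
            class = "clock_calibration")
}

#' Registry of the standard control-region clocks
#'
#' Rate-based entries: howell 0.45, kemp 0.34, endicott 0.302 and santos 0.24
#' mutations/site/Myr. The `soares_cr` entry is the control-region rho
#' calculator expressed as its linear constant, 9,058 years per mutation (the
#' time-dependent correction of the original calculator is out of scope).
#'
#' @param region_length bp used by the rate-based entries (default: the
#'   standard two-segment control region, 1018 bp).
#' @return Named list of [clock_calibration()]s.
#' @export
clock_registry <- function(region_length = region_spec()$total_length) {
  list(
    howell   = clock_calibration("howell",   "rate", 0.45,  region_length),
    kemp     = clock_calibration("kemp",     "rate", 0.34,  region_length),
    endicott = clock_calibration("endicott", "rate", 0.302, region_length),
    santos   = clock_calibration("santos",   "rate", 0.24,  region_length),
    soares_cr = clock_calibration("soares_cr", "per-mutation", 9058)
  )
}

#' Rho statistic and its standard error on a rooted network
#'
#' Rho is the count-weighted mean number of mutations separating each sampled
#' individual from the root (founder) haplotype. On a reticulated network the
#' distances are taken along a minimum-cost spanning tree rooted at the nodal
#' haplotype, with ties broken towards paths through higher-frequency
#' intermediate nodes. The standard error follows the Saillard estimator,
#' sigma^2 = sum over tree edges of (n_e / n)^2 m_e, where n_e is the number
#' of individuals whose root path uses the edge and m_e the number of
#' mutations on it. Every variant counts as one mutation regardless of its
#' site weight.
#'
#' @param net an `mj_network` (or an `ape::phylo` with edge lengths in
#'   mutations, in which case tip counts are taken from `counts`).
#' @param root motif string (or node index) of the root haplotype; for trees,
#'   the tree's root is used.
#' @param counts optional named vector of individuals per node id; defaults
#'   to the network's total counts.
#' @return List with `rho`, `sigma`, `n`.
#' @export
rho_sigma <- function(net, root = NULL, counts = NULL) {
  if (inherits(net, "phylo")) return(rho_sigma_phylo(net, counts))
  if (!inherits(net, "mj_network")) stop("need an mj_network or phylo")
  if (is.character(root)) {
    root <- match(root, net$nodes$id)
    if (is.na(root)) stop("root haplotype is not a node of the network")
  }
  v <- nrow(net$nodes)
  if (is.null(root) || root < 1L || root > v)
    stop("root must name a node of the network")
  if (is.null(counts)) counts <- setNames(net$nodes$total_count,
                                          net$nodes$id)
  nvec <- rep(0, v)
  hit <- match(names(counts), net$nodes$id)
  if (anyNA(hit)) stop("counts refer to unknown node ids")
  nvec[hit] <- as.numeric(counts)
  n <- sum(nvec)
  if (n < 1) stop("no sampled individuals")

  if (nrow(net$edges) == 0L && v > 1L) stop("network is disconnected")
  # adjacency with mutation counts
  adj <- vector("list", v)
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$from[r]; j <- net$edges$to[r]; m <- net$edges$nmut[r]
    adj[[i]] <- rbind(adj[[i]], c(j, m))
    adj[[j]] <- rbind(adj[[j]], c(i, m))
  }
  # Prim from the root, minimising mutation distance; ties prefer attaching
  # through high-frequency nodes, then lower node index.
  dist <- rep(Inf, v); dist[root] <- 0
  parent <- rep(NA_integer_, v); pmut <- rep(0, v)
  in_tree <- rep(FALSE, v)
  key <- rep(Inf, v); key[root] <- 0
  via_count <- rep(-Inf, v); via_count[root] <- Inf
  for (step in seq_len(v)) {
    cand <- which(!in_tree & is.finite(key))
    if (length(cand) == 0L) stop("network is disconnected")
    o <- cand[order(key[cand], -via_count[cand], cand)]
    u <- o[1]
    in_tree[u] <- TRUE
    if (!is.na(parent[u])) dist[u] <- dist[parent[u]] + pmut[u]
    nb <- adj[[u]]
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      wv <- nb[r, 1]; m <- nb[r, 2]
      if (!in_tree[wv] &&
          (m < key[wv] ||
           (m == key[wv] && nvec[u] > via_count[wv]))) {
        key[wv] <- m; via_count[wv] <- nvec[u]
        parent[wv] <- u; pmut[wv] <- m
      }
    }
  }
  rho <- sum(nvec * dist) / n
  # subtree individual counts below each tree edge
  sigma2 <- 0
  order_by_depth <- order(dist, decreasing = TRUE)
  below <- nvec
  for (u in order_by_depth) {
    if (!is.na(parent[u])) {
      sigma2 <- sigma2 + (below[u] / n)^2 * pmut[u]
      below[parent[u]] <- below[parent[u]] + below[u]
    }
  }
  list(rho = rho, sigma = sqrt(sigma2), n = n)
}

#' Direct rho estimate from motifs against a founder haplotype
#'
#' The star-genealogy form of the rho statistic: the mean mutational distance
#' (symmetric-difference size) between each sample's motif and the founder
#' motif. Agrees with [rho_sigma()] on star-like networks and is cheap enough
#' for replicate simulation studies.
#'
#' @param motifs list of [motif()]s.
#' @param founder the founder (nodal) [motif()].
#' @return List with `rho`, `sigma` (star-form standard error
#'   `sqrt(rho / n)`), and `n`.
#' @export
rho_direct <- function(motifs, founder = motif()) {
  ftoks <- motif_tokens(founder)
  d <- vapply(motifs, function(m) {
    t <- motif_tokens(m)
    length(setdiff(t, ftoks)) + length(setdiff(ftoks, t))
  }, 0)
  n <- length(d)
  list(rho = mean(d), sigma = sqrt(mean(d) / n), n = n)
}

rho_sigma_phylo <- function(tree, counts = NULL) {
  n_tip <- length(tree$tip.label)
  if (is.null(counts)) counts <- setNames(rep(1, n_tip), tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_len(n_tip)]
  nvec <- as.numeric(counts[tree$tip.label])
  n <- sum(nvec)
  rho <- sum(nvec * tipd) / n
  # edge-wise Saillard variance
  below <- numeric(n_tip + tree$Nnode)
  below[seq_len(n_tip)] <- nvec
  edges <- tree$edge[order(depth[tree$edge[, 2]], decreasing = TRUE), ,
                     drop = FALSE]
  lens <- tree$edge.length[order(depth[tree$edge[, 2]],
                                 decreasing = TRUE)]
  sigma2 <- 0
  for (r in seq_len(nrow(edges))) {
    child <- edges[r, 2]; par <- edges[r, 1]
    sigma2 <- sigma2 + (below[child] / n)^2 * lens[r]
    below[par] <- below[par] + below[child]
  }
  list(rho = rho, sigma = sqrt(sigma2), n = n)
}

#' Convert a rho estimate to an age in years BP
#'
#' Per-mutation calibrations give `age = rho * years_per_mutation`;
#' rate-based calibrations give `age = rho / (rate * 1e-6 * L)`. Ages are
#' rounded half-up to the nearest year. If `sigma` is supplied a 95% interval
#' (rho +- 1.96 sigma, converted identically) is attached.
#'
#' @param rho rho estimate (or the list returned by [rho_sigma()]).
#' @param calibration a [clock_calibration()].
#' @param sigma optional standard error of rho.
#' @return List with `age_years`, `calibration`, and optionally `ci`.
#' @export
rho_to_age <- function(rho, calibration, sigma = NULL) {
  if (is.list(rho) && !is.null(rho$rho)) {
    if (is.null(sigma)) sigma <- rho$sigma
    rho <- rho$rho
  }
  if (rho < 0) stop("rho must be >= 0")
  to_years <- function(r) {
    if (calibration$mode == "per-mutation") r * calibration$rate
    else {
      if (is.null(calibration$region_length))
        stop("rate-based calibration without region_length")
      r / (calibration$rate * 1e-6 * calibration$region_length)
    }
  }
  out <- list(age_years = round_half_up(to_years(rho)),
              calibration = calibration$name)
  if (!is.null(sigma) && is.finite(sigma)) {
    out$ci <- round_half_up(c(to_years(max(0, rho - 1.96 * sigma)),
                              to_years(rho + 1.96 * sigma)))
  }
  out
}

#' Rescale an age between two substitution rates
#'
#' Ages under a molecular clock are inversely proportional to the assumed
#' rate: `rescale_age(a, r1, r2) = a * r1 / r2`, rounded half-up.
#'
#' @param age_years age in years BP.
#' @param from_rate,to_rate rates in the same units, both > 0.
#' @export
rescale_age <- function(age_years, from_rate, to_rate) {
  if (from_rate <= 0 || to_rate <= 0) stop("rates must be > 0")
  round_half_up(age_years * from_rate / to_rate)
}
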