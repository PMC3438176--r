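token_position <- function(tokens) {
  as.integer(sub("^@?0*([0-9]+).*$", "\\1", tokens))
}

token_weight <- function(tokens, site_weights, default_weight) {
  if (length(tokens) == 0L) return(numeric())
  pos <- as.character(token_position(tokens))
  w <- rep(default_weight, length(tokens))
  hit <- pos %in% names(site_weights)
  w[hit] <- site_weights[pos[hit]]
  w
}

set_distance <- function(a, b, site_weights, default_weight) {
  sym <- c(setdiff(a, b), setdiff(b, a))
  sum(token_weight(sym, site_weights, default_weight))
}

pairwise_set_distance <- function(tokens, site_weights, default_weight) {
  v <- length(tokens)
  D <- matrix(0, v, v)
  if (v < 2L) return(D)
  for (i in 1:(v - 1L)) for (j in (i + 1L):v) {
    D[i, j] <- D[j, i] <-
      set_distance(tokens[[i]], tokens[[j]], site_weights, default_weight)
  }
  D
}

# Prim MST over a full distance matrix; returns edge list and total cost.
mst_edges <- function(D) {
  v <- nrow(D)
  if (v == 1L) return(list(edges = cbind(integer(), integer()), cost = 0))
  in_tree <- rep(FALSE, v); in_tree[1] <- TRUE
  best <- D[1, ]; parent <- rep(1L, v)
  edges <- matrix(0L, v - 1L, 2L); cost <- 0
  for (step in seq_len(v - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    edges[step, ] <- c(parent[nxt], nxt)
    cost <- cost + best[nxt]
    in_tree[nxt] <- TRUE
    upd <- !in_tree & D[nxt, ] < best
    best[upd] <- D[nxt, upd]; parent[upd] <- nxt
  }
  list(edges = edges, cost = cost)
}

mst_cost <- function(D) mst_edges(D)$cost

# minimax path distances over the MST of D (the component-connection level of
# every pair in the epsilon-relaxed minimum spanning network sense)
minimax_matrix <- function(D) {
  v <- nrow(D)
  M <- matrix(0, v, v)
  if (v < 2L) return(M)
  me <- mst_edges(D)$edges
  adj <- vector("list", v)
  for (r in seq_len(nrow(me))) {
    i <- me[r, 1]; j <- me[r, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, D[i, j]))
    adj[[j]] <- rbind(adj[[j]], c(i, D[i, j]))
  }
  for (s in seq_len(v)) {
    seen <- rep(FALSE, v); seen[s] <- TRUE
    stack <- list(c(s, 0))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      u <- top[1]; mx <- top[2]
      nb <- adj[[u]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]
        if (!seen[w]) {
          seen[w] <- TRUE
          M[s, w] <- max(mx, nb[r, 2])
          stack[[length(stack) + 1L]] <- c(w, M[s, w])
        }
      }
    }
  }
  M
}

#' Condense motifs into a haplotype table
#'
#' Identical motifs are merged; per-population counts are kept. Site weights
#' follow the cited network program's convention: default weight 10,
#' down-weighted homoplastic sites 5, and excluded sites should already have
#' been removed with [exclude_sites()] (an explicit weight of 0 is honoured if
#' they have not).
#'
#' @param motifs list of [motif()]s carrying population attributes.
#' @param homoplastic_sites integer rCRS positions to down-weight.
#' @param site_weights named numeric vector (names = rCRS positions)
#'   overriding individual sites.
#' @param default_weight,low_weight weights for ordinary and homoplastic
#'   sites.
#' @param include optional list of extra haplotypes (e.g. a clade's nodal
#'   motif) added with count 0 so they are present as network nodes.
#' @return An object of class `haplotype_table`.
#' @export
condense <- function(motifs, homoplastic_sites = integer(),
                     site_weights = NULL, default_weight = 10,
                     low_weight = 5, include = NULL) {
  sw <- c(setNames(rep(low_weight, length(homoplastic_sites)),
                   as.character(homoplastic_sites)))
  if (!is.null(site_weights)) sw[names(site_weights)] <- site_weights
  ids <- vapply(motifs, format_motif, "")
  pops <- vapply(motifs, function(m) {
    p <- attr(m, "population"); if (is.null(p) || is.na(p)) "all" else p
  }, "")
  extra_ids <- if (length(include)) vapply(include, format_motif, "") else character()
  hap_ids <- sort(unique(c(ids, extra_ids)))
  pop_names <- sort(unique(pops))
  counts <- matrix(0L, length(hap_ids), length(pop_names),
                   dimnames = list(hap_ids, pop_names))
  for (k in seq_along(ids)) {
    i <- match(ids[k], hap_ids); j <- match(pops[k], pop_names)
    counts[i, j] <- counts[i, j] + 1L
  }
  structure(list(
    haplotypes = hap_ids,
    tokens = lapply(hap_ids, function(s)
      if (nzchar(s)) strsplit(s, "-", fixed = TRUE)[[1]] else character()),
    counts = counts,
    site_weights = sw,
    default_weight = default_weight
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype table:", length(x$haplotypes), "haplotypes,",
      sum(x$counts), "samples,", ncol(x$counts), "population(s)\n")
  invisible(x)
}

majority_median <- function(a, b, c) {
  all_tok <- unique(c(a, b, c))
  keep <- vapply(all_tok, function(t)
    (t %in% a) + (t %in% b) + (t %in% c) >= 2L, logical(1))
  sort(all_tok[keep])
}

feasible_links <- function(D, epsilon) {
  M <- minimax_matrix(D)
  D <= M + epsilon + 1e-9 & upper.tri(D)
}

#' Build a median-joining network
#'
#' Implements the median-joining scheme on weighted binary variant characters:
#' (i) weighted pairwise distances between haplotypes (sum of site weights
#' over the symmetric difference); (ii) the epsilon-relaxed minimum spanning
#' network of feasible links; (iii) for triplets mutually linked in that
#' network, the majority-consensus (quasi-median) vector is generated and the
#' candidate that most reduces the cost of a spanning tree of the current node
#' set is added (ties broken towards the lexicographically smallest variant
#' set); this is iterated to a fixed point; (iv) median vectors left
#' unconnected (degree <= 1) are removed. Edges of the returned network are
#' the feasible links among the final nodes, labelled with the variant set
#' separating their endpoints.
#'
#' @param table a [condense()]d haplotype table.
#' @param epsilon non-negative weighted tolerance for relaxing the minimum
#'   spanning network: 0 is the strict minimum spanning network, `Inf` links
#'   every pair and gives the fully relaxed (quasi-median) regime, which is
#'   what exhaustive parsimony comparisons at small scale should use.
#' @param max_nodes growth guard: stop generating median vectors once the
#'   node set reaches this size.
#' @return An object of class `mj_network`.
#' @export
build_mj <- function(table, epsilon = 0, max_nodes = 500L) {
  if (!inherits(table, "haplotype_table")) stop("need a haplotype_table")
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0)
    stop("epsilon must be a single non-negative number")
  if (length(table$haplotypes) < 2L)
    stop("need at least two haplotypes")
  sw <- table$site_weights; dw <- table$default_weight
  tokens <- table$tokens
  ids <- table$haplotypes
  observed <- rep(TRUE, length(ids))

  repeat {
    D <- pairwise_set_distance(tokens, sw, dw)
    base_cost <- mst_cost(D)
    A <- feasible_links(D, epsilon)
    A <- A | t(A)
    v <- length(tokens)
    # quasi-median candidates: every node with two feasible neighbours
    # spans a triplet (neighbour, centre, neighbour)
    cand <- list()
    for (ctr in seq_len(v)) {
      nb <- which(A[ctr, ])
      if (length(nb) < 2L) next
      for (ai in seq_len(length(nb) - 1L)) for (b in nb[(ai + 1L):length(nb)]) {
        med <- majority_median(tokens[[ctr]], tokens[[nb[ai]]], tokens[[b]])
        id <- paste(med, collapse = "-")
        if (!(id %in% ids) && is.null(cand[[id]])) cand[[id]] <- med
      }
    }
    if (length(cand) == 0L) break
    # a median is admitted when it does not increase the cost of a spanning
    # tree of the node set (zero-cost medians carry the equally-parsimonious
    # alternative paths that show up as reticulations)
    deltas <- vapply(cand, function(med) {
      dcol <- vapply(tokens, set_distance, 0, b = med,
                     site_weights = sw, default_weight = dw)
      D2 <- rbind(cbind(D, dcol), c(dcol, 0))
      mst_cost(D2) - base_cost
    }, 0)
    admit <- sort(names(cand)[deltas <= 1e-9])
    if (length(admit) == 0L) break
    if (length(ids) + length(admit) > max_nodes) {
      warning("median generation stopped at max_nodes = ", max_nodes)
      break
    }
    for (id in admit) {
      tokens <- c(tokens, cand[id])
      ids <- c(ids, id)
      observed <- c(observed, FALSE)
    }
  }

  # drop median vectors that end up poorly connected (degree <= 1)
  repeat {
    D <- pairwise_set_distance(tokens, sw, dw)
    A <- feasible_links(D, epsilon); A <- A | t(A)
    deg <- rowSums(A)
    drop <- which(!observed & deg <= 1L)
    if (length(drop) == 0L) break
    tokens <- tokens[-drop]; ids <- ids[-drop]; observed <- observed[-drop]
  }

  new_mj_network(ids, tokens, observed, table, epsilon)
}

new_mj_network <- function(ids, tokens, observed, table, epsilon,
                           postprocessed = FALSE, cost = NA_real_) {
  sw <- table$site_weights; dw <- table$default_weight
  D <- pairwise_set_distance(tokens, sw, dw)
  A <- feasible_links(D, epsilon); A <- A | t(A)
  idx <- which(upper.tri(A) & A, arr.ind = TRUE)
  labels <- vapply(seq_len(nrow(idx)), function(r) {
    a <- tokens[[idx[r, 1]]]; b <- tokens[[idx[r, 2]]]
    paste(sort(c(setdiff(a, b), setdiff(b, a))), collapse = "-")
  }, "")
  counts <- matrix(0L, length(ids), ncol(table$counts),
                   dimnames = list(ids, colnames(table$counts)))
  hit <- match(rownames(table$counts), ids)
  ok <- !is.na(hit)
  counts[hit[ok], ] <- as.matrix(table$counts)[ok, , drop = FALSE]
  edges <- data.frame(
    from = idx[, 1], to = idx[, 2],
    weight = D[idx],
    nmut = vapply(strsplit(labels, "-", fixed = TRUE), length, 0L),
    label = labels, stringsAsFactors = FALSE)
  structure(list(
    nodes = data.frame(id = ids, observed = observed,
                       total_count = rowSums(counts),
                       stringsAsFactors = FALSE),
    tokens = tokens, counts = counts, edges = edges,
    epsilon = epsilon, site_weights = sw, default_weight = dw,
    postprocessed = postprocessed, cost = cost
  ), class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat("median-joining network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$observed), "observed ),", nrow(x$edges), "edges",
      if (!is.na(x$cost)) paste0("; spanning cost ", x$cost) else "",
      "\n")
  invisible(x)
}

# ---- exact Steiner machinery within a graph (Dreyfus-Wagner DP) -----------

# Shortest-path distances over the network's edge list.
network_sp <- function(net) {
  v <- nrow(net$nodes)
  SP <- matrix(Inf, v, v); diag(SP) <- 0
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$from[r]; j <- net$edges$to[r]; w <- net$edges$weight[r]
    SP[i, j] <- min(SP[i, j], w); SP[j, i] <- SP[i, j]
  }
  for (k in seq_len(v)) {
    SP <- pmin(SP, outer(SP[, k], SP[k, ], `+`))
  }
  SP
}

# dp[S, v]: minimum cost of a tree inside the graph spanning terminal subset S
# (bitmask over `terminals`) plus vertex v.
steiner_dp <- function(SP, terminals) {
  k <- length(terminals)
  v <- nrow(SP)
  dp <- matrix(Inf, 2^k, v)
  for (t in seq_len(k)) dp[bitwShiftL(1L, t - 1L) + 1L, ] <- SP[terminals[t], ]
  popcount <- vapply(0:(2^k - 1), function(m)
    sum(bitwAnd(m, 2^(0:(k - 1))) > 0), 0)
  for (S in (0:(2^k - 1))[order(popcount)]) {
    if (popcount[S + 1L] < 2L) next
    acc <- rep(Inf, v)
    E <- bitwAnd(S - 1L, S)
    while (E > 0L) {
      comp <- bitwXor(S, E)
      acc <- pmin(acc, dp[E + 1L, ] + dp[comp + 1L, ])
      E <- bitwAnd(E - 1L, S)
    }
    # close under shortest paths (min-plus with SP)
    relaxed <- apply(SP + acc, 2, min)
    dp[S + 1L, ] <- pmin(acc, relaxed)
  }
  dp
}

#' Maximum-parsimony post-processing of a median-joining network
#'
#' Deletes every median vector and every edge that lies on no minimum-cost
#' tree connecting the observed haplotypes within the network (the
#' maximum-parsimony option of the cited network program). Observed nodes are
#' never deleted. For up to `max_exact` observed haplotypes membership is
#' decided exactly via a Dreyfus-Wagner Steiner-tree dynamic programme on the
#' network graph; beyond that only unconnectable medians are pruned and the
#' reported cost is the spanning-tree cost of the remaining nodes (a
#' documented upper bound).
#'
#' @param net an [build_mj()] network.
#' @param max_exact largest observed-haplotype count for which the exact
#'   programme is run.
#' @return The pruned `mj_network`, with `$cost` set to the minimum cost of a
#'   spanning (Steiner) tree of the observed haplotypes within the network.
#' @export
mp_postprocess <- function(net, max_exact = 12L) {
  obs <- which(net$nodes$observed)
  k <- length(obs)
  table_stub <- list(counts = net$counts[net$nodes$observed, , drop = FALSE],
                     site_weights = net$site_weights,
                     default_weight = net$default_weight)
  if (k > max_exact) {
    D <- pairwise_set_distance(net$tokens, net$site_weights,
                               net$default_weight)
    return(new_mj_network(net$nodes$id, net$tokens, net$nodes$observed,
                          table_stub, net$epsilon, postprocessed = TRUE,
                          cost = mst_cost(D)))
  }
  SP <- network_sp(net)
  dp <- steiner_dp(SP, obs)
  full <- 2^k - 1L
  cstar <- min(dp[full + 1L, ])
  # node membership: v is on some optimal tree iff the tree can be forced
  # through it at no extra cost
  vtx <- nrow(net$nodes)
  forced <- rep(Inf, vtx)
  submasks <- 1:(full - 1L)
  for (m in seq_len(vtx)) {
    through <- min(dp[submasks + 1L, m] + dp[(full - submasks) + 1L, m])
    forced[m] <- min(through, dp[full + 1L, m])
  }
  keep_node <- net$nodes$observed | forced <= cstar + 1e-9
  new_idx <- cumsum(keep_node)
  tokens <- net$tokens[keep_node]
  ids <- net$nodes$id[keep_node]
  observed <- net$nodes$observed[keep_node]
  pruned <- new_mj_network(ids, tokens, observed, table_stub,
                           net$epsilon, postprocessed = TRUE, cost = cstar)
  # edge membership: an edge survives iff some optimal tree uses it
  ext <- function(S, x) if (S == 0L) 0 else dp[S + 1L, x]
  old_of <- which(keep_node)
  keep_edge <- vapply(seq_len(nrow(pruned$edges)), function(r) {
    u <- old_of[pruned$edges$from[r]]; v <- old_of[pruned$edges$to[r]]
    w <- pruned$edges$weight[r]
    best <- Inf
    for (S in 0:full)
      best <- min(best, ext(S, u) + w + ext(full - S, v))
    best <= cstar + 1e-9
  }, logical(1))
  pruned$edges <- pruned$edges[keep_edge, , drop = FALSE]
  rownames(pruned$edges) <- NULL
  pruned
}

#' Export a network to GraphML or DOT
#'
#' Node attributes: haplotype motif string, kind (observed/median),
#' per-population counts; edge attribute: the variant label. GraphML exports
#' can be re-imported with [import_network()].
#'
#' @param net an `mj_network`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  igraph::V(g)$name <- paste0("h", seq_len(nrow(net$nodes)))
  igraph::V(g)$motif <- net$nodes$id
  igraph::V(g)$kind <- ifelse(net$nodes$observed, "observed", "median")
  igraph::V(g)$total_count <- net$nodes$total_count
  igraph::V(g)$pop_counts <- apply(net$counts, 1, function(r)
    paste(paste0(colnames(net$counts), "=", r), collapse = "|"))
  if (nrow(net$edges))
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
  igraph::E(g)$label <- net$edges$label
  igraph::E(g)$weight <- net$edges$weight
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::V(g)$motif
  observed <- igraph::V(g)$kind == "observed"
  pc <- strsplit(igraph::V(g)$pop_counts, "|", fixed = TRUE)
  pops <- sort(unique(sub("=.*$", "", unlist(pc))))
  counts <- t(vapply(pc, function(entries) {
    val <- as.integer(sub("^.*=", "", entries))
    names(val) <- sub("=.*$", "", entries)
    val[pops]
  }, setNames(integer(length(pops)), pops)))
  dimnames(counts) <- list(ids, pops)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      weight = igraph::E(g)$weight,
                      nmut = vapply(strsplit(igraph::E(g)$label, "-",
                                             fixed = TRUE), length, 0L),
                      label = igraph::E(g)$label, stringsAsFactors = FALSE)
  structure(list(
    nodes = data.frame(id = ids, observed = observed,
                       total_count = rowSums(counts),
                       stringsAsFactors = FALSE),
    tokens = lapply(ids, function(s)
      if (nzchar(s)) strsplit(s, "-", fixed = TRUE)[[1]] else character()),
    counts = counts, edges = edges,
    epsilon = NA_real_, site_weights = numeric(), default_weight = 10,
    postprocessed = NA, cost = NA_real_
  ), class = "mj_network")
}
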