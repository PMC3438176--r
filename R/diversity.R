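seqs_to_matrix <- function(seqs) {
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Summary diversity statistics
#'
#' Computes the classic control-region summary statistics for one group: the
#' number of segregating sites S, haplotype diversity Hd (with the Nei 1987
#' variance), the mean number of pairwise differences K, and nucleotide
#' diversity pi = K / L (with the Tajima 1983 total variance).
#'
#' @param x either a list of [motif()]s or a character vector of aligned
#'   sequences of equal length.
#' @param group label for the output row.
#' @param L sequence length used for pi; defaults to the default region
#'   length for motif input, or the alignment length for sequences.
#' @return One-row `data.frame`: group, n, S, Hd, Hd_se, K, pi, pi_se.
#' @export
summary_stats <- function(x, group = "all", L = NULL) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "dloop_motif"))) {
    n <- length(x)
    if (n < 2L) stop("need at least two samples")
    if (is.null(L)) L <- region_spec()$total_length
    ids <- vapply(x, format_motif, "")
    toksets <- lapply(x, motif_tokens)
    all_tok <- unique(unlist(toksets))
    if (length(all_tok)) {
      pres <- vapply(toksets, function(t) all_tok %in% t,
                     logical(length(all_tok)))
      pres <- matrix(pres, nrow = length(all_tok))
      varying <- apply(pres, 1, function(r) any(r) && !all(r))
      S <- length(unique(token_position(all_tok[varying])))
    } else S <- 0L
    diffs <- numeric()
    if (n >= 2L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        diffs <- c(diffs, length(c(setdiff(toksets[[i]], toksets[[j]]),
                                   setdiff(toksets[[j]], toksets[[i]]))))
      }
    }
    K <- mean(diffs)
  } else {
    seqs <- as.character(x)
    n <- length(seqs)
    if (n < 2L) stop("need at least two samples")
    if (length(unique(nchar(seqs))) != 1L)
      stop("sequences must be aligned to equal length")
    if (is.null(L)) L <- nchar(seqs[1])
    M <- seqs_to_matrix(seqs)
    valid <- matrix(M %in% ACGT, nrow = n)
    S <- sum(apply(M, 2, function(col) {
      states <- unique(col[col %in% ACGT])
      length(states) >= 2L
    }))
    ids <- seqs
    diffs <- numeric()
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      both <- valid[i, ] & valid[j, ]
      diffs <- c(diffs, sum(M[i, both] != M[j, both]))
    }
    K <- mean(diffs)
  }
  p <- as.numeric(table(ids)) / n
  sp2 <- sum(p^2); sp3 <- sum(p^3)
  Hd <- n * (1 - sp2) / (n - 1)
  hd_var <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sp3 - sp2^2) + sp2 - sp2^2)
  pi <- K / L
  pi_var <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  data.frame(group = group, n = n, S = as.integer(S),
             Hd = Hd, Hd_se = sqrt(max(0, hd_var)),
             K = K, pi = pi, pi_se = sqrt(max(0, pi_var)),
             stringsAsFactors = FALSE)
}

#' Tamura-Nei (1993) distance with gamma rate heterogeneity
#'
#' Pairwise TN93 distance (two transition classes plus transversions,
#' empirical base frequencies) with the standard gamma correction (shape
#' `gamma_alpha`, default 0.26). Gap and ambiguity columns are removed
#' pairwise. When the model is degenerate for a pair (a required frequency
#' class empty with observed changes) the uncorrected p-distance is returned
#' with a warning.
#'
#' @param seq1,seq2 equal-length sequences.
#' @param gamma_alpha gamma shape; `Inf` disables the correction.
#' @return Substitutions per site.
#' @export
tn93_distance <- function(seq1, seq2, gamma_alpha = 0.26) {
  m <- tn93_matrix(c(a = seq1, b = seq2), gamma_alpha = gamma_alpha)
  m[1, 2]
}

#' @rdname tn93_distance
#' @param seqs named character vector of aligned sequences.
#' @return `tn93_matrix()`: symmetric matrix of distances.
#' @export
tn93_matrix <- function(seqs, gamma_alpha = 0.26) {
  M <- seqs_to_matrix(seqs)
  rownames(M) <- names(seqs) %||% paste0("s", seq_along(seqs))
  bin <- ape::as.DNAbin(tolower(M))
  gamma <- if (is.finite(gamma_alpha)) gamma_alpha else FALSE
  d <- ape::dist.dna(bin, model = "TN93", gamma = gamma,
                     pairwise.deletion = TRUE)
  d <- as.matrix(d)
  if (any(!is.finite(d))) {
    warning("degenerate base frequencies for some pair(s); ",
            "falling back to p-distance there")
    praw <- as.matrix(ape::dist.dna(bin, model = "raw",
                                    pairwise.deletion = TRUE))
    d[!is.finite(d)] <- praw[!is.finite(d)]
  }
  d
}

# Two-level AMOVA variance components from a matrix of squared
# inter-individual distances (Arlequin convention: the supplied molecular
# distance is used as the squared deviation).
amova_phist <- function(d2, groups) {
  N <- length(groups)
  gs <- split(seq_len(N), groups)
  G <- length(gs)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- sum(vapply(gs, function(idx) {
    if (length(idx) < 2L) return(0)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 0))
  ss_among <- ss_total - ss_within
  df_a <- G - 1L; df_w <- N - G
  sigma_w <- ss_within / df_w
  n_prime <- (N - sum(vapply(gs, length, 0L)^2) / N) / df_a
  sigma_a <- (ss_among / df_a - sigma_w) / n_prime
  denom <- sigma_a + sigma_w
  phi <- if (denom <= 0) 0 else sigma_a / denom
  list(phi_st = phi, sigma_a = sigma_a, sigma_w = sigma_w)
}

#' Pairwise PhiST between populations
#'
#' Distance-based AMOVA PhiST (the behaviour of the standard population
#' genetics program for sequence data), from pairwise TN93+gamma distances
#' (`method = "molecular"`) or from haplotype identity (`method =
#' "haplotype"`, the frequency-based FST analogue). An optional permutation
#' test shuffles individuals between the two populations.
#'
#' @param x list of [motif()]s (substitution variants are materialised onto
#'   the reference; indels are skipped for the molecular distances) or a
#'   character vector of aligned sequences.
#' @param populations character vector of population labels (defaults to the
#'   motifs' population attributes).
#' @param method `"molecular"` or `"haplotype"`.
#' @param gamma_alpha gamma shape for the molecular distances.
#' @param permutations number of label permutations for p-values (0 = none).
#' @param seed RNG seed for the permutations.
#' @param region region used to materialise motifs.
#' @return List with `phist` (matrix), `results` (long `data.frame` with
#'   `phi_st` and optional `p_value`), and `excluded` (populations with n<2).
#' @export
pairwise_phist <- function(x, populations = NULL,
                           method = c("molecular", "haplotype"),
                           gamma_alpha = 0.26, permutations = 0L,
                           seed = 1L, region = region_spec()) {
  method <- match.arg(method)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "dloop_motif"))) {
    if (is.null(populations))
      populations <- vapply(x, function(m) attr(m, "population"), "")
    if (method == "molecular") {
      ref <- rcrs_slice(region)
      seqs <- vapply(x, function(m) {
        subs <- m[m$kind %in% c("transition", "transversion"), ,
                  drop = FALSE]
        apply_motif(ref, motif(subs), region)
      }, "")
      d <- tn93_matrix(setNames(seqs, seq_along(seqs)),
                       gamma_alpha = gamma_alpha)
    } else {
      ids <- vapply(x, format_motif, "")
      d <- outer(ids, ids, `!=`) * 1
    }
  } else {
    seqs <- as.character(x)
    if (is.null(populations)) stop("populations must be given for sequences")
    d <- if (method == "molecular")
      tn93_matrix(setNames(seqs, seq_along(seqs)), gamma_alpha = gamma_alpha)
    else outer(seqs, seqs, `!=`) * 1
  }
  populations <- as.character(populations)
  sizes <- table(populations)
  excluded <- names(sizes)[sizes < 2L]
  if (length(excluded))
    warning("excluding population(s) with n < 2: ",
            paste(excluded, collapse = ", "))
  pops <- setdiff(names(sizes), excluded)
  if (length(pops) < 2L) stop("need at least two populations with n >= 2")

  combs <- utils::combn(pops, 2)
  phimat <- matrix(NA_real_, length(pops), length(pops),
                   dimnames = list(pops, pops))
  diag(phimat) <- 0
  rows <- list()
  set.seed(seed)
  for (cc in seq_len(ncol(combs))) {
    p1 <- combs[1, cc]; p2 <- combs[2, cc]
    idx <- which(populations %in% c(p1, p2))
    sub <- d[idx, idx, drop = FALSE]
    grp <- populations[idx]
    obs <- amova_phist(sub, grp)$phi_st
    pval <- NA_real_
    if (permutations > 0L) {
      hits <- 0L
      for (b in seq_len(permutations)) {
        perm <- sample(grp)
        if (amova_phist(sub, perm)$phi_st >= obs - 1e-12) hits <- hits + 1L
      }
      pval <- (hits + 1L) / (permutations + 1L)
    }
    phimat[p1, p2] <- phimat[p2, p1] <- obs
    rows[[cc]] <- data.frame(pop1 = p1, pop2 = p2, phi_st = obs,
                             p_value = pval, stringsAsFactors = FALSE)
  }
  list(phist = phimat, results = do.call(rbind, rows), excluded = excluded)
}

#' Neighbor-joining dendrogram from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape) with deterministic handling of
#' negative branch lengths: each negative branch is clamped to zero and its
#' excess moved to the adjacent ancestral branch, preserving root-to-tip path
#' lengths.
#'
#' @param D symmetric distance matrix with zero diagonal (e.g. a PhiST
#'   matrix).
#' @param clamp clamp negative branch lengths?
#' @return An `ape::phylo`; use `ape::write.tree()` for Newick output.
#' @export
nj_tree <- function(D, clamp = TRUE) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be 0")
  tr <- ape::nj(stats::as.dist(D))
  if (clamp) {
    for (pass in 1:10) {
      neg <- which(tr$edge.length < 0)
      if (length(neg) == 0L) break
      for (e in neg) {
        len <- tr$edge.length[e]
        parent_node <- tr$edge[e, 1]
        up <- which(tr$edge[, 2] == parent_node)
        tr$edge.length[e] <- 0
        if (length(up) == 1L)
          tr$edge.length[up] <- tr$edge.length[up] + len
      }
    }
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
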