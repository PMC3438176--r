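# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementations they check.

# Exact Steiner minimal tree cost for binary haplotypes over s unit-weight
# sites, by Dreyfus-Wagner dynamic programming over the full 2^s hypercube.
steiner_hypercube <- function(term_vecs) {
  s <- ncol(term_vecs); k <- nrow(term_vecs); V <- 2^s
  allv <- as.matrix(expand.grid(rep(list(0:1), s)))
  H <- as.matrix(dist(allv, method = "manhattan"))
  tid <- apply(term_vecs, 1, function(r) sum(r * 2^(0:(s - 1))) + 1L)
  dp <- matrix(Inf, 2^k, V)
  for (t in seq_len(k)) dp[2^(t - 1) + 1L, ] <- H[tid[t], ]
  pc <- vapply(0:(2^k - 1), function(m)
    sum(bitwAnd(m, 2^(0:(k - 1))) > 0), 0)
  for (S in (0:(2^k - 1))[order(pc)]) {
    if (pc[S + 1L] < 2L) next
    acc <- rep(Inf, V)
    E <- bitwAnd(S - 1L, S)
    while (E > 0L) {
      acc <- pmin(acc, dp[E + 1L, ] + dp[bitwXor(S, E) + 1L, ])
      E <- bitwAnd(E - 1L, S)
    }
    dp[S + 1L, ] <- pmin(acc, apply(H + acc, 2, min))
  }
  min(dp[2^k, ])
}

# random binary instance -> list(vecs, motifs); positions offset into HVS2
random_steiner_instance <- function(k, s) {
  repeat {
    vecs <- matrix(rbinom(k * s, 1, 0.5), k, s)
    if (!anyDuplicated(vecs)) break
  }
  toks <- apply(vecs, 1, function(r) {
    p <- which(r == 1)
    if (!length(p)) "" else
      paste(formatC(p + 100, width = 3, flag = "0"), collapse = "-")
  })
  list(vecs = vecs, motifs = lapply(toks, parse_motif))
}

# Tamura-Nei (1993) distance with gamma correction, evaluated directly from
# the published closed form.
tn93_gamma_algebraic <- function(seq1, seq2, alpha) {
  a <- strsplit(seq1, "")[[1]]; b <- strsplit(seq2, "")[[1]]
  n <- length(a)
  g <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) / (2 * n)
  gA <- g["A"]; gC <- g["C"]; gG <- g["G"]; gT <- g["T"]
  gR <- gA + gG; gY <- gC + gT
  pairs <- paste0(pmin(a, b), pmax(a, b))
  P1 <- mean(pairs == "AG")
  P2 <- mean(pairs == "CT")
  Q <- mean(a != b) - P1 - P2
  e1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  e2 <- 1 - gY * P2 / (2 * gT * gC) - Q / (2 * gY)
  e3 <- 1 - Q / (2 * gR * gY)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  corr <- function(x) alpha * (x^(-1 / alpha) - 1)   # gamma form of -log(x)
  unname(k1 * corr(e1) + k2 * corr(e2) + k3 * corr(e3))
}

# Two-level AMOVA from first principles: explicit sums of squared
# inter-individual distances and the variance-component identities.
amova_bruteforce <- function(d2, groups) {
  N <- length(groups)
  ss_total <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / N
  ss_within <- 0
  for (gname in unique(groups)) {
    idx <- which(groups == gname)
    if (length(idx) < 2) next
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + d2[i, j]
    ss_within <- ss_within + acc / length(idx)
  }
  G <- length(unique(groups))
  sw <- ss_within / (N - G)
  nprime <- (N - sum(table(groups)^2) / N) / (G - 1)
  sa <- ((ss_total - ss_within) / (G - 1) - sw) / nprime
  if (sa + sw <= 0) 0 else sa / (sa + sw)
}

motif_tokens_for_test <- function(m) {
  if (nrow(m) == 0L) return(character())
  vapply(seq_len(nrow(m)), function(i) format_variant(m[i, ]), "")
}

# deterministic random motif over the default control region
random_motif <- function(n_var = 5L, region = region_spec(),
                         transitions_only = FALSE) {
  pos <- sample(region$positions, n_var)
  toks <- vapply(pos, function(p) {
    ref <- substr(rcrs_reference(), p, p)
    if (!transitions_only && runif(1) < 0.25) {
      others <- setdiff(c("A", "C", "G", "T"),
                        c(ref, switch(ref, A = "G", G = "A", C = "T",
                                      T = "C")))
      paste0(formatC(p, width = 3, flag = "0"), sample(others, 1))
    } else {
      formatC(p, width = 3, flag = "0")
    }
  }, "")
  parse_motif(paste(sort(toks), collapse = "-"))
}
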