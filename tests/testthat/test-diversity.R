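test_that("identical samples give zero diversity", {
  s <- summary_stats(rep("ACGTACGT", 4), L = 100)
  expect_equal(s$S, 0L)
  expect_equal(s$Hd, 0)
  expect_equal(s$K, 0)
  expect_equal(s$pi, 0)
})

test_that("all-distinct haplotypes give Hd = 1", {
  s <- summary_stats(c("AAAA", "AAAT", "AATT", "ATTT"))
  expect_equal(s$Hd, 1)
})

test_that("the 2+2 haplotype toy matches its hand enumeration", {
  h1 <- paste0(strrep("A", 97), "AAA")
  h2 <- paste0(strrep("A", 97), "TTT")   # 3 differences over 100 sites
  s <- summary_stats(c(h1, h1, h2, h2))
  expect_equal(s$Hd, 2 / 3)
  expect_equal(s$K, 2)            # (4 pairs x 3) / 6
  expect_equal(s$pi, 0.02)
  expect_equal(s$S, 3L)
})

test_that("motif-based summaries agree with sequence-based ones", {
  region <- region_spec()
  ref <- rcrs_slice(region)
  strs <- c("073", "073", "073-146", "152-263")
  mots <- lapply(strs, parse_motif)
  sm <- summary_stats(mots, L = region$total_length)
  seqs <- vapply(mots, function(m) apply_motif(ref, m, region), "")
  ss <- summary_stats(seqs)
  expect_equal(sm$Hd, ss$Hd)
  expect_equal(sm$K, ss$K)
  expect_equal(sm$S, ss$S)
  # a variant fixed in all samples does not segregate
  fixed <- summary_stats(lapply(c("073", "073"), parse_motif), L = 1018)
  expect_equal(fixed$S, 0L)
})

test_that("TN93+gamma matches an independent algebraic evaluation", {
  expect_equal(tn93_distance("ACGT", "ACGT"), 0)
  s1 <- paste(rep(c("A", "C", "G", "T"), each = 25), collapse = "")
  s2 <- paste(c("G", rep("A", 24), rep("C", 25), rep("G", 25),
                rep("T", 25)), collapse = "")
  expect_equal(tn93_distance(s1, s2, 0.26),
               tn93_gamma_algebraic(s1, s2, 0.26), tolerance = 1e-8)
  # model correction can only stretch distances
  p <- mean(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  expect_gte(tn93_distance(s1, s2, Inf), p)
  expect_gte(tn93_distance(s1, s2, 0.26), tn93_distance(s1, s2, Inf))
})

test_that("PhiST takes its boundary values", {
  # populations that are identical and internally homogeneous carry no
  # variance at all: PhiST is 0 by convention
  same <- lapply(rep("073", 4), parse_motif)
  pops <- c("a", "a", "b", "b")
  r0 <- pairwise_phist(same, pops, method = "haplotype")
  expect_lt(abs(r0$phist["a", "b"]), 1e-12)

  # identical mixed multisets expose the small-sample bias of the
  # variance-component estimator: sigma_a = -sigma_w / n' exactly, so
  # PhiST = -1/(n' - 1) (here n' = 4 with 4 + 4 individuals)
  mixed <- lapply(rep(c("073", "073", "146", "146"), 2), parse_motif)
  p8 <- rep(c("a", "b"), each = 4)
  rmix <- pairwise_phist(mixed, p8, method = "haplotype")
  expect_equal(rmix$phist["a", "b"], -1 / 3, tolerance = 1e-10)

  fixed <- lapply(c("073", "073", "146-152", "146-152"), parse_motif)
  r2 <- pairwise_phist(fixed, pops, method = "haplotype")
  expect_equal(r2$phist["a", "b"], 1)
  r2m <- pairwise_phist(fixed, pops, method = "molecular")
  expect_equal(r2m$phist["a", "b"], 1)
})

test_that("PhiST equals the brute-force AMOVA oracle", {
  ids <- c("A", "A", "B", "C", "C", "C")
  pops <- rep(c("p1", "p2"), each = 3)
  mots <- lapply(c("073", "073", "146", "152", "152", "152"), parse_motif)
  r <- pairwise_phist(mots, pops, method = "haplotype")
  d2 <- outer(ids, ids, `!=`) * 1
  expect_equal(r$phist["p1", "p2"], amova_bruteforce(d2, pops))
  expect_equal(r$phist["p1", "p2"], 2 / 3)

  # molecular mode against the same oracle on the TN93 matrix
  region <- region_spec()
  ref <- rcrs_slice(region)
  seqs <- vapply(mots, function(m) apply_motif(ref, m, region), "")
  dmol <- tn93_matrix(setNames(seqs, seq_along(seqs)))
  rm <- pairwise_phist(mots, pops, method = "molecular")
  expect_equal(rm$phist["p1", "p2"], amova_bruteforce(dmol, pops),
               tolerance = 1e-10)
})

test_that("permutation p-values behave sensibly", {
  mots <- lapply(rep(c("073", "146-152-263"), each = 5), parse_motif)
  pops <- rep(c("a", "b"), each = 5)
  r <- pairwise_phist(mots, pops, method = "haplotype",
                      permutations = 199, seed = 5)
  expect_lte(r$results$p_value, 0.05)
  same <- pairwise_phist(lapply(rep("073", 10), parse_motif), pops,
                         method = "haplotype", permutations = 99, seed = 5)
  expect_gte(same$results$p_value, 0.5)
})

test_that("populations below n = 2 are excluded with a warning", {
  mots <- lapply(c("073", "146", "073", "146", "152"), parse_motif)
  pops <- c("a", "a", "b", "b", "tiny")
  expect_warning(r <- pairwise_phist(mots, pops, method = "haplotype"),
                 "tiny")
  expect_equal(r$excluded, "tiny")
  expect_equal(rownames(r$phist), c("a", "b"))
})

test_that("three-taxon NJ solves the path equations exactly", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(D)
  pd <- cophenetic(tr)
  expect_equal(pd[rownames(D), colnames(D)], D)
})

test_that("NJ recovers an additive four-taxon matrix exactly", {
  true_tree <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):1);")
  D <- cophenetic(true_tree)
  tr <- nj_tree(D)
  expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D)
  # permuting taxa does not change the topology
  perm <- c("C", "A", "D", "B")
  tr2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
})

test_that("NJ rejects malformed matrices and clamps negatives", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(D), "symmetric")
  set.seed(23)
  n <- 6
  M <- matrix(runif(n * n, 0, 0.02), n, n)
  M <- (M + t(M)) / 2; diag(M) <- 0
  dimnames(M) <- list(letters[1:n], letters[1:n])
  tr <- nj_tree(M)
  expect_true(all(tr$edge.length >= 0))
})
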