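test_that("a fixed seed reproduces genealogy and motifs exactly", {
  cfg <- sim_config(n = 8, seed = 77, founder_motif = parse_motif("470"))
  g1 <- simulate_genealogy(cfg)
  g2 <- simulate_genealogy(cfg)
  expect_identical(ape::write.tree(g1$tree), ape::write.tree(g2$tree))
  m1 <- sprinkle_mutations(g1, cfg)
  m2 <- sprinkle_mutations(g2, cfg)
  expect_identical(vapply(m1$motifs, format_motif, ""),
                   vapply(m2$motifs, format_motif, ""))
})

test_that("pairwise coalescence time matches E[T2] = N generations", {
  N <- 1000; g <- 25
  t2 <- vapply(1:2000, function(r) {
    cfg <- sim_config(n = 2, seed = 10000 + r,
                      demography = demography_constant(N))
    simulate_genealogy(cfg)$tmrca_years / g
  }, 0)
  expect_lt(abs(mean(t2) - N) / N, 0.05)
})

test_that("TMRCA matches the coalescent expectation 2N(1 - 1/n)", {
  N <- 1000; n <- 30; g <- 25
  tm <- vapply(1:2000, function(r) {
    cfg <- sim_config(n = n, seed = 300000 + r,
                      demography = demography_constant(N))
    simulate_genealogy(cfg)$tmrca_years / g
  }, 0)
  expect_lt(abs(mean(tm) - 2 * N * (1 - 1 / n)) / (2 * N), 0.05)
})

test_that("genealogies are ultrametric with matching TMRCA", {
  cfg <- sim_config(n = 12, seed = 5)
  gen <- simulate_genealogy(cfg)
  expect_true(ape::is.ultrametric(gen$tree, tol = 1e-6))
  expect_equal(max(ape::branching.times(gen$tree)), gen$tmrca_years,
               tolerance = 1e-6)
})

test_that("zero mutation rate leaves every tip on the founder motif", {
  founder <- parse_motif("073-263-470")
  cfg <- sim_config(n = 6, seed = 9, mutation_rate = 0,
                    founder_motif = founder)
  mut <- sprinkle_mutations(simulate_genealogy(cfg), cfg)
  for (m in mut$motifs) expect_equal(format_motif(m), "073-263-470")
  expect_true(all(mut$branch_mutations == 0L))
})

test_that("mean pairwise differences track 2 mu L E[T2]", {
  N <- 2000; g <- 25
  mu_site_year <- 0.302e-6
  L <- region_spec()$total_length
  diffs <- t2 <- numeric(300)
  n_mutable <- NA_integer_
  for (r in 1:300) {
    cfg <- sim_config(n = 2, seed = 40000 + r, gamma_alpha = Inf,
                      demography = demography_constant(N))
    gen <- simulate_genealogy(cfg)
    mut <- sprinkle_mutations(gen, cfg)
    n_mutable <- length(mut$sites)
    a <- motif_tokens_for_test(mut$motifs[[1]])
    b <- motif_tokens_for_test(mut$motifs[[2]])
    diffs[r] <- length(setdiff(a, b)) + length(setdiff(b, a))
    t2[r] <- gen$tmrca_years
  }
  expect_lt(n_mutable, L)
  expected <- 2 * mu_site_year * n_mutable * mean(t2)
  expect_lt(abs(mean(diffs) - expected) / expected, 0.15)
})

test_that("gamma site rates concentrate mutations on fast sites", {
  cfg_het <- sim_config(n = 20, seed = 21, gamma_alpha = 0.26,
                        demography = demography_constant(5000))
  cfg_uni <- sim_config(n = 20, seed = 21, gamma_alpha = Inf,
                        demography = demography_constant(5000))
  gen <- simulate_genealogy(cfg_het)
  n_sites <- function(cfg) {
    mut <- sprinkle_mutations(gen, cfg)
    length(unique(unlist(lapply(mut$motifs, motif_tokens_for_test))))
  }
  # same genealogy and comparable mutation counts: heterogeneity re-uses
  # fast sites, so fewer distinct sites are hit
  expect_lt(n_sites(cfg_het), n_sites(cfg_uni))
})

test_that("demography constructors validate their inputs", {
  expect_error(demography_constant(-5))
  expect_error(demography_piecewise(c(5000, 1000), c(1, 2, 3)),
               "increasing")
  expect_error(demography_piecewise(1000, 5), "one more size")
  d <- demography_piecewise(c(1000, 3000), c(500, 2000, 100))
  expect_length(d, 3L)
  expect_equal(d[[3]]$t1, Inf)
})

test_that("b2l-like scenarios classify entirely to B2l", {
  sc <- make_scenario("b2l-like", n = 40, seed = 7)
  asn <- classify_all(sc$motifs)
  expect_equal(unname(table(asn$clade)["B2l"]), 40L)
})

test_that("two isolated demes are strongly differentiated", {
  sig <- vapply(1:20, function(r) {
    sc <- make_scenario("two-deme", n = 8, seed = 6000 + r)
    pops <- vapply(sc$motifs, function(m) attr(m, "population"), "")
    res <- pairwise_phist(sc$motifs, pops, method = "molecular",
                          permutations = 99, seed = r)
    res$results$p_value < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("scenario output files are complete and consistent", {
  dir <- file.path(tempdir(), "scen")
  sc <- make_scenario("d1g-like", n = 10, seed = 12, out_dir = dir)
  expect_true(all(file.exists(sc$files)))
  seqs <- read_fasta(sc$files["fasta"])
  expect_length(seqs, 10L)
  truth <- jsonlite::read_json(sc$files["truth"], simplifyVector = TRUE)
  expect_equal(truth$tmrca_years, sc$truth$tmrca_years, tolerance = 1e-8)
  tr <- ape::read.tree(sc$files["newick"])
  expect_equal(max(ape::branching.times(tr)), truth$tmrca_years,
               tolerance = 1e-4)
  # motif truth round-trips through the FASTA via align_and_call
  m_back <- align_and_call(seqs[[1]], region = sc$config$region)
  orig <- sc$motifs[[match(names(seqs)[1],
                           vapply(sc$motifs, attr, "", "sample_id"))]]
  expect_identical(format_motif(m_back), format_motif(orig))
})

test_that("unknown presets are rejected", {
  expect_error(make_scenario("weird", n = 5, seed = 1))
})
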