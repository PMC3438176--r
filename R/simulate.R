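#' Demographic models for the coalescent generator
#'
#' Female effective population size (Nef) trajectories, looking backwards in
#' time from the present (t = 0 years BP). `demography_constant()` is a fixed
#' size; `demography_exponential()` interpolates exponentially from
#' `n_present` at t = 0 to `n_ancient` at `t_start_years` and is constant
#' before; `demography_piecewise()` is stepwise constant with breakpoints
#' `times` (ascending years BP) separating `sizes` (length(times) + 1 values,
#' present first).
#'
#' @param nef,n_present,n_ancient,sizes female effective sizes (> 0).
#' @param t_start_years,times times in years BP.
#' @return A list of epochs of class `demography`; each epoch has `t0`, `t1`
#'   (years BP, `t1 = Inf` for the last) and sizes `N0` (young end), `N1`
#'   (old end) interpolated exponentially.
#' @export
demography_constant <- function(nef) {
  stopifnot(nef > 0)
  structure(list(list(t0 = 0, t1 = Inf, N0 = nef, N1 = nef)),
            class = "demography")
}

#' @rdname demography_constant
#' @export
demography_exponential <- function(n_present, n_ancient, t_start_years) {
  stopifnot(n_present > 0, n_ancient > 0, t_start_years > 0)
  structure(list(
    list(t0 = 0, t1 = t_start_years, N0 = n_present, N1 = n_ancient),
    list(t0 = t_start_years, t1 = Inf, N0 = n_ancient, N1 = n_ancient)
  ), class = "demography")
}

#' @rdname demography_constant
#' @export
demography_piecewise <- function(times, sizes) {
  if (length(sizes) != length(times) + 1L)
    stop("need one more size than breakpoints")
  if (is.unsorted(times, strictly = TRUE) || any(times <= 0))
    stop("breakpoints must be strictly increasing and positive")
  if (any(sizes <= 0)) stop("sizes must be > 0")
  bounds <- c(0, times, Inf)
  structure(lapply(seq_along(sizes), function(i)
    list(t0 = bounds[i], t1 = bounds[i + 1L],
         N0 = sizes[i], N1 = sizes[i])), class = "demography")
}

# advance time (generations) until `x` units of coalescent intensity
# (integral of dt/N) have accumulated, starting from time t
demography_advance <- function(epochs_gen, t, x) {
  for (ep in epochs_gen) {
    if (t >= ep$t1) next
    s <- max(t, ep$t0)
    if (ep$N0 == ep$N1) {
      cap <- if (is.finite(ep$t1)) (ep$t1 - s) / ep$N0 else Inf
      if (x <= cap) return(s + x * ep$N0)
      x <- x - cap
    } else {
      r <- log(ep$N1 / ep$N0) / (ep$t1 - ep$t0)
      # N(u) = N0 * exp(r (u - t0)); intensity from s to u:
      # (exp(-r(s-t0)) - exp(-r(u-t0))) / (N0 r)
      e_s <- exp(-r * (s - ep$t0))
      e_end <- exp(-r * (ep$t1 - ep$t0))
      cap <- (e_s - e_end) / (ep$N0 * r)
      if (x <= cap) {
        e_u <- e_s - x * ep$N0 * r
        return(ep$t0 - log(e_u) / r)
      }
      x <- x - cap
    }
    t <- ep$t1
  }
  stop("demography ran out of epochs")   # unreachable: last epoch is infinite
}

#' Simulation configuration
#'
#' @param n samples (>= 2).
#' @param seed mandatory RNG seed (integer).
#' @param mutation_rate mutations/site/Myr (default 0.302).
#' @param region a [region_spec()].
#' @param gamma_alpha gamma shape for site-rate heterogeneity (default 0.26;
#'   `Inf` = uniform rates).
#' @param founder_motif [motif()] carried by the clade founder.
#' @param demography a demography object.
#' @param generation_time years per generation (default 25).
#' @param ts_bias probability that a new mutation is a transition.
#' @param mask_diagnostic exclude the founder-motif and registry-diagnostic
#'   positions from the mutable site set, so classification truth stays
#'   unambiguous.
#' @param population population label given to the simulated samples.
#' @export
sim_config <- function(n, seed, mutation_rate = 0.302,
                       region = region_spec(), gamma_alpha = 0.26,
                       founder_motif = motif(),
                       demography = demography_constant(5000),
                       generation_time = 25, ts_bias = 0.95,
                       mask_diagnostic = TRUE, population = "pop1") {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory")
  if (n < 2L) stop("n must be >= 2")
  if (!inherits(demography, "demography")) stop("invalid demography")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 mutation_rate = mutation_rate, region = region,
                 gamma_alpha = gamma_alpha, founder_motif = founder_motif,
                 demography = demography,
                 generation_time = generation_time, ts_bias = ts_bias,
                 mask_diagnostic = mask_diagnostic, population = population),
            class = "sim_config")
}

#' Simulate a coalescent genealogy
#'
#' Haploid (female-line) Kingman coalescent with pair-coalescence rate 1/Nef
#' per generation and deterministic time rescaling for non-constant Nef.
#'
#' @param config a [sim_config()].
#' @return List with `tree` (ultrametric `ape::phylo`, branch lengths in
#'   years, tips `s1..sn`) and `tmrca_years`.
#' @export
simulate_genealogy <- function(config) {
  set.seed(config$seed)
  g <- config$generation_time
  epochs_gen <- lapply(config$demography, function(ep)
    list(t0 = ep$t0 / g, t1 = ep$t1 / g, N0 = ep$N0, N1 = ep$N1))
  n <- config$n
  nwk <- paste0("s", seq_len(n))
  height <- rep(0, n)          # generations
  t <- 0
  while (length(nwk) > 1L) {
    k <- length(nwk)
    x <- 2 * rexp(1) / (k * (k - 1))
    t <- demography_advance(epochs_gen, t, x)
    pair <- sample.int(k, 2L)
    a <- pair[1]; b <- pair[2]
    merged <- sprintf("(%s:%.8f,%s:%.8f)",
                      nwk[a], (t - height[a]) * g,
                      nwk[b], (t - height[b]) * g)
    keep <- setdiff(seq_len(k), pair)
    nwk <- c(nwk[keep], merged)
    height <- c(height[keep], t)
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  list(tree = tree, tmrca_years = t * g)
}

# positions used by any registry definition (kept out of the mutable set by
# default so simulated clades classify unambiguously)
registry_positions <- function(registry = default_registry()) {
  toks <- unlist(lapply(seq_len(nrow(registry)), function(i) c(
    if (nzchar(registry$cr_variants[i]))
      motif_tokens(parse_motif(registry$cr_variants[i])),
    if (nzchar(registry$coding_variants[i]))
      motif_tokens(parse_motif(registry$coding_variants[i]))
  )))
  sort(unique(token_position(toks)))
}

#' Sprinkle mutations onto a genealogy
#'
#' Finite-sites mutation with gamma-distributed site rates (shape
#' `gamma_alpha`, mean `mutation_rate`), Poisson numbers of mutations per
#' branch, and state toggling: a mutation at an already-derived site reverts
#' it. New mutations are transitions with probability `ts_bias`, otherwise a
#' random transversion.
#'
#' @param gen output of [simulate_genealogy()].
#' @param config the same [sim_config()].
#' @return List with `motifs` (tip motifs, founder variants included),
#'   `branch_mutations` (per-edge counts, in `gen$tree` edge order), and
#'   `sites` (the mutable positions used).
#' @export
sprinkle_mutations <- function(gen, config) {
  set.seed(config$seed + 1013L)
  region <- config$region
  sites <- region$positions
  if (config$mask_diagnostic) {
    masked <- union(registry_positions(), config$founder_motif$position)
    sites <- setdiff(sites, masked)
  }
  ns <- length(sites)
  rel <- if (is.finite(config$gamma_alpha))
    rgamma(ns, shape = config$gamma_alpha, rate = config$gamma_alpha)
  else rep(1, ns)
  mu_site_year <- config$mutation_rate * 1e-6
  rate <- rel * mu_site_year
  total_rate <- sum(rate)

  ref <- rcrs_reference()
  tree <- gen$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  founder_tokens <- motif_tokens(config$founder_motif)
  founder_by_pos <- setNames(founder_tokens,
                             as.character(config$founder_motif$position))

  branch_mut <- integer(nrow(tree$edge))
  tip_tokens <- vector("list", n_tip)

  toggle <- function(state, pos) {
    key <- as.character(pos)
    if (!is.na(state[key])) return(state[setdiff(names(state), key)])
    b <- substr(ref, pos, pos)
    partner <- unname(.transition_partner[b])
    tok <- if (runif(1) < config$ts_bias) {
      formatC(pos, width = 3, flag = "0")
    } else {
      paste0(formatC(pos, width = 3, flag = "0"),
             sample(setdiff(ACGT, c(b, partner)), 1L))
    }
    c(state, setNames(tok, key))
  }

  walk <- function(node, state) {
    for (e in children[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      nmut <- rpois(1L, total_rate * len)
      branch_mut[e] <<- nmut
      st <- state
      if (nmut > 0L) {
        hit <- sample.int(ns, nmut, replace = TRUE, prob = rel)
        for (h in hit) st <- toggle(st, sites[h])
      }
      if (child <= n_tip) tip_tokens[[child]] <<- unname(st)
      else walk(child, st)
    }
  }
  init <- setNames(character(0), character(0))
  walk(root, init)

  motifs <- lapply(seq_len(n_tip), function(i) {
    toks <- sort(unique(c(founder_tokens, tip_tokens[[i]])))
    parse_motif(paste(toks, collapse = "-"),
                sample_id = tree$tip.label[i],
                population = config$population)
  })
  list(motifs = motifs, branch_mutations = branch_mut, sites = sites)
}

#' Simulate a clean two-population split
#'
#' Two demes of constant size `nef` with no migration, merging into a single
#' ancestral deme of the same size `split_generations` ago.
#'
#' @param n_per_deme samples per deme.
#' @param nef female effective size of each deme and of the ancestor.
#' @param split_generations split time, generations BP.
#' @param seed RNG seed.
#' @param generation_time years per generation.
#' @return As [simulate_genealogy()], plus `populations` (named by tip).
#' @export
simulate_two_deme <- function(n_per_deme, nef, split_generations, seed,
                              generation_time = 25) {
  set.seed(seed)
  g <- generation_time
  demes <- list(
    list(nwk = paste0("a", seq_len(n_per_deme)), h = rep(0, n_per_deme)),
    list(nwk = paste0("b", seq_len(n_per_deme)), h = rep(0, n_per_deme))
  )
  # within-deme coalescence until the split
  for (d in 1:2) {
    t <- 0
    while (length(demes[[d]]$nwk) > 1L) {
      k <- length(demes[[d]]$nwk)
      w <- rexp(1, rate = k * (k - 1) / (2 * nef))
      if (t + w > split_generations) break
      t <- t + w
      pair <- sample.int(k, 2L)
      merged <- sprintf("(%s:%.8f,%s:%.8f)",
                        demes[[d]]$nwk[pair[1]],
                        (t - demes[[d]]$h[pair[1]]) * g,
                        demes[[d]]$nwk[pair[2]],
                        (t - demes[[d]]$h[pair[2]]) * g)
      keep <- setdiff(seq_len(k), pair)
      demes[[d]]$nwk <- c(demes[[d]]$nwk[keep], merged)
      demes[[d]]$h <- c(demes[[d]]$h[keep], t)
    }
  }
  nwk <- c(demes[[1]]$nwk, demes[[2]]$nwk)
  height <- c(demes[[1]]$h, demes[[2]]$h)
  t <- split_generations
  while (length(nwk) > 1L) {
    k <- length(nwk)
    t <- t + rexp(1, rate = k * (k - 1) / (2 * nef))
    pair <- sample.int(k, 2L)
    merged <- sprintf("(%s:%.8f,%s:%.8f)",
                      nwk[pair[1]], (t - height[pair[1]]) * g,
                      nwk[pair[2]], (t - height[pair[2]]) * g)
    keep <- setdiff(seq_len(k), pair)
    nwk <- c(nwk[keep], merged)
    height <- c(height[keep], t)
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  pops <- setNames(ifelse(startsWith(tree$tip.label, "a"), "deme1", "deme2"),
                   tree$tip.label)
  list(tree = tree, tmrca_years = t * g, populations = pops)
}

#' Named simulation scenarios with known truth
#'
#' Presets emulating the demographic narratives of the Southern Cone clades:
#' `"b2l-like"` (constant Nef 5,000; founder = B2 nodal + 470), `"d1g-like"`
#' (growth from 500 to 5,000 females beginning 9,000 years BP; founder = D1
#' nodal + 16187), `"c1b13-like"` (order-of-magnitude expansion from 500 to
#' 5,000 beginning 5,000 years BP; founder = C1b nodal + 258) and
#' `"two-deme"` (one population split into two isolated demes, for PhiST
#' testing). Scenario sizes are the package's own calibration of the
#' narratives; see the methods vignette.
#'
#' @param name preset name.
#' @param n samples (per deme for `"two-deme"`).
#' @param seed RNG seed.
#' @param out_dir optional directory; if given, writes `sequences.fasta`,
#'   `samples.tsv`, `genealogy.nwk` and `truth.json`.
#' @param split_generations split time for the `"two-deme"` preset.
#' @return List with `config`, `genealogy`, `motifs`, `truth` (and file
#'   paths when `out_dir` is used).
#' @export
make_scenario <- function(name = c("b2l-like", "d1g-like", "c1b13-like",
                                   "two-deme"),
                          n = 40L, seed, out_dir = NULL,
                          split_generations = 10000) {
  name <- match.arg(name)
  if (missing(seed)) stop("seed is mandatory")
  founders <- list(
    "b2l-like" = "16183C-16189-16217-073-263-315+C-499-470",
    "d1g-like" = "16223-16325-16362-073-263-315+C-489-16187",
    "c1b13-like" = paste0("16223-16298-16325-16327-073-249d-263-290d-",
                          "291d-315+C-489-493-522d-523d-258")
  )
  if (name == "two-deme") {
    gen <- simulate_two_deme(n, nef = 1000, split_generations, seed = seed)
    cfg <- sim_config(n = 2L * n, seed = seed,
                      founder_motif = motif(),
                      demography = demography_constant(1000))
    mut <- sprinkle_mutations(gen, cfg)
    motifs <- lapply(mut$motifs, function(m) {
      attr(m, "population") <- unname(gen$populations[attr(m, "sample_id")])
      m
    })
  } else {
    demo <- switch(name,
      "b2l-like" = demography_constant(5000),
      "d1g-like" = demography_exponential(5000, 500, 9000),
      "c1b13-like" = demography_exponential(5000, 500, 5000))
    cfg <- sim_config(n = n, seed = seed,
                      founder_motif = parse_motif(founders[[name]]),
                      demography = demo, population = name)
    gen <- simulate_genealogy(cfg)
    mut <- sprinkle_mutations(gen, cfg)
    motifs <- mut$motifs
  }
  truth <- list(
    scenario = name, seed = seed, n = length(motifs),
    tmrca_years = gen$tmrca_years,
    founder_motif = if (name == "two-deme") "" else founders[[name]],
    genealogy_newick = ape::write.tree(gen$tree),
    branch_mutations = mut$branch_mutations,
    demography = if (name == "two-deme")
      list(kind = "two-deme", nef = 1000,
           split_generations = split_generations)
    else lapply(cfg$demography, function(e)
      list(t0 = e$t0, t1 = e$t1, N0 = e$N0, N1 = e$N1))
  )
  out <- list(config = cfg, genealogy = gen, motifs = motifs, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ref <- rcrs_slice(cfg$region)
    seqs <- lapply(motifs, function(m) apply_motif(ref, m, cfg$region))
    ids <- vapply(motifs, function(m) attr(m, "sample_id"), "")
    fasta <- file.path(out_dir, "sequences.fasta")
    seqinr::write.fasta(lapply(seqs, function(s) strsplit(s, "")[[1]]),
                        names = ids, file.out = fasta, nbchar = 70)
    samples <- file.path(out_dir, "samples.tsv")
    write.table(data.frame(
      sample_id = ids,
      population = vapply(motifs, function(m) attr(m, "population"), "")),
      samples, sep = "\t", quote = FALSE, row.names = FALSE)
    nwk <- file.path(out_dir, "genealogy.nwk")
    ape::write.tree(gen$tree, file = nwk)
    tj <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
    out$files <- c(fasta = fasta, samples = samples, newick = nwk,
                   truth = tj)
  }
  out
}
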