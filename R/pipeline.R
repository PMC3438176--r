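#' Read a FASTA file of control-region sequences
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Read a sample table (sample_id, population)
#'
#' @param path TSV with columns `sample_id` and `population`.
#' @export
read_sample_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(tab)))
    stop("sample table needs columns sample_id and population")
  tab
}

#' Read / write a motif table (sample_id, population, motif)
#'
#' @param path TSV with columns `sample_id`, `population`, `motif`.
#' @return `read_motif_table()`: list of [motif()]s.
#' @export
read_motif_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  lapply(seq_len(nrow(tab)), function(i)
    parse_motif(tab$motif[i], sample_id = tab$sample_id[i],
                population = tab$population[i]))
}

#' @rdname read_motif_table
#' @param motifs list of motifs.
#' @export
write_motif_table <- function(motifs, path) {
  tab <- data.frame(
    sample_id = vapply(motifs, function(m) attr(m, "sample_id"), ""),
    population = vapply(motifs, function(m) attr(m, "population"), ""),
    motif = vapply(motifs, format_motif, ""),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param fasta path to the input FASTA (aligned to the region by
#'   [align_and_call()]); alternatively supply `motifs`.
#' @param sample_table path to the sample TSV (sample_id, population).
#' @param motifs optional list of pre-called [motif()]s (bypasses alignment).
#' @param out_dir output directory.
#' @param seed seed for the permutation tests.
#' @param region a [region_spec()].
#' @param registry a clade registry.
#' @param clocks clock registry, see [clock_registry()].
#' @param grouping `"by-population"` or `"by-clade"` for the diversity
#'   tables.
#' @param epsilon network tolerance.
#' @param min_clade_n smallest clade for which a network and a rho estimate
#'   are attempted.
#' @param permutations PhiST permutation count.
#' @export
run_config <- function(fasta = NULL, sample_table = NULL, motifs = NULL,
                       out_dir, seed = 1L, region = region_spec(),
                       registry = default_registry(),
                       clocks = clock_registry(),
                       grouping = c("by-population", "by-clade"),
                       epsilon = 0, min_clade_n = 3L,
                       permutations = 200L) {
  grouping <- match.arg(grouping)
  if (is.null(motifs) && (is.null(fasta) || is.null(sample_table)))
    stop("supply either motifs or fasta + sample_table")
  structure(list(fasta = fasta, sample_table = sample_table,
                 motifs = motifs, out_dir = out_dir, seed = as.integer(seed),
                 region = region, registry = registry, clocks = clocks,
                 grouping = grouping, epsilon = epsilon,
                 min_clade_n = as.integer(min_clade_n),
                 permutations = as.integer(permutations)),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full control-region workflow
#'
#' Sequences (or pre-called motifs) -> motifs -> site exclusions ->
#' haplogroup assignments and frequency table -> per-clade median-joining
#' networks (GraphML) -> rho dating table across all calibrations ->
#' per-group diversity summaries -> pairwise PhiST matrix and NJ dendrogram.
#' All outputs are plain text and byte-deterministic for a fixed seed and
#' input.
#'
#' @param config a [run_config()].
#' @return Invisible list of the in-memory results; files are written under
#'   `config$out_dir`.
#' @export
run_full <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  # -- stage: variants --------------------------------------------------
  if (!is.null(config$motifs)) {
    motifs <- config$motifs
  } else {
    seqs <- read_fasta(config$fasta)
    samples <- read_sample_table(config$sample_table)
    missing <- setdiff(samples$sample_id, names(seqs))
    if (length(missing))
      stop("variants stage: samples without sequences: ",
           paste(missing, collapse = ", "))
    motifs <- lapply(seq_len(nrow(samples)), function(i)
      align_and_call(seqs[[samples$sample_id[i]]], region = config$region,
                     sample_id = samples$sample_id[i],
                     population = samples$population[i]))
  }
  n_in <- length(motifs)
  motifs <- exclude_sites(motifs, dloop_exclusions("global"))
  stage_log("variants", "%d samples, global site exclusions applied", n_in)
  write_motif_table(motifs, out("motifs.tsv"))

  # -- stage: classify --------------------------------------------------
  assignments <- classify_all(motifs, registry = config$registry)
  n_uncl <- sum(assignments$clade == "unclassified")
  if (n_uncl > 0L)
    stage_log("classify", "warning: %d sample(s) outside the registry kept as 'unclassified'",
              n_uncl)
  stage_log("classify", "%d samples -> %d clades", nrow(assignments),
            length(unique(assignments$clade)))
  write.table(assignments, out("assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  freq <- count_by_clade(assignments)
  write.table(freq, out("clade_frequencies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # -- stage: networks + rho dating ------------------------------------
  net_motifs <- exclude_sites(motifs, dloop_exclusions("network"))
  clades <- sort(setdiff(unique(assignments$clade), "unclassified"))
  rho_list <- list(); networks <- list()
  for (cl in clades) {
    idx <- which(assignments$clade == cl)
    if (length(idx) < config$min_clade_n) next
    nodal_tokens <- unlist(lapply(clade_path(config$registry, cl),
                                  clade_tokens, registry = config$registry,
                                  mode = "control"))
    nodal <- exclude_sites(
      parse_motif(paste(sort(unique(nodal_tokens)), collapse = "-")),
      dloop_exclusions("network"))
    tab <- condense(net_motifs[idx], include = list(nodal))
    if (length(tab$haplotypes) < 2L) next
    net <- mp_postprocess(build_mj(tab, epsilon = config$epsilon))
    networks[[cl]] <- net
    export_network(net, out(paste0("network_", cl, ".graphml")), "graphml")
    rho_list[[cl]] <- rho_sigma(net, root = format_motif(nodal))
    stage_log("network", "%s: %d haplotypes, rho = %.3f", cl,
              sum(net$nodes$observed), rho_list[[cl]]$rho)
  }
  t1 <- make_table1(rho_list, clocks = config$clocks)
  write.table(t1, out("ages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # -- stage: diversity -------------------------------------------------
  groups <- if (config$grouping == "by-population")
    vapply(motifs, function(m) attr(m, "population"), "")
  else assignments$clade
  div <- do.call(rbind, lapply(sort(unique(groups)), function(gr) {
    idx <- which(groups == gr)
    if (length(idx) < 2L) return(NULL)
    summary_stats(motifs[idx], group = gr,
                  L = config$region$total_length)
  }))
  write.table(div, out("diversity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_log("diversity", "%d groups summarised", nrow(div))

  # -- stage: phist + dendrogram ---------------------------------------
  pops <- vapply(motifs, function(m) attr(m, "population"), "")
  phist <- NULL; njt <- NULL
  if (length(unique(pops)) >= 2L) {
    phist <- pairwise_phist(motifs, populations = pops,
                            permutations = config$permutations,
                            seed = config$seed, region = config$region)
    write.table(round(phist$phist, 6), out("phist_matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    if (nrow(phist$phist) >= 3L) {
      njt <- nj_tree(phist$phist)
      ape::write.tree(njt, file = out("phist_nj.nwk"))
    }
    stage_log("phist", "%d population pairs", nrow(phist$results))
  }

  # -- manifest ---------------------------------------------------------
  cfg_txt <- out("config_echo.txt")
  writeLines(c(
    sprintf("seed = %d", config$seed),
    sprintf("grouping = %s", config$grouping),
    sprintf("epsilon = %g", config$epsilon),
    sprintf("permutations = %d", config$permutations),
    sprintf("region = %s", paste(vapply(config$region$segments,
      function(s) paste0(s[1], "-", s[2]), ""), collapse = "+"))
  ), cfg_txt)
  manifest <- list(
    package = "dloopr",
    version = as.character(packageVersion("dloopr")),
    seed = config$seed,
    n_samples = n_in,
    n_unclassified = n_uncl,
    config_md5 = unname(tools::md5sum(cfg_txt))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(list(motifs = motifs, assignments = assignments, freq = freq,
                 networks = networks, rho = rho_list, ages = t1,
                 diversity = div, phist = phist, nj = njt))
}

#' Build a clade-by-calibration dating table
#'
#' Per-mutation calibrations convert rho directly. Rate-based columns are
#' computed from `base_ages` (rescaled between rates) when supplied, and from
#' rho with the rate formula otherwise.
#'
#' @param rho_list named list of [rho_sigma()] results (one per clade).
#' @param clocks clock registry.
#' @param base_ages optional named numeric vector of ages (years BP) per
#'   clade under `base_clock`, used for rescaling mode.
#' @param base_clock name of the calibration `base_ages` refer to.
#' @return `data.frame` with one row per clade and one age column per
#'   calibration.
#' @export
make_table1 <- function(rho_list, clocks = clock_registry(),
                        base_ages = NULL, base_clock = "endicott") {
  cols <- names(clocks)
  if (length(rho_list) == 0L && is.null(base_ages))
    return(setNames(
      data.frame(matrix(nrow = 0L, ncol = length(cols) + 2L)),
      c("clade", "rho", cols)))
  clades <- if (length(rho_list)) names(rho_list) else names(base_ages)
  rows <- lapply(clades, function(cl) {
    est <- rho_list[[cl]]
    ages <- vapply(cols, function(cn) {
      cal <- clocks[[cn]]
      if (is.null(cal)) stop("missing calibration: ", cn)
      if (cal$mode == "rate" && !is.null(base_ages)) {
        if (is.null(clocks[[base_clock]]))
          stop("missing calibration: ", base_clock)
        rescale_age(base_ages[[cl]], clocks[[base_clock]]$rate, cal$rate)
      } else if (!is.null(est)) {
        rho_to_age(est$rho, cal)$age_years
      } else NA_real_
    }, 0)
    cbind(data.frame(clade = cl,
                     rho = if (is.null(est)) NA_real_ else est$rho),
          as.data.frame(as.list(ages)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
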