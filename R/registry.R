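#' Default clade registry
#'
#' The classification tree used throughout the package, encoded as one row per
#' clade: `name`, `parent` (empty string for clades hanging directly off the
#' reference root), `cr_variants` (hyphen-joined control-region motif),
#' `coding_variants` (coding-region diagnostics, only used in `with-coding`
#' mode) and `provisional`.
#'
#' Nodal motifs: D1 `16223-16325-16362-073-263-315+C-489` with D1g adding
#' `16187`; D1g1/D1g2 are coding-defined nested clades of D1g (8116, and
#' 10202/10724/13020); B2 `16183C-16189-16217-073-263-315+C-499` with the
#' Patagonian B2l adding `470`, plus the two Andean clusters B2+16188 and
#' B2+146-215-455+T; C1b `16223-16298-16325-16327-073-249d-263-290d-291d-
#' 315+C-489-493-522d-523d` with C1b13 adding `258`; D4h3a `16241-16342` with
#' D4h3a5 adding `16051`. A2, C1c, C1d and C1d1e are provisional placeholders
#' with conventional control-region diagnostics.
#'
#' @return A `data.frame` of class `clade_registry`.
#' @export
default_registry <- function() {
  rows <- rbind(
    c("D1",      "",      "16223-16325-16362-073-263-315+C-489", "", FALSE),
    c("D1g",     "D1",    "16187",                               "", FALSE),
    c("D1g1",    "D1g",   "",                     "8116",            FALSE),
    c("D1g2",    "D1g",   "",                     "10202-10724-13020", FALSE),
    c("D4h3a",   "",      "16241-16342",                         "", FALSE),
    c("D4h3a5",  "D4h3a", "16051",                               "", FALSE),
    c("B2",      "",      "16183C-16189-16217-073-263-315+C-499", "", FALSE),
    c("B2l",     "B2",    "470",                                 "", FALSE),
    c("B2-16188", "B2",   "16188",                               "", FALSE),
    c("B2-455T", "B2",    "146-215-455+T",                       "", FALSE),
    c("C1b",     "",
      "16223-16298-16325-16327-073-249d-263-290d-291d-315+C-489-493-522d-523d",
      "", FALSE),
    c("C1b13",   "C1b",   "258",                                 "", FALSE),
    c("A2",      "",
      "16111-16223-16290-16319-16362-073-235-263-315+C",         "", TRUE),
    c("C1c",     "",
      "16223-16298-16325-16327-073-249d-263-290d-291d-315+C-489-493",
      "1888", TRUE),
    c("C1d",     "",
      "16051-16223-16298-16325-16327-073-249d-263-290d-291d-315+C-489",
      "", TRUE),
    c("C1d1e",   "C1d",   "194",                                 "", TRUE)
  )
  reg <- data.frame(name = rows[, 1], parent = rows[, 2],
                    cr_variants = rows[, 3], coding_variants = rows[, 4],
                    provisional = as.logical(rows[, 5]),
                    stringsAsFactors = FALSE)
  validate_registry(reg)
}

validate_registry <- function(reg) {
  stopifnot(all(c("name", "parent", "cr_variants", "coding_variants")
                %in% names(reg)))
  if (!"provisional" %in% names(reg)) reg$provisional <- FALSE
  if (anyDuplicated(reg$name)) stop("duplicate clade names in registry")
  bad <- reg$parent != "" & !(reg$parent %in% reg$name)
  if (any(bad)) stop("unknown parent clade: ",
                     paste(reg$parent[bad], collapse = ", "))
  # acyclic parent chains + non-empty definitions
  for (i in seq_len(nrow(reg))) {
    if (!nzchar(reg$cr_variants[i]) && !nzchar(reg$coding_variants[i]))
      stop("clade '", reg$name[i], "' has no defining variants")
    seen <- character(); cur <- reg$name[i]
    while (nzchar(cur)) {
      if (cur %in% seen) stop("cycle in registry parent chain at ", cur)
      seen <- c(seen, cur)
      cur <- reg$parent[match(cur, reg$name)]
    }
  }
  class(reg) <- c("clade_registry", "data.frame")
  reg
}

#' Read / write a clade registry as a plain-text table
#'
#' @param path TSV file with columns name, parent, cr_variants,
#'   coding_variants and optionally provisional.
#' @export
read_registry <- function(path) {
  validate_registry(read.delim(path, stringsAsFactors = FALSE,
                               na.strings = NULL))
}

#' @rdname read_registry
#' @param registry a `clade_registry`.
#' @export
write_registry <- function(registry, path) {
  write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ancestors first, clade last
clade_path <- function(registry, clade) {
  path <- character(); cur <- clade
  while (nzchar(cur)) {
    path <- c(cur, path)
    cur <- registry$parent[match(cur, registry$name)]
  }
  path
}

# token sets of the defining variants of one clade, by mode
clade_tokens <- function(registry, clade, mode) {
  i <- match(clade, registry$name)
  toks <- character()
  if (nzchar(registry$cr_variants[i]))
    toks <- motif_tokens(parse_motif(registry$cr_variants[i]))
  if (mode == "with-coding" && nzchar(registry$coding_variants[i]))
    toks <- c(toks, motif_tokens(parse_motif(registry$coding_variants[i])))
  toks
}

#' Assign a motif to a haplogroup
#'
#' Walks the registry tree from the root towards the leaves. A clade is
#' entered when the number of its defining variants missing from the motif,
#' accumulated along the whole path, does not exceed `tolerance` (default 1,
#' absorbing one private back mutation). Among admissible clades the winner
#' maximises the matched-variant count, then minimises the missing count,
#' then maximises depth: a deeper clade is only preferred when the motif
#' actually carries its extra diagnostics, so a nodal haplotype never falls
#' into a tolerant subclade. Remaining ties are broken alphabetically with
#' `ambiguous = TRUE`. In `control-region-only` mode coding diagnostics are
#' ignored and purely coding-defined clades (D1g1, D1g2) are not assignable.
#'
#' @param m a [motif()] (rCRS coordinates).
#' @param registry a clade registry, see [default_registry()].
#' @param mode `"control"` or `"with-coding"`.
#' @param tolerance maximum defining variants allowed missing along the path.
#' @return A one-row `data.frame`: `sample_id`, `clade`, `score`, `missing`,
#'   `private`, `ambiguous`.
#' @export
classify <- function(m, registry = default_registry(),
                     mode = c("control", "with-coding"), tolerance = 1L) {
  mode <- match.arg(mode)
  toks <- motif_tokens(m)
  best <- list(clade = "unclassified", depth = 0L, score = 0L,
               missing = 0L, path_tokens = character(), ties = character())

  recurse <- function(clade, depth, miss_so_far, path_tokens) {
    defining <- setdiff(clade_tokens(registry, clade, mode), path_tokens)
    if (length(defining) == 0L && depth > 0L) return()  # not assignable here
    miss <- sum(!(defining %in% toks))
    total_miss <- miss_so_far + miss
    if (total_miss > tolerance) return()
    new_path <- c(path_tokens, defining)
    score <- sum(new_path %in% toks)
    cmp <- if (score != best$score) sign(score - best$score)
      else if (total_miss != best$missing) sign(best$missing - total_miss)
      else sign(depth - best$depth)
    if (cmp > 0) {
      best <<- list(clade = clade, depth = depth, score = score,
                    missing = total_miss, path_tokens = new_path,
                    ties = character())
    } else if (cmp == 0 && best$clade != "unclassified") {
      best$ties <<- c(best$ties, clade)
    }
    for (child in registry$name[registry$parent == clade])
      recurse(child, depth + 1L, total_miss, new_path)
  }
  for (root in registry$name[registry$parent == ""])
    recurse(root, 1L, 0L, character())

  ambiguous <- length(best$ties) > 0L
  clade <- best$clade
  if (ambiguous) clade <- sort(c(clade, best$ties))[1]
  data.frame(
    sample_id = attr(m, "sample_id") %||% NA_character_,
    population = attr(m, "population") %||% NA_character_,
    clade = clade,
    score = best$score,
    missing = best$missing,
    private = sum(!(toks %in% best$path_tokens)),
    ambiguous = ambiguous,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a list of motifs
#'
#' @param motifs list of [motif()]s.
#' @inheritParams classify
#' @return A `data.frame` with one row per motif.
#' @export
classify_all <- function(motifs, registry = default_registry(),
                         mode = c("control", "with-coding"), tolerance = 1L) {
  mode <- match.arg(mode)
  do.call(rbind, lapply(motifs, classify, registry = registry, mode = mode,
                        tolerance = tolerance))
}

#' Haplogroup frequency table per population
#'
#' @param assignments output of [classify_all()] (must carry populations).
#' @return Long `data.frame`: population, clade, n, pct (within-population
#'   percentage rounded to the nearest integer), total.
#' @export
count_by_clade <- function(assignments) {
  if (anyNA(assignments$population))
    stop("every assignment must carry a population")
  tab <- as.data.frame(table(population = assignments$population,
                             clade = assignments$clade),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0L, , drop = FALSE]
  tot <- tapply(assignments$population, assignments$population, length)
  tab$total <- as.integer(tot[tab$population])
  tab$pct <- round_half_up(100 * tab$n / tab$total)
  tab <- tab[order(tab$population, -tab$n, tab$clade), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Count samples assigned to a clade or any of its subclades
#'
#' @param assignments output of [classify_all()].
#' @param registry the registry used for classification.
#' @param clade ancestor clade name.
#' @export
count_in_clade <- function(assignments, registry, clade) {
  in_clade <- vapply(assignments$clade, function(cl) {
    cl != "unclassified" && clade %in% clade_path(registry, cl)
  }, logical(1))
  sum(in_clade)
}

round_half_up <- function(x) floor(x + 0.5)
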