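#' Primer pair constructor
#'
#' @param name assay name.
#' @param forward,reverse primer sequences, 5' to 3'.
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 15L || nchar(reverse) < 15L)
    stop("primers must be at least 15 nt")
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' The 8116 SmaI typing assay primers
#'
#' Amplifies a 275-bp product around coding position 8116; the A8116G
#' transition creates a SmaI site (CCCGGG) so derived alleles are cut.
#' @export
primers_8116 <- function() {
  primer_pair("8116-SmaI",
              forward = "TGAAGCCCCCATTCGTATAA",
              reverse = "GTGGGCTCTAGAGGGGGTAG")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
        collapse = "")
}

find_all <- function(needle, haystack) {
  hits <- gregexpr(needle, haystack, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

#' Predict a PCR amplicon by exact primer matching
#'
#' The forward primer must match the template sense strand exactly once and
#' the reverse complement of the reverse primer exactly once, downstream. The
#' product runs from the 5' end of the forward site to the 5' end of the
#' reverse site (both primers included).
#'
#' @param template template sequence (sense strand).
#' @param primers a [primer_pair()].
#' @return List with `product`, `length`, `start`, `end` (1-based template
#'   coordinates).
#' @export
predict_amplicon <- function(template, primers) {
  template <- toupper(template)
  f_hits <- find_all(primers$forward, template)
  r_hits <- find_all(revcomp(primers$reverse), template)
  if (length(f_hits) != 1L || length(r_hits) != 1L)
    stop(sprintf(
      "primer binding must be unique: forward matched %d time(s), reverse matched %d time(s)",
      length(f_hits), length(r_hits)))
  start <- f_hits[1]
  end <- r_hits[1] + nchar(primers$reverse) - 1L
  if (end <= start)
    stop("reverse primer site is not downstream of the forward site")
  product <- substr(template, start, end)
  list(product = product, length = nchar(product), start = start, end = end)
}

#' In-silico restriction digest
#'
#' Cuts a product at every occurrence of a fixed recognition word, at a blunt
#' offset within the site (SmaI CCC^GGG: offset 3).
#'
#' @param product sequence to digest.
#' @param recognition recognition site (default SmaI, `CCCGGG`).
#' @param cut_offset cut position within the site (bases 5' of the cut).
#' @return Integer vector of ordered fragment lengths; always sums to
#'   `nchar(product)`.
#' @export
digest <- function(product, recognition = "CCCGGG", cut_offset = 3L) {
  product <- toupper(product)
  sites <- find_all(toupper(recognition), product)
  if (length(sites) == 0L) return(nchar(product))
  cuts <- sort(sites + cut_offset - 1L)   # last base of left fragment
  bounds <- c(0L, cuts, nchar(product))
  diff(bounds)
}
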