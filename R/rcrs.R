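#' @importFrom stats setNames rexp runif rgamma rpois
#' @importFrom utils read.delim write.table packageVersion
NULL

# package-local cache (reference sequence, parsed registries)
.dloopr_cache <- new.env(parent = emptyenv())

RCRS_LENGTH <- 16569L

# Watson-Crick transition partners
.transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Synthetic rCRS-like mitochondrial reference
#'
#' Returns a full-length (16,569 bp) human mitochondrial reference sequence in
#' rCRS coordinates. The true revised Cambridge Reference Sequence cannot be
#' redistributed here, so this is a *synthetic* stand-in built deterministically
#' from the older public human mtDNA reference bundled with the seqinr package
#' (NC_001807.4): the homopolymer runs at 303-315 and 16183-16193 are
#' normalised to the canonical rCRS structure, the placeholder N at 3107 is
#' inserted so coordinates match rCRS numbering exactly, and every position the
#' package's clade registry, variant notation or PCR/RFLP logic relies on is
#' patched to its documented rCRS state. Positions not touched by any of these
#' may differ from the true rCRS; all motif arithmetic in this package is
#' relative, so only the patched landmark positions matter.
#'
#' @return A single upper-case character string of length 16,569.
#' @export
rcrs_reference <- function() {
  if (!is.null(.dloopr_cache$rcrs)) return(.dloopr_cache$rcrs)
  fa <- system.file("sequences", "humanMito.fasta", package = "seqinr")
  if (fa == "") stop("seqinr reference scaffold not found")
  scaffold <- toupper(paste(seqinr::getSequence(
    seqinr::read.fasta(fa, seqtype = "DNA", as.string = TRUE)[[1]],
    as.string = TRUE
  ), collapse = ""))
  x <- strsplit(scaffold, "")[[1]]
  if (length(x) != 16571L) stop("unexpected scaffold length: ", length(x))

  # Edits applied from high to low coordinate (file coordinates of NC_001807.4).
  # 1. 16183 homopolymer: file 16184..16195 (12 C) -> rCRS 16183..16193
  #    "A CCCCC T CCCC" (restores 16183A/16189T, removes one surplus base).
  if (!all(x[16184:16195] == "C")) stop("scaffold 16184-16195 not a C-run")
  x <- c(x[1:16183], strsplit("ACCCCCTCCCC", "")[[1]], x[16196:length(x)])
  # 2. placeholder N at rCRS 3107 (file coordinate 3109 while the upstream
  #    C-run still carries its two extra bases).
  x <- c(x[1:3108], "N", x[3109:length(x)])
  # 3. 303-315 C-run: file 303..317 (8C,T,6C) -> rCRS "7C,T,5C".
  if (!identical(paste(x[303:317], collapse = ""), "CCCCCCCCTCCCCCC"))
    stop("scaffold 303-317 unexpected")
  x <- c(x[1:302], strsplit("CCCCCCCTCCCCC", "")[[1]], x[318:length(x)])
  if (length(x) != RCRS_LENGTH) stop("reference normalisation failed")

  # Landmark substitutions: rCRS state implied by the standard variant
  # notation (a token like "C16187T" or a bare transition "470" fixes the
  # reference base at that position).
  landmarks <- c(
    `73` = "A", `146` = "T", `152` = "T", `194` = "C", `215` = "A",
    `235` = "A", `249` = "A", `258` = "C", `263` = "A", `290` = "A",
    `291` = "A", `310` = "T", `470` = "A", `489` = "T", `493` = "A",
    `499` = "G", `522` = "C", `523` = "A",
    `16051` = "A", `16111` = "C", `16182` = "A", `16183` = "A",
    `16187` = "C", `16188` = "C", `16189` = "T", `16217` = "T",
    `16223` = "C", `16241` = "A", `16290` = "C", `16298` = "T",
    `16319` = "G", `16325` = "T", `16327` = "C", `16342` = "T",
    `16356` = "T", `16362` = "T", `16519` = "T"
  )
  x[as.integer(names(landmarks))] <- unname(landmarks)

  ref <- paste(x, collapse = "")
  # sanity: the 8116 SmaI logic must hold on the assembled reference
  if (substr(ref, 8111, 8116) != "CCCGGA")
    stop("reference assembly failed at the 8111-8116 SmaI context")
  .dloopr_cache$rcrs <- ref
  ref
}

#' Control-region specification
#'
#' A region is a list of non-overlapping 1-based inclusive rCRS segments. The
#' default is the common two-segment survey layout: HVS1 16032-16544 followed
#' by 51-555 (513 + 505 = 1018 bp). `total_length` is always the computed sum
#' of segment lengths.
#'
#' @param segments list of length-2 integer vectors `c(start, end)`.
#' @return An object of class `region_spec` with elements `segments`,
#'   `total_length` and `positions` (the rCRS coordinate of every slice base).
#' @export
region_spec <- function(segments = list(c(16032L, 16544L), c(51L, 555L))) {
  segs <- lapply(segments, function(s) {
    s <- as.integer(s)
    if (length(s) != 2L || anyNA(s) || s[1] > s[2])
      stop("each segment must be c(start, end) with start <= end")
    if (s[1] < 1L || s[2] > RCRS_LENGTH)
      stop("segment outside 1..", RCRS_LENGTH)
    s
  })
  pos <- unlist(lapply(segs, function(s) seq.int(s[1], s[2])))
  if (anyDuplicated(pos)) stop("region segments overlap")
  structure(
    list(segments = segs, total_length = length(pos), positions = pos),
    class = "region_spec"
  )
}

#' @export
print.region_spec <- function(x, ...) {
  segs <- vapply(x$segments, function(s) paste0(s[1], "-", s[2]), "")
  cat("rCRS region:", paste(segs, collapse = " + "),
      sprintf("(%d bp)\n", x$total_length))
  invisible(x)
}

#' Extract the reference slice covered by a region
#'
#' @param region a [region_spec()].
#' @param reference full-length reference string; defaults to
#'   [rcrs_reference()].
#' @return Character string of length `region$total_length`.
#' @export
rcrs_slice <- function(region = region_spec(), reference = rcrs_reference()) {
  chars <- strsplit(reference, "")[[1]]
  paste(chars[region$positions], collapse = "")
}

# rCRS position -> 1-based slice offset (NA outside the region)
position_to_slice <- function(positions, region) {
  match(as.integer(positions), region$positions)
}

# 1-based slice offset -> rCRS position
slice_to_position <- function(idx, region) {
  region$positions[idx]
}

#' @rdname rcrs_slice
#' @param positions integer rCRS positions.
#' @return `position_in_region()`: logical vector.
#' @export
position_in_region <- function(positions, region = region_spec()) {
  !is.na(position_to_slice(positions, region))
}
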