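ACGT <- c("A", "C", "G", "T")

#' Align a sample sequence to the reference region and call its motif
#'
#' Performs a global pairwise alignment (match +1, mismatch -1, gap open -5,
#' gap extend -2) of the sample against the reference slice of `region`, then
#' extracts the column-wise differences as a motif. Indels are canonicalised to
#' their 3'-most equivalent placement on the forward strand (the forensic
#' convention), and coordinates are mapped back to rCRS numbering across the
#' region segments. IUPAC ambiguity codes are treated as missing data: no
#' variant is called at those columns.
#'
#' @param sample character string (IUPAC DNA).
#' @param reference reference slice for `region`; defaults to the packaged
#'   reference.
#' @param region a [region_spec()].
#' @param min_identity minimum percent identity below which the input is
#'   rejected as not being a control-region sequence.
#' @inheritParams motif
#' @return A [motif()].
#' @export
align_and_call <- function(sample, reference = NULL, region = region_spec(),
                           min_identity = 70, sample_id = NA_character_,
                           population = NA_character_) {
  if (is.null(reference)) reference <- rcrs_slice(region)
  sample <- toupper(gsub("[^A-Za-z]", "", sample))
  if (!nzchar(sample) || !nzchar(reference))
    stop("sample and reference must be non-empty")
  if (nchar(reference) != region$total_length)
    stop("reference length does not match the region")

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = sample, subject = reference, type = "global",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
  if (Biostrings::pid(aln) < min_identity)
    stop("not a control-region sequence (identity ",
         round(Biostrings::pid(aln), 1), "% < ", min_identity, "%)")

  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refchars <- strsplit(reference, "")[[1]]
  L <- length(refchars)

  subs <- list(); ins <- list(); dels <- list()
  i <- 1L; refidx <- 0L; n <- length(p)
  while (i <= n) {
    a <- p[i]; b <- s[i]
    if (b != "-" && a != "-") {
      refidx <- refidx + 1L
      if (a != b && a %in% ACGT && b %in% ACGT)
        subs[[length(subs) + 1L]] <- list(idx = refidx, alt = a)
      i <- i + 1L
    } else if (b == "-") {
      j <- i
      while (j <= n && s[j] == "-") j <- j + 1L
      string <- paste(p[i:(j - 1L)], collapse = "")
      if (refidx > 0L && grepl("^[ACGT]+$", string))
        ins[[length(ins) + 1L]] <- list(idx = refidx, string = string)
      i <- j
    } else {
      j <- i
      while (j <= n && p[j] == "-" && s[j] != "-") j <- j + 1L
      len <- j - i
      dels[[length(dels) + 1L]] <- list(from = refidx + 1L,
                                        to = refidx + len)
      refidx <- refidx + len
      i <- j
    }
  }

  vars <- list()
  for (sb in subs) {
    pos <- slice_to_position(sb$idx, region)
    rb <- refchars[sb$idx]
    kind <- if (identical(unname(.transition_partner[rb]), sb$alt))
      "transition" else "transversion"
    vars[[length(vars) + 1L]] <- parse_variant(
      paste0(rb, pos, sb$alt))
  }
  for (iv in ins) {
    idx <- iv$idx; string <- iv$string
    # 3'-most equivalent placement: slide right through equal bases
    while (idx + 1L <= L && refchars[idx + 1L] == substr(string, 1L, 1L)) {
      string <- paste0(substring(string, 2L), substr(string, 1L, 1L))
      idx <- idx + 1L
    }
    vars[[length(vars) + 1L]] <- parse_variant(
      paste0(slice_to_position(idx, region), "+", string))
  }
  for (dv in dels) {
    from <- dv$from; to <- dv$to
    while (to + 1L <= L && refchars[from] == refchars[to + 1L]) {
      from <- from + 1L; to <- to + 1L
    }
    for (k in from:to)
      vars[[length(vars) + 1L]] <- parse_variant(
        paste0(slice_to_position(k, region), "d"))
  }
  motif(vars, sample_id = sample_id, population = population)
}

#' Apply a motif to the reference region
#'
#' Inverse of [align_and_call()]: mutates the reference slice according to the
#' motif. For any indel-free motif, and for indel motifs already in canonical
#' 3' placement, `align_and_call(apply_motif(ref, m), ref)` recovers `m`.
#' Variants flagged as reverted (`@`) restore the reference state and are
#' skipped.
#'
#' @param reference reference slice (defaults to the packaged reference).
#' @param m a [motif()].
#' @param region a [region_spec()].
#' @return Mutated sequence string.
#' @export
apply_motif <- function(reference = NULL, m, region = region_spec()) {
  if (is.null(reference)) reference <- rcrs_slice(region)
  if (nchar(reference) != region$total_length)
    stop("reference length does not match the region")
  chars <- strsplit(reference, "")[[1]]
  append_after <- rep("", length(chars))
  m <- m[!m$reverted, , drop = FALSE]
  if (nrow(m)) {
    idx <- position_to_slice(m$position, region)
    if (anyNA(idx))
      stop("motif position(s) outside region: ",
           paste(m$position[is.na(idx)], collapse = ", "))
    for (i in seq_len(nrow(m))) {
      k <- idx[i]
      switch(m$kind[i],
        transition   = { chars[k] <- m$derived[i] },
        transversion = { chars[k] <- m$derived[i] },
        deletion     = { chars[k] <- "" },
        insertion    = {
          append_after[k] <- paste0(append_after[k], m$derived[i])
        })
    }
  }
  paste(paste0(chars, append_after), collapse = "")
}
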