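#' Parse a variant token in forensic mtDNA notation
#'
#' Understands the usual control-region dialect relative to the rCRS:
#' `"C16187T"` (reference + position + derived), `"16183C"` (position +
#' derived), bare `"073"` (transition at that position), `"315+C"` /
#' `"309+CC"` (insertions), `"249d"` (deletion), and an `"@"` prefix marking a
#' back mutation (reversion). Leading zeros are allowed. For bare tokens the
#' derived base is the Watson-Crick transition partner of the reference base.
#'
#' @param token a single character token.
#' @param reference full-length reference, used to infer transition partners.
#' @return A one-row `data.frame` of class `dloop_variant` with columns
#'   `position`, `kind`, `derived`, `insert_index`, `reverted`.
#' @export
parse_variant <- function(token, reference = rcrs_reference()) {
  if (length(token) != 1L || !nzchar(token))
    stop("malformed variant token: ", deparse(token))
  raw <- token
  reverted <- startsWith(token, "@")
  if (reverted) token <- substring(token, 2L)
  token <- toupper(token)

  new_var <- function(position, kind, derived, insert_index = 1L) {
    if (position < 1L || position > RCRS_LENGTH)
      stop("position outside 1..", RCRS_LENGTH, " in token: ", raw)
    structure(
      data.frame(position = as.integer(position), kind = kind,
                 derived = derived, insert_index = as.integer(insert_index),
                 reverted = reverted, stringsAsFactors = FALSE),
      class = c("dloop_variant", "data.frame")
    )
  }
  ref_base <- function(pos) {
    if (is.na(pos) || pos < 1L || pos > RCRS_LENGTH)
      stop("position outside 1..", RCRS_LENGTH, " in token: ", raw)
    substr(reference, pos, pos)
  }

  if (grepl("^[0-9]+D$", token)) {                     # deletion "249d"
    return(new_var(as.integer(sub("D$", "", token)), "deletion", ""))
  }
  if (grepl("^[0-9]+\\+[ACGT]+$", token)) {            # insertion "315+C"
    parts <- strsplit(token, "\\+")[[1]]
    return(new_var(as.integer(parts[1]), "insertion", parts[2]))
  }
  if (grepl("^[ACGT][0-9]+[ACGT]$", token)) {          # "C16187T"
    pos <- as.integer(gsub("[ACGT]", "", token))
    ref <- substr(token, 1L, 1L)
    alt <- substr(token, nchar(token), nchar(token))
    kind <- if (identical(unname(.transition_partner[ref]), alt))
      "transition" else "transversion"
    return(new_var(pos, kind, alt))
  }
  if (grepl("^[0-9]+[ACGT]$", token)) {                # "16183C"
    pos <- as.integer(sub("[ACGT]$", "", token))
    alt <- substr(token, nchar(token), nchar(token))
    rb <- ref_base(pos)
    kind <- if (identical(unname(.transition_partner[rb]), alt))
      "transition" else "transversion"
    return(new_var(pos, kind, alt))
  }
  if (grepl("^[0-9]+$", token)) {                      # bare transition "073"
    pos <- as.integer(token)
    rb <- ref_base(pos)
    if (!rb %in% names(.transition_partner))
      stop("no transition partner for reference base '", rb,
           "' at ", pos, " in token: ", raw)
    return(new_var(pos, "transition", unname(.transition_partner[rb])))
  }
  stop("malformed variant token: ", raw)
}

#' Format a variant back into its canonical token
#'
#' Inverse of [parse_variant()]: transitions print as the bare position
#' (zero-padded to three digits), transversions as position + derived base,
#' insertions as `pos+BASES`, deletions as `posd`, reversions with an `@`
#' prefix.
#'
#' @param v a `dloop_variant` (or one row of a motif).
#' @return Character token.
#' @export
format_variant <- function(v) {
  pos <- formatC(v$position, width = 3, flag = "0")
  body <- switch(v$kind,
    transition   = pos,
    transversion = paste0(pos, v$derived),
    insertion    = paste0(pos, "+", v$derived),
    deletion     = paste0(pos, "d"),
    stop("unknown variant kind: ", v$kind)
  )
  if (isTRUE(v$reverted)) paste0("@", body) else body
}

#' Construct a motif (set of rCRS-relative variants)
#'
#' @param variants a list of `dloop_variant`s, a `data.frame` with the variant
#'   columns, or `NULL` for the empty (reference) motif.
#' @param sample_id,population optional identifiers carried as attributes.
#' @return A `data.frame` of class `dloop_motif`, canonically sorted by
#'   position, insertion index and kind.
#' @export
motif <- function(variants = NULL, sample_id = NA_character_,
                  population = NA_character_) {
  if (is.null(variants) || (is.list(variants) && length(variants) == 0L)) {
    df <- data.frame(position = integer(), kind = character(),
                     derived = character(), insert_index = integer(),
                     reverted = logical(), stringsAsFactors = FALSE)
  } else if (is.data.frame(variants)) {
    df <- as.data.frame(variants)[, c("position", "kind", "derived",
                                      "insert_index", "reverted")]
  } else {
    df <- do.call(rbind, lapply(variants, as.data.frame))
  }
  df <- df[order(df$position, df$insert_index, df$kind, df$derived), ,
           drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$position, df$kind, df$insert_index)
  if (anyDuplicated(key))
    stop("motif contains two variants sharing (position, kind, insert_index)")
  structure(df, class = c("dloop_motif", "data.frame"),
            sample_id = sample_id, population = population)
}

#' Parse a hyphen-joined motif string
#'
#' @param x motif string such as `"073-263-315+C-489"`; `""` gives the empty
#'   motif.
#' @inheritParams parse_variant
#' @inheritParams motif
#' @export
parse_motif <- function(x, reference = rcrs_reference(),
                        sample_id = NA_character_,
                        population = NA_character_) {
  x <- trimws(x)
  if (is.na(x) || !nzchar(x))
    return(motif(NULL, sample_id = sample_id, population = population))
  tokens <- strsplit(x, "-", fixed = TRUE)[[1]]
  motif(lapply(tokens, parse_variant, reference = reference),
        sample_id = sample_id, population = population)
}

#' Print a motif as its canonical hyphen-joined string
#'
#' Round-trips through [parse_motif()].
#' @param m a `dloop_motif`.
#' @export
format_motif <- function(m) {
  if (nrow(m) == 0L) return("")
  paste(vapply(seq_len(nrow(m)), function(i) format_variant(m[i, ]), ""),
        collapse = "-")
}

#' @export
print.dloop_motif <- function(x, ...) {
  id <- attr(x, "sample_id")
  cat(if (!is.na(id)) paste0(id, ": ") else "",
      if (nrow(x)) format_motif(x) else "(reference)", "\n", sep = "")
  invisible(x)
}

# canonical token vector of a motif (used all over the network code)
motif_tokens <- function(m) {
  if (nrow(m) == 0L) return(character())
  vapply(seq_len(nrow(m)), function(i) format_variant(m[i, ]), "")
}

#' Standard site-exclusion lists
#'
#' `"global"` removes the common-length variation of the 309 poly-C tract
#' (309+C, 309+CC) from all analyses; `"network"` additionally removes the
#' hypervariable positions 16519 and 152 before network building.
#'
#' @param set `"global"` or `"network"`.
#' @return Character vector of exclusion tokens; bare numbers exclude every
#'   variant at that position, structured tokens exclude that exact variant.
#' @export
dloop_exclusions <- function(set = c("global", "network")) {
  set <- match.arg(set)
  base <- c("309+C", "309+CC")
  if (set == "network") c(base, "16519", "152") else base
}

#' Remove excluded sites from motifs
#'
#' @param motifs a single motif or a list of motifs.
#' @param excluded exclusion tokens, see [dloop_exclusions()].
#' @return Object of the same shape with matching variants removed; inputs are
#'   not modified.
#' @export
exclude_sites <- function(motifs, excluded = dloop_exclusions("global")) {
  single <- inherits(motifs, "dloop_motif")
  if (single) motifs <- list(motifs)
  pos_only <- grepl("^[0-9]+$", excluded)
  drop_pos <- as.integer(excluded[pos_only])
  exact <- excluded[!pos_only]
  exact_keys <- if (length(exact)) vapply(exact, function(tok) {
    v <- parse_variant(tok)
    paste(v$position, v$kind, v$derived)
  }, "") else character()
  out <- lapply(motifs, function(m) {
    if (nrow(m) == 0L) return(m)
    keys <- paste(m$position, m$kind, m$derived)
    keep <- !(m$position %in% drop_pos) & !(keys %in% exact_keys)
    motif(m[keep, , drop = FALSE],
          sample_id = attr(m, "sample_id"),
          population = attr(m, "population"))
  })
  if (single) out[[1]] else out
}
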