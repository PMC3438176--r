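reg <- default_registry()

path_motif <- function(clade, mode = "control") {
  toks <- unlist(lapply(dloopr:::clade_path(reg, clade),
                        dloopr:::clade_tokens, registry = reg, mode = mode))
  parse_motif(paste(sort(unique(toks)), collapse = "-"))
}

test_that("registry entries are well-formed and look up correctly", {
  expect_s3_class(reg, "clade_registry")
  expect_equal(reg$parent[reg$name == "D1g"], "D1")
  expect_equal(reg$cr_variants[reg$name == "D1g"], "16187")
  expect_equal(reg$parent[reg$name == "B2l"], "B2")
  expect_equal(reg$cr_variants[reg$name == "B2l"], "470")
  expect_equal(reg$parent[reg$name == "C1b13"], "C1b")
  expect_equal(reg$cr_variants[reg$name == "C1b13"], "258")
  expect_error(validate_registry_roundtrip <- read_registry(
    write_registry(reg, file.path(tempdir(), "reg.tsv"))), NA)
  expect_equal(validate_registry_roundtrip$name, reg$name)
})

test_that("every clade's own path motif classifies to that clade", {
  assignable <- reg$name[nzchar(reg$cr_variants)]
  for (cl in assignable) {
    m <- path_motif(cl)
    a <- classify(m, reg)
    expect_equal(a$clade, cl)
    expect_equal(a$missing, 0L)
    expect_equal(a$private, 0L)
    expect_equal(a$score, nrow(m))
  }
})

test_that("the published nodal motifs classify as printed", {
  expect_equal(classify(parse_motif(
    "16223-16325-16362-073-263-315+C-489-16187"), reg)$clade, "D1g")
  expect_equal(classify(parse_motif(
    "16183C-16189-16217-073-263-315+C-499-470"), reg)$clade, "B2l")
  expect_equal(classify(parse_motif(
    paste0("16223-16298-16325-16327-073-249d-263-290d-291d-",
           "315+C-489-493-522d-523d-258")), reg)$clade, "C1b13")
  expect_equal(classify(parse_motif("16241-16342-16051"), reg)$clade,
               "D4h3a5")
  expect_equal(classify(motif(), reg)$clade, "unclassified")
})

test_that("coding-defined subclades need with-coding mode", {
  m_cr <- path_motif("D1g")
  m_coding <- parse_motif(paste0(format_motif(m_cr), "-8116"))
  expect_equal(classify(m_coding, reg, mode = "control")$clade, "D1g")
  expect_equal(classify(m_coding, reg, mode = "with-coding")$clade, "D1g1")
})

test_that("classification is monotone in child-defining variants", {
  kids <- reg[reg$parent != "" & nzchar(reg$cr_variants), ]
  depth_of <- function(cl) length(dloopr:::clade_path(reg, cl))
  for (i in seq_len(nrow(kids))) {
    parent_m <- path_motif(kids$parent[i])
    child_m <- path_motif(kids$name[i])
    d_parent <- depth_of(classify(parent_m, reg)$clade)
    d_child <- depth_of(classify(child_m, reg)$clade)
    expect_gte(d_child, d_parent)
  }
})

test_that("one missing defining variant is tolerated along the path", {
  full <- path_motif("D1g")
  dropped <- motif(full[full$position != 263L, , drop = FALSE])
  a <- classify(dropped, reg)
  expect_equal(a$clade, "D1g")
  expect_equal(a$missing, 1L)
  # two missing pushes the sample out of the clade
  dropped2 <- motif(full[!full$position %in% c(263L, 489L), , drop = FALSE])
  expect_false(classify(dropped2, reg)$clade == "D1g")
})

test_that("classification ignores motif variant order", {
  toks <- c("16187", "489", "073", "263", "315+C", "16223", "16325", "16362")
  set.seed(3)
  for (i in 1:5) {
    m <- motif(lapply(sample(toks), parse_variant))
    expect_equal(classify(m, reg)$clade, "D1g")
  }
})

test_that("frequency tables reconcile with their inputs", {
  mots <- c(
    replicate(4, path_motif("D1g"), simplify = FALSE),
    replicate(2, path_motif("B2l"), simplify = FALSE))
  for (i in seq_along(mots)) {
    attr(mots[[i]], "sample_id") <- paste0("s", i)
    attr(mots[[i]], "population") <- if (i <= 4) "north" else "south"
  }
  asn <- classify_all(mots, reg)
  tab <- count_by_clade(asn)
  expect_equal(sum(tab$n), 6L)
  expect_equal(tab$pct[tab$population == "north" & tab$clade == "D1g"], 100)
  expect_equal(count_in_clade(asn, reg, "D1"), 4L)
  expect_equal(count_in_clade(asn, reg, "B2"), 2L)
})

test_that("amplicon prediction follows primer arithmetic", {
  fwd <- "ACGTACGTACGTACGTACGT"
  rev <- "TGCATGCATGCATGCATGCA"
  mid <- "TTTTTTTTTT"
  template <- paste0("AAAAA", fwd, mid, dloopr:::revcomp(rev), "CCCCC")
  amp <- predict_amplicon(template, primer_pair("toy", fwd, rev))
  expect_equal(amp$length, 50L)
  expect_error(predict_amplicon(paste0("AAAAA", fwd, mid),
                                primer_pair("toy", fwd, rev)),
               "reverse matched 0")
})

test_that("the 8116 SmaI assay behaves as designed", {
  amp <- predict_amplicon(rcrs_reference(), primers_8116())
  expect_equal(amp$length, 275L)
  expect_equal(digest(amp$product), 275L)
  whole <- region_spec(list(c(1L, 16569L)))
  derived <- apply_motif(rcrs_reference(), parse_motif("8116"), whole)
  fr <- digest(predict_amplicon(derived, primers_8116())$product)
  expect_length(fr, 2L)
  expect_equal(sum(fr), 275L)
})

test_that("digest fragments always sum to the product length", {
  expect_equal(digest("AAAA"), 4L)
  prod <- paste0(strrep("A", 40), "CCCGGG", strrep("T", 54))
  expect_equal(digest(prod), c(43L, 57L))
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    expect_equal(sum(digest(s)), 300L)
  }
})
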