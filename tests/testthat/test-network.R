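mk <- function(strings, pops = NULL) {
  out <- lapply(strings, parse_motif)
  if (!is.null(pops))
    for (i in seq_along(out)) attr(out[[i]], "population") <- pops[i]
  out
}

test_that("condense merges identical motifs and keeps population counts", {
  tab <- condense(mk(c("073", "073", "073", "073", "146", "146"),
                     c("a", "a", "b", "b", "b", "b")))
  expect_length(tab$haplotypes, 2L)
  expect_equal(unname(sort(rowSums(tab$counts))), c(2, 4))
  expect_equal(sum(tab$counts), 6L)

  all_distinct <- condense(mk(c("073", "146", "152", "073-146")))
  expect_length(all_distinct$haplotypes, 4L)

  # permutation of the input order gives the identical table
  set.seed(1)
  strs <- c("073", "073", "146", "152", "073-146", "146")
  t1 <- condense(mk(strs))
  t2 <- condense(mk(sample(strs)))
  expect_identical(t1$haplotypes, t2$haplotypes)
  expect_identical(t1$counts, t2$counts)
})

test_that("two haplotypes give a single labelled edge", {
  net <- build_mj(condense(mk(c("", "073"))))
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$label, "073")
})

test_that("a median vector resolves the three-haplotype star", {
  net <- mp_postprocess(build_mj(condense(mk(c("", "073-146", "073-152")),
                                          default_weight = 1)))
  expect_equal(net$cost, 3)
  expect_true("073" %in% net$nodes$id)
  expect_false(net$nodes$observed[net$nodes$id == "073"])
  expect_equal(nrow(net$edges), 3L)
})

test_that("parallel site pairs create a reticulation", {
  net <- build_mj(condense(mk(c("", "073", "146", "073-146"))))
  # 4 nodes in a cycle: every node has degree 2
  expect_equal(nrow(net$edges), 4L)
  deg <- table(c(net$edges$from, net$edges$to))
  expect_true(all(deg == 2))
})

test_that("epsilon must be non-negative", {
  expect_error(build_mj(condense(mk(c("", "073"))), epsilon = -1),
               "non-negative")
})

test_that("spanning cost matches the exhaustive Steiner oracle", {
  set.seed(2024)
  for (i in 1:20) {
    inst <- random_steiner_instance(k = sample(3:6, 1), s = sample(4:8, 1))
    tab <- condense(inst$motifs, default_weight = 1)
    net <- mp_postprocess(build_mj(tab, epsilon = Inf))
    expect_equal(net$cost, steiner_hypercube(inst$vecs))
  }
})

test_that("observed haplotypes survive all post-processing", {
  set.seed(99)
  for (i in 1:10) {
    inst <- random_steiner_instance(k = 5, s = 6)
    tab <- condense(inst$motifs, default_weight = 1)
    net <- mp_postprocess(build_mj(tab))
    obs_ids <- vapply(inst$motifs, format_motif, "")
    expect_true(all(obs_ids %in% net$nodes$id[net$nodes$observed]))
  }
})

test_that("a tree-shaped network passes MP post-processing unchanged", {
  net <- build_mj(condense(mk(c("", "073", "073-146", "073-146-152"))))
  pruned <- mp_postprocess(net)
  expect_equal(nrow(pruned$nodes), nrow(net$nodes))
  expect_equal(nrow(pruned$edges), nrow(net$edges))
  expect_equal(pruned$cost, sum(net$edges$weight))
})

test_that("network cost is invariant to input order and population labels", {
  set.seed(31)
  inst <- random_steiner_instance(k = 5, s = 6)
  perm <- sample(length(inst$motifs))
  relabel <- lapply(seq_along(inst$motifs), function(i) {
    m <- inst$motifs[[i]]
    attr(m, "population") <- paste0("pop", i %% 2)
    m
  })
  c1 <- mp_postprocess(build_mj(condense(inst$motifs,
                                         default_weight = 1)))$cost
  c2 <- mp_postprocess(build_mj(condense(inst$motifs[perm],
                                         default_weight = 1)))$cost
  c3 <- mp_postprocess(build_mj(condense(relabel,
                                         default_weight = 1)))$cost
  expect_equal(c1, c2)
  expect_equal(c1, c3)
})

test_that("weighted distances are symmetric and satisfy the triangle inequality", {
  set.seed(17)
  inst <- random_steiner_instance(k = 6, s = 7)
  tab <- condense(inst$motifs, homoplastic_sites = c(101L, 103L))
  D <- dloopr:::pairwise_set_distance(tab$tokens, tab$site_weights,
                                      tab$default_weight)
  expect_equal(D, t(D))
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("down-weighted homoplastic sites reduce edge weights", {
  tab <- condense(mk(c("", "073")), homoplastic_sites = 73L)
  net <- build_mj(tab)
  expect_equal(net$edges$weight, 5)
})

test_that("graphml export round-trips nodes, counts and labels", {
  net <- mp_postprocess(build_mj(condense(
    mk(c("", "073-146", "073-152", "073-152"),
       c("north", "south", "south", "north")))))
  path <- file.path(tempdir(), "net.graphml")
  export_network(net, path, "graphml")
  back <- import_network(path)
  expect_equal(sort(back$nodes$id), sort(net$nodes$id))
  expect_equal(back$counts[order(rownames(back$counts)), ],
               net$counts[order(rownames(net$counts)), ])
  expect_setequal(back$edges$label, net$edges$label)

  dot <- file.path(tempdir(), "net.dot")
  export_network(net, dot, "dot")
  expect_true(file.exists(dot) && file.size(dot) > 0)
  expect_error(export_network(net, tempfile(), "nexus"))
})
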