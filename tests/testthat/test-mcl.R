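clique_edges <- function(genes, w = 1) {
  do.call(rbind, lapply(utils::combn(genes, 2L, simplify = FALSE),
                        function(p) data.frame(geneX = p[1L], geneY = p[2L],
                                               C = w)))
}

test_that("transition matrices are column-stochastic with max-weight loops", {
  ## single node
  M <- build_transition_matrix(data.frame(geneX = character(),
                                          geneY = character(),
                                          C = numeric()), nodes = "g1")
  expect_identical(M, matrix(1, 1, 1, dimnames = list("g1", "g1")))

  ## two nodes, one edge of weight w: self-loop equals w, columns 1/2 each
  M <- build_transition_matrix(data.frame(geneX = "a", geneY = "b", C = 0.4))
  expect_equal(unname(M), matrix(0.5, 2, 2))

  ## random weighted graph
  set.seed(17)
  genes <- sprintf("g%02d", 1:20)
  e <- clique_edges(genes)[sample(190, 60), ]
  e$C <- runif(60)
  M <- build_transition_matrix(e)
  expect_equal(colSums(M), rep(1, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(M >= 0))

  expect_error(build_transition_matrix(data.frame(geneX = "a", geneY = "b",
                                                  C = -0.1)), "negative")
  ## empty network
  expect_identical(dim(build_transition_matrix(
    data.frame(geneX = character(), geneY = character(), C = numeric()))),
    c(0L, 0L))
})

test_that("every inflation step preserves column stochasticity", {
  set.seed(29)
  genes <- sprintf("g%02d", 1:15)
  e <- clique_edges(genes)[sample(105, 40), ]
  e$C <- runif(40)
  M <- build_transition_matrix(e)
  for (i in 1:12) {
    M <- phylocoevo:::inflate(M %*% M, 2, 1e-5)
    expect_lt(max(abs(colSums(M) - 1)), 1e-9)
    expect_true(all(M >= 0))
  }
})

test_that("MCL recovers obvious structure deterministically", {
  ## identity (no edges): all singletons
  nodes <- paste0("g", 1:5)
  M <- build_transition_matrix(data.frame(geneX = character(),
                                          geneY = character(),
                                          C = numeric()), nodes = nodes)
  p <- mcl_cluster(M)
  expect_identical(lengths(p), rep(1L, 5L))

  ## two disconnected 4-cliques
  e <- rbind(clique_edges(paste0("a", 1:4)), clique_edges(paste0("b", 1:4)))
  p <- mcl_cluster(build_transition_matrix(e))
  expect_identical(sort(vapply(p, paste, "", collapse = " ")),
                   c("a1 a2 a3 a4", "b1 b2 b3 b4"))

  ## two 5-cliques joined by one weak edge; partition frozen from the
  ## independent reference implementation run on the same edge list
  e <- rbind(clique_edges(paste0("a", 1:5)), clique_edges(paste0("b", 1:5)),
             data.frame(geneX = "a1", geneY = "b1", C = 0.05))
  p <- mcl_cluster(build_transition_matrix(e), inflation = 2)
  got <- sort(vapply(p, function(cl) paste(sort(cl), collapse = " "), ""))
  expect_identical(got, c("a1 a2 a3 a4 a5", "b1 b2 b3 b4 b5"))

  ## determinism: identical inputs, identical partition
  p2 <- mcl_cluster(build_transition_matrix(e), inflation = 2)
  expect_identical(p, p2)

  ## input validation
  bad <- matrix(c(0.5, 0.2, 0.5, 0.2), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(mcl_cluster(bad), "stochastic")
  expect_error(mcl_cluster(build_transition_matrix(e), inflation = 1),
               "inflation")
})

test_that("idempotent doubly-stochastic block matrices are fixed points", {
  blk <- function(k) matrix(1 / k, k, k)
  M <- rbind(cbind(blk(3), matrix(0, 3, 2)),
             cbind(matrix(0, 2, 3), blk(2)))
  dimnames(M) <- list(paste0("g", 1:5), paste0("g", 1:5))
  p <- mcl_cluster(M)
  expect_identical(sort(vapply(p, function(cl) paste(sort(cl), collapse = " "),
                               "")),
                   c("g1 g2 g3", "g4 g5"))
})

test_that("partitions are disjoint covers of the node set", {
  set.seed(41)
  genes <- sprintf("g%02d", 1:18)
  e <- clique_edges(genes)[sample(153, 70), ]
  e$C <- runif(70, 0.2, 1)
  M <- build_transition_matrix(e)
  p <- mcl_cluster(M)
  members <- unlist(p)
  expect_identical(sort(members), sort(rownames(M)))
  expect_false(anyDuplicated(members) > 0)
})

test_that("threshold sweeps nest edges and shrink the query cluster", {
  ## concentric structure: edge weight decreases with the larger node index,
  ## so each threshold leaves a complete graph on a prefix of the nodes
  genes <- paste0("g", 1:8)
  w <- c(NA, 0.95, 0.9, 0.8, 0.7, 0.65, 0.6, 0.55)
  e <- do.call(rbind, lapply(utils::combn(8, 2, simplify = FALSE),
                             function(p) data.frame(geneX = genes[p[1L]],
                                                    geneY = genes[p[2L]],
                                                    C = w[max(p)])))
  net <- coevolution_network(e, nodes = genes, threshold = 0.5)
  sw <- sweep_thresholds(net, seq(0.5, 0.9, by = 0.1), query_gene = "g1")
  expect_false(is.unsorted(-sw$trajectory$n_edges))
  expect_false(is.unsorted(-sw$trajectory$query_cluster_size))
  expect_identical(sw$trajectory$query_cluster_size[1L], 8L)
  ## a threshold above every weight leaves the query unclustered
  sw2 <- sweep_thresholds(net, 1.1, query_gene = "g1")
  expect_identical(sw2$trajectory$query_cluster_size, 0L)
  expect_length(sw2$partitions[[1L]], 0L)
  expect_error(sweep_thresholds(net, c(0.9, 0.5), "g1"), "ascending")
})
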