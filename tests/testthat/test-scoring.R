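## A 3-organism fixture with known content overlap: organisms P, Q share
## 6 of their 10/8 genes as BBHs; R shares nothing.
overlap_fixture <- function() {
  mk <- function(org, fams) {
    data.frame(organism = org, gene = paste0(org, "_", fams), replicon = "c1",
               rank = seq_along(fams) - 1L, strand = "+", length = 200L)
  }
  famP <- sprintf("f%02d", 1:10)
  famQ <- sprintf("f%02d", 1:8)   # f01..f06 shared as orthologs
  famR <- sprintf("r%02d", 1:5)
  panel <- organism_panel(rbind(mk("P", famP), mk("Q", famQ), mk("R", famR)))
  shared <- sprintf("f%02d", 1:6)
  hits <- data.frame(query = c(paste0("P_", shared), paste0("Q_", shared)),
                     subject = c(paste0("Q_", shared), paste0("P_", shared)),
                     identity = 90, alignment_length = 200L, self = FALSE)
  list(panel = panel, hits = hits)
}

test_that("organism distance follows the content-overlap formula", {
  fx <- overlap_fixture()
  os <- ortholog_sets(fx$hits, fx$panel)
  expect_identical(organism_distance(fx$panel, os, "P", "P"), 0)
  ## N(P)=10, N(Q)=8, N(P,Q)=6 -> 1 - 6/10
  expect_equal(organism_distance(fx$panel, os, "P", "Q"), 0.4)
  ## no shared orthologs -> distance 1
  expect_equal(organism_distance(fx$panel, os, "P", "R"), 1)
  expect_error(organism_distance(fx$panel, os, "P", "X"), "not in panel")

  D <- organism_distance_matrix(fx$panel, os)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("max co-occurrence distance equals the brute-force pairwise max", {
  set.seed(13)
  n <- 10L
  D <- matrix(runif(n * n), n); D <- (D + t(D)) / 2; diag(D) <- 0
  for (rep in 1:50) {
    px <- rbinom(n, 1L, 0.5); py <- rbinom(n, 1L, 0.5)
    S <- which(px == 1L & py == 1L)
    brute <- 0
    if (length(S) > 1L) {
      for (a in S) for (b in S) brute <- max(brute, D[a, b])
    }
    expect_identical(max_cooccurrence_distance(px, py, D), brute)
  }
  ## empty and singleton co-occurrence kill the distance
  expect_identical(max_cooccurrence_distance(rep(0, n), rep(1, n), D), 0)
  one <- c(1, rep(0, n - 1))
  expect_identical(max_cooccurrence_distance(one, one, D), 0)
})

test_that("the co-evolution score composes phi, dmax^3 and K", {
  expect_equal(0.9 * 0.5^3 * 0.9, 0.10125)  # the score arithmetic at a glance
  we <- make_worked_example()
  os <- ortholog_sets(we$hits, we$panel)
  P <- build_profiles(os, we$panel, "O1")
  D <- organism_distance_matrix(we$panel, os)
  sc <- coevolution_score("O1_m1a", "O1_m1b", P, D, we$panel, os)
  expect_equal(sc$C, sc$phi * sc$dmax^3 * sc$k)
  ## symmetry under argument swap
  sw <- coevolution_score("O1_m1b", "O1_m1a", P, D, we$panel, os)
  expect_equal(sw$C, sc$C)
  expect_equal(sw$dmax, sc$dmax)
  ## phi = 1, dmax = 1, K = 1 -> C = 1 upper bound sanity
  expect_equal(1 * 1^3 * 1, 1)
  ## monotone in dmax with phi, K held fixed
  grid <- seq(0, 1, by = 0.05)
  expect_false(is.unsorted(0.8 * grid^3 * 0.9))
})

test_that("all-pairs scoring dedups by symmetry and applies the threshold", {
  we <- make_worked_example()
  os <- ortholog_sets(we$hits, we$panel)
  P3 <- build_profiles(os, we$panel, "O1")[c("O1_m1a", "O1_m1b", "O1_m1c"), ]
  D <- organism_distance_matrix(we$panel, os)
  net <- score_all_pairs(we$panel, P3, D, os, threshold = -1)
  expect_identical(nrow(net$edges), 3L)  # n(n-1) ordered = 3 unordered
  net_hi <- score_all_pairs(we$panel, P3, D, os, threshold = 1.1)
  expect_identical(nrow(net_hi$edges), 0L)

  ## the phi-prefilter shortcut equals exhaustive scoring above the threshold
  P <- build_profiles(os, we$panel, "O1")
  full <- score_all_pairs(we$panel, P, D, os, threshold = -1)
  fast <- score_all_pairs(we$panel, P, D, os, threshold = 0.15)
  kept <- full$edges[full$edges$C > 0.15, ]
  expect_setequal(paste(fast$edges$geneX, fast$edges$geneY),
                  paste(kept$geneX, kept$geneY))

  ## raising the threshold never adds edges
  key <- function(n) paste(n$edges$geneX, n$edges$geneY)
  prev <- key(score_all_pairs(we$panel, P, D, os, threshold = 0.05))
  for (thr in c(0.1, 0.15, 0.5)) {
    cur <- key(score_all_pairs(we$panel, P, D, os, threshold = thr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("query mode reports every partner with full score records", {
  we <- make_worked_example()
  os <- ortholog_sets(we$hits, we$panel)
  P <- build_profiles(os, we$panel, "O1")
  D <- organism_distance_matrix(we$panel, os)
  q <- query_gene_scores("O1_m1a", we$panel, P, D, os)
  expect_identical(nrow(q), nrow(P) - 1L)
  expect_false(is.unsorted(rev(q$C)))
  expect_equal(q$C, q$phi * q$dmax^3 * q$k)
})
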