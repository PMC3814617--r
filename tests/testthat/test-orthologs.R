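test_that("similarity score is identity times coverage, range-checked", {
  expect_identical(similarity_score(100, 1), 100)
  expect_identical(similarity_score(0, 1), 0)
  expect_identical(similarity_score(90, 0.5), 45)
  expect_equal(similarity_score(c(50, 80), c(0.5, 0.25)), c(25, 20))
  expect_error(similarity_score(101, 1), "identity")
  expect_error(similarity_score(-1, 1), "identity")
  expect_error(similarity_score(50, 0), "coverage")
  expect_error(similarity_score(50, 1.2), "coverage")
})

test_that("BBH matches the definition on hand cases", {
  ## a1 <-> b1 mutual best
  s <- matrix(c(90, 10, 10, 80), 2, dimnames = list(c("a1", "a2"),
                                                    c("b1", "b2")))
  fx <- matrix_fixture(s, s)
  got <- bidirectional_best_hits(fx$hits, fx$panel, "A", "B")
  expect_identical(got$gene_a, c("a1", "a2"))
  expect_identical(got$gene_b, c("b1", "b2"))

  ## a1's best is b1 but b1's best is a2 -> a1 unpaired
  s_ab <- matrix(c(90, 95, 10, 10), 2, dimnames = list(c("a1", "a2"),
                                                       c("b1", "b2")))
  fx <- matrix_fixture(s_ab, s_ab)
  got <- bidirectional_best_hits(fx$hits, fx$panel, "A", "B")
  expect_false("a1" %in% got$gene_a)
  expect_identical(got$gene_b[got$gene_a == "a2"], "b1")
})

test_that("BBH equals the exhaustive mutual-argmax oracle on random matrices", {
  set.seed(11)
  for (rep in 1:25) {
    na <- sample(2:20, 1L); nb <- sample(2:20, 1L)
    s_ab <- matrix(round(runif(na * nb, 5, 95), 1), na,
                   dimnames = list(sprintf("a%02d", 1:na),
                                   sprintf("b%02d", 1:nb)))
    s_ba <- matrix(round(runif(na * nb, 5, 95), 1), na,
                   dimnames = dimnames(s_ab))
    fx <- matrix_fixture(s_ab, s_ba)
    got <- bidirectional_best_hits(fx$hits, fx$panel, "A", "B")
    rownames(got) <- NULL
    exp <- bbh_oracle(s_ab, s_ba)
    rownames(exp) <- NULL
    expect_identical(got, exp)
  }
})

test_that("score densities behave like a KDE and honour conventions", {
  expect_identical(score_density(42), 1)
  expect_identical(score_density(rep(60, 5)), rep(1, 5))

  s <- c(rep(80, 10) + seq(-1, 1, length.out = 10), 20)
  d <- score_density(s)
  expect_true(all(d > 0))
  expect_gt(d[1L], d[11L])  # mass near 80 beats the 20 outlier

  ## matches an independent KDE (binned FFT estimate, interpolated)
  set.seed(3)
  for (rep in 1:10) {
    s <- runif(sample(5:40, 1L), 0, 100)
    ref <- stats::density(s, bw = "nrd0", n = 4096, cut = 4)
    at_s <- stats::approx(ref$x, ref$y, xout = s)$y
    expect_equal(score_density(s), at_s, tolerance = 1e-3)
  }

  ## order invariance
  s <- runif(15, 0, 100)
  p <- sample(15)
  expect_equal(score_density(s)[p], score_density(s[p]))
  expect_error(score_density(numeric(0)), "at least one")
})

test_that("adaptive selection follows the mean-score OR mean-density rule", {
  cand <- data.frame(organism = c("O2", "O3", "O4"), s = c(90, 80, 10))
  out <- select_orthologs(cand)
  expect_identical(out$selected, c(TRUE, TRUE, FALSE))

  ## all-equal sample: strict inequalities fail, tie rule retains all
  out <- select_orthologs(data.frame(s = rep(55, 4)))
  expect_true(all(out$selected))

  ## zero candidates in, zero out
  out <- select_orthologs(data.frame(s = numeric(0)))
  expect_identical(nrow(out), 0L)

  ## clustered sample: dense high mass kept, stray low score dropped
  s <- c(78, 79, 80, 80, 81, 81, 82, 82, 83, 84, 20)
  out <- select_orthologs(data.frame(s = s))
  expect_false(out$selected[11L])
  expect_true(all(out$selected[1:10]))
  expect_identical(out$selected, as.vector(eq4_oracle(s)))
})

test_that("selection is a superset of the mean-score rule and order-invariant", {
  set.seed(23)
  for (rep in 1:100) {
    s <- round(runif(sample(2:30, 1L), 0, 100), 2)
    out <- select_orthologs(data.frame(s = s))
    ## OR-union monotonicity over the plain mean-score criterion
    eq2 <- s > mean(s)
    expect_true(all(out$selected[eq2]))
    ## matches the independent brute-force evaluation
    expect_identical(out$selected, as.vector(eq4_oracle(s)))
    ## permutation invariance
    p <- sample(length(s))
    expect_identical(out$selected[p],
                     select_orthologs(data.frame(s = s[p]))$selected)
  }
})

test_that("panel-wide ortholog sets agree with per-gene selection", {
  we <- make_worked_example()
  os <- ortholog_sets(we$hits, we$panel)
  expect_s3_class(os, "ortholog_sets")
  ## every gene has at most one candidate per foreign organism
  expect_false(any(duplicated(os[, c("target_gene", "organism")])))
  ## per-gene grouped selection equals select_orthologs on that gene
  for (g in c("O1_m1a", "O1_b5", "O2_b1")) {
    rows <- os[os$target_gene == g, ]
    expect_identical(rows$selected,
                     select_orthologs(rows[, c("organism", "s")])$selected)
  }
  ## restricting to a target organism only drops other targets
  os1 <- ortholog_sets(we$hits, we$panel, target_organism = "O1")
  expect_setequal(unique(substr(os1$target_gene, 1, 2)), "O1")
})
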