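## Independent oracles and small constructed fixtures shared across tests.

## Exhaustive mutual-argmax BBH oracle on a dense score matrix.
## rows = genes of organism A, cols = genes of organism B; ties broken by
## higher identity then lexicographic subject id, mirroring the contract.
bbh_oracle <- function(s_ab, s_ba, id_ab = s_ab, id_ba = s_ba) {
  ga <- rownames(s_ab); gb <- colnames(s_ab)
  best_in_b <- vapply(ga, function(a) {
    o <- order(-s_ab[a, ], -id_ab[a, ], gb, method = "radix")
    gb[o[1L]]
  }, character(1L))
  best_in_a <- vapply(gb, function(b) {
    o <- order(-s_ba[, b], -id_ba[, b], ga, method = "radix")
    ga[o[1L]]
  }, character(1L))
  pairs <- data.frame(gene_a = ga, gene_b = best_in_b,
                      stringsAsFactors = FALSE)
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    best_in_a[[pairs$gene_b[i]]] == pairs$gene_a[i]
  }, logical(1L))
  pairs <- pairs[keep, , drop = FALSE]
  pairs[order(pairs$gene_a, method = "radix"), , drop = FALSE]
}

## Build a two-organism panel plus hit table from dense score matrices so
## BBH can be exercised against the oracle. Identity == score (coverage 1).
matrix_fixture <- function(s_ab, s_ba) {
  ga <- rownames(s_ab); gb <- colnames(s_ab)
  genes <- rbind(
    data.frame(organism = "A", gene = ga, replicon = "c1",
               rank = seq_along(ga) - 1L, strand = "+", length = 100L),
    data.frame(organism = "B", gene = gb, replicon = "c1",
               rank = seq_along(gb) - 1L, strand = "+", length = 100L))
  panel <- organism_panel(genes)
  hits <- rbind(
    data.frame(query = rep(ga, each = length(gb)),
               subject = rep(gb, times = length(ga)),
               identity = as.vector(t(s_ab)), alignment_length = 100L),
    data.frame(query = rep(gb, each = length(ga)),
               subject = rep(ga, times = length(gb)),
               identity = as.vector(s_ba), alignment_length = 100L))
  hits$self <- FALSE
  list(panel = panel, hits = hits)
}

## Brute-force evaluation of the adaptive retention rule, with the KDE
## computed by direct double-loop Gaussian sums (independent code path).
eq4_oracle <- function(s) {
  n <- length(s)
  if (n == 1L || stats::var(s) == 0) {
    d <- rep(1, n)
  } else {
    h <- stats::bw.nrd0(s)
    d <- vapply(s, function(x) {
      sum(exp(-0.5 * ((x - s) / h)^2) / sqrt(2 * pi)) / (n * h)
    }, numeric(1L))
  }
  sel <- s > mean(s) | d > mean(d)
  if (!any(sel)) sel[] <- TRUE
  sel
}

## Random 0/1 profile pair with non-constant margins.
random_profile_pair <- function(n) {
  repeat {
    px <- stats::rbinom(n, 1L, stats::runif(1, 0.2, 0.8))
    py <- stats::rbinom(n, 1L, stats::runif(1, 0.2, 0.8))
    if (length(unique(px)) > 1L && length(unique(py)) > 1L) {
      return(list(px = px, py = py))
    }
  }
}

## One full recovery run of the pipeline on a simulated default panel.
## Returns the truth/recovered labels over the target's module genes and
## the module-background edge keys of the thresholded network.
recovery_run <- function(seed, sampling_bias = NULL, threshold = 0.77,
                         inflation = 2) {
  sim <- simulate_panel(simulation_config(seed = seed,
                                          sampling_bias = sampling_bias))
  os <- ortholog_sets(sim$hits, sim$panel)
  mods <- sim$truth$modules
  fam_mod <- rep(seq_along(mods), lengths(mods))
  names(fam_mod) <- unlist(mods)
  pres <- sim$truth$presence[names(fam_mod), , drop = FALSE]
  tgt <- colnames(pres)[which.max(colSums(pres))]
  P <- build_profiles(os, sim$panel, tgt)
  D <- organism_distance_matrix(sim$panel, os)
  net <- score_all_pairs(sim$panel, P, D, os, threshold = threshold)
  sub <- coevolution_network(net$edges,
                             nodes = unique(c(net$edges$geneX,
                                              net$edges$geneY)),
                             threshold = threshold)
  part <- mcl_cluster(build_transition_matrix(sub), inflation = inflation)
  mg <- paste0(tgt, "_", names(fam_mod))[pres[, tgt] == 1]
  truth_lab <- fam_mod[pres[, tgt] == 1]
  rec <- rep(NA_character_, length(mg))
  names(rec) <- mg
  for (i in seq_along(part)) rec[intersect(mg, part[[i]])] <- paste0("c", i)
  rec[is.na(rec)] <- paste0("s", seq_len(sum(is.na(rec))))
  is_mod <- function(g) grepl("_mod", g)
  modbg <- paste(net$edges$geneX, net$edges$geneY)[
    xor(is_mod(net$edges$geneX), is_mod(net$edges$geneY))]
  list(truth = truth_lab, recovered = rec, modbg = modbg, network = net,
       partition = part, target = tgt)
}
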