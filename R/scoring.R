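## Co-evolution scoring: C(X,Y) = phi(X,Y) * Dmax^3 * K(X,Y), where Dmax is
## the content-based distance of the most distant organism pair in which X
## and Y co-occur. The cubic weighting discounts co-occurrence confined to
## near-identical genomes — the mechanism that protects the method against
## a phylogenetically skewed genome sample.

#' Construct a co-evolution network object
#'
#' @param edges data.frame with columns `geneX`, `geneY`, `phi`, `dmax`,
#'   `k`, `C` (one row per retained unordered pair).
#' @param nodes character vector of all genes that were scored.
#' @param threshold the edge-retention threshold used (edges satisfy
#'   `C > threshold`).
#' @return object of class `coevolution_network`.
#' @export
coevolution_network <- function(edges, nodes, threshold) {
  need <- c("geneX", "geneY", "C")
  if (!all(need %in% names(edges))) {
    stop("network edges need columns ", paste(need, collapse = ", "))
  }
  for (col in c("phi", "dmax", "k")) {
    if (!col %in% names(edges)) edges[[col]] <- NA_real_
  }
  edges <- as.data.frame(edges)[, c("geneX", "geneY", "phi", "dmax", "k", "C")]
  structure(list(edges = edges, nodes = as.character(nodes),
                 threshold = threshold),
            class = "coevolution_network")
}

#' @export
print.coevolution_network <- function(x, ...) {
  cat("<coevolution_network> ", length(x$nodes), " genes scored, ",
      nrow(x$edges), " edges (C > ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

## BBH pair counts per organism pair: every mutual best-hit pair counts
## for N(A,B), whether or not the per-gene adaptive selection retained it.
## N measures genome-content overlap; tying it to the selection would let
## per-gene threshold noise inflate the distance between near-identical
## genomes and defeat the sampling-bias damping that D exists to provide.
bbh_pair_counts <- function(osets) {
  dt <- data.table::as.data.table(as.data.frame(osets))
  if (nrow(dt) == 0L) {
    return(data.table::data.table(org_a = character(), org_b = character(),
                                  n = integer()))
  }
  panel <- attr(osets, "panel")
  home <- panel$genes$organism[match(dt$target_gene, panel$genes$gene)]
  dt[, `:=`(pair_a = pmin(target_gene, ortholog_gene),
            pair_b = pmax(target_gene, ortholog_gene))]
  dt[, `:=`(org_a = pmin(home, organism), org_b = pmax(home, organism))]
  uni <- unique(dt[, .(pair_a, pair_b, org_a, org_b)])
  uni[, .(n = .N), by = .(org_a, org_b)]
}

#' Content-based distance matrix over the organism panel
#'
#' `D(A,B) = 1 - N(A,B) / max(N(A), N(B))`, with `N(A)` the gene count of
#' organism A from the genome table and `N(A,B)` the number of
#' bidirectional-best-hit ortholog pairs between A and B (content overlap;
#' deliberately not filtered by the per-gene adaptive selection, so that
#' near-identical genomes always come out near distance 0). `D(A,A) = 0`;
#' organisms sharing no ortholog are at distance 1.
#'
#' @param panel an [organism_panel()].
#' @param osets panel-wide [ortholog_sets()] (computed with
#'   `target_organism = NULL`).
#' @return symmetric matrix in `[0, 1]` with organism dimnames.
#' @export
organism_distance_matrix <- function(panel, osets) {
  orgs <- panel$organisms
  n_genes <- stats::setNames(tabulate(factor(panel$genes$organism,
                                             levels = orgs),
                                      nbins = length(orgs)), orgs)
  D <- matrix(1, length(orgs), length(orgs), dimnames = list(orgs, orgs))
  cnt <- bbh_pair_counts(osets)
  if (nrow(cnt) > 0L) {
    ia <- match(cnt$org_a, orgs); ib <- match(cnt$org_b, orgs)
    shared <- cnt$n / pmax(n_genes[ia], n_genes[ib])
    D[cbind(ia, ib)] <- 1 - shared
    D[cbind(ib, ia)] <- 1 - shared
  }
  diag(D) <- 0
  pmin(pmax(D, 0), 1)
}

#' Content-based distance between two organisms
#'
#' @inheritParams organism_distance_matrix
#' @param organism_a,organism_b organism ids (must be in the panel).
#' @return `D(A,B)` in `[0, 1]`.
#' @export
organism_distance <- function(panel, osets, organism_a, organism_b) {
  if (!all(c(organism_a, organism_b) %in% panel$organisms)) {
    stop("organism not in panel")
  }
  if (organism_a == organism_b) return(0)
  organism_distance_matrix(panel, osets)[organism_a, organism_b]
}

#' Distance of the most distant organism pair where two genes co-occur
#'
#' Over `S = {o : px[o] = 1 and py[o] = 1}`, returns `max D(A,B)` for
#' `(A,B)` in `S x S`. If the genes co-occur in at most one organism there
#' is no organism pair to witness co-evolution and 0 is returned, which
#' zeroes the co-evolution score.
#'
#' @param px,py 0/1 profiles over the panel order of `D`.
#' @param D organism distance matrix (see [organism_distance_matrix()]).
#' @return value in `[0, 1]`.
#' @export
max_cooccurrence_distance <- function(px, py, D) {
  s <- which(px != 0 & py != 0)
  if (length(s) <= 1L) return(0)
  max(D[s, s])
}

#' Co-evolution score of one gene pair
#'
#' `C = phi * dmax^exponent * K` with `phi` the profile correlation, `dmax`
#' the most-distant co-occurrence distance and `K` the synteny factor
#' (1 if the pair is observed at least once in conserved neighborhood,
#' 0.9 otherwise). Symmetric in the two genes.
#'
#' @param gene_x,gene_y gene ids of the target organism.
#' @param profiles 0/1 profile matrix from [build_profiles()].
#' @param D organism distance matrix.
#' @param panel an [organism_panel()].
#' @param osets panel-wide [ortholog_sets()].
#' @param window synteny window (intervening genes), default 5.
#' @param exponent distance exponent, default 3.
#' @return data.frame row with `geneX`, `geneY`, `phi`, `dmax`, `k`, `C`.
#' @export
coevolution_score <- function(gene_x, gene_y, profiles, D, panel, osets,
                              window = 5L, exponent = 3) {
  if (!all(c(gene_x, gene_y) %in% rownames(profiles))) {
    stop("both genes must be profiled")
  }
  phi <- phi_coefficient(profiles[gene_x, ], profiles[gene_y, ])
  dmax <- max_cooccurrence_distance(profiles[gene_x, ], profiles[gene_y, ], D)
  k <- synteny_factor(gene_x, gene_y, panel, osets, window = window)$k
  data.frame(geneX = gene_x, geneY = gene_y, phi = phi, dmax = dmax, k = k,
             C = phi * dmax^exponent * k, stringsAsFactors = FALSE)
}

#' Score all gene pairs of a target organism
#'
#' Evaluates `C` for every unordered pair of the target organism's genes
#' (the n(n-1) ordered scores collapse to n(n-1)/2 by symmetry) and keeps
#' edges with `C > threshold`. Since `dmax^exponent` and `K` both lie in
#' `[0, 1]`, `C <= phi`; for a non-negative threshold pairs with
#' `phi <= threshold` are skipped without computing `dmax` or `K` — this is
#' an exact shortcut, not an approximation.
#'
#' @param panel an [organism_panel()].
#' @param profiles profile matrix of the target organism's genes.
#' @param D organism distance matrix.
#' @param osets panel-wide [ortholog_sets()].
#' @param threshold edge retention threshold on C (default 0.77).
#' @param window synteny window, default 5.
#' @param exponent distance exponent, default 3.
#' @return a `coevolution_network`; nodes are all profiled genes.
#' @export
score_all_pairs <- function(panel, profiles, D, osets, threshold = 0.77,
                            window = 5L, exponent = 3) {
  genes <- rownames(profiles)
  phi <- phi_matrix(profiles)
  if (threshold >= 0) {
    cand <- which(upper.tri(phi) & phi > threshold, arr.ind = TRUE)
  } else {
    cand <- which(upper.tri(phi), arr.ind = TRUE)
  }
  rows <- vector("list", nrow(cand))
  n_kept <- 0L
  if (nrow(cand) > 0L) {
    Pl <- profiles != 0
    for (i in seq_len(nrow(cand))) {
      gi <- cand[i, 1L]; gj <- cand[i, 2L]
      S <- which(Pl[gi, ] & Pl[gj, ])
      dmax <- if (length(S) <= 1L) 0 else max(D[S, S])
      p <- phi[gi, gj]
      base <- p * dmax^exponent
      ## K <= 1 cannot lift base above the threshold
      if (threshold >= 0 && base <= threshold) next
      k <- synteny_factor(genes[gi], genes[gj], panel, osets,
                          window = window)$k
      C <- base * k
      if (C > threshold) {
        n_kept <- n_kept + 1L
        rows[[n_kept]] <- data.frame(geneX = genes[gi], geneY = genes[gj],
                                     phi = p, dmax = dmax, k = k, C = C,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (n_kept > 0L) {
    do.call(rbind, rows[seq_len(n_kept)])
  } else {
    data.frame(geneX = character(), geneY = character(), phi = numeric(),
               dmax = numeric(), k = numeric(), C = numeric(),
               stringsAsFactors = FALSE)
  }
  coevolution_network(edges, nodes = genes, threshold = threshold)
}

#' Co-evolution scores of one gene against all others
#'
#' Query mode: the full score record (phi, dmax, K, C) of `gene` against
#' every other profiled gene, regardless of any threshold.
#'
#' @inheritParams score_all_pairs
#' @param gene query gene id (must be profiled).
#' @return data.frame sorted by decreasing C.
#' @export
query_gene_scores <- function(gene, panel, profiles, D, osets,
                              window = 5L, exponent = 3) {
  if (!gene %in% rownames(profiles)) stop("gene not profiled: ", gene)
  others <- setdiff(rownames(profiles), gene)
  out <- do.call(rbind, lapply(others, function(g) {
    coevolution_score(gene, g, profiles, D, panel, osets,
                      window = window, exponent = exponent)
  }))
  out[order(-out$C, out$geneY, method = "radix"), , drop = FALSE]
}
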