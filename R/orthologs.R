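## Bidirectional-best-hit orthology with the per-gene adaptive retention
## rule: an ortholog is retained when its similarity score s = identity x
## coverage exceeds the gene's own mean score, OR when the kernel density of
## s at that ortholog exceeds the mean density. Both averages are taken over
## the gene's own candidates only — there is no global threshold, because
## genes evolve at different rates while remaining functional.

#' Similarity score of a pairwise protein hit
#'
#' `s = identity * coverage`, where identity is the BLAST percent identity
#' in `[0, 100]` and coverage is the alignment length divided by the length
#' of the longest of the two proteins, in `(0, 1]`. `s` therefore lives on a
#' 0-100 scale.
#'
#' @param identity percent identity, in `[0, 100]`. Vectorised.
#' @param coverage alignment coverage fraction, in `(0, 1]`. Vectorised.
#' @return numeric score(s) in `[0, 100]`.
#' @export
similarity_score <- function(identity, coverage) {
  if (any(is.na(identity)) || any(identity < 0 | identity > 100)) {
    stop("identity must lie in [0, 100]")
  }
  if (any(is.na(coverage)) || any(coverage <= 0 | coverage > 1)) {
    stop("coverage must lie in (0, 1]")
  }
  identity * coverage
}

## Annotate raw hits with organisms, coverage and s. Coverage uses the
## longest of the two proteins (lengths from the genome table) and is
## clamped at 1 so end-gap artefacts cannot push s above the identity.
score_hits <- function(hits, panel) {
  dt <- data.table::as.data.table(hits)
  idx_q <- match(dt$query, panel$genes$gene)
  idx_s <- match(dt$subject, panel$genes$gene)
  if (anyNA(idx_q) || anyNA(idx_s)) {
    stop("hit table references gene ids absent from the panel")
  }
  dt[, qorg := panel$genes$organism[idx_q]]
  dt[, sorg := panel$genes$organism[idx_s]]
  longest <- pmax(panel$genes$length[idx_q], panel$genes$length[idx_s])
  dt[, coverage := pmin(alignment_length / longest, 1)]
  dt[, s := identity * coverage]
  dt
}

## Best subject per (query gene, subject organism). Ties broken by higher s,
## then higher identity, then lexicographic subject id; duplicated
## (query, subject) rows collapse to their best-scoring occurrence.
best_hits <- function(scored) {
  dt <- scored[qorg != sorg]
  if (nrow(dt) == 0L) return(dt)
  data.table::setorderv(dt, c("query", "sorg", "s", "identity", "subject"),
                        order = c(1L, 1L, -1L, -1L, 1L))
  dt[dt[, .I[1L], by = .(query, sorg)]$V1]
}

## All BBH candidate rows across the whole panel: one row per (target gene,
## foreign organism) where the best hits are mutual. Columns: target_gene,
## organism (of the ortholog), ortholog_gene, identity, coverage, s (all
## taken from the target -> ortholog direction).
bbh_candidates <- function(scored) {
  best <- best_hits(scored)
  if (nrow(best) == 0L) {
    return(data.table::data.table(target_gene = character(),
                                  organism = character(),
                                  ortholog_gene = character(),
                                  identity = numeric(), coverage = numeric(),
                                  s = numeric()))
  }
  fwd <- best[, .(target_gene = query, organism = sorg,
                  ortholog_gene = subject, identity, coverage, s)]
  rev <- best[, .(target_gene = subject, ortholog_gene = query)]
  mutual <- merge(fwd, rev,
                  by = c("target_gene", "ortholog_gene"), sort = FALSE)
  data.table::setorderv(mutual, c("target_gene", "organism"))
  mutual[, .(target_gene, organism, ortholog_gene, identity, coverage, s)]
}

#' Bidirectional best hits between two organisms
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best-scoring subject in
#' organism B (by `s`, ties by identity then subject id) and `a` is `b`'s
#' best-scoring subject in organism A. Pairs are disjoint by construction.
#'
#' @param hits hit table (see [read_hit_table()]).
#' @param panel an [organism_panel()].
#' @param organism_a,organism_b the two organism ids.
#' @return data.frame with columns `gene_a`, `gene_b` (genes of
#'   `organism_a` / `organism_b`), sorted by `gene_a`.
#' @export
bidirectional_best_hits <- function(hits, panel, organism_a, organism_b) {
  if (!all(c(organism_a, organism_b) %in% panel$organisms)) {
    stop("organism not in panel")
  }
  scored <- score_hits(hits, panel)
  scored <- scored[(qorg == organism_a & sorg == organism_b) |
                     (qorg == organism_b & sorg == organism_a)]
  cand <- bbh_candidates(scored)
  cand <- cand[organism == organism_b]
  out <- data.frame(gene_a = cand$target_gene, gene_b = cand$ortholog_gene,
                    stringsAsFactors = FALSE)
  out[radix_order(out$gene_a), , drop = FALSE]
}

#' Kernel density of similarity scores, evaluated at the scores themselves
#'
#' Gaussian kernel density estimate over a gene's candidate scores with
#' Silverman's rule-of-thumb bandwidth ([stats::bw.nrd0()]), evaluated at
#' each candidate's own score. Degenerate samples (a single candidate, or
#' zero variance) get the conventional uniform density 1 so that downstream
#' strict inequalities fall through to the tie rule.
#'
#' @param scores numeric vector of `s` values, length >= 1.
#' @return numeric vector of densities, same length and order as `scores`;
#'   all values > 0.
#' @export
score_density <- function(scores) {
  n <- length(scores)
  if (n == 0L) stop("score_density needs at least one score")
  if (n == 1L || stats::var(scores) == 0) return(rep(1, n))
  h <- stats::bw.nrd0(scores)
  ## mean of Gaussian kernels centred on the sample, at the sample points
  z <- outer(scores, scores, "-") / h
  rowMeans(stats::dnorm(z)) / h
}

#' Adaptive ortholog selection for one gene
#'
#' Retains candidate `k` iff `s_k > mean(s)` OR `d(s_k) > mean(d)`, with
#' both means over this gene's candidates only. If the strict inequalities
#' retain nothing (all scores equal), all candidates are retained: equal
#' scores mean equally credible orthologs.
#'
#' @param candidates data.frame of one gene's BBH candidates with at least
#'   a numeric `s` column (one row per organism).
#' @return the same data.frame with `density` and logical `selected`
#'   columns appended. Zero rows in, zero rows out.
#' @export
select_orthologs <- function(candidates) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0L) {
    candidates$density <- numeric(0)
    candidates$selected <- logical(0)
    return(candidates)
  }
  d <- score_density(candidates$s)
  sel <- candidates$s > mean(candidates$s) | d > mean(d)
  if (!any(sel)) sel[] <- TRUE
  candidates$density <- d
  candidates$selected <- sel
  candidates
}

#' BBH candidates and adaptive selection for every gene
#'
#' Runs bidirectional best hits across all organism pairs of the panel,
#' groups the resulting candidates per target gene and applies
#' [select_orthologs()] to each. Genes with no cross-genome hit simply have
#' no rows.
#'
#' @param hits hit table (see [read_hit_table()]).
#' @param panel an [organism_panel()].
#' @param target_organism optional organism id; if given, only genes of that
#'   organism are used as targets (candidates are still drawn panel-wide).
#'   Default `NULL` computes sets for every gene of every organism, as
#'   needed by [organism_distance_matrix()].
#' @return data.frame of class `ortholog_sets` with columns `target_gene`,
#'   `organism`, `ortholog_gene`, `identity`, `coverage`, `s`, `density`,
#'   `selected`; the panel is attached as attribute `panel`.
#' @export
ortholog_sets <- function(hits, panel, target_organism = NULL) {
  scored <- score_hits(hits, panel)
  cand <- bbh_candidates(scored)
  if (!is.null(target_organism)) {
    if (!target_organism %in% panel$organisms) {
      stop("organism not in panel: ", target_organism)
    }
    keep <- panel$genes$gene[panel$genes$organism == target_organism]
    cand <- cand[target_gene %in% keep]
  }
  if (nrow(cand) > 0L) {
    cand[, c("density", "selected") := {
      d <- score_density(s)
      sel <- s > mean(s) | d > mean(d)
      if (!any(sel)) sel[] <- TRUE
      list(d, sel)
    }, by = target_gene]
  } else {
    cand[, `:=`(density = numeric(0), selected = logical(0))]
  }
  out <- as.data.frame(cand)
  attr(out, "panel") <- panel
  class(out) <- c("ortholog_sets", "data.frame")
  out
}

#' Write ortholog sets as TSV
#'
#' Columns: `target_gene`, `organism`, `ortholog_gene`, `s`, `selected`
#' (0/1), sorted by target gene then organism.
#'
#' @param osets an `ortholog_sets` data.frame.
#' @param path output path.
#' @export
write_ortholog_sets <- function(osets, path) {
  o <- as.data.frame(osets)
  o <- o[radix_order(o$target_gene, o$organism), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("target_gene", "organism", "ortholog_gene", "s",
                     "selected"), collapse = "\t"), con)
  if (nrow(o) > 0L) {
    writeLines(paste(o$target_gene, o$organism, o$ortholog_gene,
                     fmt_num(o$s), as.integer(o$selected), sep = "\t"), con)
  }
  invisible(path)
}
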