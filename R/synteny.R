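## Gene-neighborhood (synteny) factor K of the co-evolution score. Two
## genes are "in synteny" when, in at least one organism of the panel
## (including their own genome), their representatives sit on the same
## replicon separated by at most `window` intervening gene positions.
## K = 1 when that happens at least once anywhere, 0.9 otherwise — a mild
## bonus, so this windowed proximity criterion (rather than a full
## graph-matching synteny engine) is enough to feed the score.

#' Synteny verdict and factor K for a gene pair
#'
#' For every organism, the representative of a gene is the gene itself in
#' its home genome, or its selected ortholog elsewhere. The pair is in
#' synteny in an organism when both representatives exist, share a replicon
#' and are separated by `<= window` intervening rank positions (adjacent
#' genes have 0 intervening positions). Strand is ignored.
#'
#' @param gene_x,gene_y gene ids (any organism, typically the target's).
#' @param panel an [organism_panel()].
#' @param osets panel-wide or target [ortholog_sets()].
#' @param window maximum number of intervening genes, default 5 (>= 1
#'   behaviour; 0 would mean strict adjacency).
#' @return list with `gene_x`, `gene_y`, `in_synteny` (logical), `k` (1 or
#'   0.9) and `witness_organism` (first organism in panel order where the
#'   pair is syntenic, or `NA`).
#' @export
synteny_factor <- function(gene_x, gene_y, panel, osets, window = 5L) {
  g <- panel$genes
  ix <- match(gene_x, g$gene); iy <- match(gene_y, g$gene)
  if (is.na(ix) || is.na(iy)) stop("gene not in panel")
  os <- as.data.frame(osets)

  reps_of <- function(gene_id, idx) {
    ## organism -> representative gene id (home gene + selected orthologs)
    sel <- os[os$target_gene == gene_id & os$selected, , drop = FALSE]
    stats::setNames(c(gene_id, sel$ortholog_gene),
                    c(g$organism[idx], sel$organism))
  }
  rx <- reps_of(gene_x, ix)
  ry <- reps_of(gene_y, iy)
  shared <- intersect(names(rx), names(ry))
  shared <- panel$organisms[panel$organisms %in% shared]

  for (org in shared) {
    jx <- match(rx[[org]], g$gene); jy <- match(ry[[org]], g$gene)
    if (is.na(jx) || is.na(jy)) next
    if (g$replicon[jx] != g$replicon[jy]) next
    gap <- abs(g$rank[jx] - g$rank[jy]) - 1L
    if (gap <= window) {
      return(list(gene_x = gene_x, gene_y = gene_y, in_synteny = TRUE,
                  k = 1, witness_organism = org))
    }
  }
  list(gene_x = gene_x, gene_y = gene_y, in_synteny = FALSE, k = 0.9,
       witness_organism = NA_character_)
}
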