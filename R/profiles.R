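## Binary occurrence profiles and their comparison with the phi
## coefficient (Pearson correlation specialised to 0/1 variables).

#' Build the occurrence profile of one gene
#'
#' A 0/1 vector over the panel's organism ordering: 1 for the gene's own
#' organism (it exists there by construction) and for every organism hosting
#' a selected ortholog.
#'
#' @param ortholog_set rows of an `ortholog_sets` data.frame for one target
#'   gene (must contain `organism` and `selected`).
#' @param panel an [organism_panel()].
#' @param home_organism the target gene's own organism id.
#' @return named integer 0/1 vector of length `length(panel$organisms)`.
#' @export
build_profile <- function(ortholog_set, panel, home_organism) {
  if (!home_organism %in% panel$organisms) {
    stop("organism not in panel: ", home_organism)
  }
  v <- stats::setNames(integer(length(panel$organisms)), panel$organisms)
  v[home_organism] <- 1L
  sel <- ortholog_set$organism[ortholog_set$selected]
  v[sel[sel %in% panel$organisms]] <- 1L
  v
}

#' Occurrence profiles for every gene of a target organism
#'
#' @param osets an `ortholog_sets` data.frame (see [ortholog_sets()]).
#' @param panel an [organism_panel()].
#' @param target_organism organism whose genes are profiled.
#' @return integer 0/1 matrix, rows = genes of `target_organism` (in
#'   genome-table order), columns = organisms in panel order.
#' @export
build_profiles <- function(osets, panel, target_organism) {
  if (!target_organism %in% panel$organisms) {
    stop("organism not in panel: ", target_organism)
  }
  genes <- panel$genes$gene[panel$genes$organism == target_organism]
  P <- matrix(0L, nrow = length(genes), ncol = length(panel$organisms),
              dimnames = list(genes, panel$organisms))
  P[, target_organism] <- 1L
  sel <- osets[osets$selected & osets$target_gene %in% genes, , drop = FALSE]
  if (nrow(sel) > 0L) {
    P[cbind(match(sel$target_gene, genes),
            match(sel$organism, panel$organisms))] <- 1L
  }
  P
}

phi_from_counts <- function(n11, n00, n10, n01) {
  den <- sqrt((n11 + n10) * (n01 + n00) * (n10 + n00) * (n01 + n11))
  num <- n11 * n00 - n10 * n01
  ifelse(den == 0, 0, num / den)
}

#' Phi coefficient of two binary occurrence profiles
#'
#' `phi = (n11*n00 - n10*n01) / sqrt((n11+n10)(n01+n00)(n10+n00)(n01+n11))`
#' from the 2x2 contingency counts of the two 0/1 vectors; this equals the
#' Pearson correlation of the vectors. If either vector is constant a
#' marginal factor vanishes and 0 is returned by convention (no evidence of
#' co-evolution), which also drops ubiquitous genes from networks naturally.
#'
#' @param px,py 0/1 vectors of equal length >= 2 over the same panel order.
#' @return value in `[-1, 1]`; symmetric in its arguments.
#' @export
phi_coefficient <- function(px, py) {
  if (length(px) != length(py)) stop("profiles have different lengths")
  if (length(px) < 2L) stop("profiles must cover at least two organisms")
  px <- as.integer(px != 0); py <- as.integer(py != 0)
  n11 <- sum(px & py)
  n00 <- sum(!px & !py)
  n10 <- sum(px & !py)
  n01 <- sum(!px & py)
  phi_from_counts(n11, n00, n10, n01)
}

#' Phi coefficients for all row pairs of a profile matrix
#'
#' Vectorised contingency counting via cross-products; identical to calling
#' [phi_coefficient()] on every pair.
#'
#' @param P 0/1 matrix, rows = genes, columns = organisms.
#' @return symmetric matrix of phi values with unit diagonal for
#'   non-constant rows (constant rows give 0 everywhere).
#' @export
phi_matrix <- function(P) {
  storage.mode(P) <- "double"
  Q <- 1 - P
  n11 <- tcrossprod(P)
  n00 <- tcrossprod(Q)
  n10 <- tcrossprod(P, Q)
  n01 <- t(n10)
  phi <- phi_from_counts(n11, n00, n10, n01)
  dimnames(phi) <- list(rownames(P), rownames(P))
  phi
}
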