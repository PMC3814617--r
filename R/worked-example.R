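## A tiny, fully hand-specified panel: 6 organisms, 12 gene families of the
## target organism O1 — one 4-gene module (m1a..m1d), one 3-gene module
## (m2a..m2c) and 5 background genes (b1..b5). Every hit has an exact,
## hand-set identity with full coverage, so every downstream quantity
## (s, phi, D, dmax, K, C, clusters) can be verified by hand. No RNG.

we_presence <- function() {
  orgs <- paste0("O", 1:6)
  fams <- c("m1a", "m1b", "m1c", "m1d", "m2a", "m2b", "m2c",
            "b1", "b2", "b3", "b4", "b5")
  pres <- matrix(0L, length(fams), length(orgs),
                 dimnames = list(fams, orgs))
  pres[c("m1a", "m1b", "m1c", "m1d"), c("O1", "O2", "O3", "O6")] <- 1L
  pres[c("m2a", "m2b", "m2c"), c("O1", "O4", "O5")] <- 1L
  pres["b1", ] <- 1L
  pres["b2", c("O1", "O2")] <- 1L
  pres["b3", c("O1", "O3", "O4")] <- 1L
  pres["b4", "O1"] <- 1L
  pres["b5", c("O1", "O2", "O3", "O4", "O5")] <- 1L
  pres
}

#' The committed worked example: a 6-organism, 12-gene panel
#'
#' Two planted modules (4 and 3 genes, each sharing one presence history)
#' and five background genes. In O1 the two modules sit on different
#' replicons (`c1` and `p1`), so cross-module pairs are never syntenic
#' (K = 0.9) while within-module pairs are operon-like (K = 1). Each gene
#' family has one fixed percent identity for all its ortholog pairs and
#' full alignment coverage, so `s` equals the identity and all candidates
#' of a gene tie — the adaptive selection retains all of them, making the
#' occurrence profiles equal the planted presence matrix by construction.
#'
#' @return list with `panel`, `hits`, `truth` (presence matrix plus module
#'   gene sets) and `target_organism` (`"O1"`).
#' @export
make_worked_example <- function() {
  pres <- we_presence()
  orgs <- colnames(pres)
  fams <- rownames(pres)
  fam_len <- c(m1a = 310L, m1b = 275L, m1c = 420L, m1d = 180L,
               m2a = 350L, m2b = 240L, m2c = 300L,
               b1 = 500L, b2 = 220L, b3 = 260L, b4 = 330L, b5 = 400L)
  fam_id <- c(m1a = 92, m1b = 92, m1c = 92, m1d = 92,
              m2a = 88, m2b = 88, m2c = 88,
              b1 = 85, b2 = 80, b3 = 78, b4 = 82, b5 = 75)

  ## gene layout: O1 on two replicons, others on one
  layout <- list(
    O1 = list(c1 = c("m1a", "m1b", "m1c", "m1d", "b1", "b2", "b3"),
              p1 = c("m2a", "m2b", "m2c", "b4", "b5")))
  gene_rows <- list()
  for (o in orgs) {
    if (o %in% names(layout)) {
      reps <- layout[[o]]
    } else {
      reps <- list(c1 = fams[pres[, o] == 1L])
    }
    for (r in names(reps)) {
      fs <- reps[[r]]
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(organism = o, gene = paste0(o, "_", fs), replicon = r,
                   rank = seq_along(fs) - 1L,
                   strand = rep(c("+", "-"), length.out = length(fs)),
                   length = fam_len[fs], stringsAsFactors = FALSE)
    }
  }
  panel <- organism_panel(do.call(rbind, gene_rows), organisms = orgs)

  ## reciprocal full-coverage hits per family, identity fixed per family
  qs <- character(0); ss <- character(0); idn <- numeric(0); aln <- integer(0)
  for (f in fams) {
    w <- orgs[pres[f, ] == 1L]
    if (length(w) < 2L) next
    pr <- utils::combn(w, 2L)
    ga <- paste0(pr[1L, ], "_", f); gb <- paste0(pr[2L, ], "_", f)
    qs <- c(qs, ga, gb); ss <- c(ss, gb, ga)
    idn <- c(idn, rep(fam_id[[f]], 2L * ncol(pr)))
    aln <- c(aln, rep(fam_len[[f]], 2L * ncol(pr)))
  }
  ## two decoy off-target hits, far below any true hit
  qs <- c(qs, "O2_m1a", "O3_b5"); ss <- c(ss, "O3_b5", "O2_m1a")
  idn <- c(idn, 30, 28); aln <- c(aln, 100L, 90L)
  hits <- data.frame(query = qs, subject = ss, identity = idn,
                     alignment_length = aln, self = FALSE,
                     stringsAsFactors = FALSE)

  list(panel = panel, hits = hits,
       truth = list(presence = pres,
                    modules = list(c("m1a", "m1b", "m1c", "m1d"),
                                   c("m2a", "m2b", "m2c"))),
       target_organism = "O1")
}
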