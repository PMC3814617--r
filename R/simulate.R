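## Synthetic genome panels with planted co-evolution structure. Gene
## families descend from a root repertoire by loss on a phylogeny; each
## planted module is gained/lost as a single block, so its genes share one
## presence history (the co-evolution signal). Lineages also acquire de
## novo families at a constant rate (an open pangenome), which keeps
## distant genomes sharing only a small fraction of their gene content, as
## in real bacterial panels. Hit tables are fabricated around an identity
## decay curve of the patristic distance, so BBH recovery and the adaptive
## selection see realistic inputs without running any aligner.

#' Simulation configuration
#'
#' @param tree a rooted `phylo` object, a newick string, or `NULL` to draw
#'   a random `n_tips`-tip tree ([ape::rtree()]) from the seeded RNG.
#' @param n_tips tips of the random tree when `tree` is `NULL` (default 30).
#' @param modules list of planted modules, each a list with `size`,
#'   `loss_rate` (block loss events per unit branch length) and optional
#'   `rate_mult` (per-gene sequence-divergence multiplier, recycled over
#'   the module's genes; default 1). Module regain is disabled: a lost
#'   block stays lost, keeping truth profiles unambiguous.
#' @param n_background independent background families at the root.
#' @param background_loss per-family loss rate per unit branch length for
#'   background and gained families.
#' @param pangenome_gain de novo family gains per unit branch length
#'   (lineage-specific gene influx). 0 gives a closed, loss-only panel.
#' @param regain_rate rate at which a root background family lost on a
#'   lineage is re-acquired (default 0 = disabled).
#' @param identity_at_zero,identity_at_diameter,identity_floor the percent
#'   identity decay line: expected identity falls linearly from
#'   `identity_at_zero` at patristic distance 0 to `identity_at_diameter`
#'   at the tree diameter, floored at `identity_floor`.
#' @param identity_sd Gaussian noise (identity points) on each drawn hit,
#'   independent per gene family and organism pair.
#' @param pair_effect_sd lineage-effect noise (identity points at the tree
#'   diameter): one offset per organism pair, shared by all gene families
#'   of that pair, with standard deviation scaled by the pair's patristic
#'   distance relative to the diameter. Models systematic rate variation
#'   between lineages — it dominates the family-level scatter for distant
#'   pairs and vanishes for near-identical strains.
#' @param coverage_mean,coverage_sd alignment coverage is drawn from this
#'   Gaussian, clamped to `[0.5, 1]`.
#' @param decoy_rate expected off-target (wrong-family) hits per family.
#' @param sampling_bias named integer vector `tip -> copies`: each named
#'   tip is expanded into that many near-identical genomes (taxon-sampling
#'   skew). `NULL` disables.
#' @param bias_distance patristic distance between bias copies (default
#'   0.02, i.e. near-identical).
#' @param seed integer RNG seed; identical configs give identical output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(tree = NULL, n_tips = 30L,
                              modules = list(list(size = 8L, loss_rate = 0.8),
                                             list(size = 6L, loss_rate = 1.0),
                                             list(size = 5L, loss_rate = 1.2)),
                              n_background = 40L,
                              background_loss = 2,
                              pangenome_gain = 1000,
                              regain_rate = 0,
                              identity_at_zero = 95,
                              identity_at_diameter = 30,
                              identity_floor = 25,
                              identity_sd = 0.2,
                              pair_effect_sd = 4,
                              coverage_mean = 0.97,
                              coverage_sd = 0.005,
                              decoy_rate = 0.3,
                              sampling_bias = NULL,
                              bias_distance = 0.02,
                              seed = 1L) {
  cfg <- list(tree = tree, n_tips = as.integer(n_tips), modules = modules,
              n_background = as.integer(n_background),
              background_loss = background_loss,
              pangenome_gain = pangenome_gain, regain_rate = regain_rate,
              identity_at_zero = identity_at_zero,
              identity_at_diameter = identity_at_diameter,
              identity_floor = identity_floor, identity_sd = identity_sd,
              pair_effect_sd = pair_effect_sd,
              coverage_mean = coverage_mean, coverage_sd = coverage_sd,
              decoy_rate = decoy_rate, sampling_bias = sampling_bias,
              bias_distance = bias_distance, seed = as.integer(seed))
  rates <- c(background_loss, pangenome_gain, regain_rate, decoy_rate,
             vapply(modules, function(m) m$loss_rate, numeric(1L)))
  if (any(rates < 0)) stop("rates must be >= 0")
  class(cfg) <- "simulation_config"
  cfg
}

#' Random clade-structured phylogeny
#'
#' Genome databases sample taxa in tight clusters (many strains of few
#' genera), not uniformly: this generator emulates that by grafting small,
#' shallow clades onto a backbone with long stems. Patristic distances then
#' fall into discrete clumps (small within a clade, large between clades),
#' which is the regime the distance weighting and the adaptive selection
#' are designed for. Draws from the current RNG.
#'
#' @param n_clades number of clades on the backbone.
#' @param tips_per_clade tips in each clade.
#' @param stem_range backbone branch lengths are uniform in this range.
#' @param within_height total height of each clade (its tips are within
#'   `2 * within_height` of each other).
#' @return a `phylo` object with `n_clades * tips_per_clade` tips labelled
#'   `cXX_tY`.
#' @export
clade_tree <- function(n_clades = 15L, tips_per_clade = 2L,
                       stem_range = c(0.25, 0.55), within_height = 0.05) {
  ## star backbone: the deep radiation of bacterial phyla is essentially
  ## unresolved, so clades hang off the root on near-equal stems
  tr <- ape::stree(n_clades, type = "star")
  tr$edge.length <- stats::runif(n_clades, stem_range[1L], stem_range[2L])
  if (tips_per_clade < 2L) return(tr)
  for (i in seq_len(n_clades)) {
    ct <- ape::rcoal(tips_per_clade)
    depth <- max(ape::node.depth.edgelength(ct))
    ct$edge.length <- ct$edge.length / depth * within_height
    ct$tip.label <- sprintf("c%02d_t%d", i, seq_len(tips_per_clade))
    tr <- ape::bind.tree(tr, ct, where = which(tr$tip.label == paste0("t", i)))
  }
  tr
}

resolve_tree <- function(cfg) {
  tr <- cfg$tree
  if (is.null(tr)) {
    tpc <- if (cfg$n_tips >= 20L) 2L else 1L
    tr <- clade_tree(n_clades = ceiling(cfg$n_tips / tpc),
                     tips_per_clade = tpc)
  } else if (is.character(tr)) {
    tr <- tryCatch(suppressWarnings(ape::read.tree(text = tr)),
                   error = function(e) NULL)
    if (is.null(tr) || !inherits(tr, "phylo")) stop("invalid newick tree")
  }
  if (!inherits(tr, "phylo")) stop("tree must be a phylo object or newick")
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  tr
}

#' Simulate a genome panel with planted co-evolving modules
#'
#' Evolves the root repertoire down the tree (module genes as blocks,
#' background genes independently, de novo gains per lineage), lays each
#' surviving genome out on one replicon with module genes contiguous
#' (operon-like), fabricates a reciprocal all-vs-all hit table around the
#' identity decay curve plus low-identity decoy hits, and records the exact
#' truth.
#'
#' @param config a [simulation_config()].
#' @return list with `panel` (an [organism_panel()]), `hits` (data.frame in
#'   [read_hit_table()] layout), `truth` (list: `presence` family-by-
#'   organism 0/1 matrix, `families` registry with module membership,
#'   `modules` the module gene sets), `tree` (the `phylo` used) and
#'   `config`.
#' @export
simulate_panel <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  tree <- resolve_tree(cfg)
  ntip <- length(tree$tip.label)
  nmod <- length(cfg$modules)

  ## --- family registry -----------------------------------------------
  fam_name <- character(0); fam_module <- integer(0); fam_mult <- numeric(0)
  for (m in seq_len(nmod)) {
    sz <- cfg$modules[[m]]$size
    mult <- cfg$modules[[m]]$rate_mult %||% 1
    fam_name <- c(fam_name, sprintf("mod%d_g%02d", m, seq_len(sz)))
    fam_module <- c(fam_module, rep(m, sz))
    fam_mult <- c(fam_mult, rep_len(mult, sz))
  }
  fam_name <- c(fam_name, sprintf("bg%03d", seq_len(cfg$n_background)))
  fam_module <- c(fam_module, rep(NA_integer_, cfg$n_background))
  fam_mult <- c(fam_mult, rep(1, cfg$n_background))
  n_root_bg <- cfg$n_background
  fam_len <- sample(120:600, length(fam_name), replace = TRUE)
  n_fam <- length(fam_name)
  bg_root_idx <- which(is.na(fam_module))

  ## --- evolve presence down the tree ---------------------------------
  ## state per node: module presence (logical) + indices of present
  ## background/gained families
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  root <- ntip + 1L
  n_nodes <- ntip + tree$Nnode
  st_mod <- vector("list", n_nodes)
  st_bg <- vector("list", n_nodes)
  st_mod[[root]] <- rep(TRUE, nmod)
  st_bg[[root]] <- bg_root_idx

  gained_name <- character(0); gained_len <- integer(0)
  mod_rates <- vapply(cfg$modules, function(m) m$loss_rate, numeric(1L))

  for (e in seq_len(nrow(tree_cw$edge))) {
    p <- tree_cw$edge[e, 1L]; child <- tree_cw$edge[e, 2L]
    len <- tree_cw$edge.length[e]
    mods <- st_mod[[p]]
    if (nmod > 0L) {
      lose <- mods & (runif(nmod) < 1 - exp(-mod_rates * len))
      mods[lose] <- FALSE
    }
    bg <- st_bg[[p]]
    if (length(bg) > 0L) {
      keep <- runif(length(bg)) >= 1 - exp(-cfg$background_loss * len)
      bg <- bg[keep]
    }
    if (cfg$regain_rate > 0) {
      lost_root <- setdiff(bg_root_idx, bg)
      back <- lost_root[runif(length(lost_root)) <
                          1 - exp(-cfg$regain_rate * len)]
      bg <- sort(c(bg, back))
    }
    n_gain <- if (cfg$pangenome_gain > 0) rpois(1L, cfg$pangenome_gain * len)
              else 0L
    if (n_gain > 0L) {
      new_idx <- n_fam + length(gained_name) + seq_len(n_gain)
      gained_name <- c(gained_name,
                       sprintf("acq%05d", length(gained_name) + seq_len(n_gain)))
      gained_len <- c(gained_len, sample(120:600, n_gain, replace = TRUE))
      bg <- c(bg, new_idx)
    }
    st_mod[[child]] <- mods
    st_bg[[child]] <- bg
  }

  if (length(gained_name) > 0L) {
    fam_name <- c(fam_name, gained_name)
    fam_module <- c(fam_module, rep(NA_integer_, length(gained_name)))
    fam_mult <- c(fam_mult, rep(1, length(gained_name)))
    fam_len <- c(fam_len, gained_len)
    n_fam <- length(fam_name)
  }

  ## --- organisms (with sampling-bias copies) -------------------------
  tips <- tree$tip.label
  orgs <- character(0); src_tip <- character(0)
  for (t_i in seq_along(tips)) {
    tp <- tips[t_i]
    copies <- 1L
    if (!is.null(cfg$sampling_bias) && tp %in% names(cfg$sampling_bias)) {
      copies <- as.integer(cfg$sampling_bias[[tp]])
    }
    ids <- if (copies == 1L) tp else c(tp, paste0(tp, ".b", 2:copies))
    orgs <- c(orgs, ids)
    src_tip <- c(src_tip, rep(tp, copies))
  }

  org_fams <- lapply(seq_along(orgs), function(i) {
    t_idx <- match(src_tip[i], tips)
    mods <- which(st_mod[[t_idx]])
    mod_fams <- which(fam_module %in% mods)
    sort(c(mod_fams, st_bg[[t_idx]]))
  })
  names(org_fams) <- orgs

  ## --- genome tables: one replicon, modules contiguous ----------------
  gene_rows <- lapply(seq_along(orgs), function(i) {
    fams <- org_fams[[i]]
    data.frame(organism = orgs[i],
               gene = paste0(orgs[i], "_", fam_name[fams]),
               replicon = "c1",
               rank = seq_along(fams) - 1L,
               strand = sample(c("+", "-"), length(fams), replace = TRUE),
               length = fam_len[fams],
               stringsAsFactors = FALSE)
  })
  panel <- organism_panel(do.call(rbind, gene_rows), organisms = orgs)

  ## --- expanded patristic distances -----------------------------------
  dmat_tip <- ape::cophenetic.phylo(tree)
  diam <- max(dmat_tip)
  if (diam <= 0) diam <- 1
  dmat <- dmat_tip[src_tip, src_tip, drop = FALSE]
  dimnames(dmat) <- list(orgs, orgs)
  same_tip <- outer(src_tip, src_tip, "==")
  dmat[same_tip] <- cfg$bias_distance
  diag(dmat) <- 0

  ## --- hit table -------------------------------------------------------
  ## lineage effect: one identity offset per organism pair, shared by all
  ## families of that pair
  n_org <- length(orgs)
  pair_eff <- matrix(0, n_org, n_org)
  if (cfg$pair_effect_sd > 0 && n_org > 1L) {
    ut <- upper.tri(pair_eff)
    pair_eff[ut] <- rnorm(sum(ut), 0, cfg$pair_effect_sd)
    pair_eff <- pair_eff + t(pair_eff)
    pair_eff <- pair_eff * (dmat / diam)
  }
  fam_where <- vector("list", n_fam)
  for (i in seq_along(orgs)) {
    for (f in org_fams[[i]]) fam_where[[f]] <- c(fam_where[[f]], i)
  }
  qs <- list(); ss <- list(); ids <- list(); alns <- list()
  hk <- 0L
  for (f in seq_len(n_fam)) {
    w <- fam_where[[f]]
    k <- length(w)
    if (k < 2L) next
    pr <- utils::combn(k, 2L)
    a <- w[pr[1L, ]]; b <- w[pr[2L, ]]
    d <- dmat[cbind(a, b)]
    mu <- cfg$identity_at_zero -
      (cfg$identity_at_zero - cfg$identity_at_diameter) *
      (d / diam) * fam_mult[f]
    idn <- pmin(pmax(mu + pair_eff[cbind(a, b)] +
                       rnorm(length(a), 0, cfg$identity_sd),
                     cfg$identity_floor), 99.5)
    cov <- pmin(pmax(rnorm(length(a), cfg$coverage_mean, cfg$coverage_sd),
                     0.5), 1)
    aln <- pmax(1L, as.integer(round(cov * fam_len[f])))
    ga <- paste0(orgs[a], "_", fam_name[f])
    gb <- paste0(orgs[b], "_", fam_name[f])
    hk <- hk + 1L
    qs[[hk]] <- c(ga, gb); ss[[hk]] <- c(gb, ga)
    ids[[hk]] <- c(idn, idn); alns[[hk]] <- c(aln, aln)
  }
  hits <- data.frame(query = unlist(qs), subject = unlist(ss),
                     identity = unlist(ids),
                     alignment_length = unlist(alns),
                     stringsAsFactors = FALSE)

  ## decoy off-target hits (single direction, low identity)
  n_decoy <- if (cfg$decoy_rate > 0) rpois(1L, cfg$decoy_rate * n_fam) else 0L
  if (n_decoy > 0L && nrow(panel$genes) > 1L) {
    gi <- sample.int(nrow(panel$genes), n_decoy, replace = TRUE)
    gj <- sample.int(nrow(panel$genes), n_decoy, replace = TRUE)
    ok <- panel$genes$organism[gi] != panel$genes$organism[gj]
    gi <- gi[ok]; gj <- gj[ok]
    if (length(gi) > 0L) {
      lenj <- pmax(panel$genes$length[gi], panel$genes$length[gj])
      decoys <- data.frame(query = panel$genes$gene[gi],
                           subject = panel$genes$gene[gj],
                           identity = runif(length(gi), 20, 35),
                           alignment_length = pmax(1L, as.integer(
                             round(runif(length(gi), 0.2, 0.5) * lenj))),
                           stringsAsFactors = FALSE)
      hits <- rbind(hits, decoys)
    }
  }
  hits$self <- FALSE

  ## --- truth -----------------------------------------------------------
  presence <- matrix(0L, n_fam, length(orgs),
                     dimnames = list(fam_name, orgs))
  for (i in seq_along(orgs)) presence[org_fams[[i]], i] <- 1L
  module_sets <- lapply(seq_len(nmod), function(m) fam_name[which(fam_module == m)])
  families <- data.frame(family = fam_name, module = fam_module,
                         length = fam_len, rate_mult = fam_mult,
                         stringsAsFactors = FALSE)

  list(panel = panel, hits = hits,
       truth = list(presence = presence, families = families,
                    modules = module_sets),
       tree = tree, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated panel to a directory
#'
#' Emits `genomes.tsv`, `hits.tsv` and `truth.tsv` (family-by-organism 0/1
#' presence with module membership) in the package's io formats.
#'
#' @param sim result of [simulate_panel()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_table(sim$panel, file.path(dir, "genomes.tsv"))
  write_hit_table(sim$hits, file.path(dir, "hits.tsv"))
  tr <- data.frame(family = rownames(sim$truth$presence),
                   module = ifelse(is.na(sim$truth$families$module), "",
                                   sim$truth$families$module),
                   stringsAsFactors = FALSE)
  tr <- cbind(tr, as.data.frame(sim$truth$presence))
  con <- file(file.path(dir, "truth.tsv"), open = "wt")
  writeLines(paste(colnames(tr), collapse = "\t"), con)
  writeLines(do.call(paste, c(tr, sep = "\t")), con)
  close(con)
  invisible(dir)
}
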