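## End-to-end driver: orthologs -> profiles -> distances -> scores ->
## clusters, with every stage's artifact written to disk so a run can be
## resumed or inspected per stage. Deterministic: identical inputs and
## config give byte-identical artifacts and the same config hash.

## Polynomial rolling hash over the serialised config; enough to detect
## config drift between runs in the log.
config_hash <- function(x) {
  txt <- paste(utils::capture.output(dput(x)), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param genomes path to the genome table TSV.
#' @param hits path to the all-vs-all hit table.
#' @param target_organism organism whose genes are profiled and scored.
#' @param out_dir output directory for the stage artifacts.
#' @param threshold edge retention threshold on C (default 0.77).
#' @param window synteny window in intervening genes (default 5).
#' @param inflation MCL inflation (default 2).
#' @param exponent distance exponent of the score (default 3).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genomes, hits, target_organism, out_dir,
                            threshold = 0.77, window = 5L, inflation = 2,
                            exponent = 3) {
  structure(list(genomes = genomes, hits = hits,
                 target_organism = target_organism, out_dir = out_dir,
                 threshold = threshold, window = as.integer(window),
                 inflation = inflation, exponent = exponent),
            class = "pipeline_config")
}

#' Run the whole co-evolution pipeline
#'
#' Stages: read inputs, panel-wide BBH + adaptive ortholog selection,
#' occurrence profiles of the target organism, content-based organism
#' distances, co-evolution scores and thresholded network, MCL partition.
#' Artifacts written to `config$out_dir`: `orthosets.tsv`, `profiles.tsv`,
#' `edges.tsv`, `edges.abc`, `clusters.tsv`, `config.yaml` (the echoed
#' config with its hash) and `run_log.txt`. Any stage failure aborts with
#' the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list with `panel`, `osets`, `profiles`, `D`, `network`,
#'   `partition`, `config_hash` and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("phylocoevo ",
                        as.character(utils::packageVersion("phylocoevo"))),
                 paste0("R ", R.version$major, ".", R.version$minor))

  panel <- stage("read_genomes", read_genome_table(cfg$genomes))
  hits <- stage("read_hits", read_hit_table(cfg$hits, panel))
  if (!cfg$target_organism %in% panel$organisms) {
    stop("pipeline stage 'read_genomes' failed: target organism '",
         cfg$target_organism, "' not in panel", call. = FALSE)
  }
  osets <- stage("orthologs", ortholog_sets(hits, panel))
  write_ortholog_sets(osets[osets$target_gene %in%
                              panel$genes$gene[panel$genes$organism ==
                                                 cfg$target_organism], ,
                            drop = FALSE],
                      file.path(cfg$out_dir, "orthosets.tsv"))
  profiles <- stage("profiles",
                    build_profiles(osets, panel, cfg$target_organism))
  write_profiles(profiles, file.path(cfg$out_dir, "profiles.tsv"))
  D <- stage("distances", organism_distance_matrix(panel, osets))
  network <- stage("score",
                   score_all_pairs(panel, profiles, D, osets,
                                   threshold = cfg$threshold,
                                   window = cfg$window,
                                   exponent = cfg$exponent))
  write_edge_list(network, file.path(cfg$out_dir, "edges.tsv"),
                  abc_path = file.path(cfg$out_dir, "edges.abc"))
  sub <- coevolution_network(network$edges,
                             nodes = unique(c(network$edges$geneX,
                                              network$edges$geneY)),
                             threshold = cfg$threshold)
  partition <- stage("cluster",
                     mcl_cluster(build_transition_matrix(sub),
                                 inflation = cfg$inflation))
  write_clusters(partition, file.path(cfg$out_dir, "clusters.tsv"))

  hash <- config_hash(unclass(cfg))
  yaml::write_yaml(c(unclass(cfg), list(config_hash = hash)),
                   file.path(cfg$out_dir, "config.yaml"))
  log_lines <- c(log_lines,
                 paste0("config_hash ", hash),
                 paste0("organisms ", length(panel$organisms)),
                 paste0("genes ", nrow(panel$genes)),
                 paste0("hits ", nrow(hits)),
                 paste0("profiled_genes ", nrow(profiles)),
                 paste0("edges ", nrow(network$edges)),
                 paste0("clusters ", length(partition)))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(panel = panel, osets = osets, profiles = profiles, D = D,
                 network = network, partition = partition,
                 config_hash = hash, out_dir = cfg$out_dir))
}
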