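## Readers and writers for the pipeline's plain-text formats.
##
## All writers are byte-stable: fixed column orders, radix (C-locale) sorts
## and 6-significant-digit float formatting, so identical inputs always give
## identical files.

fmt_num <- function(x) sprintf("%.6g", x)

radix_order <- function(...) order(..., method = "radix")

#' Construct an organism panel
#'
#' A panel is the fixed, ordered organism list plus one row of gene
#' coordinates per gene (`organism`, `gene`, `replicon`, `rank`, `strand`,
#' `length`). The organism ordering is frozen at construction and reused for
#' every occurrence profile.
#'
#' @param genes data.frame with columns `organism`, `gene`, `replicon`,
#'   `rank` (0-based dense position along the replicon), `strand` (`+`/`-`),
#'   `length` (protein length, residues >= 1).
#' @param organisms optional character vector fixing the organism order;
#'   defaults to first-appearance order in `genes`.
#' @return An object of class `organism_panel`.
#' @export
organism_panel <- function(genes, organisms = NULL) {
  req <- c("organism", "gene", "replicon", "rank", "strand", "length")
  miss <- setdiff(req, names(genes))
  if (length(miss) > 0L) {
    stop("genome table is missing columns: ", paste(miss, collapse = ", "))
  }
  genes <- as.data.frame(genes)[, req]
  genes$organism <- as.character(genes$organism)
  genes$gene <- as.character(genes$gene)
  genes$replicon <- as.character(genes$replicon)
  genes$strand <- as.character(genes$strand)
  genes$rank <- as.integer(genes$rank)
  genes$length <- as.integer(genes$length)
  if (nrow(genes) == 0L) stop("no records in genome table")
  dup <- genes$gene[duplicated(genes$gene)]
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in genome table: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- which(genes$rank < 0L | genes$length < 1L | is.na(genes$rank) |
                 is.na(genes$length))
  if (length(bad) > 0L) {
    stop("invalid rank/length at record ", bad[1L],
         " (gene ", genes$gene[bad[1L]], ")")
  }
  if (is.null(organisms)) organisms <- unique(genes$organism)
  organisms <- as.character(organisms)
  if (anyDuplicated(organisms)) stop("duplicate organism ids in panel")
  if (!all(genes$organism %in% organisms)) {
    stop("genes reference organisms absent from the panel ordering")
  }
  structure(list(organisms = organisms, genes = genes),
            class = "organism_panel")
}

#' @export
print.organism_panel <- function(x, ...) {
  cat("<organism_panel> ", length(x$organisms), " organisms, ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read a genome table
#'
#' Expects a TSV with header columns `organism`, `gene`, `replicon`, `rank`,
#' `strand`, `length`. Organism order is the order of first appearance.
#' Duplicated gene ids and negative ranks/lengths are hard errors.
#'
#' @param path path to the TSV file.
#' @return An [organism_panel()].
#' @export
read_genome_table <- function(path) {
  if (!file.exists(path)) stop("genome table not found: ", path)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop("no records in genome table: ", path))
  if (nrow(tab) == 0L) stop("no records in genome table: ", path)
  organism_panel(tab)
}

#' Write a genome table
#'
#' Inverse of [read_genome_table()]; rows ordered by (organism in panel
#' order, replicon, rank) for byte stability.
#'
#' @param panel an [organism_panel()].
#' @param path output path.
#' @export
write_genome_table <- function(panel, path) {
  g <- panel$genes
  g <- g[radix_order(match(g$organism, panel$organisms), g$replicon, g$rank), ]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("organism", "gene", "replicon", "rank", "strand",
                     "length"), collapse = "\t"), con)
  writeLines(paste(g$organism, g$gene, g$replicon, g$rank, g$strand,
                   g$length, sep = "\t"), con)
  invisible(path)
}

#' Read an all-vs-all protein hit table
#'
#' Accepts the BLAST tabular dialect: no header, >= 4 tab-separated columns,
#' of which the first four are interpreted as query id, subject id, percent
#' identity and alignment length; any further (genuine outfmt-6) columns are
#' ignored. Protein lengths come from the genome table, not from the hit
#' file. Hits within one organism are kept but flagged `self`.
#'
#' @param path path to the hit table.
#' @param panel an [organism_panel()]; every gene id must resolve in it.
#' @return data.frame with columns `query`, `subject`, `identity`,
#'   `alignment_length`, `self`, in file order.
#' @export
read_hit_table <- function(path, panel) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(raw) < 4L) stop("hit table needs >= 4 columns: ", path)
  hits <- data.frame(query = raw[[1L]], subject = raw[[2L]],
                     identity = as.numeric(raw[[3L]]),
                     alignment_length = as.integer(round(as.numeric(raw[[4L]]))),
                     stringsAsFactors = FALSE)
  org_of <- panel$genes$organism[match(hits$query, panel$genes$gene)]
  org_of_s <- panel$genes$organism[match(hits$subject, panel$genes$gene)]
  bad <- which(is.na(org_of) | is.na(org_of_s))
  if (length(bad) > 0L) {
    ids <- unique(c(hits$query[bad], hits$subject[bad]))
    ids <- ids[!ids %in% panel$genes$gene]
    stop("hit table references unknown gene id(s): ",
         paste(utils::head(ids, 5L), collapse = ", "))
  }
  if (any(is.na(hits$identity) | hits$identity < 0 | hits$identity > 100)) {
    stop("percent identity outside [0,100] in hit table: ", path)
  }
  if (any(is.na(hits$alignment_length) | hits$alignment_length < 1L)) {
    stop("alignment length < 1 in hit table: ", path)
  }
  hits$self <- org_of == org_of_s
  hits
}

#' Write a hit table in the BLAST tabular dialect
#'
#' @param hits data.frame as returned by [read_hit_table()] (the `self`
#'   column, if present, is not written).
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(hits$query, hits$subject, fmt_num(hits$identity),
                   hits$alignment_length, sep = "\t"), con)
  invisible(path)
}

#' Write a co-evolution network as an edge list
#'
#' Emits a TSV with header `geneX geneY phi dmax k C` and, optionally, the
#' three-column MCL "abc" file (`geneX geneY C`, no header). Edges are
#' written with geneX < geneY (C collation) and sorted lexically, floats at
#' 6 significant digits.
#'
#' @param network a `coevolution_network` (see [score_all_pairs()]).
#' @param path output TSV path.
#' @param abc_path optional path for the abc companion file.
#' @export
write_edge_list <- function(network, path, abc_path = NULL) {
  e <- network$edges
  swap <- e$geneX > e$geneY
  tmp <- e$geneX[swap]; e$geneX[swap] <- e$geneY[swap]; e$geneY[swap] <- tmp
  e <- e[radix_order(e$geneX, e$geneY), , drop = FALSE]
  con <- file(path, open = "wt")
  writeLines(paste(c("geneX", "geneY", "phi", "dmax", "k", "C"),
                   collapse = "\t"), con)
  if (nrow(e) > 0L) {
    writeLines(paste(e$geneX, e$geneY, fmt_num(e$phi), fmt_num(e$dmax),
                     fmt_num(e$k), fmt_num(e$C), sep = "\t"), con)
  }
  close(con)
  if (!is.null(abc_path)) {
    con <- file(abc_path, open = "wt")
    if (nrow(e) > 0L) {
      writeLines(paste(e$geneX, e$geneY, fmt_num(e$C), sep = "\t"), con)
    }
    close(con)
  }
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path edge list TSV path.
#' @return a `coevolution_network` object.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  n_lines <- length(readLines(path))
  if (n_lines <= 1L) {
    e <- data.frame(geneX = character(), geneY = character(),
                    phi = numeric(), dmax = numeric(), k = numeric(),
                    C = numeric(), stringsAsFactors = FALSE)
  } else {
    e <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  coevolution_network(e, nodes = sort(unique(c(e$geneX, e$geneY))),
                      threshold = NA_real_)
}

#' Write a cluster partition
#'
#' One cluster per line, tab-separated gene ids; clusters ordered by
#' descending size then lexically by first member; members sorted lexically.
#' An empty partition yields an empty file.
#'
#' @param partition a `cluster_partition` (see [mcl_cluster()]) or a plain
#'   list of character vectors.
#' @param path output path.
#' @export
write_clusters <- function(partition, path) {
  cl <- lapply(unclass(partition), function(m) m[radix_order(m)])
  if (length(cl) > 0L) {
    first <- vapply(cl, `[`, character(1L), 1L)
    cl <- cl[radix_order(-lengths(cl), first)]
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in cl) writeLines(paste(m, collapse = "\t"), con)
  invisible(path)
}

#' Read a cluster partition written by [write_clusters()]
#'
#' @param path cluster file path.
#' @return a `cluster_partition`.
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cluster_partition(lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]]))
}

#' Write occurrence profiles as a 0/1 matrix TSV
#'
#' Rows are genes (lexical order), columns organisms in panel order; first
#' column header is `gene`.
#'
#' @param profiles 0/1 matrix, rownames = genes, colnames = organisms.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.matrix(profiles))
  profiles <- profiles[radix_order(rownames(profiles)), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(profiles)), collapse = "\t"), con)
  body <- apply(profiles, 1L, function(r) paste(as.integer(r), collapse = "\t"))
  writeLines(paste(rownames(profiles), body, sep = "\t"), con)
  invisible(path)
}

#' Read a profile matrix written by [write_profiles()]
#'
#' @param path profile TSV path.
#' @return integer 0/1 matrix, rownames = genes, colnames = organisms.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1L]]
  m
}
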