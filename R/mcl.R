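## From-scratch Markov Cluster algorithm (flow simulation on graphs):
## alternate expansion (matrix squaring) and inflation (entrywise power and
## column renormalisation) with pruning of vanishing entries, then read the
## clusters off the attractor structure of the limit matrix. Networks here
## are small (genes of one organism), so dense base-R linear algebra is the
## right tool.

#' Construct a cluster partition
#'
#' @param clusters list of character vectors (disjoint gene sets; singletons
#'   allowed).
#' @return object of class `cluster_partition` (a list).
#' @export
cluster_partition <- function(clusters) {
  clusters <- lapply(clusters, as.character)
  all_g <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_g)) stop("clusters are not disjoint")
  structure(clusters, class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> ", length(x), " clusters over ",
      length(unlist(x)), " genes; sizes: ",
      paste(sort(lengths(x), decreasing = TRUE), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Build the column-stochastic transition matrix of a network
#'
#' Adjacency of the retained (non-negative) edges plus a self-loop per node
#' equal to its maximum incident edge weight (1 for isolated nodes) — the
#' standard convention that damps odd-length path parity effects — then
#' column normalisation.
#'
#' @param network a `coevolution_network`, or a data.frame of edges with
#'   columns `geneX`, `geneY`, `C`.
#' @param nodes optional node set; defaults to the network's nodes (or the
#'   genes incident to an edge for a plain data.frame).
#' @return column-stochastic matrix with gene dimnames; `0 x 0` for an
#'   empty network.
#' @export
build_transition_matrix <- function(network, nodes = NULL) {
  edges <- if (inherits(network, "coevolution_network")) network$edges
           else as.data.frame(network)
  if (is.null(nodes)) {
    nodes <- if (inherits(network, "coevolution_network")) network$nodes
             else unique(c(edges$geneX, edges$geneY))
  }
  nodes <- sort(as.character(nodes), method = "radix")
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (n == 0L) return(A)
  if (nrow(edges) > 0L) {
    if (any(edges$C < 0)) stop("negative edge weights are not allowed")
    i <- match(edges$geneX, nodes); j <- match(edges$geneY, nodes)
    A[cbind(i, j)] <- edges$C
    A[cbind(j, i)] <- edges$C
  }
  loops <- apply(A, 2L, max)
  diag(A) <- ifelse(loops > 0, loops, 1)
  sweep(A, 2L, colSums(A), "/")
}

stop_if_not_stochastic <- function(M, tol = 1e-9) {
  if (nrow(M) == 0L) return(invisible(M))
  if (any(M < 0) || any(abs(colSums(M) - 1) > tol)) {
    stop("matrix is not column-stochastic")
  }
  invisible(M)
}

## One inflation step: entrywise power, pruning, column renormalisation.
## The per-column maximum always survives pruning so no column can vanish.
inflate <- function(M, inflation, prune_cutoff) {
  M <- M^inflation
  if (prune_cutoff > 0) {
    idx <- cbind(max.col(t(M)), seq_len(ncol(M)))
    vmax <- M[idx]
    M[M < prune_cutoff] <- 0
    M[idx] <- vmax
  }
  sweep(M, 2L, colSums(M), "/")
}

#' Markov Cluster algorithm
#'
#' Iterates expansion (`M %*% M`) and inflation (entrywise power
#' `inflation`, pruning of entries below `prune_cutoff`, column
#' renormalisation) until the largest entry change drops below `tol` or
#' `max_iter` is reached (the latter with a warning; clusters are then read
#' from the current state). Clusters are the attractor systems of the limit
#' matrix: rows with positive diagonal mass are attractors, attractors
#' connected through positive flow are merged, and every node joins the
#' attractor receiving most of its column mass (ties broken towards the
#' lexicographically smallest attractor). Deterministic for fixed inputs.
#'
#' @param M column-stochastic matrix from [build_transition_matrix()].
#' @param inflation inflation exponent, > 1; default 2.
#' @param max_iter iteration cap, default 100.
#' @param tol convergence tolerance on the max entry change, default 1e-8.
#' @param prune_cutoff entries below this are dropped after inflation
#'   (default 1e-5); the column maximum is always retained.
#' @return a `cluster_partition` over the matrix's nodes.
#' @export
mcl_cluster <- function(M, inflation = 2, max_iter = 100L, tol = 1e-8,
                        prune_cutoff = 1e-5) {
  if (inflation <= 1) stop("inflation must be > 1")
  stop_if_not_stochastic(M)
  if (nrow(M) == 0L) return(cluster_partition(list()))
  nodes <- rownames(M)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    M_new <- inflate(M %*% M, inflation, prune_cutoff)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; clustering current state")
  }
  interpret_attractors(M, nodes, prune_cutoff)
}

## Read clusters from a (near-)limit MCL matrix.
interpret_attractors <- function(M, nodes, eps) {
  n <- length(nodes)
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0L) attractors <- seq_len(n)  # degenerate guard
  ## union-find over attractors connected by positive flow
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in attractors) for (j in attractors) {
    if (i < j && (M[i, j] > eps || M[j, i] > eps)) union(i, j)
  }
  ## assign every node to the attractor holding most of its column mass
  assignment <- integer(n)
  for (j in seq_len(n)) {
    mass <- M[attractors, j]
    pos <- which(mass > 0)
    if (length(pos) == 0L) { assignment[j] <- j; next }  # stray singleton
    best <- pos[mass[pos] == max(mass[pos])]
    a <- attractors[best[order(nodes[attractors[best]], method = "radix")[1L]]]
    assignment[j] <- find(a)
  }
  groups <- split(nodes, assignment)
  cluster_partition(unname(groups))
}

#' Cluster the network over a sweep of edge thresholds
#'
#' For each threshold `t` the network is re-filtered to edges with `C > t`
#' (so raising the threshold can only remove edges — edge sets are nested),
#' re-clustered with MCL, and the size of the cluster containing
#' `query_gene` is recorded (0 when the gene has no surviving edge at that
#' threshold). Nodes are the edge-incident genes at each threshold.
#'
#' @param network a `coevolution_network` whose edges were retained at a
#'   threshold no larger than `min(thresholds)`.
#' @param thresholds ascending numeric vector of thresholds.
#' @param query_gene gene whose cluster-size trajectory is tracked.
#' @param inflation,max_iter,tol,prune_cutoff passed to [mcl_cluster()].
#' @return list with `partitions` (one `cluster_partition` per threshold)
#'   and `trajectory` (data.frame `threshold`, `n_edges`,
#'   `query_cluster_size`).
#' @export
sweep_thresholds <- function(network, thresholds, query_gene,
                             inflation = 2, max_iter = 100L, tol = 1e-8,
                             prune_cutoff = 1e-5) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  parts <- vector("list", length(thresholds))
  sizes <- integer(length(thresholds))
  n_edges <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    e <- network$edges[network$edges$C > thresholds[i], , drop = FALSE]
    n_edges[i] <- nrow(e)
    sub <- coevolution_network(e, nodes = unique(c(e$geneX, e$geneY)),
                               threshold = thresholds[i])
    M <- build_transition_matrix(sub)
    parts[[i]] <- mcl_cluster(M, inflation = inflation, max_iter = max_iter,
                              tol = tol, prune_cutoff = prune_cutoff)
    hit <- vapply(parts[[i]], function(cl) query_gene %in% cl, logical(1L))
    sizes[i] <- if (any(hit)) lengths(parts[[i]])[which(hit)[1L]] else 0L
  }
  list(partitions = parts,
       trajectory = data.frame(threshold = thresholds, n_edges = n_edges,
                               query_cluster_size = sizes))
}
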