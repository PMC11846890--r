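# Signature discovery: binarized co-positivity networks over dynamic genes
# in aged cells, per-pair permutation-thresholded edges, Louvain hubs.

#' Binarize aged cells over a dynamic-gene subset
#'
#' Restricts the counts to the supplied dynamic genes and to aged cells
#' (mice older than `age_floor` months, default 21; humans at or above 48
#' years), then binarizes at one UMI. Populations with fewer than
#' `min_cells` aged cells are not tested further.
#'
#' @param data An [annotated_counts()] with raw counts.
#' @param genes Character vector of dynamic genes.
#' @param species `"mouse"` or `"human"`.
#' @param age_floor Age cutoff: mouse cells must be strictly older
#'   (default 21 months); human cells at least this old (default 48 years).
#' @param min_cells Minimum aged cells (100).
#' @param cells Optional additional cell filter (e.g. one cell type).
#' @return A cells x genes binary matrix (dgCMatrix), or `NULL` when the
#'   subset is too small (a message is logged).
#' @export
binarize_subset <- function(data, genes, species = c("mouse", "human"),
                            age_floor = NULL, min_cells = 100L, cells = NULL) {
  species <- match.arg(species)
  if (is.null(age_floor)) age_floor <- if (species == "mouse") 21 else 48
  keep <- if (species == "mouse") {
    data$cell_meta$age > age_floor
  } else {
    data$cell_meta$age >= age_floor
  }
  if (!is.null(cells)) {
    sel <- rep(FALSE, length(keep))
    sel[cells] <- TRUE
    keep <- keep & sel
  }
  if (sum(keep) < min_cells) {
    inform(sprintf(
      "binarize_subset: only %d aged cells (< %d); subset not tested",
      sum(keep), min_cells
    ))
    return(NULL)
  }
  genes <- intersect(genes, data$genes)
  sub <- data$counts[genes, which(keep), drop = FALSE]
  b <- Matrix::t(sub)
  b@x <- rep(1, length(b@x))
  b
}

# phi/Pearson correlation matrix between binary columns, from co-positive
# counts and margins; columns with zero variance yield NA
binary_cor <- function(b) {
  n <- nrow(b)
  k <- Matrix::colSums(b)
  co <- as.matrix(Matrix::crossprod(b))
  denom <- sqrt(k * (n - k))
  r <- (n * co - outer(k, k)) / outer(denom, denom)
  r[!is.finite(r)] <- NA_real_
  r
}

# null r for a pair with margins (ki, kj) given the shuffled overlap count m
r_from_overlap <- function(m, n, ki, kj) {
  (n * m - ki * kj) / sqrt(ki * (n - ki) * kj * (n - kj))
}

#' Pairwise co-positivity correlations with per-pair permutation thresholds
#'
#' For every unordered gene pair, computes Pearson's correlation of the
#' binary positivity vectors (the phi coefficient). Each pair's null is
#' built by reshuffling one gene's binary vector across cells `n_perm`
#' times and recomputing r; a pair is kept when `r > 0` and `r` exceeds the
#' 99th percentile of its null by more than 0.05 (strict inequality).
#' Constant genes (all 0 or all 1) have undefined correlations; their pairs
#' are dropped with a logged count.
#'
#' @param b Cells x genes binary matrix from [binarize_subset()].
#' @param n_perm Permutations per pair (default 500).
#' @param seed Integer seed.
#' @param q Percentile of the null (default 0.99), linear interpolation
#'   between order statistics.
#' @param margin Threshold margin above the null percentile (default 0.05).
#' @return A tibble (`senesig_edges`): `gene_i`, `gene_j`, `r`, `t`
#'   (threshold), `kept`.
#' @export
pairwise_r <- function(b, n_perm = 500L, seed = 1L, q = 0.99, margin = 0.05) {
  if (ncol(b) < 2) abort("need at least 2 genes", class = "senesig_data_error")
  set.seed(seed)
  n <- nrow(b)
  genes <- colnames(b)
  k <- Matrix::colSums(b)
  r_mat <- binary_cor(b)
  pairs <- which(upper.tri(r_mat), arr.ind = TRUE)
  gi <- pairs[, 1]
  gj <- pairs[, 2]
  r <- r_mat[pairs]
  defined <- !is.na(r)
  if (any(!defined)) {
    inform(sprintf(
      "pairwise_r: dropped %d pair(s) with a constant gene vector",
      sum(!defined)
    ))
  }
  t_vals <- rep(NA_real_, length(r))
  idx <- which(defined)
  for (p in idx) {
    # reshuffling gene j's positives across cells makes the co-positive
    # count hypergeometric with the pair's margins fixed
    m_null <- rhyper(n_perm, m = k[gj[p]], n = n - k[gj[p]], k = k[gi[p]])
    r_null <- r_from_overlap(m_null, n, k[gi[p]], k[gj[p]])
    t_vals[p] <- quantile(r_null, q, names = FALSE, type = 7) + margin
  }
  edges <- tibble(
    gene_i = genes[gi], gene_j = genes[gj], r = r, t = t_vals,
    kept = defined & r > 0 & r > t_vals
  )
  edges$kept[is.na(edges$kept)] <- FALSE
  class(edges) <- c("senesig_edges", class(edges))
  edges
}

#' Build the co-positivity network and cluster it with Louvain
#'
#' @param edges Edge table from [pairwise_r()].
#' @param resolution Louvain resolution (default 1).
#' @param seed Integer seed (Louvain uses R's RNG; a fixed seed makes the
#'   partition reproducible).
#' @return An `igraph` graph over the genes with at least one kept edge,
#'   edge weights `r`, and a vertex attribute `hub` holding the Louvain
#'   community label. Empty edge sets yield an empty graph.
#' @export
build_and_cluster <- function(edges, resolution = 1, seed = 1L) {
  kept <- edges[edges$kept, , drop = FALSE]
  if (!nrow(kept)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$gene_i, to = kept$gene_j, weight = kept$r),
    directed = FALSE
  )
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  igraph::V(g)$hub <- igraph::membership(comm)
  g
}

#' Prune Louvain clusters into hubs
#'
#' Clusters with fewer than `min_size` genes are removed. Within each
#' remaining cluster, genes with fewer than `log(n_cluster_genes)`
#' within-cluster connections are removed (natural log by default), after
#' which the size rule is re-applied once (or iterated to a fixed point
#' with `prune_to_fixpoint = TRUE`). A gene's importance is its final
#' within-hub degree.
#'
#' @param network Clustered graph from [build_and_cluster()].
#' @param species,tissue,cell_type Provenance recorded on each hub.
#' @param min_size Minimum hub size (5).
#' @param log_base Base of the degree threshold log (natural log).
#' @param prune_to_fixpoint Iterate degree/size pruning until stable.
#' @param background_genes Optional expressed-gene universe stored on the
#'   collection.
#' @return A [hub_collection()]; hubs are labelled `<cell_type>_<k>`.
#' @export
prune_hubs <- function(network, species = "unspecified", tissue = "unspecified",
                       cell_type = "unspecified", min_size = 5L,
                       log_base = exp(1), prune_to_fixpoint = FALSE,
                       background_genes = NULL) {
  hubs <- list()
  if (igraph::vcount(network) == 0) {
    return(hub_collection(hubs, background_genes = background_genes))
  }
  labels <- sort(unique(igraph::V(network)$hub))
  k <- 0L
  for (lab in labels) {
    members <- igraph::V(network)[igraph::V(network)$hub == lab]
    sub <- igraph::induced_subgraph(network, members)
    repeat {
      if (igraph::vcount(sub) < min_size) {
        sub <- NULL
        break
      }
      deg <- igraph::degree(sub)
      thr <- log(igraph::vcount(sub), base = log_base)
      weak <- names(deg)[deg < thr]
      if (!length(weak)) break
      sub <- igraph::delete_vertices(sub, weak)
      if (!prune_to_fixpoint) {
        if (igraph::vcount(sub) < min_size) sub <- NULL
        break
      }
    }
    if (is.null(sub) || igraph::vcount(sub) < min_size) next
    deg <- igraph::degree(sub)
    deg <- deg[deg >= 1] # genes with no remaining correlations are removed
    if (length(deg) < min_size) next
    hubs[[length(hubs) + 1]] <- hub(
      sprintf("%s_%d", cell_type, k), deg,
      species = species, tissue = tissue, cell_type = cell_type,
      min_size = min_size
    )
    k <- k + 1L
  }
  hub_collection(hubs, background_genes = background_genes)
}

#' Discover senescence signature hubs for one population
#'
#' Convenience wrapper for the discovery pipeline on a single population:
#' binarize aged cells over the dynamic genes, threshold pairwise
#' co-positivity by per-pair permutation, cluster with Louvain, and prune
#' into hubs.
#'
#' @inheritParams binarize_subset
#' @inheritParams pairwise_r
#' @inheritParams prune_hubs
#' @param tissue,cell_type Provenance for the emitted hubs.
#' @return A [hub_collection()] (possibly empty).
#' @export
build_signatures <- function(data, genes, species = c("mouse", "human"),
                             tissue = "unspecified", cell_type = "unspecified",
                             n_perm = 500L, seed = 1L, resolution = 1,
                             min_cells = 100L, min_size = 5L, cells = NULL,
                             log_base = exp(1), prune_to_fixpoint = FALSE) {
  species <- match.arg(species)
  b <- binarize_subset(data, genes,
    species = species, min_cells = min_cells, cells = cells
  )
  if (is.null(b)) {
    return(hub_collection(list(), background_genes = data$genes))
  }
  edges <- pairwise_r(b, n_perm = n_perm, seed = seed)
  net <- build_and_cluster(edges, resolution = resolution, seed = seed)
  prune_hubs(net,
    species = species, tissue = tissue, cell_type = cell_type,
    min_size = min_size, log_base = log_base,
    prune_to_fixpoint = prune_to_fixpoint, background_genes = data$genes
  )
}
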