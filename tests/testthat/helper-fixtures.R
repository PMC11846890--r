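# Shared fixtures and independent oracles used across the suite.

# small deterministic annotated_counts: 6 genes x 8 cells, two ages
tiny_counts <- function() {
  m <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3, 3, 3, 4, 5, 6, 6),
    j = c(1, 5, 2, 1, 5, 6, 7, 8, 3, 7),
    x = c(2, 1, 1, 3, 1, 2, 1, 4, 1, 1),
    dims = c(6, 8)
  )
  meta <- tibble::tibble(
    cell_id = paste0("c", 1:8),
    age = c(3, 3, 3, 3, 24, 24, 24, 24),
    age_unit = "months", tissue = "lung", cell_type = "fib",
    sample_id = rep(c("s1", "s2"), 4)
  )
  annotated_counts(m, paste0("g", 1:6), meta)
}

# annotated_counts from a dense matrix with ages
counts_from_dense <- function(m, ages, age_unit = "months",
                              cell_type = "fib", tissue = "lung",
                              sample_id = NULL) {
  n <- ncol(m)
  meta <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n)), age = ages, age_unit = age_unit,
    tissue = tissue, cell_type = cell_type,
    sample_id = sample_id %||% rep("s1", n)
  )
  annotated_counts(Matrix::Matrix(m, sparse = TRUE), rownames(m) %||%
    paste0("g", seq_len(nrow(m))), meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cells x genes binary sparse matrix from a list of 0/1 vectors
binary_matrix <- function(...) {
  vecs <- list(...)
  b <- do.call(cbind, vecs)
  colnames(b) <- paste0("g", seq_along(vecs))
  methods::as(Matrix::Matrix(b, sparse = TRUE), "CsparseMatrix")
}

# hand-built edge table for build_and_cluster / prune_hubs
edge_tbl <- function(gene_i, gene_j, r = 0.8) {
  tibble::tibble(
    gene_i = gene_i, gene_j = gene_j, r = r, t = 0.05, kept = TRUE
  )
}

# fully connected clique edge list over the given genes
clique_edges <- function(genes, r = 0.8) {
  pr <- utils::combn(genes, 2)
  edge_tbl(pr[1, ], pr[2, ], r = r)
}

# --- independent oracles -------------------------------------------------

# exhaustive hypergeometric survival function P(overlap >= ov) by
# enumerating all C(N, a) draws of list A against a fixed list B
enum_hyper_sf <- function(N, a, b, ov) {
  draws <- utils::combn(N, a)
  hits <- apply(draws, 2, function(d) sum(d <= b) >= ov)
  mean(hits)
}

# exhaustive Poisson-binomial tail by enumerating all 2^k inclusion patterns
enum_genfun <- function(p, m, tail = c("gt", "geq")) {
  tail <- match.arg(tail)
  k <- length(p)
  pmf <- numeric(k + 1)
  for (pattern in 0:(2^k - 1)) {
    inc <- as.integer(intToBits(pattern))[seq_len(k)]
    prob <- prod(ifelse(inc == 1, p, 1 - p))
    pmf[sum(inc) + 1] <- pmf[sum(inc) + 1] + prob
  }
  list(
    pmf = pmf,
    p_value = if (tail == "gt") sum(pmf[seq_len(k + 1) > m + 1]) else
      sum(pmf[seq_len(k + 1) >= m + 1])
  )
}

# dense brute-force Moran's I with truncated inverse-distance weights
brute_moran <- function(coords, values, cutoff = 3) {
  n <- nrow(coords)
  xc <- values - mean(values)
  num <- 0
  wsum <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((coords$x[i] - coords$x[j])^2 + (coords$y[i] - coords$y[j])^2)
      if (d > 0 && d <= cutoff) {
        w <- 1 / d
        num <- num + w * xc[i] * xc[j]
        wsum <- wsum + w
      }
    }
  }
  n * num / (wsum * sum(xc^2))
}

# cached mid-size simulated dataset shared by scoring/outlier tests
.fixture_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_counts(sim_spec(
      n_genes = 3000L, n_cells_per_age = 500L, seed = 11L
    ))
  }
  .fixture_env$sim
}
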