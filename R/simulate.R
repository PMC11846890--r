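# Seeded synthetic single-cell and spatial fixtures with the statistical
# structure the method assumes: age-stratified populations, minority
# senescent subpopulations co-expressing planted gene programs, dropout.
#
# Counts are generated as Bernoulli positivity x (1 + Poisson magnitude)
# rather than a full negative-binomial hierarchy: every statistic in the
# discovery pipeline consumes the binary positivity layer, so fidelity
# beyond that layer is unnecessary (see the methods vignette).

#' Specification for a synthetic single-cell dataset
#'
#' @param n_genes Total genes (default 20000).
#' @param n_cells_per_age Cells per age group (default 1000).
#' @param age_groups Numeric ages (default `c(3, 24)` months: a young and an
#'   old mouse baseline).
#' @param age_unit `"months"` or `"years"`.
#' @param senescent_fraction Named numeric: fraction of senescent cells per
#'   age group (default 1% young, 10% old — senescent cells accumulate with
#'   age but remain a minority).
#' @param programs List of planted programs, each a list with `n_genes`
#'   (default 15), `co_positive_rate` (positivity of program genes within
#'   senescent cells, default 0.9) and `background_positivity` (their
#'   positivity elsewhere, default 0.01).
#' @param base_shape1,base_shape2 Beta parameters for background per-gene
#'   positivity rates (defaults 0.3, 6: right-skewed, mean ~5%, matching the
#'   sparsity of UMI data).
#' @param dropout_rate Probability that a positive entry is zeroed after
#'   generation (default 0).
#' @param tissue,cell_type,n_samples Population annotations.
#' @param seed Integer seed.
#' @return A `senesig_sim_spec` list.
#' @export
sim_spec <- function(n_genes = 20000L, n_cells_per_age = 1000L,
                     age_groups = c(3, 24), age_unit = "months",
                     senescent_fraction = c("3" = 0.01, "24" = 0.10),
                     programs = list(list(
                       n_genes = 15L, co_positive_rate = 0.9,
                       background_positivity = 0.01
                     )),
                     base_shape1 = 0.3, base_shape2 = 6,
                     dropout_rate = 0, tissue = "lung",
                     cell_type = "fibroblast", n_samples = 2L, seed = 1L) {
  stopifnot(
    all(unlist(senescent_fraction) >= 0), all(unlist(senescent_fraction) <= 1),
    dropout_rate >= 0, dropout_rate <= 1
  )
  total_program <- sum(vapply(programs, function(p) p$n_genes, numeric(1)))
  if (total_program > n_genes) {
    abort("program genes exceed n_genes", class = "senesig_data_error")
  }
  if (!all(as.character(age_groups) %in% names(senescent_fraction))) {
    abort("senescent_fraction must name every age group",
      class = "senesig_data_error"
    )
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_cells_per_age = as.integer(n_cells_per_age),
      age_groups = age_groups, age_unit = age_unit,
      senescent_fraction = senescent_fraction, programs = programs,
      base_shape1 = base_shape1, base_shape2 = base_shape2,
      dropout_rate = dropout_rate, tissue = tissue, cell_type = cell_type,
      n_samples = as.integer(n_samples), seed = as.integer(seed)
    ),
    class = "senesig_sim_spec"
  )
}

# sparse triplets for one gene: sampled positive cells and magnitudes
gene_triplets <- function(gene_idx, cell_idx, rate, lambda = 0.5) {
  n_pos <- rbinom(1, length(cell_idx), rate)
  if (n_pos == 0) return(NULL)
  cells <- sample(cell_idx, n_pos)
  list(
    i = rep.int(gene_idx, n_pos), j = cells,
    x = 1 + rpois(n_pos, lambda)
  )
}

#' Simulate an age-annotated single-cell dataset with planted programs
#'
#' Background genes receive independent sparse draws at per-gene positivity
#' rates; in each age group a `senescent_fraction` of cells is co-positive
#' for each planted program's genes at `co_positive_rate` (the remaining
#' cells at `background_positivity`); dropout is applied last. Ground-truth
#' senescent labels and the planted gene lists are returned alongside.
#'
#' @param spec A [sim_spec()].
#' @return A list: `data` ([annotated_counts()]), `truth` (tibble `cell_id`,
#'   `age`, `is_senescent`, `program_id`), `program_genes` (named list of
#'   character vectors).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "senesig_sim_spec"))
  set.seed(spec$seed)
  n_genes <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(n_genes))
  prog_sizes <- vapply(spec$programs, function(p) p$n_genes, integer(1))
  prog_idx <- split(
    sample.int(n_genes, sum(prog_sizes)),
    rep(seq_along(prog_sizes), prog_sizes)
  )
  base_rate <- stats::rbeta(n_genes, spec$base_shape1, spec$base_shape2)
  base_rate <- pmin(base_rate, 0.5)

  n_per_age <- spec$n_cells_per_age
  ages <- rep(spec$age_groups, each = n_per_age)
  n_cells <- length(ages)
  cell_ids <- sprintf("c%06d", seq_len(n_cells))
  sample_id <- paste0(
    "s", 1 + (seq_len(n_cells) %% spec$n_samples), "_age", ages
  )
  sen_frac <- unlist(spec$senescent_fraction)[as.character(ages)]
  is_sen <- runif(n_cells) < sen_frac
  # senescent cells are split across programs
  program_id <- rep(NA_integer_, n_cells)
  program_id[is_sen] <- sample.int(length(spec$programs), sum(is_sen),
    replace = TRUE
  )

  trip <- vector("list", n_genes)
  prog_of_gene <- rep(0L, n_genes)
  for (p in seq_along(prog_idx)) prog_of_gene[prog_idx[[p]]] <- p
  for (g in seq_len(n_genes)) {
    p <- prog_of_gene[g]
    if (p == 0L) {
      trip[[g]] <- gene_triplets(g, seq_len(n_cells), base_rate[g])
    } else {
      prog <- spec$programs[[p]]
      sen_cells <- which(program_id == p)
      other <- which(is.na(program_id) | program_id != p)
      trip[[g]] <- list(
        gene_triplets(g, sen_cells, prog$co_positive_rate),
        gene_triplets(g, other, prog$background_positivity)
      )
    }
  }
  trip <- purrr::flatten(purrr::map(trip, function(t) {
    if (is.null(t)) list() else if (is.list(t[[1]]) || is.null(t[[1]])) {
      t[!vapply(t, is.null, logical(1))]
    } else {
      list(t)
    }
  }))
  i <- unlist(lapply(trip, `[[`, "i"))
  j <- unlist(lapply(trip, `[[`, "j"))
  x <- unlist(lapply(trip, `[[`, "x"))
  if (spec$dropout_rate > 0) {
    keep <- runif(length(x)) >= spec$dropout_rate
    i <- i[keep]; j <- j[keep]; x <- x[keep]
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_genes, n_cells))
  meta <- tibble(
    cell_id = cell_ids, age = ages, age_unit = spec$age_unit,
    tissue = spec$tissue, cell_type = spec$cell_type, sample_id = sample_id
  )
  list(
    data = annotated_counts(m, genes, meta, layer_kind = "raw"),
    truth = tibble(
      cell_id = cell_ids, age = ages, is_senescent = is_sen,
      program_id = program_id
    ),
    program_genes = setNames(
      lapply(prog_idx, function(idx) genes[idx]),
      paste0("program", seq_along(prog_idx))
    )
  )
}

#' Simulate a spatial spot grid with a planted senescent patch
#'
#' Spots lie on a unit-spaced rectangular grid. Spots inside the planted
#' patch(es) express the program genes at high positivity and magnitude;
#' all other expression is background. Spot depth is Visium-like (most
#' genes detected in a majority of spots) so the detected-gene filter of
#' [preprocess_spots()] is meaningful.
#'
#' @param n_genes Total genes (default 2000).
#' @param grid_dims `c(nx, ny)` grid dimensions (default `c(20, 20)`).
#' @param patches List of patches, each `c(x0, y0, x1, y1)` (inclusive
#'   corners, grid units). Default one 4x4 patch. Use `list()` for a pure
#'   noise grid.
#' @param n_program_genes Planted program size (default 15).
#' @param program_rate,program_lambda Positivity and Poisson magnitude of
#'   program genes inside the patch (defaults 0.95, 5).
#' @param base_shape1,base_shape2 Beta parameters of background per-gene
#'   positivity (defaults 5, 4: mean ~0.56, Visium-like detection).
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return A list: `data` ([annotated_counts()] with coordinates), `truth`
#'   (tibble `cell_id`, `x`, `y`, `in_patch`, `patch_id`), `program_genes`.
#' @export
simulate_spatial <- function(n_genes = 2000L, grid_dims = c(20L, 20L),
                             patches = list(c(3, 3, 6, 6)),
                             n_program_genes = 15L, program_rate = 0.95,
                             program_lambda = 5, base_shape1 = 5,
                             base_shape2 = 4, sample_id = "spatial1",
                             seed = 1L) {
  set.seed(seed)
  xy <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]))
  n_spots <- nrow(xy)
  patch_id <- rep(NA_integer_, n_spots)
  for (p in seq_along(patches)) {
    pa <- patches[[p]]
    if (pa[1] < 1 || pa[2] < 1 || pa[3] > grid_dims[1] || pa[4] > grid_dims[2]) {
      abort("patch outside grid", class = "senesig_data_error")
    }
    inside <- xy$x >= pa[1] & xy$x <= pa[3] & xy$y >= pa[2] & xy$y <= pa[4]
    patch_id[inside] <- p
  }
  in_patch <- !is.na(patch_id)
  genes <- sprintf("g%05d", seq_len(n_genes))
  prog <- sample.int(n_genes, n_program_genes)
  base_rate <- stats::rbeta(n_genes, base_shape1, base_shape2)
  trip <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    if (g %in% prog) {
      trip[[g]] <- list(
        gene_triplets(g, which(in_patch), program_rate, lambda = program_lambda),
        gene_triplets(g, which(!in_patch), base_rate[g] * 0.2, lambda = 0.5)
      )
    } else {
      trip[[g]] <- list(gene_triplets(g, seq_len(n_spots), base_rate[g], lambda = 1))
    }
  }
  trip <- purrr::flatten(purrr::map(trip, function(t) {
    t[!vapply(t, is.null, logical(1))]
  }))
  m <- Matrix::sparseMatrix(
    i = unlist(lapply(trip, `[[`, "i")),
    j = unlist(lapply(trip, `[[`, "j")),
    x = unlist(lapply(trip, `[[`, "x")),
    dims = c(n_genes, n_spots)
  )
  ids <- sprintf("spot%04d", seq_len(n_spots))
  meta <- tibble(
    cell_id = ids, age = 3, age_unit = "months", tissue = "heart",
    cell_type = "spot", sample_id = sample_id, x = xy$x, y = xy$y
  )
  list(
    data = annotated_counts(m, genes, meta, layer_kind = "raw"),
    truth = tibble(
      cell_id = ids, x = xy$x, y = xy$y, in_patch = in_patch,
      patch_id = patch_id
    ),
    program_genes = genes[prog]
  )
}

#' Write a simulated dataset as the standard MTX/TSV trio plus truth sidecar
#'
#' @param sim Output of [simulate_counts()] or [simulate_spatial()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_counts(sim$data, dir)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, truth_path, progress = FALSE)
  invisible(c(paths, truth_path))
}
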