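# Candidate age-dynamic gene discovery: positivity proportions per age
# stratum, piecewise GAD scoring, and a sparsity-preserving permutation null.

MOUSE_AGE_GROUPS <- c(1, 3, 18, 21, 24, 30)

#' Proportion of cells positive for each gene
#'
#' A cell is positive for a gene when it has at least one UMI. For young
#' baseline groups, genes seen in zero cells are imputed at `1/n` (the
#' inverse of the cell count) so that old/young ratios stay finite; the
#' `imputed` flag records this.
#'
#' @param data An [annotated_counts()] with `layer_kind = "raw"`.
#' @param cells Index (logical/integer/character) of the cell subset.
#' @param genes Optional gene subset; default all genes.
#' @param impute_zero Impute zero positivity as `1/n` (young baselines).
#' @return A tibble: `gene`, `n_pos`, `n_cells`, `p`, `imputed`.
#' @export
positivity <- function(data, cells = NULL, genes = NULL, impute_zero = FALSE) {
  stopifnot(inherits(data, "annotated_counts"))
  sub <- subset_cells(data, cells = cells, genes = genes)
  n <- ncol(sub$counts)
  if (n < 1) abort("positivity: empty cell set", class = "senesig_data_error")
  n_pos <- positive_counts(sub$counts)
  p <- n_pos / n
  imputed <- rep(FALSE, length(p))
  if (impute_zero) {
    imputed <- n_pos == 0
    p[imputed] <- 1 / n
  }
  tibble(gene = sub$genes, n_pos = n_pos, n_cells = n, p = p, imputed = imputed)
}

# number of cells with count >= 1, per gene (rows of a dgCMatrix)
positive_counts <- function(counts) {
  x <- counts
  x@x <- rep(1, length(x@x))
  as.integer(Matrix::rowSums(x))
}

#' Stratify mouse data into young/old baselines per tissue and cell type
#'
#' The young baseline is the 3-month group when it has at least 200 cells,
#' otherwise the 3-month and 1-month cells aggregated. The old baseline is
#' the 30-month group when it has at least 200 cells, otherwise the 24-month
#' group. Populations lacking a usable young or old baseline are skipped with
#' a logged reason. Ages not in \{1, 3, 18, 21, 24, 30\} months are assigned
#' to the nearest listed group with a warning.
#'
#' @param data An [annotated_counts()] with ages in months.
#' @param min_cells Cell count above which a single age group suffices (200).
#' @return A tibble with one row per eligible population: `tissue`,
#'   `cell_type`, `n_young`, `n_old`, and list-columns `young_cells`,
#'   `old_cells` of integer cell indices.
#' @export
stratify_mouse <- function(data, min_cells = 200L) {
  stopifnot(inherits(data, "annotated_counts"))
  meta <- data$cell_meta
  if (!all(meta$age_unit == "months")) {
    abort("stratify_mouse expects ages in months", class = "senesig_data_error")
  }
  age <- meta$age
  off_grid <- !(age %in% MOUSE_AGE_GROUPS)
  if (any(off_grid)) {
    warn(sprintf(
      "%d cell(s) have off-grid ages; assigned to the nearest mouse age group",
      sum(off_grid)
    ))
    age[off_grid] <- vapply(
      age[off_grid],
      function(a) MOUSE_AGE_GROUPS[which.min(abs(MOUSE_AGE_GROUPS - a))],
      numeric(1)
    )
  }
  pops <- unique(meta[, c("tissue", "cell_type")])
  out <- list()
  for (i in seq_len(nrow(pops))) {
    sel <- meta$tissue == pops$tissue[i] & meta$cell_type == pops$cell_type[i]
    idx3 <- which(sel & age == 3)
    idx1 <- which(sel & age == 1)
    young <- if (length(idx3) >= min_cells) idx3 else c(idx3, idx1)
    idx30 <- which(sel & age == 30)
    idx24 <- which(sel & age == 24)
    old <- if (length(idx30) >= min_cells) idx30 else idx24
    if (length(young) < 1 || length(old) < 1) {
      inform(sprintf(
        "stratify_mouse: skipping %s/%s (no usable %s baseline)",
        pops$tissue[i], pops$cell_type[i],
        if (length(young) < 1) "young" else "old"
      ))
      next
    }
    if (length(young) < min_cells) {
      inform(sprintf(
        "stratify_mouse: %s/%s young baseline has only %d cells",
        pops$tissue[i], pops$cell_type[i], length(young)
      ))
    }
    out[[length(out) + 1]] <- tibble(
      tissue = pops$tissue[i], cell_type = pops$cell_type[i],
      n_young = length(young), n_old = length(old),
      young_cells = list(young), old_cells = list(old)
    )
  }
  if (!length(out)) return(tibble(
    tissue = character(), cell_type = character(),
    n_young = integer(), n_old = integer(),
    young_cells = list(), old_cells = list()
  ))
  bind_rows(out)
}

#' Assign human ages (years) to 10-year bins indexed 8, 18, ..., 88
#'
#' @param age_years Numeric ages in years.
#' @return Integer bin indices.
#' @export
human_age_bin <- function(age_years) {
  b <- 8 + 10 * floor((age_years - 8) / 10)
  as.integer(pmin(pmax(b, 8), 88))
}

#' Stratify human data into eligible binned populations
#'
#' Ages are binned into 10-year bins indexed from 8 (8-17 years) to 88.
#' A (dataset, tissue, cell type) population is eligible when, within a
#' single dataset, it has (a) three distinct bins with at least `min_cells`
#' cells each, or a bin at or below 28 and a bin at or above 58 each with at
#' least `min_cells` cells; and (b) a bin at or above 48 with at least
#' `min_cells` cells. Only bins meeting `min_cells` are retained.
#'
#' @param data An [annotated_counts()] with ages in years. A `dataset`
#'   column in `cell_meta` is honoured; otherwise all cells are treated as
#'   one dataset.
#' @param min_cells Minimum cells per bin (100).
#' @return A tibble with one row per eligible population: `dataset`,
#'   `tissue`, `cell_type`, and list-columns `bin_ages` (integer vector) and
#'   `bin_cells` (list of integer index vectors, same order).
#' @export
stratify_human <- function(data, min_cells = 100L) {
  stopifnot(inherits(data, "annotated_counts"))
  meta <- data$cell_meta
  if (!all(meta$age_unit %in% c("years", "bin_index"))) {
    abort("stratify_human expects ages in years (or pre-binned indices)",
      class = "senesig_data_error"
    )
  }
  bins <- ifelse(meta$age_unit == "bin_index", as.integer(meta$age),
    human_age_bin(meta$age)
  )
  dataset <- if ("dataset" %in% names(meta)) meta$dataset else "dataset1"
  pops <- unique(tibble(
    dataset = dataset, tissue = meta$tissue, cell_type = meta$cell_type
  ))
  out <- list()
  for (i in seq_len(nrow(pops))) {
    sel <- dataset == pops$dataset[i] & meta$tissue == pops$tissue[i] &
      meta$cell_type == pops$cell_type[i]
    tab <- table(bins[sel])
    ok_bins <- sort(as.integer(names(tab)[tab >= min_cells]))
    path_a <- length(ok_bins) >= 3
    path_b <- any(ok_bins <= 28) && any(ok_bins >= 58)
    has_old <- any(ok_bins >= 48)
    if (!((path_a || path_b) && has_old)) {
      inform(sprintf(
        "stratify_human: skipping %s/%s/%s (age-bin eligibility not met)",
        pops$dataset[i], pops$tissue[i], pops$cell_type[i]
      ))
      next
    }
    cells <- lapply(ok_bins, function(b) which(sel & bins == b))
    out[[length(out) + 1]] <- tibble(
      dataset = pops$dataset[i], tissue = pops$tissue[i],
      cell_type = pops$cell_type[i],
      bin_ages = list(ok_bins), bin_cells = list(cells)
    )
  }
  if (!length(out)) return(tibble(
    dataset = character(), tissue = character(), cell_type = character(),
    bin_ages = list(), bin_cells = list()
  ))
  bind_rows(out)
}

# --- internal lenient GAD evaluation used for observed tables and nulls ----

# mouse: tolerate r = 0 (zero old positivity) by letting ratio(0) = 0
mouse_gad_vec <- function(x_young, x_old, r) {
  gad_old(x_old) + gad_gain(x_old - x_young) + gad_young(x_young) + gad_ratio(r)
}

# x_* on percent scale from young/old positive counts with 1/n imputation
mouse_stats <- function(k_young, n_young, k_old, n_old) {
  p_young <- ifelse(k_young == 0, 1 / n_young, k_young / n_young)
  p_old <- k_old / n_old
  list(
    x_young = 100 * p_young, x_old = 100 * p_old, r = p_old / p_young,
    imputed = k_young == 0
  )
}

# human: per-gene stats from a genes x bins positive-count matrix
human_stats <- function(k_mat, bin_ages, n_per_bin) {
  p <- sweep(k_mat, 2, n_per_bin, "/")
  age_max <- max(bin_ages)
  old_col <- which.max(bin_ages)
  young_bins <- which(bin_ages <= 28)
  if (length(young_bins)) {
    yb <- young_bins[which.min(bin_ages[young_bins])]
    p_young <- ifelse(p[, yb] == 0, 1 / n_per_bin[yb], p[, yb])
  } else {
    # least-squares extrapolation to 18 years, floored at 1/n of youngest bin
    a_c <- bin_ages - mean(bin_ages)
    denom <- sum(a_c^2)
    slope0 <- as.vector(p %*% a_c) / denom
    p_young <- rowMeans(p) + slope0 * (18 - mean(bin_ages))
    p_young[p_young <= 0] <- 1 / n_per_bin[which.min(bin_ages)]
  }
  a_c <- bin_ages - mean(bin_ages)
  slope <- as.vector(p %*% a_c) / sum(a_c^2) # proportion per year
  # peak bin, ties broken towards the oldest bin
  ord <- order(bin_ages)
  peak <- bin_ages[ord][max.col(p[, ord, drop = FALSE], ties.method = "last")]
  list(
    x_young = 100 * p_young, x_old = 100 * p[, old_col],
    slope_pct = 100 * slope, age_of_peak = peak, age_max = age_max
  )
}

human_gad_vec <- function(st, dmax_literal = FALSE) {
  d_max <- if (dmax_literal) st$age_of_peak - st$age_max else st$age_max - st$age_of_peak
  dmax <- ifelse(d_max < 50, 1, -(d_max - 50))
  amax <- ifelse(st$age_max >= 38, 1, st$age_max - 38)
  gad_old(st$x_old) + gad_gain(st$x_old - st$x_young) + gad_young(st$x_young) +
    dmax + amax + 5 * st$slope_pct
}

# multivariate hypergeometric split of K positives over groups of given sizes;
# returns a genes x groups count matrix. This is exactly the distribution of
# per-group positive counts when each gene's positive cells are independently
# reshuffled across all cells, so totals and sparsity are preserved.
split_positives <- function(K, group_sizes) {
  n_groups <- length(group_sizes)
  remaining <- sum(group_sizes)
  k_left <- K
  out <- matrix(0L, nrow = length(K), ncol = n_groups)
  for (g in seq_len(n_groups - 1)) {
    draw <- rhyper(length(K), m = group_sizes[g], n = remaining - group_sizes[g], k = k_left)
    out[, g] <- draw
    k_left <- k_left - draw
    remaining <- remaining - group_sizes[g]
  }
  out[, n_groups] <- k_left
  out
}

#' Permutation null distribution of GAD scores for one population
#'
#' Each permutation independently reshuffles, per gene, the assignment of
#' that gene's positive cells across all cells of the population (bin/group
#' membership fixed), preserving the gene's total positive count and the
#' matrix sparsity, then recomputes the GAD score of every gene. All values
#' are pooled into a single null distribution for the population.
#'
#' @param k_pos Integer vector: observed positive-cell count per tested gene
#'   (summed over the population's groups).
#' @param group_sizes Integer vector of cell counts per group: `c(young,
#'   old)` for mouse, per-bin counts for human.
#' @param species `"mouse"` or `"human"`.
#' @param bin_ages For humans, the age-bin indices matching `group_sizes`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; fixed seed reproduces the null exactly.
#' @param dmax_literal Passed to the human GAD (see [gad_human()]).
#' @return A `senesig_null` list: `values` (pooled null GADs,
#'   `n_perm * length(k_pos)` of them), `n_permutations`, `seed`.
#' @export
permutation_null <- function(k_pos, group_sizes, species = c("mouse", "human"),
                             bin_ages = NULL, n_perm = 1000L, seed = 1L,
                             dmax_literal = FALSE) {
  species <- match.arg(species)
  if (n_perm < 1) abort("n_perm must be >= 1", class = "senesig_data_error")
  if (species == "mouse" && length(group_sizes) != 2) {
    abort("mouse null expects group_sizes = c(n_young, n_old)",
      class = "senesig_data_error"
    )
  }
  if (species == "human" && (is.null(bin_ages) ||
    length(bin_ages) != length(group_sizes))) {
    abort("human null needs bin_ages matching group_sizes",
      class = "senesig_data_error"
    )
  }
  set.seed(seed)
  values <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    k <- split_positives(k_pos, group_sizes)
    if (species == "mouse") {
      st <- mouse_stats(k[, 1], group_sizes[1], k[, 2], group_sizes[2])
      values[[b]] <- mouse_gad_vec(st$x_young, st$x_old, st$r)
    } else {
      st <- human_stats(k, bin_ages, group_sizes)
      values[[b]] <- human_gad_vec(st, dmax_literal)
    }
  }
  structure(
    list(
      values = unlist(values), n_permutations = as.integer(n_perm),
      n_genes = length(k_pos), seed = as.integer(seed), species = species
    ),
    class = "senesig_null"
  )
}

#' Call dynamic genes against a permutation null
#'
#' The empirical p-value of a gene is `(1 + #null >= observed) / (1 +
#' n_null)` over the population's pooled null distribution. A gene is
#' dynamic when its empirical p is at or below `alpha`; human genes must
#' additionally have a positive positivity slope (enforced upstream via the
#' `candidate` column when present).
#'
#' @param observed A tibble with a `gad` column (and optionally `candidate`).
#' @param null A `senesig_null` from [permutation_null()], or a numeric
#'   vector of pooled null GAD values.
#' @param alpha Significance threshold on the empirical p (default 0.01).
#' @return `observed` with `empirical_p` and `dynamic` columns added.
#' @export
call_dynamic <- function(observed, null, alpha = 0.01) {
  values <- if (inherits(null, "senesig_null")) null$values else as.numeric(null)
  if (!length(values)) abort("empty null distribution", class = "senesig_data_error")
  sorted <- sort(values)
  n_null <- length(sorted)
  # count of null values >= each observed gad
  n_ge <- n_null - findInterval(observed$gad, sorted, left.open = TRUE)
  observed$empirical_p <- (1 + n_ge) / (1 + n_null)
  observed$dynamic <- observed$empirical_p <= alpha
  if ("candidate" %in% names(observed)) {
    observed$dynamic <- observed$dynamic & observed$candidate
  }
  observed
}

#' Find age-dynamic genes in every eligible population
#'
#' End-to-end wrapper: stratifies the data by species rules, computes
#' positivity proportions and observed GAD scores for every gene detected in
#' the population, builds the permutation null, and calls dynamic genes.
#'
#' @param data An [annotated_counts()] with raw counts.
#' @param species `"mouse"` or `"human"`.
#' @param alpha Empirical-p threshold (default 0.01).
#' @param n_perm Permutations for the null (default 1000).
#' @param seed Integer seed.
#' @param dmax_literal See [gad_human()].
#' @return A tibble with one row per (population, tested gene): population
#'   columns, `gene`, `x_young`, `x_old`, `gain`, `ratio_or_slope`, `gad`,
#'   `empirical_p`, `dynamic`.
#' @export
find_dynamic_genes <- function(data, species = c("mouse", "human"),
                               alpha = 0.01, n_perm = 1000L, seed = 1L,
                               dmax_literal = FALSE) {
  species <- match.arg(species)
  out <- list()
  if (species == "mouse") {
    strata <- stratify_mouse(data)
    for (i in seq_len(nrow(strata))) {
      young <- strata$young_cells[[i]]
      old <- strata$old_cells[[i]]
      k_young <- positive_counts(data$counts[, young, drop = FALSE])
      k_old <- positive_counts(data$counts[, old, drop = FALSE])
      tested <- which(k_young + k_old > 0)
      st <- mouse_stats(k_young[tested], length(young), k_old[tested], length(old))
      obs <- tibble(
        tissue = strata$tissue[i], cell_type = strata$cell_type[i],
        gene = data$genes[tested],
        x_young = st$x_young, x_old = st$x_old,
        gain = st$x_old - st$x_young, ratio_or_slope = st$r,
        gad = mouse_gad_vec(st$x_young, st$x_old, st$r)
      )
      null <- permutation_null(
        k_young[tested] + k_old[tested],
        c(length(young), length(old)),
        species = "mouse", n_perm = n_perm, seed = seed + i
      )
      out[[length(out) + 1]] <- call_dynamic(obs, null, alpha)
    }
  } else {
    strata <- stratify_human(data)
    for (i in seq_len(nrow(strata))) {
      bins <- strata$bin_cells[[i]]
      bin_ages <- strata$bin_ages[[i]]
      sizes <- lengths(bins)
      k_mat <- do.call(cbind, lapply(bins, function(idx) {
        positive_counts(data$counts[, idx, drop = FALSE])
      }))
      tested <- which(rowSums(k_mat) > 0)
      st <- human_stats(k_mat[tested, , drop = FALSE], bin_ages, sizes)
      obs <- tibble(
        dataset = strata$dataset[i], tissue = strata$tissue[i],
        cell_type = strata$cell_type[i], gene = data$genes[tested],
        x_young = st$x_young, x_old = st$x_old,
        gain = st$x_old - st$x_young, ratio_or_slope = st$slope_pct,
        gad = human_gad_vec(st, dmax_literal),
        candidate = st$slope_pct > 0
      )
      null <- permutation_null(
        rowSums(k_mat)[tested], sizes,
        species = "human", bin_ages = bin_ages,
        n_perm = n_perm, seed = seed + i, dmax_literal = dmax_literal
      )
      out[[length(out) + 1]] <- call_dynamic(obs, null, alpha)
    }
  }
  if (!length(out)) {
    abort("no eligible population found", class = "senesig_data_error")
  }
  bind_rows(out)
}
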