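# Spatial transcriptomics: spot preprocessing, hub scoring of spots, and
# inverse-distance Moran's I on outlier indicators.

#' Preprocess spatial spot counts
#'
#' Removes spots with fewer than `min_genes` detected genes, scales each
#' remaining spot to `target_sum` total counts, and applies `log(1 + x)`.
#' The result carries `layer_kind = "normalized_log"`.
#'
#' @param data An [annotated_counts()] with raw spot counts and `x`, `y`
#'   coordinate columns in `cell_meta`.
#' @param min_genes Minimum detected genes per spot (default 1000).
#' @param target_sum Per-spot total after scaling (default 10000).
#' @return A normalized [annotated_counts()].
#' @export
preprocess_spots <- function(data, min_genes = 1000L, target_sum = 10000) {
  stopifnot(inherits(data, "annotated_counts"))
  if (data$layer_kind != "raw") {
    abort("preprocess_spots expects raw counts", class = "senesig_data_error")
  }
  if (!all(c("x", "y") %in% names(data$cell_meta))) {
    abort("spot metadata needs x and y coordinates", class = "senesig_schema_error")
  }
  detected <- Matrix::colSums(data$counts > 0)
  keep <- which(detected >= min_genes)
  if (!length(keep)) {
    abort("all spots removed by the detected-gene filter",
      class = "senesig_data_error"
    )
  }
  if (length(keep) < ncol(data$counts)) {
    inform(sprintf(
      "preprocess_spots: removed %d spot(s) with < %d detected genes",
      ncol(data$counts) - length(keep), min_genes
    ))
  }
  m <- data$counts[, keep, drop = FALSE]
  totals <- Matrix::colSums(m)
  m <- m %*% Matrix::Diagonal(x = target_sum / totals)
  m@x <- log1p(m@x)
  annotated_counts(m, data$genes, data$cell_meta[keep, , drop = FALSE],
    layer_kind = "normalized_log"
  )
}

#' Score spatial spots with a hub collection and call outlier spots
#'
#' Each hub is scored on the normalized layer with `binarize = FALSE` and
#' `use_importance = FALSE` (spot data have higher gene counts than single
#' cells). Outlier spots per hub are called in `"both"` mode — a spot must
#' exceed mu + 3 sigma of both its own sample's distribution and the pooled
#' distribution — and merged across hubs. Hubs with no gene on the panel
#' are skipped with a log message.
#'
#' @param data Preprocessed spots from [preprocess_spots()].
#' @param hubs A [hub_collection()].
#' @param params Optional [score_params()]; `binarize`/`use_importance` are
#'   forced off.
#' @return A list: `scores` (per spot x hub tibble with outlier flags),
#'   `merged` (per-spot merged calls joined with coordinates and sample),
#'   `burden` (per-sample outlier proportion).
#' @export
score_spots <- function(data, hubs, params = score_params()) {
  stopifnot(inherits(data, "annotated_counts"),
    inherits(hubs, "senesig_hub_collection"))
  params$binarize <- FALSE
  params$use_importance <- FALSE
  all_scores <- list()
  calls <- list()
  for (h in hubs$hubs) {
    if (!length(intersect(names(h$genes), data$genes))) {
      inform(sprintf("score_spots: hub '%s' has no gene on the panel; skipped",
        h$hub_id
      ))
      next
    }
    sc <- score_all_cells(data, h, strata = "sample_id", params = params)
    sc <- call_outliers(sc, mode = "both")
    all_scores[[h$hub_id]] <- sc
    calls[[h$hub_id]] <- sc
  }
  if (!length(calls)) {
    abort("no hub could be scored on this panel", class = "senesig_data_error")
  }
  merged <- merge_outliers(calls)
  coords <- data$cell_meta[, c("cell_id", "sample_id", "x", "y")]
  merged <- left_join(merged, coords, by = "cell_id")
  burden <- senescence_burden(
    merged[, c("cell_id", "outlier")],
    groups = coords[, c("cell_id", "sample_id")]
  )
  list(scores = bind_rows(all_scores), merged = merged, burden = burden)
}

#' Moran's I with truncated inverse-distance weights
#'
#' Spatial autocorrelation of per-spot values (typically 0/1 outlier
#' indicators) with weights `w_ij = 1 / d(i, j)` for `0 < d(i, j) <=
#' cutoff` and 0 beyond the cutoff or on the diagonal. Spots at identical
#' coordinates get weight 0 with a warning. The analytic p-value is
#' `1 - Phi(I)` with Phi the standard normal CDF, exactly as the score is
#' defined; a permutation p-value (`p_method = "permutation"`, recommended)
#' reshuffles the values over the spots.
#'
#' @param coords A data frame with `x` and `y` columns (one row per spot).
#' @param values Numeric vector of per-spot values, not all equal.
#' @param cutoff Maximum Euclidean distance with nonzero weight (default 3,
#'   in the units of the input coordinates).
#' @param p_method `"analytic"` (default) or `"permutation"`.
#' @param n_perm Permutations for the permutation p (default 999).
#' @param seed Integer seed for the permutation p.
#' @return A list of class `senesig_moran`: `I`, `p`, `n_spots`,
#'   `weight_spec`, `p_method`.
#' @export
morans_i <- function(coords, values, cutoff = 3,
                     p_method = c("analytic", "permutation"),
                     n_perm = 999L, seed = 1L) {
  p_method <- match.arg(p_method)
  n <- nrow(coords)
  stopifnot(length(values) == n)
  if (n < 3) abort("need at least 3 spots", class = "senesig_data_error")
  if (var(values) == 0) {
    abort("values have zero variance", class = "senesig_data_error")
  }
  d <- as.matrix(stats::dist(coords[, c("x", "y")]))
  if (any(d[upper.tri(d)] == 0)) {
    warn("morans_i: coincident spots found; their pair weights are set to 0")
  }
  w <- ifelse(d > 0 & d <= cutoff, 1 / d, 0)
  diag(w) <- 0
  if (sum(w) == 0) {
    abort("all pairwise distances exceed the cutoff; I is undefined",
      class = "senesig_data_error"
    )
  }
  moran_stat <- function(x) {
    xc <- x - mean(x)
    n * as.numeric(xc %*% w %*% xc) / (sum(w) * sum(xc^2))
  }
  i_obs <- moran_stat(values)
  if (p_method == "analytic") {
    p <- 1 - pnorm(i_obs)
  } else {
    set.seed(seed)
    i_null <- replicate(n_perm, moran_stat(sample(values)))
    p <- (1 + sum(i_null >= i_obs)) / (1 + n_perm)
  }
  structure(
    list(
      I = i_obs, p = p, n_spots = n,
      weight_spec = list(kind = "inverse_distance", cutoff = cutoff),
      p_method = p_method
    ),
    class = "senesig_moran"
  )
}

#' @export
print.senesig_moran <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (n = %d spots, cutoff = %g, %s p = %.4g)\n",
    x$I, x$n_spots, x$weight_spec$cutoff, x$p_method, x$p
  ))
  invisible(x)
}

#' @export
tidy.senesig_moran <- function(x, ...) {
  tibble(I = x$I, p.value = x$p, n_spots = x$n_spots,
    cutoff = x$weight_spec$cutoff, p_method = x$p_method)
}

#' @export
glance.senesig_moran <- function(x, ...) tidy(x)

#' Spatial senescence report: per-sample burden and clustering
#'
#' Runs [score_spots()] and then [morans_i()] per sample on the merged
#' outlier indicators.
#'
#' @param data Preprocessed spots ([preprocess_spots()]).
#' @param hubs A [hub_collection()].
#' @param cutoff Moran distance cutoff (default 3).
#' @param p_method Passed to [morans_i()].
#' @param params Optional [score_params()].
#' @return A tibble with one row per sample: `sample_id`, `n_spots`,
#'   `burden`, `moran_i`, `moran_p`.
#' @export
spatial_report <- function(data, hubs, cutoff = 3,
                           p_method = c("analytic", "permutation"),
                           params = score_params()) {
  p_method <- match.arg(p_method)
  res <- score_spots(data, hubs, params = params)
  purrr::map_dfr(unique(res$merged$sample_id), function(s) {
    sub <- res$merged[res$merged$sample_id == s, ]
    mi <- tryCatch(
      morans_i(sub, as.numeric(sub$outlier), cutoff = cutoff,
        p_method = p_method, seed = params$seed),
      error = function(e) NULL
    )
    tibble(
      sample_id = s, n_spots = nrow(sub), burden = mean(sub$outlier),
      moran_i = if (is.null(mi)) NA_real_ else mi$I,
      moran_p = if (is.null(mi)) NA_real_ else mi$p
    )
  })
}
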