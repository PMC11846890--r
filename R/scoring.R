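# Per-cell senescence scoring against a hub with expression-bin-matched
# background genes, and mu + 3*sigma outlier calling.

#' Scoring parameters
#'
#' @param n_bins Number of equal-size mean-expression bins (default 25).
#' @param ctrl_size Background genes sampled per signature gene (default 50).
#' @param binarize Binarize counts at one UMI before scoring (default TRUE,
#'   the binary senescence-state flavor; use FALSE on normalized data such
#'   as Visium spots).
#' @param use_importance Multiply signature-gene values by their hub
#'   importance (default TRUE). Background genes are never amplified.
#' @param seed Integer seed controlling background sampling.
#' @return A `senesig_score_params` list.
#' @export
score_params <- function(n_bins = 25L, ctrl_size = 50L, binarize = TRUE,
                         use_importance = TRUE, seed = 1L) {
  stopifnot(n_bins >= 1, ctrl_size >= 1)
  structure(
    list(
      n_bins = as.integer(n_bins), ctrl_size = as.integer(ctrl_size),
      binarize = isTRUE(binarize), use_importance = isTRUE(use_importance),
      seed = as.integer(seed)
    ),
    class = "senesig_score_params"
  )
}

# equal-size bins by mean-expression rank; ties broken by rank order
expression_bins <- function(means, n_bins) {
  ord <- order(means, seq_along(means))
  bin <- integer(length(means))
  bin[ord] <- as.integer(ceiling(seq_along(means) / (length(means) / n_bins)))
  pmin(bin, n_bins)
}

#' Score cells against one hub signature
#'
#' Implements the bin-matched module score: (1) per-gene mean expression
#' over all cells; (2) genes ranked by mean and split into `n_bins`
#' equal-size bins; (3) for each signature gene, `ctrl_size` background
#' genes sampled from its bin (signature genes excluded; bins smaller than
#' `ctrl_size` are sampled with replacement and logged), the union forming
#' the background set BG; (4) optional binarization at one UMI; (5) optional
#' amplification of signature-gene values by hub importance; (6) per-cell
#' score = mean over the signature genes minus mean over BG.
#'
#' With `binarize = TRUE` the raw layer is required (positivity is defined
#' on UMIs); with `binarize = FALSE` a `normalized_log` layer is expected.
#'
#' @param data An [annotated_counts()].
#' @param hub A [hub()] already translated into the dataset's universe.
#' @param params A [score_params()] object.
#' @return A tibble of class `senesig_scores`: `cell_id`, `hub_id`, `score`,
#'   plus attributes `background_used` (character) and `params`.
#' @export
score_hub <- function(data, hub, params = score_params()) {
  stopifnot(inherits(data, "annotated_counts"), inherits(hub, "senesig_hub"))
  if (ncol(data$counts) < 2) {
    abort("need at least 2 cells to score", class = "senesig_data_error")
  }
  if (params$binarize && data$layer_kind != "raw") {
    abort("binarized scoring needs the raw layer", class = "senesig_data_error")
  }
  sig <- intersect(names(hub$genes), data$genes)
  if (!length(sig)) {
    abort(sprintf("hub '%s': no gene present in the dataset; translate first",
      hub$hub_id
    ), class = "senesig_data_error")
  }
  means <- Matrix::rowSums(data$counts) / ncol(data$counts)
  bins <- expression_bins(means, params$n_bins)
  names(bins) <- data$genes
  set.seed(params$seed)
  bg <- character(0)
  with_replacement <- FALSE
  for (s in sig) {
    pool <- data$genes[bins == bins[s]]
    pool <- setdiff(pool, sig)
    if (!length(pool)) next
    if (length(pool) >= params$ctrl_size) {
      bg <- c(bg, sample(pool, params$ctrl_size))
    } else {
      with_replacement <- TRUE
      bg <- c(bg, sample(pool, params$ctrl_size, replace = TRUE))
    }
  }
  if (with_replacement) {
    inform("score_hub: some expression bins smaller than ctrl_size; sampled with replacement")
  }
  bg <- unique(bg)
  if (!length(bg)) {
    abort("no background gene could be sampled", class = "senesig_data_error")
  }
  z_sig <- data$counts[sig, , drop = FALSE]
  z_bg <- data$counts[bg, , drop = FALSE]
  if (params$binarize) {
    z_sig@x <- rep(1, length(z_sig@x))
    z_bg@x <- rep(1, length(z_bg@x))
  }
  if (params$use_importance) {
    z_sig <- Matrix::Diagonal(x = unname(hub$genes[sig])) %*% z_sig
  }
  score <- Matrix::colSums(z_sig) / length(sig) - Matrix::colSums(z_bg) / length(bg)
  out <- tibble(
    cell_id = data$cells, hub_id = hub$hub_id, score = as.numeric(score)
  )
  attr(out, "background_used") <- bg
  attr(out, "params") <- params
  class(out) <- c("senesig_scores", class(out))
  out
}

#' Score all cells stratified by metadata categories
#'
#' Applies [score_hub()] independently within each stratum (gene means,
#' expression bins and backgrounds are recomputed per stratum) so that
#' cell-type or sample composition does not confound the score. Strata with
#' fewer than 2 cells are skipped with a logged reason.
#'
#' @param data An [annotated_counts()].
#' @param hub A [hub()].
#' @param strata Character vector of `cell_meta` column names to stratify
#'   by (e.g. `c("sample_id", "cell_type")`); `NULL` scores all cells as
#'   one stratum.
#' @param params A [score_params()].
#' @return A `senesig_scores` tibble with an added `stratum` column.
#' @export
score_all_cells <- function(data, hub, strata = NULL, params = score_params()) {
  stopifnot(inherits(data, "annotated_counts"))
  if (is.null(strata)) {
    out <- score_hub(data, hub, params)
    out$stratum <- "all"
    return(out)
  }
  missing <- setdiff(strata, names(data$cell_meta))
  if (length(missing)) {
    abort(paste0("unknown strata column(s): ", paste(missing, collapse = ", ")),
      class = "senesig_schema_error"
    )
  }
  key <- do.call(paste, c(data$cell_meta[strata], sep = "/"))
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) {
      inform(sprintf("score_all_cells: stratum '%s' has < 2 cells; skipped", k))
      next
    }
    sc <- score_hub(subset_cells(data, cells = idx), hub, params)
    sc$stratum <- k
    out[[length(out) + 1]] <- sc
  }
  if (!length(out)) {
    abort("no stratum with at least 2 cells", class = "senesig_data_error")
  }
  res <- bind_rows(out)
  class(res) <- c("senesig_scores", class(res))
  res
}

#' Call outlier (senescent) cells from score distributions
#'
#' A cell is an outlier when its score is strictly greater than
#' `mean + 3 * sd` of the relevant score distribution. In `"per-stratum"`
#' mode each stratum's own distribution is used; in `"combined"` mode the
#' pooled distribution; in `"both"` mode (spatial usage) a cell must exceed
#' both its own stratum's threshold and the pooled threshold. Zero-variance
#' distributions yield no outliers (logged).
#'
#' @param scores A `senesig_scores` tibble with `stratum` (added when
#'   missing) and `score` columns.
#' @param mode `"per-stratum"`, `"combined"`, or `"both"`.
#' @param n_sd Number of standard deviations (default 3).
#' @return The input with `threshold` and `outlier` columns added.
#' @export
call_outliers <- function(scores, mode = c("per-stratum", "combined", "both"),
                          n_sd = 3) {
  mode <- match.arg(mode)
  if (!"stratum" %in% names(scores)) scores$stratum <- "all"
  pooled_thr <- mean(scores$score) + n_sd * sd(scores$score)
  if (!is.finite(pooled_thr)) {
    inform("call_outliers: zero-variance pooled distribution; no outliers")
    pooled_thr <- Inf
  }
  scores <- scores |>
    group_by(.data$stratum) |>
    mutate(threshold = {
      thr <- mean(.data$score) + n_sd * sd(.data$score)
      if (!is.finite(thr)) thr <- Inf
      thr
    }) |>
    ungroup()
  scores$outlier <- switch(mode,
    "per-stratum" = scores$score > scores$threshold,
    "combined" = scores$score > pooled_thr,
    "both" = scores$score > scores$threshold & scores$score > pooled_thr
  )
  if (mode != "per-stratum") attr(scores, "pooled_threshold") <- pooled_thr
  scores
}

#' Merge outlier calls across hubs
#'
#' A cell carries potential senescence burden when any hub flags it; the
#' merge is a per-cell logical OR over the supplied calls.
#'
#' @param calls A list of tibbles from [call_outliers()] over the same cell
#'   universe (same `cell_id` sets).
#' @return A tibble: `cell_id`, `n_hubs_flagging`, `outlier`.
#' @export
merge_outliers <- function(calls) {
  stopifnot(length(calls) >= 1)
  ids <- lapply(calls, function(x) sort(unique(x$cell_id)))
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    abort("outlier calls cover different cell sets", class = "senesig_data_error")
  }
  merged <- bind_rows(calls) |>
    group_by(.data$cell_id) |>
    summarise(n_hubs_flagging = sum(.data$outlier), .groups = "drop") |>
    mutate(outlier = .data$n_hubs_flagging > 0)
  merged
}

#' Senescence burden per population
#'
#' @param merged Output of [merge_outliers()] (or any tibble with `cell_id`
#'   and `outlier`).
#' @param groups Optional tibble mapping `cell_id` to grouping columns
#'   (e.g. sample, cell type); `NULL` gives the overall proportion.
#' @return A tibble with the proportion of flagged cells (`burden`) per group.
#' @export
senescence_burden <- function(merged, groups = NULL) {
  if (is.null(groups)) {
    return(tibble(
      n_cells = nrow(merged), n_outliers = sum(merged$outlier),
      burden = mean(merged$outlier)
    ))
  }
  left_join(merged, groups, by = "cell_id") |>
    group_by(across(all_of(setdiff(names(groups), "cell_id")))) |>
    summarise(
      n_cells = n(), n_outliers = sum(.data$outlier),
      burden = mean(.data$outlier), .groups = "drop"
    )
}
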