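test_that("score_hub separates a fully positive planted signature", {
  # 10 hub genes positive in the planted cells, ~absent elsewhere;
  # expected planted score ~ 1 - background positivity
  set.seed(8)
  n_genes <- 400
  n_cells <- 300
  planted_cells <- 1:30
  hub_genes <- paste0("g", sprintf("%04d", 1:10))
  m <- matrix(rbinom(n_genes * n_cells, 1, 0.02), n_genes, n_cells)
  m[1:10, planted_cells] <- 1
  rownames(m) <- paste0("g", sprintf("%04d", 1:n_genes))
  ac <- counts_from_dense(m, ages = rep(24, n_cells))
  h <- hub("p", setNames(rep(1, 10), hub_genes))
  sc <- score_hub(ac, h, score_params(seed = 1))
  expect_gt(mean(sc$score[planted_cells]), 0.9)
  expect_gt(min(sc$score[planted_cells]), 0.8)
  expect_lt(max(sc$score[-planted_cells]), 0.6)

  # doubling every importance doubles exactly the signature term
  h2 <- hub("p2", setNames(rep(2, 10), hub_genes))
  sc2 <- score_hub(ac, h2, score_params(seed = 1))
  bg <- attr(sc, "background_used")
  bg_mean <- Matrix::colSums(ac$counts[bg, ] > 0) / length(bg)
  sig_term <- sc$score + bg_mean
  expect_equal(sc2$score + bg_mean, 2 * sig_term, tolerance = 1e-12)

  # a hub expressed in no cell scores <= 0 everywhere
  m0 <- m
  m0[1:10, ] <- 0
  ac0 <- counts_from_dense(m0, ages = rep(24, n_cells))
  # keep the genes in the universe but dark
  sc0 <- score_hub(ac0, h, score_params(seed = 1))
  expect_true(all(sc0$score <= 0))
})

test_that("random gene sets score near zero (bin-matched null calibration)", {
  sim <- shared_sim()
  young <- subset_cells(sim$data, cells = which(sim$truth$age == 3))
  bg_genes <- setdiff(young$genes, unlist(sim$program_genes))
  set.seed(14)
  n_draws <- 60
  means <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    size <- sample(10:100, 1)
    rand_hub <- hub("rand", setNames(rep(1, size), sample(bg_genes, size)))
    sc <- score_hub(young, rand_hub, score_params(seed = d))
    means[d] <- mean(sc$score)
  }
  se <- sd(means) / sqrt(n_draws)
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("background sampling is deterministic, bin-matched and excludes the signature", {
  sim <- shared_sim()
  h <- hub("p", setNames(rep(1, 15), sim$program_genes$program1))
  sc1 <- score_hub(sim$data, h, score_params(seed = 5))
  sc2 <- score_hub(sim$data, h, score_params(seed = 5))
  expect_identical(sc1$score, sc2$score)
  expect_identical(attr(sc1, "background_used"), attr(sc2, "background_used"))
  bg <- attr(sc1, "background_used")
  expect_length(intersect(bg, names(h$genes)), 0)
  expect_lte(length(bg), 15 * 50)
  # background genes come from the signature genes' expression bins
  means <- Matrix::rowSums(sim$data$counts) / ncol(sim$data$counts)
  bins <- senesig:::expression_bins(means, 25)
  names(bins) <- sim$data$genes
  expect_true(all(bins[bg] %in% bins[names(h$genes)]))
})

test_that("stratified scoring equals per-stratum scoring and is order-invariant", {
  sim <- shared_sim()
  h <- hub("p", setNames(rep(1, 15), sim$program_genes$program1))
  params <- score_params(seed = 2)
  all_sc <- score_all_cells(sim$data, h, strata = "age", params = params)
  # scoring one stratum alone reproduces its rows
  idx3 <- which(sim$data$cell_meta$age == 3)
  alone <- score_hub(subset_cells(sim$data, cells = idx3), h, params)
  merged <- all_sc[all_sc$stratum == "3", ]
  expect_equal(
    setNames(merged$score, merged$cell_id)[alone$cell_id],
    setNames(alone$score, alone$cell_id)
  )
  # shuffling cell order leaves per-cell scores unchanged
  set.seed(3)
  perm <- sample(ncol(sim$data$counts))
  shuffled <- subset_cells(sim$data, cells = perm)
  sc_shuf <- score_all_cells(shuffled, h, strata = "age", params = params)
  expect_equal(
    setNames(sc_shuf$score, sc_shuf$cell_id)[all_sc$cell_id],
    setNames(all_sc$score, all_sc$cell_id)
  )
  # strata with different profiles get different backgrounds (recomputed)
  sc_young <- score_hub(subset_cells(sim$data, cells = idx3), h, params)
  sc_old <- score_hub(
    subset_cells(sim$data, cells = setdiff(seq_len(ncol(sim$data$counts)), idx3)),
    h, params
  )
  expect_false(identical(
    attr(sc_young, "background_used"), attr(sc_old, "background_used")
  ))
})

test_that("binary and normalized scoring flavors are highly correlated", {
  sim <- shared_sim()
  h <- hub("p", setNames(rep(1, 15), sim$program_genes$program1))
  sc_bin <- score_hub(sim$data, h, score_params(seed = 6, binarize = TRUE))
  # normalized_log layer of the same counts
  m <- sim$data$counts
  m <- m %*% Matrix::Diagonal(x = 10000 / Matrix::colSums(m))
  m@x <- log1p(m@x)
  norm <- annotated_counts(m, sim$data$genes, sim$data$cell_meta,
    layer_kind = "normalized_log"
  )
  sc_norm <- score_hub(norm, h, score_params(seed = 6, binarize = FALSE))
  expect_gt(cor(sc_bin$score, sc_norm$score), 0.8)
})

test_that("adding a planted gene never decreases the planted-cell mean score", {
  sim <- shared_sim()
  planted <- sim$program_genes$program1
  sen <- which(sim$truth$is_senescent)
  params <- score_params(seed = 7)
  mean_with_k <- vapply(c(5, 10, 15), function(k) {
    h <- hub("p", setNames(rep(1, k), planted[1:k]))
    mean(score_hub(sim$data, h, params)$score[sen])
  }, numeric(1))
  expect_true(all(diff(mean_with_k) >= -0.02))
})

test_that("outlier calling applies mu + 3 sigma per stratum and in both mode", {
  set.seed(10)
  scores <- tibble::tibble(
    cell_id = paste0("c", 1:401), hub_id = "h",
    score = c(rnorm(400), 6), # one clear outlier at +6 sigma
    stratum = rep(c("s1", "s2"), length.out = 401)
  )
  calls <- call_outliers(scores, mode = "per-stratum")
  expect_true(calls$outlier[calls$cell_id == "c401"])
  expect_lte(sum(calls$outlier), 5)
  thr <- calls$threshold[calls$stratum == "s1"][1]
  s1 <- calls[calls$stratum == "s1", ]
  expect_equal(
    thr, mean(s1$score) + 3 * sd(s1$score)
  )
  # all-equal scores: zero variance, no outliers
  const <- tibble::tibble(
    cell_id = paste0("c", 1:10), hub_id = "h", score = 1, stratum = "s"
  )
  expect_false(any(suppressMessages(call_outliers(const))$outlier))
  # both mode requires exceeding the stratum AND pooled thresholds
  two <- tibble::tibble(
    cell_id = paste0("c", 1:60), hub_id = "h",
    score = c(rnorm(30, 0, 0.1), rnorm(29, 10, 0.1), 10.5),
    stratum = rep(c("low", "high"), each = 30)
  )
  both <- call_outliers(two, mode = "both")
  # c60 is modestly above its own stratum but not above the pooled threshold
  expect_false(any(both$outlier))
})

test_that("outlier merges are a per-cell OR with burden proportions", {
  calls_a <- tibble::tibble(
    cell_id = paste0("c", 1:100), outlier = c(rep(TRUE, 3), rep(FALSE, 97))
  )
  calls_b <- tibble::tibble(
    cell_id = paste0("c", 1:100), outlier = c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 96))
  )
  merged <- merge_outliers(list(calls_a, calls_b))
  expect_equal(sum(merged$outlier), 4)
  expect_equal(merged$n_hubs_flagging[merged$cell_id == "c1"], 2)
  expect_equal(senescence_burden(merged)$burden, 0.04)
  expect_error(
    merge_outliers(list(calls_a, calls_b[1:50, ])),
    class = "senesig_data_error"
  )
})
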