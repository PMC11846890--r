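test_that("weighted cosine similarity matches direct evaluation", {
  a <- hub("a", c(g1 = 1, g2 = 1))
  b <- hub("b", c(g1 = 1, g3 = 1))
  expect_equal(cosine_similarity(a, b), 0.5)
  # identity and disjointness
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, hub("c", c(g4 = 3, g5 = 2))), 0)
  # symmetry, range, and weight sensitivity on random hubs
  set.seed(1)
  for (i in 1:10) {
    ga <- sample(letters, 6)
    gb <- sample(letters, 6)
    ha <- hub("ha", setNames(sample(1:5, 6, TRUE), ga))
    hb <- hub("hb", setNames(sample(1:5, 6, TRUE), gb))
    s <- cosine_similarity(ha, hb)
    expect_equal(s, cosine_similarity(hb, ha))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("hypergeometric overlap matches exhaustive enumeration for small N", {
  cases <- list(
    c(N = 10, a = 5, b = 5, ov = 5), # 1/252
    c(N = 10, a = 5, b = 5, ov = 3),
    c(N = 4, a = 2, b = 2, ov = 1), # 5/6
    c(N = 12, a = 6, b = 4, ov = 2),
    c(N = 12, a = 3, b = 7, ov = 0) # sf = 1
  )
  for (cs in cases) {
    bg <- paste0("G", seq_len(cs["N"]))
    # B occupies the first b genes; A overlaps B in exactly ov genes
    ga <- c(bg[seq_len(cs["ov"])], bg[cs["b"] + seq_len(cs["a"] - cs["ov"])])
    gb <- bg[seq_len(cs["b"])]
    sf <- hypergeometric_overlap(ga, gb, bg)
    expect_equal(sf, enum_hyper_sf(cs["N"], cs["a"], cs["b"], cs["ov"]),
      tolerance = 1e-12
    )
  }
  expect_equal(
    hypergeometric_overlap(paste0("G", 1:5), paste0("G", 1:5), paste0("G", 1:10)),
    1 / 252
  )
  expect_error(
    hypergeometric_overlap(c("G1", "ZZ"), "G1", paste0("G", 1:5)),
    class = "senesig_data_error"
  )
})

test_that("the generating-function tail matches 2^k enumeration and the binomial", {
  set.seed(2)
  for (k in c(3, 7, 12)) {
    sizes <- sample(5:40, k, replace = TRUE)
    N <- 100
    for (m in c(0, 1, k %/% 2, k)) {
      gf <- generating_function_p(sizes, N, m)
      oracle <- enum_genfun(sizes / N, m)
      expect_equal(gf$pmf, oracle$pmf, tolerance = 1e-10)
      expect_equal(gf$p_value, oracle$p_value, tolerance = 1e-10)
      expect_equal(sum(gf$pmf), 1, tolerance = 1e-12)
    }
  }
  # equal p_i collapses to the binomial
  gf <- generating_function_p(rep(20, 9), 100, 3)
  expect_equal(gf$pmf, dbinom(0:9, 9, 0.2), tolerance = 1e-12)
  # printed worked case: p = {0.5, 0.5}, m = 1
  gf <- generating_function_p(c(5, 5), 10, 1)
  expect_equal(gf$pmf, c(0.25, 0.5, 0.25))
  expect_equal(gf$p_value, 0.25)
  # m = k yields 0 under the printed strict tail; geq keeps the atom
  expect_equal(generating_function_p(c(5, 5), 10, 2)$p_value, 0)
  expect_equal(generating_function_p(c(5, 5), 10, 2, tail = "geq")$p_value, 0.25)
  # p non-increasing in m for fixed sizes
  ps <- vapply(0:9, function(m) generating_function_p(rep(20, 9), 100, m)$p_value,
    numeric(1)
  )
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(generating_function_p(c(200), 100, 0), class = "senesig_data_error")
})

test_that("43 signatures yield exactly 903 evaluated pairs", {
  bg <- paste0("G", 1:300)
  set.seed(3)
  hubs <- lapply(1:43, function(i) {
    hub(paste0("h", i), setNames(rep(1, 8), sample(bg, 8)))
  })
  coll <- hub_collection(hubs, background_genes = bg)
  pairs <- pairwise_similarity_network(coll)
  expect_equal(nrow(pairs), 903)
  expect_equal(nrow(pairs), choose(43, 2))
  # a duplicated hub attains the minimal corrected overlap p of all pairs
  coll2 <- hub_collection(c(hubs, list(
    hub("dup", hubs[[1]]$genes)
  )), background_genes = bg)
  pairs2 <- pairwise_similarity_network(coll2)
  dup_row <- pairs2[pairs2$hub_a == "h1" & pairs2$hub_b == "dup", ]
  expect_equal(dup_row$adjusted_p, min(pairs2$adjusted_p))
  expect_equal(dup_row$cosine, 1)
  # non-significant pairs carry no similarity edge
  expect_true(all(is.na(pairs$similarity_score[pairs$adjusted_p >= 0.05])))
})

test_that("permutation overrepresentation brackets the extremes", {
  bg <- paste0("G", 1:50)
  # one gene present in all 6 hubs, the rest random singletons
  set.seed(4)
  hubs <- lapply(1:6, function(i) {
    hub(paste0("h", i), setNames(rep(1, 5), c("G1", sample(bg[-1], 4))))
  })
  coll <- hub_collection(hubs, background_genes = bg)
  res <- permutation_overrepresentation(coll, n_perm = 400, seed = 9)
  expect_equal(nrow(res), length(bg))
  g1 <- res[res$gene == "G1", ]
  expect_lte(g1$empirical_p, 0.05)
  expect_equal(g1$m, 6)
  # an absent gene has p = 1
  absent <- res[res$m == 0, ]
  expect_true(all(absent$empirical_p == 1))
  # agreement in rank with the generating-function p (shared m -> shared rank)
  gf_p <- vapply(res$m, function(m) {
    generating_function_p(rep(5, 6), 50, m)$p_value
  }, numeric(1))
  expect_gte(cor(res$empirical_p, gf_p, method = "spearman"), 0.95)
})

test_that("universal signatures flag only overrepresented genes", {
  bg <- paste0("G", 1:200)
  set.seed(5)
  # plant G1 in every hub; fill the rest randomly
  hubs <- lapply(1:12, function(i) {
    hub(paste0("h", i), setNames(rep(1, 10), c("G1", sample(bg[-1], 9))))
  })
  coll <- hub_collection(hubs, background_genes = bg)
  uni <- universal_signature(coll, alpha = 0.01)
  expect_equal(nrow(uni), length(bg))
  expect_true(uni$member[uni$gene == "G1"])
  expect_equal(uni$m[uni$gene == "G1"], 12)
  # genes in no hub: q = 1, never members
  expect_true(all(uni$q[uni$m == 0] == 1))
  expect_true(all(!uni$member[uni$m == 0]))
  # p-values agree with the direct generating-function computation
  direct <- vapply(uni$m, function(m) {
    generating_function_p(rep(10, 12), 200, m)$p_value
  }, numeric(1))
  expect_equal(uni$p, direct, tolerance = 1e-12)
  # determinism: identical inputs give identical q
  uni2 <- universal_signature(coll, alpha = 0.01)
  expect_identical(uni$q, uni2$q)
})

test_that("top_common_genes ranks by membership with lexicographic ties", {
  hubs <- list(
    hub("a", c(shared = 1, a1 = 1, zz = 1)),
    hub("b", c(shared = 1, b1 = 1, zz = 1)),
    hub("c", c(shared = 1, c1 = 1))
  )
  coll <- hub_collection(hubs)
  top <- top_common_genes(coll, n = 2)
  expect_identical(names(top$genes), c("shared", "zz"))
  expect_equal(unname(top$genes), c(3, 2))
  # tie at the cutoff resolved lexicographically
  top3 <- top_common_genes(coll, n = 3)
  expect_identical(names(top3$genes)[3], "a1")
  # n larger than the union: everything returned with a log message
  expect_message(whole <- top_common_genes(coll, n = 99), "distinct genes")
  expect_length(whole$genes, 5) # the union of all hub genes
})
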