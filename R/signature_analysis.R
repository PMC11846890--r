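# Signature comparison and merging: weighted cosine similarity,
# hypergeometric overlap, permutation overrepresentation, and the
# Poisson-binomial generating function behind the universal panel.

#' Weighted cosine similarity between two hubs
#'
#' Each hub is embedded as an importance-weight vector over the union of the
#' two gene lists (zero for non-members); the similarity is the cosine of
#' the two vectors. Nonnegative weights make the result lie in [0, 1], with
#' 1 exactly for identical hubs and 0 for disjoint ones.
#'
#' @param hub_a,hub_b [hub()] objects.
#' @return A number in [0, 1].
#' @export
#' @examples
#' a <- hub("a", c(g1 = 1, g2 = 1))
#' b <- hub("b", c(g1 = 1, g3 = 1))
#' cosine_similarity(a, b) # 0.5
cosine_similarity <- function(hub_a, hub_b) {
  union_genes <- union(names(hub_a$genes), names(hub_b$genes))
  va <- setNames(rep(0, length(union_genes)), union_genes)
  vb <- va
  va[names(hub_a$genes)] <- hub_a$genes
  vb[names(hub_b$genes)] <- hub_b$genes
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Hypergeometric overlap p-value between two hubs
#'
#' The survival function `P(X >= |A intersect B|)` of the hypergeometric
#' distribution with population size `|background|`, `|A|` draws and `|B|`
#' successes, computed as `1 - CDF(|A intersect B| - 1)`.
#'
#' @param hub_a,hub_b [hub()] objects (or character gene vectors).
#' @param background Character vector: the expressed-gene universe. Every
#'   hub gene must be in it (run [translate()] first).
#' @return The survival-function p-value.
#' @export
hypergeometric_overlap <- function(hub_a, hub_b, background) {
  ga <- if (inherits(hub_a, "senesig_hub")) names(hub_a$genes) else hub_a
  gb <- if (inherits(hub_b, "senesig_hub")) names(hub_b$genes) else hub_b
  outside <- setdiff(c(ga, gb), background)
  if (length(outside)) {
    abort(sprintf(
      "%d hub gene(s) outside the background (e.g. %s); translate first",
      length(outside), paste(head(outside, 3), collapse = ", ")
    ), class = "senesig_data_error")
  }
  ov <- length(intersect(ga, gb))
  phyper(ov - 1,
    m = length(gb), n = length(background) - length(gb),
    k = length(ga), lower.tail = FALSE
  )
}

#' All-pairs similarity of a hub collection
#'
#' Scores every unordered hub pair by weighted cosine similarity and the
#' hypergeometric overlap survival function against the collection's
#' background universe. Overlap p-values are multiple-testing corrected
#' (Bonferroni for the similarity network, as used for the network figures;
#' BH also available) and converted to a similarity score
#' `-log10(corrected p)` for pairs significant at `sig_level`.
#'
#' @param collection A [hub_collection()] with `background_genes` set (or
#'   `background` supplied).
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @param sig_level Threshold on the corrected p below which a similarity
#'   edge is emitted (default 0.05).
#' @param background Optional explicit background gene universe.
#' @return A tibble with one row per unordered pair: `hub_a`, `hub_b`,
#'   `overlap`, `cosine`, `hyper_sf`, `adjusted_p`, `similarity_score`
#'   (`NA` for non-significant pairs).
#' @export
pairwise_similarity_network <- function(collection,
                                        correction = c("bonferroni", "BH"),
                                        sig_level = 0.05, background = NULL) {
  correction <- match.arg(correction)
  background <- background %||% collection$background_genes
  if (is.null(background)) {
    abort("a background gene universe is required (none stored on the collection)",
      class = "senesig_data_error"
    )
  }
  hubs <- collection$hubs
  if (length(hubs) < 2) {
    abort("need at least 2 hubs", class = "senesig_data_error")
  }
  ids <- names(hubs)
  pairs <- utils::combn(length(hubs), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- hubs[[pairs[1, p]]]
    b <- hubs[[pairs[2, p]]]
    tibble(
      hub_a = a$hub_id, hub_b = b$hub_id,
      overlap = length(intersect(names(a$genes), names(b$genes))),
      cosine = cosine_similarity(a, b),
      hyper_sf = hypergeometric_overlap(a, b, background)
    )
  })
  res$adjusted_p <- p.adjust(res$hyper_sf, method = correction)
  res$similarity_score <- ifelse(
    res$adjusted_p < sig_level, -log10(res$adjusted_p), NA_real_
  )
  res
}

#' Permutation test of cross-signature gene overrepresentation
#'
#' For each of `n_perm` permutations, every hub is replaced by a uniform
#' without-replacement draw of the same size from the background universe,
#' and each gene's membership count across the permuted hubs is recorded.
#' A gene's empirical p is the (+1-corrected) fraction of permutations in
#' which its permuted count reaches its observed count.
#'
#' @param collection A [hub_collection()] with a background universe.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param background Optional explicit background.
#' @return A tibble: `gene`, `m` (observed membership count), `empirical_p`.
#' @export
permutation_overrepresentation <- function(collection, n_perm = 1000L,
                                           seed = 1L, background = NULL) {
  background <- background %||% collection$background_genes
  if (is.null(background)) {
    abort("a background gene universe is required", class = "senesig_data_error")
  }
  sizes <- vapply(collection$hubs, function(h) length(h$genes), integer(1))
  if (any(sizes > length(background))) {
    abort("a hub is larger than the background universe",
      class = "senesig_data_error"
    )
  }
  n_bg <- length(background)
  observed <- tabulate(
    match(unlist(lapply(collection$hubs, function(h) names(h$genes))), background),
    nbins = n_bg
  )
  set.seed(seed)
  n_ge <- integer(n_bg)
  for (b in seq_len(n_perm)) {
    counts <- integer(n_bg)
    for (s in sizes) {
      draw <- sample.int(n_bg, s)
      counts[draw] <- counts[draw] + 1L
    }
    n_ge <- n_ge + (counts >= observed)
  }
  tibble(
    gene = background, m = observed,
    empirical_p = (1 + n_ge) / (1 + n_perm)
  )
}

#' Tail probability of membership counts via the Poisson-binomial
#' generating function
#'
#' A gene enters signature `i` with probability `p_i = |S_i| / N` under the
#' null of uniform random signatures. The generating function
#' `G(x) = prod_i (1 - p_i + p_i x)` is expanded by iterative polynomial
#' convolution; its normalized coefficients give the probability that a
#' gene is found in exactly `m` of the `k` sets. The p-value is
#' `1 - CDF(m_observed)` as printed (i.e. `P(X > m)`); the conventional
#' `P(X >= m)` is available with `tail = "geq"`.
#'
#' @param set_sizes Integer vector of signature sizes `|S_i|`.
#' @param background_size Background universe size `N`.
#' @param m_observed Observed membership count (0..k).
#' @param tail `"gt"` (printed form, default) or `"geq"`.
#' @return A list: `p_value`, `pmf` (length k+1, sums to 1), `cdf`.
#' @export
generating_function_p <- function(set_sizes, background_size, m_observed,
                                  tail = c("gt", "geq")) {
  tail <- match.arg(tail)
  p <- set_sizes / background_size
  if (any(p > 1)) {
    abort("a set size exceeds the background size", class = "senesig_data_error")
  }
  if (m_observed < 0 || m_observed > length(set_sizes)) {
    abort("m_observed must be between 0 and the number of sets",
      class = "senesig_data_error"
    )
  }
  coef <- 1
  for (pi in p) {
    coef <- c(coef * (1 - pi), 0) + c(0, coef * pi)
  }
  pmf <- coef / sum(coef)
  cdf <- cumsum(pmf)
  k <- length(set_sizes)
  # upper tail summed directly (1 - cdf loses precision for tiny tails)
  p_value <- if (tail == "gt") {
    if (m_observed == k) 0 else sum(pmf[(m_observed + 2):(k + 1)])
  } else {
    sum(pmf[(m_observed + 1):(k + 1)])
  }
  list(p_value = p_value, pmf = pmf, cdf = cdf)
}

#' Universal senescence signature from a hub collection
#'
#' For every background gene, tests whether its membership count across the
#' collection's hubs is higher than expected for uniformly drawn signatures
#' of the same sizes, using [generating_function_p()]. P-values are
#' BH-adjusted over the genes observed in at least one hub (genes never
#' observed are assigned `q = 1` without entering the ranking); members are
#' genes with `q < alpha`.
#'
#' @param collection A [hub_collection()] with a background universe.
#' @param alpha FDR threshold on the adjusted p (default 0.01).
#' @param tail Passed to [generating_function_p()].
#' @param background Optional explicit background.
#' @return A tibble of class `senesig_universal`: `gene`, `m`, `p`, `q`,
#'   `member`, sorted by decreasing `m`.
#' @export
universal_signature <- function(collection, alpha = 0.01,
                                tail = c("gt", "geq"), background = NULL) {
  tail <- match.arg(tail)
  background <- background %||% collection$background_genes
  if (is.null(background)) {
    abort("a background gene universe is required", class = "senesig_data_error")
  }
  sizes <- vapply(collection$hubs, function(h) length(h$genes), integer(1))
  m <- tabulate(
    match(unlist(lapply(collection$hubs, function(h) names(h$genes))), background),
    nbins = length(background)
  )
  # identical set sizes for every gene: one PMF serves all membership counts
  gf <- generating_function_p(sizes, length(background), 0, tail = tail)
  tail_ge <- rev(cumsum(rev(gf$pmf))) # P(X >= m) for m = 0..k
  p_by_m <- if (tail == "gt") c(tail_ge[-1], 0) else tail_ge
  p <- p_by_m[m + 1]
  q <- rep(1, length(m))
  seen <- m >= 1
  q[seen] <- p.adjust(p[seen], method = "BH")
  out <- tibble(
    gene = background, m = m, p = p, q = q, member = q < alpha
  )
  out <- arrange(out, desc(.data$m), .data$gene)
  class(out) <- c("senesig_universal", class(out))
  out
}

#' Composite hub of the most common signature genes
#'
#' Ranks genes by the number of hubs containing them and returns the top
#' `n` as a composite hub whose importances are the membership counts.
#' Ties at the cutoff are broken lexicographically.
#'
#' @param collection A [hub_collection()].
#' @param n Panel size (default 150).
#' @param hub_id Identifier for the composite hub.
#' @return A [hub()].
#' @export
top_common_genes <- function(collection, n = 150L, hub_id = "top_common") {
  genes <- unlist(lapply(collection$hubs, function(h) names(h$genes)))
  if (!length(genes)) abort("empty collection", class = "senesig_data_error")
  counts <- sort(table(genes), decreasing = TRUE)
  ord <- order(-as.integer(counts), names(counts))
  counts <- counts[ord]
  if (length(counts) < n) {
    inform(sprintf(
      "top_common_genes: only %d distinct genes available (n = %d)",
      length(counts), n
    ))
    n <- length(counts)
  }
  sel <- counts[seq_len(n)]
  species <- unique(vapply(collection$hubs, `[[`, character(1), "species"))
  hub(hub_id, setNames(as.integer(sel), names(sel)),
    species = if (length(species) == 1) species else "mixed",
    tissue = "composite", cell_type = "composite"
  )
}
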