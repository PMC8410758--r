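test_that("significant_genes applies a strict threshold and matches step-up BH", {
  tab <- tiny_deg(LETTERS[1:5], rnorm(5), padj = c(0.01, 0.049, 0.05, 0.2, 1))
  expect_equal(sort(significant_genes(tab)$ids), c("A", "B"))

  set.seed(4)
  p <- c(runif(5, 0, 1e-4), runif(45))
  tab2 <- tiny_deg(sprintf("g%02d", 1:50), rnorm(50), padj = p, p = p)
  got <- significant_genes(tab2[, c("gene_id", "log2fc", "pvalue")],
                           adjust = TRUE)$ids
  want <- normalize_ids(tab2$gene_id[bh_reject_bruteforce(p, 0.05)])
  expect_setequal(got, want)

  expect_warning(empty <- significant_genes(tiny_deg(character(), numeric(),
                                                     numeric())), "empty")
  expect_length(empty$ids, 0)
  expect_error(significant_genes(data.frame(x = 1)), "gene_id")
})

test_that("overlap_count normalizes identifiers before intersecting", {
  a <- gene_set("a", c("A", "B", "C"))
  expect_equal(overlap_count(a, a), 3)
  expect_equal(overlap_count(a, gene_set("d", c("X", "Y"))), 0)
  expect_equal(overlap_count(a, c("b", " C", "D")), 2)
})

test_that("hypergeometric moments match enumeration and limiting cases", {
  bern <- hypergeometric_moments(1, 8, 20)          # single Bernoulli draw
  expect_equal(bern$mu, 8 / 20)
  expect_equal(bern$sigma, sqrt(0.4 * 0.6))
  exhaustive <- hypergeometric_moments(20, 8, 20)   # draw the whole universe
  expect_equal(exhaustive$mu, 8)
  expect_equal(exhaustive$sigma, 0)

  # brute-force enumeration over all C(20,5) subsets
  xs <- combn(20, 5, function(s) sum(s <= 8))
  hm <- hypergeometric_moments(5, 8, 20)
  expect_equal(hm$mu, mean(xs), tolerance = 1e-12)
  expect_equal(hm$sigma^2, mean((xs - mean(xs))^2), tolerance = 1e-12)

  expect_error(hypergeometric_moments(30, 8, 20), "universe")
  expect_error(hypergeometric_moments(1, 1, 1), ">= 2")
})

test_that("permutation null converges to the hypergeometric oracle", {
  set.seed(2)
  u <- sprintf("u%04d", 1:2000)
  target <- sample(u, 80)
  query <- c(sample(target, 12), sample(setdiff(u, target), 18))  # x = 12
  res <- permutation_enrichment(query, target, u, n_perm = 4000, seed = 5)
  hm <- hypergeometric_moments(30, 80, 2000)
  expect_equal(res$observed_overlap, 12)
  expect_lt(abs(res$null_mean - hm$mu), 4 * hm$sigma / sqrt(4000))
  z_hg <- (12 - hm$mu) / hm$sigma
  expect_lt(abs(res$z - z_hg), 0.2)
})

test_that("tiny-universe permutation matches the exhaustively enumerated null", {
  u <- sprintf("u%02d", 1:10)
  target <- u[1:4]
  query <- u[c(1, 2, 5)]
  xs <- combn(10, 3, function(s) sum(s <= 4))     # the exact null
  res <- permutation_enrichment(query, target, u, n_perm = 5000, seed = 3)
  expect_equal(res$observed_overlap, 2)
  expect_lt(abs(res$null_mean - mean(xs)), 4 * sd(xs) / sqrt(5000))
  expect_lt(abs(res$null_sd - sd(xs)), 0.1)
  hm <- hypergeometric_moments(3, 4, 10)
  expect_equal(mean(xs), hm$mu, tolerance = 1e-12)
})

test_that("z is monotone in the observed overlap at fixed sizes and seed", {
  u <- sprintf("u%03d", 1:200)
  target <- u[1:40]
  zs <- vapply(0:5, function(k) {
    q <- c(u[seq_len(k)], u[100 + seq_len(10 - k)])
    permutation_enrichment(q, target, u, n_perm = 500, seed = 11)$z
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("self-enrichment, degeneracies and reproducibility", {
  u <- sprintf("u%03d", 1:300)
  q <- u[1:25]
  self <- permutation_enrichment(q, q, u, n_perm = 500, seed = 2)
  expect_equal(self$observed_overlap, 25)
  expect_gt(self$z, 5)

  expect_error(permutation_enrichment(q, u, u, n_perm = 500, seed = 2),
               "degenerate|universe")
  expect_error(permutation_enrichment(c(q, "NOT_IN_U"), q, u, n_perm = 500),
               "subset")
  r1 <- permutation_enrichment(q, u[10:60], u, n_perm = 500, seed = 9)
  r2 <- permutation_enrichment(q, u[10:60], u, n_perm = 500, seed = 9)
  expect_identical(r1, r2)
})

test_that("direction reversal finds sign flips between contrasts", {
  ids <- sprintf("g%02d", 1:30)
  lfc <- c(rnorm(10, 2, 0.3), rnorm(10, -2, 0.3), rnorm(10, 0.5, 0.1))
  padj <- c(rep(1e-5, 20), rep(0.8, 10))
  a <- tiny_deg(ids, lfc, padj)

  flipped <- a; flipped$log2fc <- -a$log2fc
  rev1 <- suppressWarnings(direction_reversal(a, flipped, n_perm = 200, seed = 1))
  expect_setequal(rev1$reversed$ids, normalize_ids(ids[1:20]))

  rev2 <- suppressWarnings(direction_reversal(a, a, n_perm = 200, seed = 1))
  expect_length(rev2$reversed$ids, 0)

  withzero <- flipped; withzero$log2fc[1] <- 0
  expect_warning(direction_reversal(a, withzero, n_perm = 200, seed = 1),
                 "exactly 0")
})

test_that("planted rescue reversal fraction is recovered end-to-end", {
  sim <- gen_expression(small_expr_cfg(seed = 19, n_de = 200,
                                       rescue_reversal_fraction = 0.2))
  # a co-significant null gene (log2fc 0) may be excluded with a warning
  rev <- suppressWarnings(direction_reversal(sim$truth_patient,
                                             sim$truth_rescue,
                                             n_perm = 500, seed = 4))
  sig_a <- significant_genes(sim$truth_patient)$ids
  sig_b <- significant_genes(sim$truth_rescue)$ids
  expect_setequal(rev$reversed$ids, normalize_ids(sim$reversed_genes))
  # every reversed gene is co-significant with opposite signs by construction
  expect_true(all(rev$reversed$ids %in% intersect(sig_a, sig_b)))
  # Bernoulli(0.2) flips out of 200 planted genes: 3-sigma binomial band
  expect_lt(abs(length(rev$reversed) - 0.2 * 200),
            3 * sqrt(200 * 0.2 * 0.8) + 1)
  expect_gt(rev$result$z, 5)
})

test_that("top-loading selection uses absolute weights with lexicographic ties", {
  w <- c(gA = 3, gB = -5, gC = 1)
  expect_equal(top_loading_genes(w, 1)$ids, "GB")
  expect_setequal(top_loading_genes(w, 3)$ids, c("GA", "GB", "GC"))
  tie <- c(gB = 2, gA = -2, gC = 1)
  expect_equal(top_loading_genes(tie, 1)$ids, "GA")   # |2| tie -> lexicographic
  expect_error(top_loading_genes(w, 0), "integer")
  expect_error(top_loading_genes(w, 4), "exceeds")
  expect_error(top_loading_genes(unname(w), 1), "named")
})

test_that("PC1 of batch-structured counts picks batch genes, not DE genes", {
  sim <- gen_expression(small_expr_cfg(seed = 23, batch_shift_sd = 2))
  pc <- prcomp(t(log2(sim$counts + 1)), center = TRUE, scale. = FALSE)
  top100 <- top_loading_genes(pc$rotation[, 1], 100)
  n_batch <- overlap_count(top100, sim$batch_genes)
  n_de <- overlap_count(top100, sim$de_genes)
  # chance expectation for 100 draws from 2000 genes
  exp_batch <- 100 * length(sim$batch_genes) / 2000
  exp_de <- 100 * length(sim$de_genes) / 2000
  expect_gt(n_batch, 3 * exp_batch)
  expect_lt(n_de, exp_de + 3 * sqrt(exp_de) + 1)
})

test_that("p_from_z is the two-sided normal tail", {
  expect_equal(p_from_z(0), 1)
  expect_equal(p_from_z(1.95996), 0.05, tolerance = 1e-4)
  expect_equal(p_from_z(-2), p_from_z(2))
  expect_error(p_from_z(Inf), "finite")
})
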