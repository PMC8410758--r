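#' A named set of gene identifiers
#'
#' Identifiers are normalized (case-folded, whitespace-stripped) and
#' deduplicated; duplicates trigger a warning, since they usually indicate
#' an upstream merge problem.
#'
#' @param name Set label.
#' @param ids Character vector of gene identifiers.
#' @param warn_duplicates Warn when duplicates are collapsed.
#' @return An object of class `gene_set` with `name` and `ids`.
#' @export
gene_set <- function(name, ids, warn_duplicates = TRUE) {
  ids <- normalize_ids(ids)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    if (warn_duplicates)
      warning(sum(duplicated(ids)), " duplicate id(s) collapsed in set '",
              name, "'")
    ids <- unique(ids)
  }
  structure(list(name = as.character(name), ids = ids), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d ids\n", x$name, length(x$ids)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

as_gene_ids <- function(x) {
  if (inherits(x, "gene_set")) x$ids else normalize_ids(x)
}

#' Significant genes from a differential-expression table
#'
#' Genes with BH-adjusted p strictly below `alpha`. If the table has no
#' `padj` column, Benjamini-Hochberg adjustment of the raw p-values can be
#' requested with `adjust = TRUE`.
#'
#' @param table A DEG table: data.frame with `gene_id`, `log2fc`, `pvalue`
#'   and (unless `adjust = TRUE`) `padj`.
#' @param alpha Significance threshold on the adjusted p-value (strict `<`).
#' @param adjust Compute `padj` internally from `pvalue` by BH.
#' @return A [gene_set()] of the significant genes.
#' @export
significant_genes <- function(table, alpha = 0.05, adjust = FALSE) {
  if (!all(c("gene_id", "pvalue") %in% names(table)))
    stop_cfg("DEG table must have 'gene_id' and 'pvalue' columns")
  padj <- if (adjust || is.null(table$padj))
    stats::p.adjust(table$pvalue, method = "BH") else table$padj
  if (nrow(table) == 0L) {
    warning("empty DEG table: no significant genes")
    return(gene_set(sprintf("padj<%g", alpha), character()))
  }
  gene_set(sprintf("padj<%g", alpha), table$gene_id[padj < alpha])
}

#' Size of the intersection of two gene sets
#'
#' Identifiers are normalized before intersecting, so `"pax6 "` and
#' `"PAX6"` count as the same gene.
#'
#' @param a,b [gene_set()] objects or character vectors.
#' @return Integer overlap count.
#' @export
overlap_count <- function(a, b) {
  length(intersect(as_gene_ids(a), as_gene_ids(b)))
}

#' Closed-form mean and SD of the random-overlap null
#'
#' When a query set of size `n_query` is drawn uniformly without replacement
#' from a universe of size `n_universe`, its overlap with a fixed target set
#' of size `n_target` is hypergeometric with
#' \eqn{\mu = qK/N} and
#' \eqn{\sigma^2 = \mu (1 - K/N)(N - q)/(N - 1)}
#' (q = query size, K = target size, N = universe size). This is the exact
#' oracle for the permutation null.
#'
#' @param n_query,n_target,n_universe Set sizes; both sizes `<= n_universe`,
#'   `n_universe >= 2`.
#' @return A list with `mu` and `sigma`.
#' @export
hypergeometric_moments <- function(n_query, n_target, n_universe) {
  q <- check_count(n_query, "n_query", 0L)
  K <- check_count(n_target, "n_target", 0L)
  N <- check_count(n_universe, "n_universe", 2L)
  if (q > N || K > N) stop_cfg("set sizes cannot exceed the universe")
  mu <- q * (K / N)
  sigma2 <- mu * (1 - K / N) * (N - q) / (N - 1)
  list(mu = mu, sigma = sqrt(sigma2))
}

#' Permutation-null gene-set enrichment
#'
#' Tests whether the overlap between a query set (e.g. differentially
#' expressed genes) and a target set (e.g. a disease annotation list) is
#' larger than expected by chance. The null is built by drawing `n_perm`
#' random sets of the query's size uniformly without replacement from the
#' universe and recording their overlaps with the target; the observed
#' overlap is summarized as \eqn{z = (x - \mu)/\sigma} against the null
#' sample mean and SD, with the normal-approximation two-sided p-value as
#' the primary result and the empirical permutation p-value
#' \eqn{((\#\,|x_{null}-\mu| \ge |x-\mu|) + 1)/(n_{perm}+1)} alongside.
#'
#' @param query,target [gene_set()] objects (or character vectors); both
#'   must be subsets of the universe.
#' @param universe Character vector or [gene_set()]: the identifiers random
#'   sets are drawn from (typically all genes tested for differential
#'   expression).
#' @param n_perm Number of permutations, >= 100.
#' @param seed Integer RNG seed.
#' @return An object of class `enrichment_result`.
#' @export
permutation_enrichment <- function(query, target, universe,
                                   n_perm = 10000L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", 100L)
  qname <- if (inherits(query, "gene_set")) query$name else "query"
  tname <- if (inherits(target, "gene_set")) target$name else "target"
  q <- as_gene_ids(query); t <- as_gene_ids(target); u <- as_gene_ids(universe)
  u <- unique(u)
  if (length(q) == 0L) stop_cfg("query set is empty")
  if (length(t) == 0L) stop_cfg("target set is empty")
  if (!all(q %in% u)) stop_cfg("query is not a subset of the universe (%d missing)",
                               sum(!q %in% u))
  if (!all(t %in% u)) stop_cfg("target is not a subset of the universe (%d missing)",
                               sum(!t %in% u))

  x <- length(intersect(q, t))
  in_target <- u %in% t
  set.seed(check_count(seed, "seed", 0L))
  null_x <- vapply(seq_len(n_perm), function(i)
    sum(in_target[sample.int(length(u), length(q))]), integer(1L))
  mu <- mean(null_x)
  sigma <- stats::sd(null_x)  # sample SD, ddof 1
  if (sigma == 0)
    stop_cfg("degenerate null (sd 0): every random set overlaps identically%s",
             if (length(t) == length(u)) " - target equals the universe" else "")
  z <- (x - mu) / sigma
  p_emp <- (sum(abs(null_x - mu) >= abs(x - mu)) + 1) / (n_perm + 1)
  structure(list(observed_overlap = x, null_mean = mu, null_sd = sigma,
                 z = z, p_two_sided = p_from_z(z), p_empirical = p_emp,
                 n_perm = n_perm, seed = seed,
                 universe_size = length(u), query_size = length(q),
                 target_size = length(t),
                 query_name = qname, target_name = tname),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Permutation-null set enrichment\n")
  cat(sprintf("  %s (n=%d) vs %s (n=%d) in universe of %d\n",
              x$query_name, x$query_size, x$target_name, x$target_size,
              x$universe_size))
  cat(sprintf("  overlap x = %d; null mu = %.4g, sd = %.4g (%d perms, seed %d)\n",
              x$observed_overlap, x$null_mean, x$null_sd, x$n_perm, x$seed))
  cat(sprintf("  z = %.4g, two-sided p = %.4g (empirical p = %.4g)\n",
              x$z, x$p_two_sided, x$p_empirical))
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(query = x$query_name, target = x$target_name,
             observed_overlap = x$observed_overlap,
             null_mean = x$null_mean, null_sd = x$null_sd, z = x$z,
             p_two_sided = x$p_two_sided, p_empirical = x$p_empirical,
             n_perm = x$n_perm, seed = x$seed,
             universe_size = x$universe_size, query_size = x$query_size,
             target_size = x$target_size, stringsAsFactors = FALSE)
}

#' Direction-reversal concordance between two DE contrasts
#'
#' Finds genes significant (padj < `alpha`) in both tables whose effect
#' signs are opposite - e.g. genes dysregulated in patient organoids whose
#' expression moves back in a CRISPR-rescue line - and tests the count by
#' permutation: each null draw takes a random set of the second contrast's
#' significant-set size from the universe and counts how many land in the
#' first contrast's significant set with an opposite sign assigned by a
#' fair coin. Genes with log2fc exactly 0 in either table are excluded from
#' the reversed set with a warning.
#'
#' @param deg_a,deg_b DEG tables (data.frames with `gene_id`, `log2fc`,
#'   `pvalue`, `padj`) on a shared gene namespace, e.g. patient-vs-control
#'   and rescue-vs-patient.
#' @param alpha Significance threshold.
#' @param universe Universe for the permutation null; default all genes in
#'   `deg_a`.
#' @param n_perm,seed Permutation settings.
#' @return A list with `reversed` (a [gene_set()]) and `result`
#'   (an `enrichment_result` for the reversal count).
#' @export
direction_reversal <- function(deg_a, deg_b, alpha = 0.05, universe = NULL,
                               n_perm = 10000L, seed = 1L) {
  for (tb in list(deg_a, deg_b))
    if (!all(c("gene_id", "log2fc", "padj") %in% names(tb)))
      stop_cfg("DEG tables need 'gene_id', 'log2fc' and 'padj' columns")
  n_perm <- check_count(n_perm, "n_perm", 100L)
  ids_a <- normalize_ids(deg_a$gene_id); ids_b <- normalize_ids(deg_b$gene_id)
  sig_a <- ids_a[deg_a$padj < alpha]
  sig_b <- ids_b[deg_b$padj < alpha]
  common <- intersect(sig_a, sig_b)
  lfc_a <- stats::setNames(deg_a$log2fc, ids_a)[common]
  lfc_b <- stats::setNames(deg_b$log2fc, ids_b)[common]
  zero <- lfc_a == 0 | lfc_b == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with log2fc exactly 0 excluded")
    common <- common[!zero]; lfc_a <- lfc_a[!zero]; lfc_b <- lfc_b[!zero]
  }
  reversed_ids <- common[sign(lfc_a) == -sign(lfc_b)]
  x <- length(reversed_ids)

  u <- if (is.null(universe)) unique(ids_a) else unique(as_gene_ids(universe))
  if (!all(sig_b %in% u))
    stop_cfg("significant genes of deg_b missing from the universe")
  in_a <- u %in% sig_a
  set.seed(check_count(seed, "seed", 0L))
  null_x <- vapply(seq_len(n_perm), function(i) {
    hits <- sum(in_a[sample.int(length(u), length(sig_b))])
    # opposite sign by a fair coin for each co-significant null gene
    stats::rbinom(1L, hits, 0.5)
  }, integer(1L))
  mu <- mean(null_x); sigma <- stats::sd(null_x)
  if (sigma == 0) stop_cfg("degenerate reversal null (sd 0)")
  z <- (x - mu) / sigma
  p_emp <- (sum(abs(null_x - mu) >= abs(x - mu)) + 1) / (n_perm + 1)
  result <- structure(list(observed_overlap = x, null_mean = mu,
                           null_sd = sigma, z = z, p_two_sided = p_from_z(z),
                           p_empirical = p_emp, n_perm = n_perm, seed = seed,
                           universe_size = length(u),
                           query_size = length(sig_b),
                           target_size = length(sig_a),
                           query_name = "sig_b", target_name = "sig_a_reversed"),
                      class = "enrichment_result")
  list(reversed = gene_set("reversed", reversed_ids, warn_duplicates = FALSE),
       result = result)
}

#' Top-k genes by absolute component loading
#'
#' The k genes with the largest absolute weight on a principal component
#' (contribution regardless of sign); ties broken by gene-id lexicographic
#' order for reproducibility.
#'
#' @param loadings Named numeric vector of per-gene loadings for one
#'   component (names are gene ids).
#' @param k Number of genes, `1 <= k <=` number of genes.
#' @return A [gene_set()] of the top-k genes.
#' @export
top_loading_genes <- function(loadings, k) {
  if (is.null(names(loadings))) stop_cfg("'loadings' must be named by gene id")
  k <- check_count(k, "k", 1L)
  if (k > length(loadings)) stop_cfg("k exceeds the number of genes")
  ord <- order(-abs(loadings), names(loadings))
  gene_set(sprintf("top%d_loading", k), names(loadings)[ord[seq_len(k)]],
           warn_duplicates = FALSE)
}
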