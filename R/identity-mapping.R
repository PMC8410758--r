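#' Most highly expressed genes of an expression matrix
#'
#' Genes ranked by mean expression across samples (descending), ties broken
#' by gene-id lexicographic order; the first `n` are returned. The mean is
#' taken on the scale supplied (counts or log), which does not change the
#' ranking monotonically enough to matter for the intended use of selecting
#' a high-expression panel.
#'
#' @param expr Genes x samples numeric matrix with gene ids as rownames (or
#'   a data.frame whose first column is `gene_id`).
#' @param n Number of genes to return, `1 <= n <=` gene count.
#' @return A [gene_set()] with the top-`n` gene ids, in rank order.
#' @export
top_expressed_genes <- function(expr, n) {
  expr <- as_expr_matrix(expr)
  n <- check_count(n, "n", 1L)
  if (n > nrow(expr)) stop_cfg("n exceeds the number of genes")
  m <- rowMeans(expr)
  ord <- order(-m, rownames(expr))
  gene_set(sprintf("top%d_expressed", n), rownames(expr)[ord[seq_len(n)]],
           warn_duplicates = FALSE)
}

as_expr_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    ids <- as.character(expr[[1L]])
    expr <- as.matrix(expr[, -1L, drop = FALSE])
    rownames(expr) <- ids
  }
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop_cfg("expression matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(expr))) stop_cfg("duplicate gene ids in matrix")
  expr
}

#' Rank atlas profiles by Pearson correlation with a query profile
#'
#' Computes Pearson's r between the query and every labelled reference
#' profile over the supplied gene panel (typically the most highly
#' expressed genes), on the log2(x+1) scale when the inputs are counts.
#' Profiles are ranked by descending r; label-lexicographic order breaks
#' ties. A profile that is constant over the panel gets an undefined r and
#' is ranked last with a warning.
#'
#' Gene-id matching is silent when at least 90% of the requested panel is
#' found in both query and atlas, warns below that, and errors when fewer
#' than 10 shared genes remain.
#'
#' @param query Named numeric vector: the (mean) expression profile to map.
#' @param atlas Genes x profiles numeric matrix, columns labelled
#'   `"structure|age"`.
#' @param genes A [gene_set()] or character vector restricting the
#'   comparison; default all query genes.
#' @param is_counts Apply log2(x+1) before correlating (default `TRUE`;
#'   set `FALSE` for already-summarized values).
#' @return An object of class `correlation_ranking`: a data.frame with
#'   `profile_label`, `pearson_r`, `rank`, plus attribute `n_genes_used`.
#' @export
correlate_profiles <- function(query, atlas, genes = NULL, is_counts = TRUE) {
  if (is.null(names(query))) stop_cfg("'query' must be named by gene id")
  atlas <- as_expr_matrix(atlas)
  if (ncol(atlas) < 2L) stop_cfg("atlas needs at least 2 profiles")
  qids <- normalize_ids(names(query))
  aids <- normalize_ids(rownames(atlas))
  panel <- if (is.null(genes)) qids else as_gene_ids(genes)
  shared <- Reduce(intersect, list(panel, qids, aids))
  if (length(shared) < 10L)
    stop_cfg("only %d gene(s) shared between query, atlas and panel (need >= 10)",
             length(shared))
  if (length(shared) < 0.9 * length(panel))
    warning(sprintf("only %d/%d panel genes found in both query and atlas",
                    length(shared), length(panel)))
  qv <- as.numeric(query)[match(shared, qids)]
  av <- atlas[match(shared, aids), , drop = FALSE]
  if (is_counts) {
    qv <- log2(qv + 1)
    av <- log2(av + 1)
  }
  if (stats::sd(qv) == 0) stop_cfg("query profile is constant over the panel")
  sds <- apply(av, 2L, stats::sd)
  r <- rep(NA_real_, ncol(av))
  r[sds > 0] <- drop(stats::cor(qv, av[, sds > 0, drop = FALSE]))
  if (any(sds == 0))
    warning(sum(sds == 0), " constant profile(s) ranked last with undefined r")
  lab <- colnames(atlas)
  ord <- order(-r, lab, na.last = TRUE)
  out <- data.frame(profile_label = lab[ord], pearson_r = r[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "n_genes_used") <- length(shared)
  class(out) <- c("correlation_ranking", "data.frame")
  out
}

#' @export
print.correlation_ranking <- function(x, n_top = 10L, ...) {
  cat(sprintf("Identity mapping over %d genes; top %d of %d profiles:\n",
              attr(x, "n_genes_used"), min(n_top, nrow(x)), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), n_top), row.names = FALSE)
  invisible(x)
}
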