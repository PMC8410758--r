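# Shared fixtures built in code.

# discrete disk mask of radius r pixels
disk_mask <- function(r, pixel_size = c(1, 1)) {
  n <- 2L * r + 3L
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  image_mask2d((d2 <= r^2) * 1, pixel_size)
}

# small DEG table fixture
tiny_deg <- function(ids, lfc, padj, p = padj) {
  data.frame(gene_id = ids, log2fc = lfc, pvalue = p, padj = padj,
             stringsAsFactors = FALSE)
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_reject_bruteforce <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}

# a fast scaled-down expression simulation for unit tests
small_expr_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(n_genes = 2000L, n_de = 50L,
                                 n_disease_set = 80L, planted_overlap = 10L,
                                 seed = seed),
                            list(...))
  do.call(expr_sim_config, args)
}
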