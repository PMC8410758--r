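# Readers/writers. TSV (tab, UTF-8, header) is the canonical dialect; CSV is
# accepted on read. Gene ids are opaque strings.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a differential-expression table
#'
#' Accepts TSV or CSV with case-insensitive header aliases:
#' `gene_id`/`gene`, `log2fc`/`log2FoldChange`, `pvalue`/`p_value`/`pval`,
#' `padj`/`p_adj`/`fdr`. Duplicate gene rows are an error listing the
#' duplicated ids.
#'
#' @param path File path.
#' @return A data.frame with columns `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  lower <- tolower(names(df))
  alias <- list(gene_id = c("gene_id", "gene", "gene_name", "id"),
                log2fc = c("log2fc", "log2foldchange", "lfc"),
                pvalue = c("pvalue", "p_value", "pval", "p"),
                padj = c("padj", "p_adj", "fdr", "qvalue"))
  out <- list()
  for (std in names(alias)) {
    hit <- which(lower %in% alias[[std]])
    if (!length(hit)) {
      if (std == "padj") { out$padj <- NA_real_; next }
      stop_cfg("DEG table '%s' lacks a '%s' column", path, std)
    }
    out[[std]] <- df[[hit[1L]]]
  }
  out <- data.frame(out, stringsAsFactors = FALSE)
  out$gene_id <- as.character(out$gene_id)
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup))
    stop_cfg("duplicate gene rows in '%s': %s%s", path,
             paste(utils::head(dup, 5L), collapse = ", "),
             if (length(dup) > 5L) ", ..." else "")
  out
}

#' Write a differential-expression table as TSV
#' @param table DEG table data.frame.
#' @param path Output path.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set from a text file
#'
#' One identifier per line, or a two-column TSV whose second column holds
#' the identifiers (first column a set/category name). CRLF endings are
#' handled; duplicates are collapsed with a warning; an empty file is an
#' error.
#'
#' @param path File path.
#' @param name Set name; defaults to the file name.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_cfg("gene-set file '%s' is empty", path)
  ids <- if (any(grepl("\t", lines)))
    vapply(strsplit(lines, "\t"), function(f) f[[2L]], character(1L))
  else lines
  gene_set(name, ids)
}

#' Write a gene set, one identifier per line
#' @param set A [gene_set()].
#' @param path Output path.
#' @export
write_gene_set <- function(set, path) {
  writeLines(as_gene_ids(set), path)
  invisible(path)
}

#' Read/write the organoid morphometry table
#'
#' CSV with columns `line_id`, `genotype`, `organoid_id`, `week`,
#' `area_mm2`, `volume_mm3`.
#'
#' @param path File path.
#' @return A data.frame of organoid records.
#' @export
read_morphometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("line_id", "genotype", "organoid_id", "week", "area_mm2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_cfg("morphometry CSV lacks: %s", paste(miss, collapse = ", "))
  if (any(df$area_mm2 <= 0)) stop_cfg("non-positive areas in '%s'", path)
  df
}

#' @rdname read_morphometry
#' @param records Morphometry data.frame.
#' @export
write_morphometry <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a genes-by-samples expression matrix as TSV
#'
#' First column gene ids, header row of sample ids.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_expr_matrix(df)
}

#' @rdname read_expression
#' @param mat Genes x samples matrix with rownames.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference atlas TSV
#'
#' First column `gene_id`, remaining columns one per profile labelled
#' `"structure|age"`.
#'
#' @param path File path.
#' @return Genes x profiles matrix.
#' @export
read_atlas <- function(path) read_expression(path)

#' Read/write binary masks and stacks as TIFF
#'
#' Single-channel binary images; a 2-D mask is one page, a 3-D stack one
#' page per z-plane. Physical pixel/voxel sizes are not stored in the TIFF
#' and must be supplied on read - they are never assumed.
#'
#' @param path File path.
#' @param pixel_size `(dy, dx)` for masks.
#' @param voxel_size `(dz, dy, dx)` for stacks.
#' @return An [image_mask2d()] or [image_stack3d()].
#' @export
read_mask_tiff <- function(path, pixel_size) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  image_mask2d((m > 0.5) * 1, pixel_size)
}

#' @rdname read_mask_tiff
#' @export
read_stack_tiff <- function(path, voxel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    (m > 0.5) * 1
  })
  arr <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  image_stack3d(arr, voxel_size)
}

#' @rdname read_mask_tiff
#' @param mask An [image_mask2d()].
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "image_mask2d"))
  tiff::writeTIFF(mask$mask, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname read_mask_tiff
#' @param stack An [image_stack3d()].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack3d"))
  nz <- dim(stack$stack)[1L]
  pages <- lapply(seq_len(nz), function(z) {
    m <- stack$stack[z, , , drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, nrow = dim(stack$stack)[2L])
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

# journal-print style p formatting: 1-2 significant figures
format_p <- function(p, style = c("full_precision", "paper_rounded")) {
  style <- match.arg(style)
  if (style == "full_precision") return(p)
  signif(p, if (p < 0.001) 2L else 1L)
}
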