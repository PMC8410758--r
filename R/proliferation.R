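#' BrdU/Ki67 labeling index at section, organoid or line level
#'
#' The labeling index is the fraction of cycling (Ki67+) cells that
#' incorporated BrdU during the pulse, `n_double / n_ki67`. Counts are
#' pooled (summed) across sections within an organoid because sections have
#' unequal denominators; organoid-level indices are then averaged within a
#' line. Units with zero Ki67 counts are dropped with a warning.
#'
#' @param sections A data.frame of section counts with at least columns
#'   `line_id`, `organoid_id`, `n_double`, `n_ki67` (as produced by
#'   [gen_brdu_ki67()] or read from a section-count CSV).
#' @param level Aggregation level: `"section"`, `"organoid"` or `"line"`.
#' @return A data.frame with the grouping columns and `labeling_index`.
#' @export
labeling_index <- function(sections, level = c("organoid", "section", "line")) {
  level <- match.arg(level)
  req <- c("line_id", "organoid_id", "n_double", "n_ki67")
  miss <- setdiff(req, names(sections))
  if (length(miss)) stop_cfg("missing columns: %s", paste(miss, collapse = ", "))
  if (any(sections$n_double > sections$n_ki67))
    stop_cfg("n_double exceeds n_ki67 in some sections")

  if (level == "section") {
    keep <- sections$n_ki67 > 0
    if (!all(keep)) warning(sum(!keep), " section(s) with zero Ki67 dropped")
    out <- sections[keep, c("line_id", "organoid_id"), drop = FALSE]
    out$section_idx <- sections$section_idx[keep] %||% seq_len(sum(keep))
    out$labeling_index <- sections$n_double[keep] / sections$n_ki67[keep]
    rownames(out) <- NULL
    return(out)
  }

  # pool counts within organoid
  key <- interaction(sections$line_id, sections$organoid_id, drop = TRUE)
  dbl <- tapply(sections$n_double, key, sum)
  ki <- tapply(sections$n_ki67, key, sum)
  line <- tapply(sections$line_id, key, function(x) x[[1L]])
  org <- tapply(sections$organoid_id, key, function(x) x[[1L]])
  keep <- ki > 0
  if (!all(keep)) warning(sum(!keep), " organoid(s) with zero pooled Ki67 dropped")
  org_df <- data.frame(line_id = unname(unlist(line[keep])),
                       organoid_id = unname(unlist(org[keep])),
                       labeling_index = unname(dbl[keep] / ki[keep]),
                       stringsAsFactors = FALSE)
  org_df <- org_df[order(org_df$line_id, org_df$organoid_id), , drop = FALSE]
  rownames(org_df) <- NULL
  if (level == "organoid") return(org_df)

  li <- tapply(org_df$labeling_index, org_df$line_id, mean)
  data.frame(line_id = names(li), labeling_index = unname(li),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell-cycle length from a labeling index
#'
#' For a fixed S-phase length Ts, the total cell-cycle length is
#' Tc = Ts / (BrdU+/Ki67+ labeling index): the shorter the cycle, the larger
#' the fraction of cycling cells caught in S phase during the pulse.
#'
#' @param t_s S-phase length in hours.
#' @param li Labeling index, a fraction in (0, 1].
#' @return A list of class `cell_cycle_estimate` with `labeling_index`,
#'   `t_s` and `t_c` (hours).
#' @export
cell_cycle_length <- function(t_s, li) {
  t_s <- check_positive(t_s, "t_s")
  li <- check_fraction(li, "li", open_left = TRUE)
  structure(list(labeling_index = li, t_s = t_s, t_c = t_s / li),
            class = "cell_cycle_estimate")
}

#' @export
print.cell_cycle_estimate <- function(x, ...) {
  cat(sprintf("Cell-cycle estimate: LI = %.4g, Ts = %.3g h  =>  Tc = %.3g h\n",
              x$labeling_index, x$t_s, x$t_c))
  invisible(x)
}

#' Cell-cycle length of one group relative to another
#'
#' Given a reference cycle length and the fold change in labeling index
#' between groups, the other group's cycle length is
#' `t_c_reference / li_fold` - exact, because the (unknown) S-phase length
#' cancels in the ratio.
#'
#' @param t_c_reference Reference cell-cycle length (hours).
#' @param li_fold Fold change in labeling index (other / reference), > 0.
#' @return Cell-cycle length in hours.
#' @export
relative_cell_cycle <- function(t_c_reference, li_fold) {
  t_c <- check_positive(t_c_reference, "t_c_reference")
  fold <- check_positive(li_fold, "li_fold")
  t_c / fold
}

#' Total cells from a hemocytometer count
#'
#' Isotropic-fractionation arithmetic: nuclei counted in a known chamber
#' volume, scaled by the dilution factor and the total suspension volume.
#'
#' @param chamber_count Nuclei counted in the chamber.
#' @param chamber_volume Chamber volume (mL), > 0.
#' @param dilution_factor Dilution applied before counting.
#' @param suspension_volume Total suspension volume (mL).
#' @return Estimated total cell count.
#' @export
total_cells <- function(chamber_count, chamber_volume, dilution_factor = 1,
                        suspension_volume = 1) {
  n <- check_nonneg(chamber_count, "chamber_count")
  v <- check_positive(chamber_volume, "chamber_volume")
  d <- check_positive(dilution_factor, "dilution_factor")
  s <- check_positive(suspension_volume, "suspension_volume")
  n / v * d * s
}

#' Absolute marker-positive cell count
#'
#' Total cell count times a marker-positive fraction, rounded to the nearest
#' integer (ties to even, R's default rounding).
#'
#' @param total Total cell count.
#' @param fraction Marker-positive fraction in \[0, 1\].
#' @return Integer-valued count.
#' @export
absolute_marker_count <- function(total, fraction) {
  total <- check_nonneg(total, "total")
  fraction <- check_fraction(fraction, "fraction")
  round(total * fraction)
}
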