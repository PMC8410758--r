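#' Pipeline configuration
#'
#' Bundles the thresholds and simulation settings the pipeline stages use.
#' Defaults: DE significance `alpha = 0.05`, `n_perm = 10000` permutations,
#' `top_n_genes = 1000` for identity mapping, S-phase length
#' `t_s_hours = 4.5`. Unknown arguments are rejected.
#'
#' @param seed Master RNG seed; stage seeds are derived from it and recorded
#'   in the report.
#' @param out_dir Output directory for stage TSVs and the JSON report.
#' @param alpha DE significance threshold (strict `padj < alpha`).
#' @param n_perm Permutations for enrichment nulls.
#' @param top_n_genes Gene-panel size for identity mapping.
#' @param t_s_hours Assumed S-phase length (hours) for absolute Tc.
#' @param report_style `"full_precision"` or `"paper_rounded"` p-values in
#'   the report.
#' @param stages Character vector of stages to run, subset of
#'   `c("simulate", "morpho", "lmm", "cellcycle", "enrich", "reversal",
#'   "map")`, or `"all"`.
#' @param morpho A [morpho_sim_config()] (seed is overridden by `seed`).
#' @param expr An [expr_sim_config()] (seed is overridden by `seed`).
#' @param ... Unknown keys: rejected with an error.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("orgrowth_"),
                            alpha = 0.05, n_perm = 10000L,
                            top_n_genes = 1000L, t_s_hours = 4.5,
                            report_style = c("full_precision", "paper_rounded"),
                            stages = "all",
                            morpho = morpho_sim_config(),
                            expr = expr_sim_config(), ...) {
  extra <- list(...)
  if (length(extra))
    stop_cfg("unknown configuration key(s): %s",
             paste(names(extra), collapse = ", "))
  all_stages <- c("simulate", "morpho", "lmm", "cellcycle", "enrich",
                  "reversal", "map")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_cfg("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(seed = check_count(seed, "seed", 0L),
                 out_dir = out_dir,
                 alpha = check_fraction(alpha, "alpha", open_left = TRUE),
                 n_perm = check_count(n_perm, "n_perm", 100L),
                 top_n_genes = check_count(top_n_genes, "top_n_genes"),
                 t_s_hours = check_positive(t_s_hours, "t_s_hours"),
                 report_style = match.arg(report_style),
                 stages = stages, morpho = morpho, expr = expr),
            class = "pipeline_config")
}

#' Run the organoid-overgrowth analysis pipeline on synthetic data
#'
#' Sequences the stages: simulate inputs, morphometry summary and
#' area-to-volume calibration, genotype LRT on log-area, BrdU/Ki67
#' cell-cycle estimation, annotation-set permutation enrichment,
#' rescue direction-reversal, PC-loading enrichment and atlas identity
#' mapping. Every stochastic stage records its derived seed in the report,
#' per-stage tables are written as TSV/CSV under `cfg$out_dir`, and the
#' whole report is written as JSON. Re-running with the same config
#' reproduces the report exactly.
#'
#' @param cfg A [pipeline_config()].
#' @return The report, invisibly (a named list, one element per stage).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, alpha = cfg$alpha, n_perm = cfg$n_perm,
                 stages = list())
  fmt <- function(p) format_p(p, cfg$report_style)
  seeds <- cfg$seed + 0:3   # per-generator seeds, recorded below

  want <- function(s) s %in% cfg$stages
  sim <- NULL
  if (want("simulate") || length(setdiff(cfg$stages, "simulate"))) {
    morpho_cfg <- cfg$morpho; morpho_cfg$seed <- seeds[1L]
    expr_cfg <- cfg$expr; expr_cfg$seed <- seeds[3L]
    sim <- list(
      morpho = gen_morphometry(morpho_cfg),
      sections = gen_brdu_ki67(seed = seeds[2L]),
      expr = gen_expression(expr_cfg),
      atlas = gen_atlas(seed = seeds[4L]))
    if (want("simulate")) {
      write_morphometry(sim$morpho, file.path(cfg$out_dir, "morphometry.csv"))
      utils::write.csv(sim$sections, file.path(cfg$out_dir, "sections.csv"),
                       row.names = FALSE, quote = FALSE)
      write_deg_table(sim$expr$truth_patient,
                      file.path(cfg$out_dir, "deg_patient.tsv"))
      write_deg_table(sim$expr$truth_rescue,
                      file.path(cfg$out_dir, "deg_rescue.tsv"))
      write_gene_set(sim$expr$disease_set,
                     file.path(cfg$out_dir, "disease_set.txt"))
      report$stages$simulate <- list(
        status = "ok", seeds = as.list(stats::setNames(
          seeds, c("morpho", "sections", "expr", "atlas"))),
        n_organoid_records = nrow(sim$morpho),
        n_sections = nrow(sim$sections),
        n_genes = nrow(sim$expr$counts))
    } else report$stages$simulate <- list(status = "skipped")
  }

  final_week <- max(sim$morpho$week)
  wk <- sim$morpho[sim$morpho$week == final_week, , drop = FALSE]

  if (want("morpho")) {
    fold <- mean(wk$area_mm2[wk$genotype == "case"]) /
      mean(wk$area_mm2[wk$genotype == "control"])
    cal <- fit_linear(wk$area_mm2, wk$volume_mm3)
    report$stages$morpho <- list(
      status = "ok", final_week = final_week,
      area_fold_case_vs_control = fold,
      calibration = list(slope = cal$slope, intercept = cal$intercept,
                         r_squared = cal$r_squared, f_stat = cal$f_stat,
                         df1 = cal$df1, df2 = cal$df2,
                         p_value = fmt(cal$p_value)))
  } else report$stages$morpho <- list(status = "skipped")

  if (want("lmm")) {
    lrt <- lrt_genotype(wk, "log_area")
    res <- data.frame(chi2 = lrt$chi2, df = lrt$df, p = lrt$p_value,
                      beta_genotype = unname(lrt$fit_full$beta[2L]),
                      sigma_line = lrt$fit_full$sigma_line,
                      sigma_resid = lrt$fit_full$sigma_resid)
    utils::write.table(res, file.path(cfg$out_dir, "lmm_log_area.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$lmm <- list(
      status = "ok", response = "log_area", week = final_week,
      chi2 = lrt$chi2, df = lrt$df, p_value = fmt(lrt$p_value),
      genotype_log_fold = unname(lrt$fit_full$beta[2L]))
  } else report$stages$lmm <- list(status = "skipped")

  if (want("cellcycle")) {
    li_line <- labeling_index(sim$sections, level = "line")
    geno <- sub("_line\\d+$", "", li_line$line_id)
    li_geno <- tapply(li_line$labeling_index, geno, mean)
    tc <- lapply(li_geno, function(li) cell_cycle_length(cfg$t_s_hours, li)$t_c)
    utils::write.table(li_line, file.path(cfg$out_dir, "labeling_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$cellcycle <- list(
      status = "ok", t_s_hours = cfg$t_s_hours,
      labeling_index = as.list(li_geno), t_c_hours = tc,
      li_fold = unname(li_geno[["case"]] / li_geno[["control"]]))
  } else report$stages$cellcycle <- list(status = "skipped")

  universe <- rownames(sim$expr$counts)
  if (want("enrich")) {
    de <- significant_genes(sim$expr$truth_patient, alpha = cfg$alpha)
    enr <- permutation_enrichment(de, sim$expr$disease_set, universe,
                                  n_perm = cfg$n_perm, seed = seeds[3L])
    utils::write.table(as.data.frame(enr),
                       file.path(cfg$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$enrich <- list(
      status = "ok", seed = seeds[3L], n_de = length(de),
      observed_overlap = enr$observed_overlap, null_mean = enr$null_mean,
      null_sd = enr$null_sd, z = enr$z, p_two_sided = fmt(enr$p_two_sided),
      p_empirical = fmt(enr$p_empirical))
  } else report$stages$enrich <- list(status = "skipped")

  if (want("reversal")) {
    rev <- direction_reversal(sim$expr$truth_patient, sim$expr$truth_rescue,
                              alpha = cfg$alpha, n_perm = cfg$n_perm,
                              seed = seeds[3L])
    write_gene_set(rev$reversed, file.path(cfg$out_dir, "reversed_genes.txt"))
    report$stages$reversal <- list(
      status = "ok", seed = seeds[3L],
      n_reversed = length(rev$reversed), z = rev$result$z,
      p_two_sided = fmt(rev$result$p_two_sided))
  } else report$stages$reversal <- list(status = "skipped")

  if (want("map")) {
    # PC-loading enrichment on the simulated counts
    pc <- stats::prcomp(t(log2(sim$expr$counts + 1)), center = TRUE,
                        scale. = FALSE)
    top100 <- top_loading_genes(pc$rotation[, 1L], 100L)
    de_set <- gene_set("planted_de", sim$expr$de_genes, warn_duplicates = FALSE)
    pc_enr <- permutation_enrichment(top100, de_set, universe,
                                     n_perm = cfg$n_perm, seed = seeds[4L])
    # atlas identity mapping on the simulated atlas/query pair
    rk <- correlate_profiles(sim$atlas$query, sim$atlas$atlas,
                             genes = names(sim$atlas$query))
    utils::write.table(as.data.frame(rk),
                       file.path(cfg$out_dir, "identity_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$map <- list(
      status = "ok", seed = seeds[4L],
      pc1_top100_de_overlap = pc_enr$observed_overlap, pc1_z = pc_enr$z,
      pc1_variance_fraction = unname(pc$sdev[1L]^2 / sum(pc$sdev^2)),
      top_profile = rk$profile_label[1L], top_r = rk$pearson_r[1L])
  } else report$stages$map <- list(status = "skipped")

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
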