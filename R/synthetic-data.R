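#' Configuration for the organoid morphometry simulator
#'
#' Describes a longitudinal organoid growth experiment: several iPSC lines per
#' genotype, several organoids per line, measured at a set of timepoints.
#' Growth is modelled on the log scale, so line and residual effects are
#' multiplicative on area and the genotype effect is a fold change that ramps
#' linearly (on the log scale) from 0 at the first timepoint to
#' `log(genotype_fold)` at the last.
#'
#' @param n_lines_per_genotype Number of cell lines per genotype.
#' @param n_organoids_per_line Number of organoids per line.
#' @param weeks Strictly increasing vector of measurement timepoints (weeks).
#' @param baseline_area Mean projected area (mm^2) of a control organoid at
#'   the first timepoint.
#' @param genotype_fold Fold effect of the case genotype on area at the final
#'   week; 1 means no effect.
#' @param line_sd SD of the per-line random intercept on the log-area scale.
#' @param residual_sd SD of per-organoid-per-week residual noise (log scale).
#' @param volume_slope Volume per unit area (mm^3/mm^2) used to derive a
#'   noisy volume measurement from area.
#' @param week_log_growth Baseline growth rate: increase in log-area per week
#'   shared by all genotypes.
#' @param volume_noise_sd SD of additive noise on volume (mm^3).
#' @param seed Integer RNG seed.
#' @return An object of class `morpho_sim_config`.
#' @export
morpho_sim_config <- function(n_lines_per_genotype = 3L,
                              n_organoids_per_line = 7L,
                              weeks = c(4, 9, 13),
                              baseline_area = 1.0,
                              genotype_fold = 1.5,
                              line_sd = 0.10,
                              residual_sd = 0.15,
                              volume_slope = 1.5,
                              week_log_growth = 0.2,
                              volume_noise_sd = 0.05,
                              seed = 1L) {
  cfg <- list(
    n_lines_per_genotype = check_count(n_lines_per_genotype, "n_lines_per_genotype"),
    n_organoids_per_line = check_count(n_organoids_per_line, "n_organoids_per_line"),
    weeks = as.numeric(weeks),
    baseline_area = check_positive(baseline_area, "baseline_area"),
    genotype_fold = check_positive(genotype_fold, "genotype_fold"),
    line_sd = check_nonneg(line_sd, "line_sd"),
    residual_sd = check_nonneg(residual_sd, "residual_sd"),
    volume_slope = check_positive(volume_slope, "volume_slope"),
    week_log_growth = as.numeric(week_log_growth),
    volume_noise_sd = check_nonneg(volume_noise_sd, "volume_noise_sd"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$weeks) < 1L || any(diff(cfg$weeks) <= 0))
    stop_cfg("'weeks' must be strictly increasing")
  structure(cfg, class = "morpho_sim_config")
}

#' Simulate a longitudinal organoid morphometry table
#'
#' One row per organoid per week, with columns `line_id`, `genotype`
#' (`control`/`case`), `organoid_id`, `week`, `area_mm2`, `volume_mm3`.
#' log(area) = log(baseline) + growth trend + genotype ramp + line random
#' intercept + residual noise; volume = `volume_slope` * area + noise.
#' Deterministic under a fixed seed.
#'
#' @param cfg A [morpho_sim_config()].
#' @return A data.frame of organoid records.
#' @export
gen_morphometry <- function(cfg) {
  stopifnot(inherits(cfg, "morpho_sim_config"))
  set.seed(cfg$seed)
  genotypes <- c("control", "case")
  wk <- cfg$weeks
  final_w <- wk[length(wk)]
  first_w <- wk[1L]
  ramp <- if (final_w > first_w) (wk - first_w) / (final_w - first_w) else rep(1, length(wk))

  rows <- list()
  for (g in genotypes) {
    for (l in seq_len(cfg$n_lines_per_genotype)) {
      line_id <- sprintf("%s%d", if (g == "case") "P" else "C", l)
      u_line <- rnorm(1L, 0, cfg$line_sd)
      for (o in seq_len(cfg$n_organoids_per_line)) {
        eff <- if (g == "case") log(cfg$genotype_fold) * ramp else rep(0, length(wk))
        log_area <- log(cfg$baseline_area) + cfg$week_log_growth * (wk - first_w) +
          eff + u_line + rnorm(length(wk), 0, cfg$residual_sd)
        area <- exp(log_area)
        vol <- cfg$volume_slope * area + rnorm(length(wk), 0, cfg$volume_noise_sd)
        vol <- pmax(vol, 1e-6)
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = line_id, genotype = g,
          organoid_id = sprintf("%s_org%d", line_id, o),
          week = wk, area_mm2 = area, volume_mm3 = vol,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a binary 3-D blob and its exact volume
#'
#' Generates a filled (optionally anisotropic, optionally boundary-jittered)
#' ellipsoidal blob as a binary z/y/x voxel stack, together with its exact
#' volume in physical units (foreground voxel count times voxel volume).
#'
#' @param radius_voxels Sphere radius in voxels (before anisotropy), >= 2.
#' @param anisotropy Per-axis (z, y, x) scale factors on the radius.
#' @param voxel_size Physical voxel edge lengths (dz, dy, dx), e.g. mm.
#' @param jitter Width of the boundary shell (as a fraction of the radius) in
#'   which voxel membership is randomised; 0 gives a clean ellipsoid.
#' @param dim Optional stack dimensions (z, y, x); defaults to a box that
#'   just contains the blob. An ellipsoid exceeding `dim` is an error.
#' @param seed Integer RNG seed (used only when `jitter > 0`).
#' @return A list with `stack` (an [image_stack3d()]) and `true_volume`.
#' @export
gen_image_pair <- function(radius_voxels, anisotropy = c(1, 1, 1),
                           voxel_size = c(1, 1, 1), jitter = 0,
                           dim = NULL, seed = 1L) {
  r <- check_positive(radius_voxels, "radius_voxels")
  if (r < 2) stop_cfg("'radius_voxels' must be >= 2 voxels")
  stopifnot(length(anisotropy) == 3L, all(anisotropy > 0),
            length(voxel_size) == 3L, all(voxel_size > 0))
  jitter <- check_fraction(jitter, "jitter")
  semi <- r * anisotropy                      # semi-axes in voxels (z, y, x)
  need <- as.integer(2 * ceiling(semi) + 3L)
  if (is.null(dim)) dim <- need
  dim <- as.integer(dim)
  if (any(need > dim))
    stop_cfg("blob of semi-axes (%s) exceeds stack bounds (%s)",
             paste(round(semi, 1), collapse = ","), paste(dim, collapse = ","))
  ctr <- (dim + 1) / 2
  z <- (seq_len(dim[1L]) - ctr[1L]) / semi[1L]
  y <- (seq_len(dim[2L]) - ctr[2L]) / semi[2L]
  x <- (seq_len(dim[3L]) - ctr[3L]) / semi[3L]
  d2 <- outer(outer(z^2, y^2, `+`), x^2, `+`)  # normalised squared radius
  inside <- d2 <= 1
  if (jitter > 0) {
    set.seed(seed)
    shell <- abs(sqrt(d2) - 1) <= jitter
    inside[shell] <- runif(sum(shell)) < 0.5
  }
  arr <- array(as.integer(inside), dim = dim)
  stack <- image_stack3d(arr, voxel_size)
  list(stack = stack, true_volume = sum(arr) * prod(voxel_size))
}

#' Simulate per-section BrdU/Ki67 co-labeling counts
#'
#' Per histology section, the double-positive count is
#' Binomial(`n_ki67_per_section`, labeling index of that genotype). Total
#' nuclei, PAX6+ and BrdU-only counts are included so the table matches a
#' real section-count export.
#'
#' @param n_lines Lines per genotype.
#' @param n_orgs Organoids per line.
#' @param n_sections Sections per organoid.
#' @param n_ki67_per_section Ki67+ cells scored per section.
#' @param true_labeling_index Named vector of labeling indices (fractions in
#'   (0, 1]) per genotype, e.g. `c(control = 0.054, case = 0.083)`.
#' @param ki67_fraction Fraction of nuclei that are Ki67+ (sets `n_nuclei`).
#' @param pax6_fraction Fraction of nuclei that are PAX6+.
#' @param seed Integer RNG seed.
#' @return A data.frame of section counts (one row per section).
#' @export
gen_brdu_ki67 <- function(n_lines = 3L, n_orgs = 3L, n_sections = 3L,
                          n_ki67_per_section = 300L,
                          true_labeling_index = c(control = 4.5 / 83, case = 4.5 / 54),
                          ki67_fraction = 0.3, pax6_fraction = 0.5,
                          seed = 1L) {
  n_lines <- check_count(n_lines, "n_lines")
  n_orgs <- check_count(n_orgs, "n_orgs")
  n_sections <- check_count(n_sections, "n_sections")
  n_ki67 <- check_count(n_ki67_per_section, "n_ki67_per_section")
  if (is.null(names(true_labeling_index)) || any(names(true_labeling_index) == ""))
    stop_cfg("'true_labeling_index' must be a named vector (one entry per genotype)")
  for (li in true_labeling_index)
    if (!is.numeric(li) || is.na(li) || li <= 0 || li > 1)
      stop_cfg("labeling indices must lie in (0, 1]")
  set.seed(check_count(seed, "seed", 0L))

  rows <- list()
  for (g in names(true_labeling_index)) {
    li <- true_labeling_index[[g]]
    for (l in seq_len(n_lines)) {
      line_id <- sprintf("%s_line%d", g, l)
      for (o in seq_len(n_orgs)) {
        n_double <- rbinom(n_sections, n_ki67, li)
        n_nuclei <- round(n_ki67 / ki67_fraction)
        # BrdU+ cells outside the Ki67+ pool (cells that exited the cycle
        # after S-phase) keep n_double <= min(n_brdu, n_ki67)
        n_brdu <- n_double + rbinom(n_sections, n_nuclei - n_ki67, 0.01)
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = line_id, genotype = g,
          organoid_id = sprintf("%s_org%d", line_id, o),
          section_idx = seq_len(n_sections),
          n_brdu = n_brdu, n_ki67 = n_ki67, n_double = n_double,
          n_pax6 = rbinom(n_sections, n_nuclei, pax6_fraction),
          n_nuclei = n_nuclei, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for the RNA-seq count simulator
#'
#' Negative-binomial counts for three groups (control, patient, rescue) with
#' a planted differentially expressed (DE) gene set, a planted disease
#' annotation set overlapping it by an exact count, a rescue condition that
#' reverses the sign of a random subset of DE genes, and a batch effect
#' (rescue samples form a second sequencing batch) carried by a gene subset
#' disjoint from the planted DE genes.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Samples per group.
#' @param nb_mean_log_mean,nb_mean_log_sd Mean and SD (natural-log scale) of
#'   the log-normal distribution of gene baseline mean counts.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_de Number of planted DE genes (patient vs control).
#' @param de_log2fc_sd SD of planted log2 fold changes.
#' @param n_disease_set Size of the planted disease annotation set.
#' @param planted_overlap Exact number of DE genes inside the disease set.
#' @param rescue_reversal_fraction Probability that a planted DE gene has its
#'   sign reversed in the rescue condition.
#' @param batch_shift_sd SD of the per-gene log-scale batch shift applied to
#'   the batch gene subset in rescue samples.
#' @param batch_gene_fraction Fraction of genes carrying the batch shift.
#' @param seed Integer RNG seed.
#' @return An object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 20000L,
                            n_samples_per_group = 3L,
                            nb_mean_log_mean = 4,
                            nb_mean_log_sd = 1.5,
                            nb_dispersion = 0.1,
                            n_de = 339L,
                            de_log2fc_sd = 1,
                            n_disease_set = 980L,
                            planted_overlap = 19L,
                            rescue_reversal_fraction = 67 / 339,
                            batch_shift_sd = 1,
                            batch_gene_fraction = 0.05,
                            seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_samples_per_group = check_count(n_samples_per_group, "n_samples_per_group", 2L),
    nb_mean_log_mean = as.numeric(nb_mean_log_mean),
    nb_mean_log_sd = check_nonneg(nb_mean_log_sd, "nb_mean_log_sd"),
    nb_dispersion = check_positive(nb_dispersion, "nb_dispersion"),
    n_de = check_count(n_de, "n_de", 0L),
    de_log2fc_sd = check_positive(de_log2fc_sd, "de_log2fc_sd"),
    n_disease_set = check_count(n_disease_set, "n_disease_set", 0L),
    planted_overlap = check_count(planted_overlap, "planted_overlap", 0L),
    rescue_reversal_fraction = check_fraction(rescue_reversal_fraction,
                                              "rescue_reversal_fraction"),
    batch_shift_sd = check_nonneg(batch_shift_sd, "batch_shift_sd"),
    batch_gene_fraction = check_fraction(batch_gene_fraction, "batch_gene_fraction"),
    seed = check_count(seed, "seed", 0L)
  )
  if (cfg$planted_overlap > min(cfg$n_de, cfg$n_disease_set))
    stop_cfg("planted_overlap (%d) exceeds min(n_de, n_disease_set)", cfg$planted_overlap)
  if (cfg$n_de + cfg$n_disease_set - cfg$planted_overlap > cfg$n_genes)
    stop_cfg("DE set and disease set cannot both fit in %d genes", cfg$n_genes)
  structure(cfg, class = "expr_sim_config")
}

#' Simulate an RNA-seq count matrix with planted DE and annotation structure
#'
#' Returns the count matrix, two truth differential-expression tables in
#' `DEGTable` form (patient vs control; rescue vs patient, with signs flipped
#' for the reversed subset), the planted gene sets and the disease
#' annotation set. Planted genes carry near-zero p-values and null genes
#' uniform ones, then Benjamini-Hochberg adjustment, so threshold-based
#' downstream operations behave as on a real DE run.
#'
#' @param cfg An [expr_sim_config()].
#' @return A list with elements `counts` (genes x samples matrix),
#'   `samples` (data.frame with `sample_id`, `group`, `batch`),
#'   `truth_patient`, `truth_rescue` (DEG tables), `de_genes`,
#'   `reversed_genes`, `batch_genes` (character vectors) and `disease_set`
#'   (a [gene_set()]).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  base_mu <- exp(rnorm(cfg$n_genes, cfg$nb_mean_log_mean, cfg$nb_mean_log_sd))

  de_genes <- sort(sample(genes, cfg$n_de))
  lfc <- stats::setNames(numeric(cfg$n_genes), genes)
  lfc[de_genes] <- rnorm(cfg$n_de, 0, cfg$de_log2fc_sd)

  # rescue reverses a Bernoulli subset of the planted DE genes; the rest stay
  # at the patient level (rescue-vs-patient log2FC 0)
  reversed <- de_genes[runif(cfg$n_de) < cfg$rescue_reversal_fraction]
  lfc_rescue <- stats::setNames(numeric(cfg$n_genes), genes)
  lfc_rescue[reversed] <- -lfc[reversed]

  # disease annotation set: exact planted overlap with the DE set
  non_de <- setdiff(genes, de_genes)
  disease_ids <- c(sample(de_genes, cfg$planted_overlap),
                   sample(non_de, cfg$n_disease_set - cfg$planted_overlap))

  # batch genes disjoint from planted DE genes
  n_batch <- round(cfg$batch_gene_fraction * cfg$n_genes)
  batch_genes <- sort(sample(non_de, min(n_batch, length(non_de))))
  batch_shift <- stats::setNames(numeric(cfg$n_genes), genes)
  batch_shift[batch_genes] <- rnorm(length(batch_genes), 0, cfg$batch_shift_sd)

  ns <- cfg$n_samples_per_group
  groups <- rep(c("control", "patient", "rescue"), each = ns)
  sample_ids <- paste0(groups, "_", rep(seq_len(ns), times = 3))
  batch <- ifelse(groups == "rescue", 2L, 1L)

  log2mu <- log2(base_mu) +
    outer(lfc, as.numeric(groups %in% c("patient", "rescue"))) +
    outer(lfc_rescue, as.numeric(groups == "rescue")) +
    outer(batch_shift / log(2), as.numeric(batch == 2L))
  mu <- 2^log2mu
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, sample_ids))

  mk_truth <- function(effect) {
    is_de <- effect != 0
    p <- ifelse(is_de, runif(cfg$n_genes) * 1e-8, runif(cfg$n_genes))
    data.frame(gene_id = genes, log2fc = unname(effect),
               pvalue = p, padj = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  }

  list(counts = counts,
       samples = data.frame(sample_id = sample_ids, group = groups,
                            batch = batch, stringsAsFactors = FALSE),
       truth_patient = mk_truth(lfc),
       truth_rescue = mk_truth(lfc_rescue),
       de_genes = de_genes,
       reversed_genes = reversed,
       batch_genes = batch_genes,
       disease_set = gene_set("disease_set", disease_ids))
}

#' Simulate a labelled reference atlas and a matching query profile
#'
#' Generates `n_structures * n_ages` reference expression profiles labelled
#' `"structure|age"` on a shared gene namespace, plus a query profile equal
#' to the target profile plus Gaussian noise. With small noise the target is
#' guaranteed to rank first under Pearson correlation.
#'
#' @param n_structures,n_ages Numbers of structures and ages.
#' @param n_genes Number of genes.
#' @param target_label Label of the profile the query is derived from; must
#'   be among the generated labels (`"S01|age1"` ... ).
#' @param noise_sd SD of the log-scale noise added to the query.
#' @param seed Integer RNG seed.
#' @return A list with `atlas` (genes x profiles matrix with labelled
#'   columns) and `query` (named numeric vector).
#' @export
gen_atlas <- function(n_structures = 10L, n_ages = 4L, n_genes = 500L,
                      target_label = "S01|age1", noise_sd = 0.1, seed = 1L) {
  n_structures <- check_count(n_structures, "n_structures")
  n_ages <- check_count(n_ages, "n_ages")
  n_genes <- check_count(n_genes, "n_genes", 3L)
  noise_sd <- check_nonneg(noise_sd, "noise_sd")
  labels <- as.vector(outer(sprintf("S%02d", seq_len(n_structures)),
                            paste0("age", seq_len(n_ages)),
                            function(s, a) paste(s, a, sep = "|")))
  if (!target_label %in% labels)
    stop_cfg("target_label '%s' is not among the generated labels", target_label)
  set.seed(check_count(seed, "seed", 0L))
  genes <- sprintf("G%05d", seq_len(n_genes))
  base <- rnorm(n_genes, 5, 2)                 # shared log-expression baseline
  atlas <- vapply(labels, function(lbl) exp(base + rnorm(n_genes, 0, 1)),
                  numeric(n_genes))
  rownames(atlas) <- genes
  query <- exp(log(atlas[, target_label]) + rnorm(n_genes, 0, noise_sd))
  names(query) <- genes
  list(atlas = atlas, query = query)
}
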