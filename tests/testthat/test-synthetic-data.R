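test_that("morphometry generator is deterministic and honours a null effect", {
  cfg0 <- morpho_sim_config(genotype_fold = 1.0, line_sd = 0, residual_sd = 0,
                            volume_noise_sd = 0, seed = 3)
  d <- gen_morphometry(cfg0)
  for (w in cfg0$weeks) {
    a_case <- sort(d$area_mm2[d$genotype == "case" & d$week == w])
    a_ctrl <- sort(d$area_mm2[d$genotype == "control" & d$week == w])
    expect_equal(a_case, a_ctrl)
  }
  cfg <- morpho_sim_config(seed = 42)
  expect_identical(gen_morphometry(cfg), gen_morphometry(cfg))
  expect_false(identical(gen_morphometry(cfg),
                         gen_morphometry(morpho_sim_config(seed = 43))))
})

test_that("planted genotype fold on area is recovered at the final week", {
  ratios <- vapply(1:40, function(s) {
    d <- gen_morphometry(morpho_sim_config(genotype_fold = 1.5,
                                           residual_sd = 0.05, seed = s))
    wk <- d[d$week == 13, ]
    mean(wk$area_mm2[wk$genotype == "case"]) /
      mean(wk$area_mm2[wk$genotype == "control"])
  }, numeric(1))
  expect_true(all(ratios > 1))
  expect_gt(mean(ratios), 1.3)
  expect_lt(mean(ratios), 1.7)
})

test_that("morphometry config invariants are enforced", {
  expect_error(morpho_sim_config(n_organoids_per_line = 0), "integer")
  expect_error(morpho_sim_config(genotype_fold = -1), "positive")
  expect_error(morpho_sim_config(weeks = c(9, 4)), "increasing")
  expect_error(morpho_sim_config(line_sd = -0.1), "non-negative")
})

test_that("image-pair generator returns exact voxel volumes", {
  p <- gen_image_pair(radius_voxels = 10)
  expect_equal(p$true_volume, sum(p$stack$stack))
  expect_warning(regexp = NA, v <- stack_volume(p$stack))
  expect_equal(v, p$true_volume)

  iso <- gen_image_pair(radius_voxels = 8)
  ani <- gen_image_pair(radius_voxels = 8, anisotropy = c(2, 1, 1))
  # stretching z by 2 doubles the voxel count up to a boundary layer
  expect_lt(abs(ani$true_volume / iso$true_volume - 2), 0.1)

  expect_error(gen_image_pair(radius_voxels = 10, dim = c(5, 50, 50)),
               "bounds")
  expect_error(gen_image_pair(radius_voxels = 1), ">= 2")
})

test_that("jittered blobs stay consistent with their reported volume", {
  p <- gen_image_pair(radius_voxels = 6, jitter = 0.2, seed = 9)
  expect_equal(stack_volume(p$stack), p$true_volume)
  expect_identical(gen_image_pair(radius_voxels = 6, jitter = 0.2, seed = 9)$stack,
                   p$stack)
})

test_that("BrdU/Ki67 section counts follow the planted labeling index", {
  full <- gen_brdu_ki67(true_labeling_index = c(case = 1.0), seed = 1)
  expect_true(all(full$n_double == full$n_ki67))
  expect_true(all(full$n_double <= pmin(full$n_brdu, full$n_ki67)))

  s <- gen_brdu_ki67(n_lines = 1, n_orgs = 1, n_sections = 100,
                     n_ki67_per_section = 1000,
                     true_labeling_index = c(case = 0.1), seed = 2)
  pooled <- sum(s$n_double) / sum(s$n_ki67)
  expect_gt(pooled, 0.08)
  expect_lt(pooled, 0.12)

  expect_false(identical(gen_brdu_ki67(seed = 1), gen_brdu_ki67(seed = 2)))
  expect_error(gen_brdu_ki67(true_labeling_index = c(case = 1.2)), "\\(0, 1\\]")
  expect_error(gen_brdu_ki67(true_labeling_index = c(case = 0)), "\\(0, 1\\]")
})

test_that("expression generator plants DE, overlap and reversal structure", {
  sim <- gen_expression(small_expr_cfg(seed = 5))
  expect_equal(overlap_count(sim$de_genes, sim$disease_set), 10)
  expect_length(sim$de_genes, 50)
  expect_equal(length(sim$disease_set), 80)
  # batch genes disjoint from planted DE genes
  expect_length(intersect(sim$batch_genes, sim$de_genes), 0)
  # truth tables: planted genes significant, signs consistent
  sig <- significant_genes(sim$truth_patient)
  expect_true(all(sim$de_genes %in% sig$ids))

  none <- gen_expression(small_expr_cfg(seed = 5, n_de = 0, planted_overlap = 0))
  expect_true(all(none$truth_patient$log2fc == 0))

  allrev <- gen_expression(small_expr_cfg(seed = 5, rescue_reversal_fraction = 1))
  lfc_p <- setNames(allrev$truth_patient$log2fc, allrev$truth_patient$gene_id)
  lfc_r <- setNames(allrev$truth_rescue$log2fc, allrev$truth_rescue$gene_id)
  expect_true(all(sign(lfc_r[allrev$de_genes]) == -sign(lfc_p[allrev$de_genes])))

  expect_error(expr_sim_config(n_de = 5, n_disease_set = 5, planted_overlap = 6),
               "planted_overlap")
  expect_identical(gen_expression(small_expr_cfg(seed = 7))$counts,
                   gen_expression(small_expr_cfg(seed = 7))$counts)
})

test_that("atlas generator guarantees the target profile under small noise", {
  a0 <- gen_atlas(noise_sd = 0, seed = 2)
  rk <- correlate_profiles(a0$query, a0$atlas)
  expect_equal(rk$profile_label[1], "S01|age1")
  expect_equal(rk$pearson_r[1], 1.0)
  expect_identical(gen_atlas(seed = 3), gen_atlas(seed = 3))
  expect_error(gen_atlas(target_label = "nope"), "target_label")
})

test_that("under overwhelming noise the target rank-1 frequency drops to chance", {
  hits <- vapply(1:200, function(s) {
    a <- gen_atlas(noise_sd = 100, seed = s)
    correlate_profiles(a$query, a$atlas)$profile_label[1] == "S01|age1"
  }, logical(1))
  # chance level 1/40 = 0.025; allow generous Monte-Carlo slack
  expect_lt(mean(hits), 0.10)
})
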