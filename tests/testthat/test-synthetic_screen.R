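test_that("identical config and seed give bit-identical screens", {
  cfg <- screen_config(replicates = 2L)
  ts <- truth_spec(n_genes = 40L, n_inhibitors = 4L, n_decoy_genes = 2L)
  a <- simulate_screen(cfg, ts, seed = 5L)
  b <- simulate_screen(cfg, ts, seed = 5L)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth$sirnas, b$truth$sirnas)
  c <- simulate_screen(cfg, ts, seed = 6L)
  expect_false(identical(a$wells$readout_activity,
                         c$wells$readout_activity))
})

test_that("the null screen is exactly flat: all sample NPIs are 0", {
  cfg <- screen_config(replicates = 2L)
  ts <- truth_spec(n_genes = 30L, n_inhibitors = 0L, n_decoy_genes = 0L,
                   toxic_rate = 0, off_target_rate = 0, noise_cv = 0,
                   transfection_cv = 0, plate_effect_sdlog = 0)
  sim <- simulate_screen(cfg, ts, seed = 1L)
  # every sample well equals the negative-control expectation
  smp <- sim$wells[sim$wells$role == "sample", ]
  neg <- sim$wells[sim$wells$role == "neg_ctrl", ]
  expect_equal(unique(smp$readout_activity), unique(neg$readout_activity))
  norm <- normalize_wells(sim$wells, cfg)
  npis <- norm$wells$npi[norm$wells$role == "sample"]
  expect_true(all(abs(npis) < 1e-12))
})

test_that("fully toxic libraries fail the 40% viability filter", {
  cfg <- screen_config(replicates = 1L)
  ts <- truth_spec(n_genes = 20L, n_inhibitors = 0L, n_decoy_genes = 0L,
                   toxic_rate = 1, tox_loss_range = c(0.7, 0.95),
                   off_target_rate = 0, noise_cv = 0, transfection_cv = 0,
                   plate_effect_sdlog = 0)
  sim <- simulate_screen(cfg, ts, seed = 2L)
  norm <- normalize_wells(sim$wells, cfg)
  smp <- norm$wells$role == "sample"
  expect_true(all(norm$wells$exclusion_reason[smp] == "low_viability"))
})

test_that("with zero noise RSA recovers the planted effect order exactly", {
  cfg <- screen_config(replicates = 2L)
  n <- 30L
  effects <- seq(0.2, 0.9, length.out = n)
  ts <- truth_spec(n_genes = n, n_inhibitors = n,
                   inhibitor_effects = effects,
                   sirna_efficacy_range = c(0.999, 1),
                   toxic_rate = 0, off_target_rate = 0, n_decoy_genes = 0,
                   noise_cv = 0, transfection_cv = 0, plate_effect_sdlog = 0)
  sim <- simulate_screen(cfg, ts, seed = 4L)
  scores <- orient_and_combine(normalize_wells(sim$wells, cfg), cfg)
  rsa <- rsa_rank(scores)
  truth_order <- sim$truth$genes$gene_id[order(-sim$truth$genes$true_effect)]
  # full ordering (flagged genes included) follows the planted effect sizes
  expect_equal(rank_genes(rsa$gene_scores)$gene_id, truth_order)
  # the kept hit list is the same order with flagged genes dropped
  expect_equal(rsa$ranked_genes$gene_id,
               truth_order[truth_order %in% rsa$ranked_genes$gene_id])
})

test_that("plate artifacts trip the matching QC rules and nothing else", {
  cfg <- screen_config(replicates = 1L)
  ts <- truth_spec(n_genes = 120L, n_inhibitors = 0L, n_decoy_genes = 0L,
                   toxic_rate = 0, off_target_rate = 0)
  sim <- simulate_screen(cfg, ts, seed = 3L)
  plates <- unique(sim$wells$plate_id)
  expect_gte(length(plates), 2L)
  expect_identical(inject_plate_artifacts(sim$wells,
                                          data.frame(plate_id = character(0),
                                                     kind = character(0))),
                   sim$wells)
  art <- data.frame(plate_id = plates[1:2],
                    kind = c("transfection_failure", "control_drift"),
                    param = c(0.05, 0.9))
  mod <- inject_plate_artifacts(sim$wells, art, seed = 7L)
  untouched <- !sim$wells$plate_id %in% plates[1:2]
  expect_identical(mod[untouched, ], sim$wells[untouched, ])
  qc <- plate_qc_all(mod, cfg)
  expect_match(qc$reasons[qc$plate_id == plates[1]], "mean_too_low")
  expect_match(qc$reasons[qc$plate_id == plates[2]], "cv_too_high")
  expect_true(all(qc$passed[!qc$plate_id %in% plates[1:2]]))

  expect_error(inject_plate_artifacts(sim$wells,
                                      data.frame(plate_id = "nope",
                                                 kind = "control_drift")),
               "unknown plate")
})

test_that("recovery metrics match a hand-built confusion", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      inhibitor = c(rep(TRUE, 3), rep(FALSE, 7)),
                      true_effect = c(0.9, 0.8, 0.7, rep(0, 7)),
                      shared_pathway = FALSE, decoy = FALSE)
  sirnas <- data.frame(sirna_id = paste0(genes$gene_id, "_s1"),
                       gene_id = genes$gene_id, efficacy = 1,
                       toxic = c(rep(FALSE, 2), TRUE, rep(FALSE, 7)),
                       tox_loss = 0,
                       off_target_effect = c(rep(0, 5), 0.5, rep(0, 4)))
  truth <- structure(list(genes = genes, sirnas = sirnas), class = "sim_truth")

  perfect <- evaluate_recovery(genes$gene_id, truth, top_n = 3)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdp, 0)
  expect_equal(perfect$rank_recovery, 1)

  none <- evaluate_recovery(rev(genes$gene_id), truth, top_n = 3,
                            hits = character(0))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$rank_recovery, 0)
  expect_equal(unname(none$fn_by_cause["toxic"]), 1L)  # g03 has a toxic siRNA

  mixed <- evaluate_recovery(genes$gene_id, truth, top_n = 3,
                             hits = c("g01", "g06"))
  expect_equal(mixed$sensitivity, 1 / 3)
  expect_equal(mixed$fdp, 1 / 2)
  expect_equal(unname(mixed$fp_by_cause["off_target"]), 1L)
})

test_that("decoy single-siRNA genes never reach the top of the ranked list", {
  study <- run_screen_study(desk_preset(), seed = 1L)
  decoys <- study$truth$genes$gene_id[study$truth$genes$decoy]
  top <- utils::head(study$rsa$ranked_genes$gene_id, 25)
  expect_length(intersect(decoys, top), 0)
  # and every removed gene was removed for exactly the <2-OPI-hit reason
  gs <- study$rsa$gene_scores
  expect_equal(gs$excluded_low_support, gs$opi_hit_count < 2L)
})

test_that("truth tables serialize to a flat audit TSV", {
  truth <- make_truth(truth_spec(n_genes = 10L, n_inhibitors = 2L,
                                 n_decoy_genes = 1L), screen_config(), 9L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(truth$sirnas))
  expect_equal(sum(back$inhibitor) / 4, 2)
})
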