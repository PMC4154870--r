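# deterministic score-table builder: controls with median 0, known SD
ctrl_rows <- function(screen = NULL, stimulus = "TriDAP") {
  z <- seq(-0.5, 0.5, by = 0.1)  # median 0, sd ~0.3317
  out <- data.frame(sirna_id = sprintf("NEG_%02d", seq_along(z)),
                    gene_id = "", role = "neg_ctrl", stimulus = stimulus,
                    median_z = z, n_replicates_used = 4L)
  if (!is.null(screen)) out$screen <- screen
  out
}

gene_rows <- function(genes, zs, screen = NULL, stimulus = "TriDAP") {
  out <- data.frame(sirna_id = paste0(rep(genes, each = 2), "_s", 1:2),
                    gene_id = rep(genes, each = 2), role = "sample",
                    stimulus = stimulus, median_z = zs,
                    n_replicates_used = 4L)
  if (!is.null(screen)) out$screen <- screen
  out
}

test_that("validation call uses a strict 2-SD margin over the control median", {
  cfg <- screen_config()
  ctrl <- control_stats(ctrl_rows())
  m <- ctrl$median + cfg$thresholds$validation_sd * ctrl$sd
  tab <- rbind(ctrl_rows(),
               gene_rows(c("gA", "gB", "gC"),
                         c(m + 0.1 * ctrl$sd, 0.1,   # gA: 2.1 SD, strongest
                           m, m - 0.1,               # gB: exactly 2 SD
                           m + 0.5, m + 0.2)))       # gC: both pass
  call <- call_validation_hits(tab, cfg)
  expect_true("gA" %in% call$gene_hits)          # strongest-siRNA rule
  expect_false("gB" %in% call$gene_hits)         # strict inequality
  expect_true("gC" %in% call$gene_hits)

  both <- call_validation_hits(tab, cfg, rule = "both")
  expect_equal(both$gene_hits, "gC")

  expect_error(call_validation_hits(gene_rows("gA", c(1, 2)), cfg),
               "control statistics")
})

test_that("counter-screen exclusion partitions the validation hits", {
  excl <- exclude_counter_hits(c("A", "B", "C"), c("C", "D"))
  expect_equal(excl$nod1_specific, c("A", "B"))
  expect_equal(excl$tnf_excluded, "C")
  expect_equal(sort(c(excl$nod1_specific, excl$tnf_excluded)),
               c("A", "B", "C"))
  none <- exclude_counter_hits(c("A", "B"), character(0))
  expect_equal(none$nod1_specific, c("A", "B"))
})

test_that("secondary dual-readout call requires two siRNAs past 1.5 SD", {
  cfg <- screen_config()
  ctrl <- control_stats(ctrl_rows())
  sd <- ctrl$sd
  tab <- rbind(ctrl_rows(),
               gene_rows(c("gA", "gB", "gC"),
                         c(1.6 * sd, 1.8 * sd,    # gA: inhibiting
                           1.6 * sd, 1.4 * sd,    # gB: one fails
                           3.2 * sd, 1.6 * sd)))  # gC: strong
  solo <- data.frame(sirna_id = "gD_s1", gene_id = "gD", role = "sample",
                     stimulus = "TriDAP", median_z = 5,
                     n_replicates_used = 4L)
  calls <- call_thp1_hits(rbind(tab, solo), cfg)
  expect_equal(calls$status[calls$gene_id == "gA"], "inhibiting_hit")
  expect_equal(calls$status[calls$gene_id == "gB"], "none")
  expect_equal(calls$status[calls$gene_id == "gC"], "strong_inhibiting_hit")
  expect_equal(calls$status[calls$gene_id == "gD"], "none")
  expect_true(calls$insufficient_data[calls$gene_id == "gD"])
})

test_that("final intersection follows the set algebra of the flow", {
  thp1 <- data.frame(gene_id = c("B", "C", "D"),
                     status = c("inhibiting_hit", "inhibiting_hit",
                                "strong_inhibiting_hit"),
                     insufficient_data = FALSE)
  tri <- intersect_final(letters, c("A", "B", "C"), "C", thp1)
  expect_equal(tri$confirmed_both, c("B", "C"))
  expect_equal(tri$final_shortlist, "B")
  expect_equal(tri$nod1_specific, c("A", "B"))
  fc <- flow_counts(tri)
  expect_equal(fc$n_genes[fc$stage == "validation_hits"], 3L)
  expect_equal(fc$n_genes[fc$stage == "thp1_hits"], 3L)
  expect_equal(fc$n_genes[fc$stage == "confirmed_both"], 2L)
  expect_equal(fc$n_genes[fc$stage == "final_shortlist"], 1L)

  none <- intersect_final(letters, c("A", "B"), character(0), thp1[0, ])
  expect_equal(none$confirmed_both, character(0))
  all_kept <- intersect_final(letters, c("B", "C"), character(0), thp1)
  expect_equal(all_kept$final_shortlist, all_kept$confirmed_both)
})

test_that("triage invariants hold for random gene sets (property)", {
  set.seed(23)
  universe <- sprintf("g%03d", 1:150)
  for (i in 1:50) {
    val <- sample(universe, sample(0:60, 1))
    tnf <- sample(universe, sample(0:40, 1))
    thp1_genes <- sample(universe, sample(2:80, 1))
    thp1 <- data.frame(gene_id = thp1_genes,
                       status = sample(c("none", "inhibiting_hit",
                                         "strong_inhibiting_hit"),
                                       length(thp1_genes), replace = TRUE),
                       insufficient_data = FALSE)
    tri <- suppressWarnings(
      intersect_final(universe, val, intersect(tnf, val), thp1))
    expect_true(all(tri$final_shortlist %in% tri$confirmed_both))
    expect_true(all(tri$confirmed_both %in% tri$validation_hits))
    expect_true(all(tri$thp1_strong %in% tri$thp1_hits))
    expect_length(intersect(tri$nod1_specific, tri$tnf_excluded), 0)
    expect_setequal(c(tri$nod1_specific, tri$tnf_excluded),
                    tri$validation_hits)
  }
})

test_that("raising SD thresholds never enlarges hit sets (property)", {
  set.seed(29)
  for (i in 1:20) {
    genes <- sprintf("g%02d", 1:40)
    tab <- rbind(ctrl_rows(),
                 gene_rows(genes, stats::rnorm(80, 0.3, 0.6)))
    loose <- screen_config(thresholds = list(validation_sd = 1.5,
                                             thp1_sd = 1.0,
                                             thp1_strong_sd = 2.0))
    tight <- screen_config(thresholds = list(validation_sd = 2.5,
                                             thp1_sd = 2.0,
                                             thp1_strong_sd = 3.5))
    expect_true(all(call_validation_hits(tab, tight)$gene_hits %in%
                      call_validation_hits(tab, loose)$gene_hits))
    hits <- function(cfg) {
      calls <- call_thp1_hits(tab, cfg)
      calls$gene_id[calls$status != "none"]
    }
    expect_true(all(hits(tight) %in% hits(loose)))
  }
})

test_that("triage is idempotent on its own outputs", {
  thp1 <- data.frame(gene_id = c("B", "C"), status = "inhibiting_hit",
                     insufficient_data = FALSE)
  t1 <- intersect_final(letters, c("A", "B", "C"), "A", thp1)
  t2 <- intersect_final(t1$primary_ranked, t1$validation_hits,
                        t1$tnf_excluded, thp1)
  expect_identical(unclass(t1), unclass(t2))
})

test_that("staged counts reproduce known values on a deposited-style table", {
  cfg <- screen_config()
  sd <- control_stats(ctrl_rows())$sd
  tab <- rbind(
    ctrl_rows("hek_validation"),
    gene_rows(c("gA", "gB", "gC", "gD"),
              c(3.0 * sd, 2.7 * sd,     # gA: validation hit
                2.1 * sd, 0.3 * sd,     # gB: validation hit (strongest)
                1.5 * sd, 1.0 * sd,     # gC: no
                2.4 * sd, 2.2 * sd),    # gD: validation hit
              "hek_validation"),
    ctrl_rows("hek_counter_tnf", "TNF"),
    gene_rows(c("gA", "gB", "gC", "gD"),
              c(2.5 * sd, 0.1,          # gA: TNF hit -> excluded
                0.2, 0.1, 0.3, 0.2, 0.5, 0.1),
              "hek_counter_tnf", "TNF"),
    ctrl_rows("thp1"),
    gene_rows(c("gA", "gB", "gC", "gD"),
              c(1.6 * sd, 1.7 * sd,     # gA: thp1 hit
                3.2 * sd, 1.6 * sd,     # gB: strong
                0.2, 0.1,
                1.6 * sd, 1.2 * sd),    # gD: one siRNA short
              "thp1"))
  res <- stage_counts(tab, cfg)
  counts <- stats::setNames(res$counts$n_genes, res$counts$stage)
  expect_equal(counts[["validation_hits"]], 3L)   # gA gB gD
  expect_equal(counts[["nod1_specific"]], 2L)     # gB gD
  expect_equal(counts[["thp1_hits"]], 2L)         # gA gB
  expect_equal(counts[["thp1_strong"]], 1L)       # gB
  expect_equal(counts[["confirmed_both"]], 2L)    # gA gB
  expect_equal(counts[["final_shortlist"]], 1L)   # gB
  expect_error(stage_counts(tab[, -3], cfg), "missing column")
})
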