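# Pipeline driver: stage chaining, run manifest, logging, flow report.

# FNV-1a 32-bit over a string; cheap content digest for the manifest.
# h is kept as a double < 2^32; the modular multiply is split so every
# intermediate stays below 2^53.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h_hi <- h %/% 65536
    h_lo <- h %% 65536
    h <- (((h_hi * p) %% 65536) * 65536 + h_lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Digest of a screen configuration
#'
#' Stable checksum of the serialized configuration, recorded in every run
#' manifest so outputs are traceable to the exact thresholds that produced
#' them.
#'
#' @param config a `screen_config`.
#' @return 8-hex-digit string.
#' @export
config_digest <- function(config) {
  out <- unclass(config)
  out$control_layout <- as.list(out$control_layout)
  fnv1a32(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
}

# atomic table write: temp file in the same directory, then rename
write_tsv_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

log_line <- function(outdir, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  cat(line, "\n", sep = "", file = file.path(outdir, "run.log"), append = TRUE)
  invisible(line)
}

write_manifest <- function(outdir, command, config, inputs, seed) {
  manifest <- list(command = command,
                   config_digest = config_digest(config),
                   inputs = as.list(inputs),
                   seed = seed,
                   tool = "rsascreen",
                   version = as.character(utils::packageVersion("rsascreen")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

score_one_arm <- function(wells, config) {
  norm <- normalize_wells(wells, config)
  scores <- orient_and_combine(norm, config)
  list(norm = norm, scores = scores)
}

top_validation_sirnas <- function(rsa, validation_top_n, per_gene = 2L) {
  top_genes <- utils::head(rsa$ranked_genes$gene_id, validation_top_n)
  ranked <- rsa$sirna_ranked
  ranked <- ranked[ranked$gene_id %in% top_genes & !is.na(ranked$rank), ]
  ranked <- ranked[order(ranked$rank), ]
  unlist(lapply(split(ranked, ranked$gene_id),
                function(g) utils::head(g$sirna_id, per_gene)),
         use.names = FALSE)
}

#' Run the full multi-layer simulated screening study
#'
#' Chains every stage of the screening flow on synthetic data: simulate the
#' primary receptor-stimulus screen, normalize and score it, rank genes with
#' RSA and drop low-support genes, re-screen the two strongest siRNAs of the
#' top-ranked genes in a validation arm and a pathway-independent counter
#' arm, run the secondary dual-readout screen in a second cell model
#' (receptor control as NPI anchor), triage, and score recovery against the
#' planted ground truth.
#'
#' @param preset study preset from [desk_preset()] or [fullscale_preset()].
#' @param seed integer root seed; stage-level streams derive from it
#'   (`seed`, `seed + 1`, `seed + 2` for primary, validation, secondary).
#' @return list: `truth`, `primary` (norm + scores), `rsa`, `validation`,
#'   `counter`, `thp1` (score tables and calls), `triage`, `flow`,
#'   `recovery` (top-5% rank recovery), `final_recovery` (final shortlist vs
#'   truth), `decoy_removal` (fraction of planted decoy genes removed by the
#'   low-support filter).
#' @export
run_screen_study <- function(preset = desk_preset(), seed = 1L) {
  config <- preset$config
  truth <- make_truth(preset$truth_spec, config, seed)

  prim_sim <- simulate_screen(config, truth, screen_id = "primary",
                              arms = "TriDAP", seed = seed)
  primary <- score_one_arm(prim_sim$wells, config)
  rsa <- rsa_rank(primary$scores)

  decoys <- truth$genes$gene_id[truth$genes$decoy]
  flagged <- rsa$gene_scores
  decoy_scored <- decoys[decoys %in% flagged$gene_id]
  decoy_removal <- if (length(decoy_scored)) {
    mean(flagged$excluded_low_support[match(decoy_scored, flagged$gene_id)])
  } else NA_real_

  val_sirnas <- top_validation_sirnas(rsa, preset$validation_top_n)
  val_sim <- simulate_screen(config, truth, screen_id = "validation",
                             arms = c("TriDAP", "TNF"), sirnas = val_sirnas,
                             seed = seed + 1L)
  val_scores <- lapply(split(val_sim$wells, val_sim$wells$stimulus),
                       function(w) score_one_arm(w, config)$scores)
  val_call <- call_validation_hits(val_scores$TriDAP, config)
  ctr_call <- call_validation_hits(val_scores$TNF, config)
  excl <- exclude_counter_hits(val_call$gene_hits, ctr_call$gene_hits)

  thp1_config <- config
  thp1_config$npi_pos_role <- "pos_ctrl_receptor"
  thp1_sim <- simulate_screen(thp1_config, truth, screen_id = "thp1",
                              arms = "TriDAP",
                              replicates = preset$thp1_replicates,
                              sirnas = val_sirnas, seed = seed + 2L)
  thp1_scores <- score_one_arm(thp1_sim$wells, thp1_config)$scores
  thp1_calls <- call_thp1_hits(thp1_scores, thp1_config)

  triage <- intersect_final(rsa$ranked_genes, val_call$gene_hits,
                            excl$tnf_excluded, thp1_calls)
  top_n <- ceiling(0.05 * preset$truth_spec$n_genes)
  list(truth = truth,
       primary = primary,
       rsa = rsa,
       validation = list(scores = val_scores$TriDAP, call = val_call),
       counter = list(scores = val_scores$TNF, call = ctr_call,
                      excluded = excl$tnf_excluded),
       thp1 = list(scores = thp1_scores, calls = thp1_calls),
       triage = triage,
       flow = flow_counts(triage),
       recovery = evaluate_recovery(rsa$ranked_genes, truth, top_n),
       final_recovery = evaluate_recovery(rsa$ranked_genes, truth, top_n,
                                          hits = triage$final_shortlist),
       decoy_removal = decoy_removal)
}

#' Flow-chart report of a triage result
#'
#' Formats the per-stage gene counts of the screening flow as a small table.
#'
#' @param triage a `triage_result`.
#' @return data.frame from [flow_counts()] (also printed as text lines).
#' @export
build_flow_report <- function(triage) {
  fc <- flow_counts(triage)
  attr(fc, "lines") <- sprintf("%-16s %6d", fc$stage, fc$n_genes)
  fc
}

stage_deps <- list(
  simulate = character(0),
  qc = "wells_primary.tsv",
  normalize = "wells_primary.tsv",
  score = "sirna_scores.tsv",
  triage = c("ranked_genes.tsv", "truth.tsv"),
  report = "flow_counts.tsv")

check_deps <- function(outdir, command) {
  deps <- stage_deps[[command]]
  for (d in deps) {
    if (!file.exists(file.path(outdir, d))) {
      stop("stage '", command, "' requires missing upstream artifact: ", d,
           call. = FALSE)
    }
  }
}

#' Run pipeline stages against an output directory
#'
#' Stage driver behind the command-line interface. `simulate` writes the
#' primary-screen well table and ground truth; `qc`, `normalize` and `score`
#' consume the upstream TSVs; `triage` runs the validation / counter /
#' secondary layers (simulated from the ground truth in this driver) and
#' writes the triage tables; `report` formats the flow counts; `all` chains
#' every stage in screening order. Outputs are written atomically, a
#' `manifest.json` records command, config digest, inputs and seed, and
#' `run.log` records per-stage record counts and exclusions.
#'
#' @param command one of `simulate`, `qc`, `normalize`, `score`, `triage`,
#'   `report`, `all`.
#' @param outdir output directory (created if needed).
#' @param config a `screen_config` or path to a config file.
#' @param preset `"desk"`, `"fullscale"`, or a preset list as returned by
#'   [desk_preset()].
#' @param seed integer root seed (defaults to the configuration's).
#' @return invisible list of written file paths.
#' @export
run_pipeline <- function(command = c("all", "simulate", "qc", "normalize",
                                     "score", "triage", "report"),
                         outdir = "rsascreen_out",
                         config = NULL,
                         preset = c("desk", "fullscale"),
                         seed = NULL) {
  command <- match.arg(command)
  pre <- if (is.list(preset)) preset else
    switch(match.arg(preset), desk = desk_preset(),
           fullscale = fullscale_preset())
  preset <- pre
  if (is.character(config)) config <- read_screen_config(config)
  if (!is.null(config)) pre$config <- validate_config(config)
  config <- pre$config
  if (is.null(seed)) seed <- config$rng_seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (command == "all") {
    for (stage in c("simulate", "qc", "normalize", "score", "triage",
                    "report")) {
      run_pipeline(stage, outdir, config, preset, seed)
    }
    write_manifest(outdir, "all", config, character(0), seed)
    return(invisible(list.files(outdir, full.names = TRUE)))
  }

  check_deps(outdir, command)
  written <- character(0)
  path <- function(f) file.path(outdir, f)

  if (command == "simulate") {
    sim <- simulate_screen(config, pre$truth_spec, screen_id = "primary",
                           arms = "TriDAP", seed = seed)
    write_tsv_atomic(sim$wells, path("wells_primary.tsv"))
    write_truth(sim$truth, path("truth.tsv"))
    log_line(outdir, "simulate: ", nrow(sim$wells), " wells on ",
             length(unique(sim$wells$plate_id)), " plates")
    written <- c(path("wells_primary.tsv"), path("truth.tsv"))
  } else if (command == "qc") {
    wells <- read_wells(path("wells_primary.tsv"), config)
    qc <- plate_qc_all(wells, config)
    write_tsv_atomic(qc, path("plate_qc.tsv"))
    for (p in qc$plate_id[!qc$passed]) {
      log_line(outdir, "qc: plate ", p, " excluded (",
               qc$reasons[qc$plate_id == p], ")")
    }
    log_line(outdir, "qc: ", sum(qc$passed), "/", nrow(qc), " plates passed")
    written <- path("plate_qc.tsv")
  } else if (command == "normalize") {
    wells <- read_wells(path("wells_primary.tsv"), config)
    norm <- normalize_wells(wells, config)
    scores <- orient_and_combine(norm, config)
    write_tsv_atomic(norm$wells, path("normalized_wells.tsv"))
    write_tsv_atomic(scores, path("sirna_scores.tsv"))
    log_line(outdir, "normalize: ", sum(norm$wells$excluded), "/",
             nrow(norm$wells), " wells excluded (",
             sum(norm$wells$exclusion_reason == "plate_failed"),
             " plate_failed, ",
             sum(norm$wells$exclusion_reason == "low_viability"),
             " low_viability)")
    written <- c(path("normalized_wells.tsv"), path("sirna_scores.tsv"))
  } else if (command == "score") {
    scores <- utils::read.delim(path("sirna_scores.tsv"))
    rsa <- rsa_rank(scores)
    write_tsv_atomic(rsa$sirna_ranked, path("sirna_ranked.tsv"))
    write_tsv_atomic(rsa$gene_scores, path("gene_scores.tsv"))
    write_tsv_atomic(rsa$ranked_genes, path("ranked_genes.tsv"))
    log_line(outdir, "score: ", nrow(rsa$ranked_genes), " genes ranked, ",
             sum(rsa$gene_scores$excluded_low_support),
             " excluded for <2 OPI hits")
    written <- path(c("sirna_ranked.tsv", "gene_scores.tsv",
                      "ranked_genes.tsv"))
  } else if (command == "triage") {
    study <- run_screen_study(pre, seed)
    triage_tab <- data.frame(
      gene_id = study$triage$validation_hits,
      nod1_specific = study$triage$validation_hits %in%
        study$triage$nod1_specific,
      thp1_hit = study$triage$validation_hits %in% study$triage$thp1_hits,
      thp1_strong = study$triage$validation_hits %in% study$triage$thp1_strong,
      final = study$triage$validation_hits %in% study$triage$final_shortlist)
    write_tsv_atomic(study$validation$scores, path("validation_scores.tsv"))
    write_tsv_atomic(study$thp1$scores, path("thp1_scores.tsv"))
    write_tsv_atomic(triage_tab, path("triage.tsv"))
    write_tsv_atomic(study$flow, path("flow_counts.tsv"))
    jsonlite::write_json(study$recovery, path("recovery.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(outdir, "triage: ", length(study$triage$final_shortlist),
             " genes on the final shortlist")
    written <- path(c("validation_scores.tsv", "thp1_scores.tsv",
                      "triage.tsv", "flow_counts.tsv", "recovery.json"))
  } else if (command == "report") {
    fc <- utils::read.delim(path("flow_counts.tsv"))
    lines <- c("Screening flow", sprintf("%-16s %6d", fc$stage, fc$n_genes))
    writeLines(lines, path("flow_report.txt"))
    log_line(outdir, "report: flow report written")
    written <- path("flow_report.txt")
  }

  write_manifest(outdir, command, config, written, seed)
  invisible(written)
}
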