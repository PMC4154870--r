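# Seeded synthetic screens with known ground truth: planted inhibitor genes,
# toxic siRNAs, off-target siRNAs, multiplicative plate effects, and
# transfection/viability coupling of the dual readout.

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# mean-one multiplicative lognormal noise; exactly 1 when cv == 0
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sl <- cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
}

#' Ground-truth specification for a synthetic screen
#'
#' Describes the generative conditions: how many genes, which fraction are
#' planted pathway inhibitors and how strong, siRNA-level nuisance effects
#' (toxicity, off-targets), decoy genes carried by a single strong off-target
#' siRNA, noise magnitudes, and control effect sizes. All rates are
#' fractions in `[0, 1]`.
#'
#' @param n_genes library genes.
#' @param n_inhibitors planted pathway inhibitors.
#' @param effect_range gene-level knockdown inhibition range for inhibitors.
#' @param inhibitor_effects optional explicit effect vector (length
#'   `n_inhibitors`), overriding `effect_range`.
#' @param sirna_efficacy_range per-siRNA knockdown efficacy multiplier range.
#' @param shared_pathway_frac fraction of inhibitors also active under the
#'   pathway-independent (TNF) stimulus.
#' @param toxic_rate per-siRNA probability of a toxic phenotype.
#' @param tox_loss_range viability loss range of toxic siRNAs.
#' @param off_target_rate per-siRNA probability of a random off-target
#'   reporter effect (stimulus-specific arm only).
#' @param off_target_effect_range effect range of random off-targets.
#' @param n_decoy_genes non-inhibitor genes planted with exactly one strong
#'   off-target siRNA (the single-siRNA artifact the low-support filter must
#'   remove).
#' @param decoy_effect inhibition carried by each decoy off-target siRNA.
#' @param noise_cv multiplicative measurement noise CV of both channels.
#' @param transfection_cv CV of per-well transfection efficiency.
#' @param plate_effect_sdlog lognormal SD of the per-plate scale factor.
#' @param baseline_activity stimulated reporter baseline (activity units).
#' @param viability_baseline viability-channel baseline (absorbance units;
#'   default 1 so plate-QC bounds 0.2/2.5 are on the native scale).
#' @param p65_effect,nod1_effect,tox_ctrl_loss control effect sizes: pathway
#'   control inhibition (both arms), receptor control inhibition
#'   (receptor-specific arm only), and kill-control viability loss.
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(n_genes = 500L,
                       n_inhibitors = 25L,
                       effect_range = c(0.75, 0.95),
                       inhibitor_effects = NULL,
                       sirna_efficacy_range = c(0.95, 1.0),
                       shared_pathway_frac = 0.2,
                       toxic_rate = 0.01,
                       tox_loss_range = c(0.7, 0.95),
                       off_target_rate = 0.005,
                       off_target_effect_range = c(0.2, 0.5),
                       n_decoy_genes = 10L,
                       decoy_effect = 0.8,
                       noise_cv = 0.15,
                       transfection_cv = 0.20,
                       plate_effect_sdlog = 0.15,
                       baseline_activity = 100,
                       viability_baseline = 1,
                       p65_effect = 0.90,
                       nod1_effect = 0.85,
                       tox_ctrl_loss = 0.95) {
  spec <- structure(as.list(environment()), class = "truth_spec")
  rates <- c(spec$shared_pathway_frac, spec$toxic_rate, spec$off_target_rate,
             spec$decoy_effect, spec$p65_effect, spec$nod1_effect,
             spec$tox_ctrl_loss, spec$effect_range, spec$tox_loss_range,
             spec$off_target_effect_range, spec$sirna_efficacy_range)
  if (any(rates < 0 | rates > 1)) {
    stop("config error: rates and effect fractions must lie in [0, 1]",
         call. = FALSE)
  }
  if (spec$n_inhibitors + spec$n_decoy_genes > spec$n_genes) {
    stop("config error: more planted genes than library genes", call. = FALSE)
  }
  spec
}

#' Draw the ground truth of one synthetic screen
#'
#' Materialises a [truth_spec()] into per-gene and per-siRNA truth tables
#' under one seed. Inhibitor genes get a knockdown effect; every siRNA gets
#' an efficacy multiplier; decoy genes receive exactly one strong off-target
#' siRNA; further off-targets and toxic siRNAs are planted at the configured
#' rates.
#'
#' @param spec a `truth_spec`.
#' @param config a `screen_config` (sets siRNAs per gene).
#' @param seed integer seed.
#' @return object of class `sim_truth`: `genes`, `sirnas`, `spec`, `seed`.
#' @export
make_truth <- function(spec, config = screen_config(), seed = 1L) {
  stopifnot(inherits(spec, "truth_spec"))
  set.seed(seed)
  n <- spec$n_genes
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                      inhibitor = FALSE, true_effect = 0,
                      shared_pathway = FALSE, decoy = FALSE)
  inh <- sort(sample.int(n, spec$n_inhibitors))
  genes$inhibitor[inh] <- TRUE
  genes$true_effect[inh] <- if (!is.null(spec$inhibitor_effects)) {
    stopifnot(length(spec$inhibitor_effects) == spec$n_inhibitors)
    spec$inhibitor_effects
  } else {
    stats::runif(spec$n_inhibitors, spec$effect_range[1], spec$effect_range[2])
  }
  n_shared <- round(spec$shared_pathway_frac * spec$n_inhibitors)
  if (n_shared > 0) {
    genes$shared_pathway[sample(inh, n_shared)] <- TRUE
  }
  non_inh <- setdiff(seq_len(n), inh)
  if (spec$n_decoy_genes > 0) {
    genes$decoy[sample(non_inh, spec$n_decoy_genes)] <- TRUE
  }

  spg <- config$sirnas_per_gene
  sirnas <- data.frame(
    sirna_id = paste0(rep(genes$gene_id, each = spg), "_s",
                      rep(seq_len(spg), n)),
    gene_id = rep(genes$gene_id, each = spg),
    efficacy = stats::runif(n * spg, spec$sirna_efficacy_range[1],
                            spec$sirna_efficacy_range[2]),
    toxic = stats::runif(n * spg) < spec$toxic_rate,
    tox_loss = 0,
    off_target_effect = 0)
  sirnas$tox_loss[sirnas$toxic] <-
    stats::runif(sum(sirnas$toxic), spec$tox_loss_range[1],
                 spec$tox_loss_range[2])
  # decoy genes: exactly their first siRNA carries the strong off-target
  decoy_first <- match(paste0(genes$gene_id[genes$decoy], "_s1"),
                       sirnas$sirna_id)
  sirnas$off_target_effect[decoy_first] <- spec$decoy_effect
  # random weak off-targets among the remaining siRNAs
  pool <- setdiff(seq_len(nrow(sirnas)), decoy_first)
  ot <- pool[stats::runif(length(pool)) < spec$off_target_rate]
  sirnas$off_target_effect[ot] <-
    stats::runif(length(ot), spec$off_target_effect_range[1],
                 spec$off_target_effect_range[2])
  structure(list(genes = genes, sirnas = sirnas, spec = spec, seed = seed),
            class = "sim_truth")
}

# stable per-plate child stream: child = (seed * 131071 + index) mod (2^31-1)
plate_child_seed <- function(seed, plate_index) {
  as.integer((as.numeric(seed) %% 2147483647 * 131071 + plate_index) %%
               2147483647)
}

default_plate_controls <- c(neg_ctrl = 16L, pos_ctrl_pathway = 8L,
                            pos_ctrl_receptor = 8L, tox_ctrl = 8L)

control_block <- function(plate_controls) {
  prefix <- c(neg_ctrl = "CTRL_NEG", pos_ctrl_pathway = "CTRL_P65",
              pos_ctrl_receptor = "CTRL_NOD1", tox_ctrl = "CTRL_PLK")
  do.call(rbind, lapply(names(plate_controls), function(role) {
    k <- plate_controls[[role]]
    data.frame(sirna_id = sprintf("%s_%02d", prefix[[role]], seq_len(k)),
               gene_id = "", role = role)
  }))
}

# knockdown effect of each (siRNA, role) under one stimulus arm
well_effect <- function(block, truth, arm) {
  spec <- truth$spec
  eff <- numeric(nrow(block))
  smp <- block$role == "sample"
  if (any(smp)) {
    i <- match(block$sirna_id[smp], truth$sirnas$sirna_id)
    g <- match(truth$sirnas$gene_id[i], truth$genes$gene_id)
    on_target <- truth$genes$true_effect[g] * truth$sirnas$efficacy[i]
    if (arm == "TriDAP") {
      # off-targets are modelled as hits on stimulus-specific pathway genes
      eff[smp] <- 1 - (1 - on_target) *
        (1 - truth$sirnas$off_target_effect[i])
    } else if (arm == "TNF") {
      eff[smp] <- ifelse(truth$genes$shared_pathway[g], on_target, 0)
    } else {
      stop("unsupported stimulus arm: ", arm, call. = FALSE)
    }
  }
  eff[block$role == "pos_ctrl_pathway"] <- spec$p65_effect
  if (arm == "TriDAP") eff[block$role == "pos_ctrl_receptor"] <- spec$nod1_effect
  eff
}

well_tox <- function(block, truth) {
  tox <- numeric(nrow(block))
  smp <- block$role == "sample"
  if (any(smp)) {
    i <- match(block$sirna_id[smp], truth$sirnas$sirna_id)
    tox[smp] <- truth$sirnas$tox_loss[i]
  }
  tox[block$role == "tox_ctrl"] <- truth$spec$tox_ctrl_loss
  tox
}

#' Simulate a synthetic arrayed screen
#'
#' Generative model per well: transfection efficiency `t` is lognormal
#' (mean 1, configured CV); viability `v = t (1 - toxicity)`; the viability
#' channel reads `plate_factor * v * (1 + noise)`; reporter activity is the
#' stimulated baseline scaled by `(1 - knockdown effect)` and the activity
#' channel reads `plate_factor * t * activity * (1 + noise)`. Knockdown
#' effects follow the ground truth: inhibitor genes act under the
#' receptor-specific stimulus, only shared-pathway genes under the
#' pathway-independent one; the pathway control inhibits in both arms, the
#' receptor control only in the specific arm; kill controls lose nearly all
#' viability. All noise is multiplicative lognormal. One root seed; each
#' plate draws from a child stream derived by a stable documented rule, so
#' identical (config, truth, seed) gives bit-identical tables.
#'
#' @param config a `screen_config`.
#' @param truth a `truth_spec` (materialised internally with `seed`) or a
#'   prebuilt `sim_truth` (reused, e.g. for secondary screens on the same
#'   library).
#' @param screen_id label prefixed to plate ids.
#' @param arms stimulus arms to simulate (`"TriDAP"`, `"TNF"`).
#' @param replicates biological replicates (plates) per arm.
#' @param sirnas optional character vector restricting the screen to a subset
#'   of library siRNAs (validation-plate design).
#' @param plate_controls named integer vector of control wells per plate.
#' @param seed integer root seed.
#' @return list with `wells` (validated well table) and `truth`
#'   (`sim_truth`).
#' @export
simulate_screen <- function(config = screen_config(),
                            truth = truth_spec(),
                            screen_id = "primary",
                            arms = "TriDAP",
                            replicates = config$replicates,
                            sirnas = NULL,
                            plate_controls = default_plate_controls,
                            seed = config$rng_seed) {
  if (inherits(truth, "truth_spec")) truth <- make_truth(truth, config, seed)
  stopifnot(inherits(truth, "sim_truth"))
  spec <- truth$spec

  lib <- truth$sirnas[, c("sirna_id", "gene_id")]
  if (!is.null(sirnas)) {
    missing_ids <- setdiff(sirnas, lib$sirna_id)
    if (length(missing_ids)) {
      stop("unknown siRNA id(s): ", paste(utils::head(missing_ids, 3),
                                          collapse = ", "), call. = FALSE)
    }
    lib <- lib[match(sirnas, lib$sirna_id), , drop = FALSE]
  }
  lib$role <- "sample"

  ctrl <- control_block(plate_controls)
  wells_per_plate <- config$plate_format - nrow(ctrl)
  stopifnot(wells_per_plate > 0)
  n_plates <- ceiling(nrow(lib) / wells_per_plate)
  positions <- well_names(config$plate_format)

  plate_index <- 0L
  out <- vector("list", length(arms) * replicates * n_plates)
  oi <- 0L
  for (arm in arms) {
    for (rep_i in seq_len(replicates)) {
      for (p in seq_len(n_plates)) {
        plate_index <- plate_index + 1L
        rows <- seq.int((p - 1L) * wells_per_plate,
                        length.out = wells_per_plate) + 1L
        rows <- rows[rows <= nrow(lib)]
        block <- rbind(lib[rows, , drop = FALSE], ctrl)
        nw <- nrow(block)
        set.seed(plate_child_seed(seed, plate_index))
        plate_factor <- if (spec$plate_effect_sdlog == 0) 1 else
          stats::rlnorm(1, 0, spec$plate_effect_sdlog)
        t_eff <- rlnorm_mean1(nw, spec$transfection_cv)
        kd <- well_effect(block, truth, arm)
        tox <- well_tox(block, truth)
        v <- t_eff * (1 - tox)
        viab <- plate_factor * spec$viability_baseline * v *
          rlnorm_mean1(nw, spec$noise_cv)
        act <- plate_factor * spec$baseline_activity * t_eff * (1 - kd) *
          rlnorm_mean1(nw, spec$noise_cv)
        oi <- oi + 1L
        out[[oi]] <- data.frame(
          screen_id = screen_id,
          plate_id = sprintf("%s_%s_r%d_p%02d", screen_id, arm, rep_i, p),
          well = positions[seq_len(nw)],
          replicate = rep_i,
          sirna_id = block$sirna_id,
          gene_id = block$gene_id,
          role = block$role,
          stimulus = arm,
          readout_activity = act,
          readout_viability = viab)
      }
    }
  }
  wells <- do.call(rbind, out[seq_len(oi)])
  rownames(wells) <- NULL
  list(wells = validate_wells(wells, config), truth = truth)
}

#' Inject plate-level artifacts
#'
#' Modifies listed plates to trip the plate-QC rules: `transfection_failure`
#' scales every viability readout on the plate by `param` (default 0.05,
#' driving the negative-control mean below the lower bound);
#' `control_drift` multiplies each negative-control viability readout by
#' mean-one lognormal noise with CV `param` (default 0.8, inflating the
#' control CV). Untouched plates are returned bit-identical.
#'
#' @param wells well table.
#' @param artifacts data.frame with columns `plate_id`, `kind` and optional
#'   `param`.
#' @param seed integer seed for the drift noise.
#' @return modified copy of `wells`.
#' @export
inject_plate_artifacts <- function(wells, artifacts, seed = 1L) {
  if (!nrow(artifacts)) return(wells)
  unknown <- setdiff(artifacts$plate_id, wells$plate_id)
  if (length(unknown)) {
    stop("unknown plate id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  for (i in seq_len(nrow(artifacts))) {
    idx <- which(wells$plate_id == artifacts$plate_id[i])
    param <- if ("param" %in% names(artifacts) && !is.na(artifacts$param[i]))
      artifacts$param[i] else NA_real_
    kind <- artifacts$kind[i]
    if (kind == "transfection_failure") {
      f <- if (is.na(param)) 0.05 else param
      wells$readout_viability[idx] <- wells$readout_viability[idx] * f
    } else if (kind == "control_drift") {
      cv <- if (is.na(param)) 0.8 else param
      neg <- idx[wells$role[idx] == "neg_ctrl"]
      wells$readout_viability[neg] <- wells$readout_viability[neg] *
        rlnorm_mean1(length(neg), cv)
    } else {
      stop("unknown artifact kind: ", kind, call. = FALSE)
    }
  }
  wells
}

#' Score recovery of planted inhibitors
#'
#' Compares a ranked gene list (and optionally a called hit set) against the
#' ground truth: sensitivity, false-discovery proportion, fraction of planted
#' inhibitors within the top `top_n` ranks, and an error breakdown by cause
#' (toxic siRNA, off-target siRNA, noise).
#'
#' @param ranked_genes ranked gene table (from [rsa_rank()]) or character
#'   vector of gene ids in rank order.
#' @param truth a `sim_truth`.
#' @param top_n size of the top list used for rank-based recovery.
#' @param hits optional called hit set; defaults to the top `top_n` genes.
#' @return list: `n_planted`, `sensitivity`, `fdp`, `top_n`, `rank_recovery`,
#'   `fn_by_cause`, `fp_by_cause`.
#' @export
evaluate_recovery <- function(ranked_genes, truth, top_n, hits = NULL) {
  if (is.data.frame(ranked_genes)) ranked_genes <- ranked_genes$gene_id
  planted <- truth$genes$gene_id[truth$genes$inhibitor]
  top <- utils::head(ranked_genes, top_n)
  if (is.null(hits)) hits <- top
  toxic_genes <- unique(truth$sirnas$gene_id[truth$sirnas$toxic])
  ot_genes <- unique(truth$sirnas$gene_id[truth$sirnas$off_target_effect > 0])
  fn <- setdiff(planted, hits)
  fp <- setdiff(hits, planted)
  list(n_planted = length(planted),
       sensitivity = if (length(planted)) mean(planted %in% hits) else NA_real_,
       fdp = if (length(hits)) length(fp) / length(hits) else 0,
       top_n = top_n,
       rank_recovery = if (length(planted)) mean(planted %in% top) else NA_real_,
       fn_by_cause = c(toxic = sum(fn %in% toxic_genes),
                       noise = sum(!fn %in% toxic_genes)),
       fp_by_cause = c(off_target = sum(fp %in% ot_genes),
                       noise = sum(!fp %in% ot_genes)))
}

#' Write / read a ground-truth table
#'
#' Flat TSV serialisation of a `sim_truth` (gene and siRNA truth joined), so
#' simulated screens can be audited alongside their well tables.
#'
#' @param truth a `sim_truth`.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  tab <- merge(truth$sirnas, truth$genes, by = "gene_id", sort = FALSE)
  utils::write.table(tab[order(tab$sirna_id), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Study presets
#'
#' `desk_preset()` is the default benchmarking scale: 500 genes x 4 siRNAs in
#' quadruplicate (about six 384-well plates per replicate and arm) with 25
#' planted inhibitors, 15% measurement noise and 10 single-siRNA decoy genes;
#' the validation layer carries the top 50 genes (two siRNAs each) and the
#' secondary screen runs in triplicate. `fullscale_preset()` keeps the
#' published geometry: ~7000 genes with 435 validation candidates.
#'
#' @return list with `config`, `truth_spec`, `validation_top_n`,
#'   `thp1_replicates`.
#' @export
desk_preset <- function() {
  list(config = screen_config(),
       truth_spec = truth_spec(),
       validation_top_n = 50L,
       thp1_replicates = 3L)
}

#' @rdname desk_preset
#' @export
fullscale_preset <- function() {
  list(config = screen_config(),
       truth_spec = truth_spec(n_genes = 7000L, n_inhibitors = 350L,
                               n_decoy_genes = 140L),
       validation_top_n = 435L,
       thp1_replicates = 3L)
}
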