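# Plate/well quality control and the normalization cascade:
# activity ratio -> NPI -> per-replicate robust z -> median z per siRNA.

#' Plate-level quality control on the negative-control viability channel
#'
#' A plate is excluded when the mean viability readout of its non-targeting
#' controls is above `plate_viability_hi`, below `plate_viability_lo`, or when
#' its coefficient of variation (SD/mean) exceeds `plate_viability_cv`. All
#' inequalities are strict; several reasons may co-occur.
#'
#' @param wells well table restricted to one plate.
#' @param config a `screen_config`.
#' @return one-row data.frame: `plate_id`, `neg_mean_viability`,
#'   `neg_cv_viability`, `passed`, `reasons` (comma-separated).
#' @export
plate_qc <- function(wells, config = screen_config()) {
  stopifnot(length(unique(wells$plate_id)) == 1L)
  neg <- wells$readout_viability[wells$role == "neg_ctrl"]
  if (length(neg) < 2L) {
    stop("insufficient controls: plate ", wells$plate_id[1],
         " has fewer than 2 neg_ctrl wells", call. = FALSE)
  }
  th <- config$thresholds
  m <- mean(neg)
  cv <- stats::sd(neg) / m
  reasons <- c(if (m > th$plate_viability_hi) "mean_too_high",
               if (m < th$plate_viability_lo) "mean_too_low",
               if (cv > th$plate_viability_cv) "cv_too_high")
  data.frame(plate_id = wells$plate_id[1],
             neg_mean_viability = m,
             neg_cv_viability = cv,
             passed = length(reasons) == 0L,
             reasons = paste(reasons, collapse = ","))
}

#' @rdname plate_qc
#' @param wells well table spanning any number of plates.
#' @return `plate_qc_all`: one row per plate.
#' @export
plate_qc_all <- function(wells, config = screen_config()) {
  out <- lapply(split(wells, wells$plate_id), plate_qc, config = config)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$plate_id), , drop = FALSE]
}

#' Well-level viability exclusion on one passing plate
#'
#' Flags every well (controls included) whose viability readout falls strictly
#' below `well_viability_frac` times the plate's negative-control mean
#' viability. Wells exactly at the threshold are kept.
#'
#' @param wells well table restricted to one plate that passed [plate_qc()].
#' @param config a `screen_config`.
#' @return logical vector, `TRUE` where the well is excluded for low
#'   viability.
#' @export
exclude_low_viability <- function(wells, config = screen_config()) {
  neg <- wells$readout_viability[wells$role == "neg_ctrl"]
  if (!length(neg)) {
    stop("plate ", wells$plate_id[1], " has no neg_ctrl wells", call. = FALSE)
  }
  wells$readout_viability < config$thresholds$well_viability_frac * mean(neg)
}

#' Viability-ratio normalization of the reporter channel
#'
#' The reporter readout divided by the viability/transfection readout
#' (RLU/ABS405 or QB/XTT), cancelling per-well transfection efficiency.
#'
#' @param activity,viability non-negative readout vectors.
#' @return `activity / viability`.
#' @export
normalize_activity <- function(activity, viability) {
  if (any(viability == 0)) {
    stop("undefined ratio: viability readout of 0 ",
         "(well must already be excluded)", call. = FALSE)
  }
  activity / viability
}

#' Normalized percent inhibition
#'
#' Rescales a ratio-normalized activity so the negative-control mean maps to
#' 0 and the positive-control mean to 1: `(neg_mean - x) / (neg_mean -
#' pos_mean)`. Monotone increasing in inhibition strength when the positive
#' control inhibits the reporter.
#'
#' @param n_activity ratio-normalized activity value(s).
#' @param neg_mean,pos_mean plate means of the ratio-normalized activity of
#'   surviving negative and positive control wells.
#' @return NPI value(s).
#' @export
npi_normalize <- function(n_activity, neg_mean, pos_mean) {
  if (isTRUE(all.equal(neg_mean, pos_mean))) {
    stop("degenerate controls: negative and positive control means coincide",
         call. = FALSE)
  }
  (neg_mean - n_activity) / (neg_mean - pos_mean)
}

#' Full per-well normalization cascade
#'
#' Applies, in order: plate-level QC (wells on failed plates are excluded with
#' reason `plate_failed`), the 40%-of-negative-control viability filter
#' (reason `low_viability`), the activity/viability ratio, and per-plate NPI
#' using only control wells that survive the viability filter. Plate-level
#' exclusion precedes well-level exclusion: wells on a failed plate carry
#' `plate_failed` only.
#'
#' @param wells validated well table (one screen arm or several; NPI and QC
#'   are computed per plate, so mixed tables are safe as long as plates are
#'   not shared across arms).
#' @param config a `screen_config`.
#' @return list with `wells` (input plus `n_activity`, `npi`, `excluded`,
#'   `exclusion_reason`) and `plate_qc` (per-plate QC report).
#' @export
normalize_wells <- function(wells, config = screen_config()) {
  qc <- plate_qc_all(wells, config)
  failed <- qc$plate_id[!qc$passed]

  wells$excluded <- wells$plate_id %in% failed
  wells$exclusion_reason <- ifelse(wells$excluded, "plate_failed", "none")
  wells$n_activity <- NA_real_
  wells$npi <- NA_real_

  for (p in qc$plate_id[qc$passed]) {
    idx <- which(wells$plate_id == p)
    sub <- wells[idx, ]
    low <- exclude_low_viability(sub, config)
    wells$excluded[idx][low] <- TRUE
    wells$exclusion_reason[idx][low] <- "low_viability"
    keep <- idx[!low]
    if (!length(keep)) next
    wells$n_activity[keep] <-
      normalize_activity(wells$readout_activity[keep],
                         wells$readout_viability[keep])
    kept_roles <- wells$role[keep]
    neg_mean <- mean(wells$n_activity[keep][kept_roles == "neg_ctrl"])
    pos_mean <- mean(wells$n_activity[keep][kept_roles == config$npi_pos_role])
    if (is.nan(neg_mean) || is.nan(pos_mean)) {
      warning("plate ", p, ": surviving controls missing, NPI not computed",
              call. = FALSE)
      next
    }
    wells$npi[keep] <- npi_normalize(wells$n_activity[keep],
                                     neg_mean, pos_mean)
  }
  list(wells = wells, plate_qc = qc)
}

# robust per-plate z-scores ---------------------------------------------------

plate_scale <- function(values, roles, zscore_scale) {
  s <- switch(zscore_scale,
    sample_mad = stats::mad(values[roles == "sample"]),
    neg_sd = stats::sd(values[roles == "neg_ctrl"]),
    stop("unknown zscore_scale: ", zscore_scale, call. = FALSE))
  if (!is.finite(s) || s == 0) {
    stop("degenerate scale: zero or undefined spread on a plate",
         call. = FALSE)
  }
  s
}

#' Per-replicate robust z-scores and per-siRNA median z
#'
#' On every replicate plate, each surviving well's value is centred on the
#' median of that plate's negative-control values and divided by a robust
#' plate scale (1.4826 x MAD of the plate's sample wells by default, or the
#' negative-control SD). Per siRNA, the median over surviving replicates and
#' the number of replicates used are recorded. Because the centring value is
#' the negative-control median, higher NPI-based z means stronger inhibition.
#'
#' @param normwells normalized well table from [normalize_wells()] (the
#'   `wells` element), one screen arm.
#' @param config a `screen_config`.
#' @param value_col column to standardize (default `"npi"`).
#' @return list with `well_z` (per-well z on surviving wells) and `scores`
#'   (per siRNA: `sirna_id`, `gene_id`, `role`, `stimulus`, `median_z`,
#'   `n_replicates_used`).
#' @export
replicate_zscores <- function(normwells, config = screen_config(),
                              value_col = "npi") {
  keep <- normwells[!normwells$excluded & !is.na(normwells[[value_col]]), ]
  if (!nrow(keep)) stop("no surviving wells to score", call. = FALSE)
  keep$z <- NA_real_
  for (p in unique(keep$plate_id)) {
    idx <- which(keep$plate_id == p)
    vals <- keep[[value_col]][idx]
    roles <- keep$role[idx]
    centre <- stats::median(vals[roles == "neg_ctrl"])
    if (is.na(centre)) {
      stop("plate ", p, " has no surviving neg_ctrl wells for centring",
           call. = FALSE)
    }
    keep$z[idx] <- (vals - centre) / plate_scale(vals, roles,
                                                 config$zscore_scale)
  }
  agg <- split(keep, keep$sirna_id)
  scores <- do.call(rbind, lapply(agg, function(s) {
    data.frame(sirna_id = s$sirna_id[1],
               gene_id = s$gene_id[1],
               role = s$role[1],
               stimulus = s$stimulus[1],
               median_z = stats::median(s$z),
               n_replicates_used = length(unique(s$replicate)))
  }))
  rownames(scores) <- NULL
  list(well_z = keep, scores = scores)
}

#' Assemble the screen-level oriented score table
#'
#' One row per siRNA per stimulus arm. The score is the per-siRNA median z of
#' NPI values, so larger positive scores mean stronger inhibition of reporter
#' activity; the orientation is recorded in the `orientation` attribute.
#' siRNAs present in the well table but with zero surviving replicates are
#' emitted with `median_z = NA` and `n_replicates_used = 0`.
#'
#' @param normalized output of [normalize_wells()] for one arm (or a
#'   combined table; arms are split on `stimulus`).
#' @param config a `screen_config`.
#' @return data.frame of per-siRNA scores across arms, attribute
#'   `orientation = "higher_is_stronger_inhibition"`.
#' @export
orient_and_combine <- function(normalized, config = screen_config()) {
  wells <- normalized$wells
  out <- lapply(unique(wells$stimulus), function(arm) {
    sub <- wells[wells$stimulus == arm, ]
    scored <- replicate_zscores(sub, config)$scores
    all_sirnas <- unique(sub[, c("sirna_id", "gene_id", "role")])
    dropped <- all_sirnas[!all_sirnas$sirna_id %in% scored$sirna_id, ,
                          drop = FALSE]
    if (nrow(dropped)) {
      scored <- rbind(scored,
                      data.frame(sirna_id = dropped$sirna_id,
                                 gene_id = dropped$gene_id,
                                 role = dropped$role,
                                 stimulus = arm,
                                 median_z = NA_real_,
                                 n_replicates_used = 0L))
    }
    scored
  })
  out <- do.call(rbind, out)
  out <- out[order(out$stimulus, out$sirna_id), ]
  rownames(out) <- NULL
  attr(out, "orientation") <- "higher_is_stronger_inhibition"
  out
}
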