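# Multi-screen hit triage: validation-screen call, counter-screen exclusion,
# secondary (THP1-type) dual-readout call, and the final set intersection.

#' Negative-control score statistics of one screen arm
#'
#' Median and SD of the non-targeting-control score distribution used by all
#' SD-margin hit rules of the same arm.
#'
#' @param scores per-siRNA score table of one arm (must contain `role` and
#'   `median_z`).
#' @return list with `median`, `sd`, `n`.
#' @export
control_stats <- function(scores) {
  z <- scores$median_z[scores$role == "neg_ctrl" & !is.na(scores$median_z)]
  if (length(z) < 2L) {
    stop("missing control statistics: need >= 2 scored neg_ctrl siRNAs",
         call. = FALSE)
  }
  list(median = stats::median(z), sd = stats::sd(z), n = length(z))
}

sirna_margin <- function(scores, ctrl) {
  (scores$median_z - ctrl$median) / ctrl$sd
}

#' Validation / counter-screen hit call
#'
#' An siRNA is an inhibiting hit when its inhibition-oriented median z exceeds
#' the negative-control median by strictly more than `validation_sd` control
#' SDs. The gene-level call uses the strongest siRNA by default (a gene is a
#' hit if its best siRNA passes); `rule = "both"` requires every scored siRNA
#' of the gene to pass.
#'
#' @param scores per-siRNA score table of one arm.
#' @param config a `screen_config`.
#' @param ctrl optional precomputed [control_stats()]; computed from `scores`
#'   when omitted.
#' @param rule gene-level rule, defaults to `config$validation_gene_rule`.
#' @return list: `sirna_calls` (sample siRNAs with `margin_sd` and `hit`),
#'   `gene_hits` (character vector), `ctrl`.
#' @export
call_validation_hits <- function(scores, config = screen_config(),
                                 ctrl = NULL, rule = NULL) {
  if (is.null(ctrl)) ctrl <- control_stats(scores)
  rule <- if (is.null(rule)) config$validation_gene_rule else
    match.arg(rule, c("strongest", "both"))
  smp <- scores[scores$role == "sample" & !is.na(scores$median_z), ,
                drop = FALSE]
  smp$margin_sd <- sirna_margin(smp, ctrl)
  smp$hit <- smp$margin_sd > config$thresholds$validation_sd
  by_gene <- split(smp$hit, smp$gene_id)
  gene_hits <- names(by_gene)[vapply(by_gene,
                                     if (rule == "strongest") any else all,
                                     logical(1))]
  list(sirna_calls = smp, gene_hits = sort(gene_hits), ctrl = ctrl)
}

#' Counter-screen exclusion
#'
#' Removes genes that also score as hits under the pathway-independent
#' stimulus: only stimulus-specific genes survive.
#'
#' @param validation_hits genes called in the stimulus-specific validation
#'   arm.
#' @param counter_hits genes called (by the same rule) in the counter arm.
#' @return list: `nod1_specific` (validation hits not in the counter set) and
#'   `tnf_excluded` (validation hits removed); their union is the input.
#' @export
exclude_counter_hits <- function(validation_hits, counter_hits) {
  list(nod1_specific = sort(setdiff(validation_hits, counter_hits)),
       tnf_excluded = sort(intersect(validation_hits, counter_hits)))
}

#' Secondary dual-readout (THP1-type) hit call
#'
#' A gene is a validated inhibiting hit when two of its siRNAs exceed the
#' negative-control median by strictly more than `thp1_sd` control SDs; a
#' subset with at least one siRNA beyond `thp1_strong_sd` SDs are strong
#' inhibiting hits. Genes with fewer than two scored siRNAs are flagged
#' `insufficient_data` and called `none`.
#'
#' @param scores per-siRNA score table of the secondary screen (nQB-based,
#'   inhibition-oriented).
#' @param config a `screen_config`.
#' @param ctrl optional precomputed [control_stats()].
#' @return data.frame per gene: `gene_id`, `n_sirnas`, `n_pass`,
#'   `max_margin_sd`, `status` in `none`/`inhibiting_hit`/
#'   `strong_inhibiting_hit`, `insufficient_data`.
#' @export
call_thp1_hits <- function(scores, config = screen_config(), ctrl = NULL) {
  if (is.null(ctrl)) ctrl <- control_stats(scores)
  smp <- scores[scores$role == "sample" & !is.na(scores$median_z), ,
                drop = FALSE]
  smp$margin_sd <- sirna_margin(smp, ctrl)
  th <- config$thresholds
  out <- lapply(split(smp, smp$gene_id), function(g) {
    n <- nrow(g)
    insufficient <- n < 2L
    n_pass <- sum(g$margin_sd > th$thp1_sd)
    hit <- !insufficient && n_pass >= 2L
    strong <- hit && any(g$margin_sd > th$thp1_strong_sd)
    data.frame(gene_id = g$gene_id[1],
               n_sirnas = n,
               n_pass = n_pass,
               max_margin_sd = max(g$margin_sd),
               status = if (strong) "strong_inhibiting_hit"
                        else if (hit) "inhibiting_hit" else "none",
               insufficient_data = insufficient)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Final cross-screen intersection
#'
#' Assembles the triage result: genes confirmed in both the validation screen
#' and the secondary cell line, minus counter-screen hits.
#'
#' @param primary_ranked ranked gene list of the primary screen (character
#'   vector or the `ranked_genes` table from [rsa_rank()]).
#' @param validation_hits genes called in the validation arm.
#' @param tnf_excluded validation genes removed by the counter screen.
#' @param thp1_calls output of [call_thp1_hits()].
#' @return object of class `triage_result`: sets `primary_ranked`,
#'   `validation_hits`, `tnf_excluded`, `nod1_specific`, `thp1_hits`,
#'   `thp1_strong`, `confirmed_both`, `final_shortlist`.
#' @export
intersect_final <- function(primary_ranked, validation_hits, tnf_excluded,
                            thp1_calls) {
  if (is.data.frame(primary_ranked)) primary_ranked <- primary_ranked$gene_id
  thp1_hits <- thp1_calls$gene_id[thp1_calls$status %in%
                                    c("inhibiting_hit", "strong_inhibiting_hit")]
  thp1_strong <- thp1_calls$gene_id[thp1_calls$status == "strong_inhibiting_hit"]
  validation_hits <- sort(unique(validation_hits))
  tnf_excluded <- sort(intersect(tnf_excluded, validation_hits))
  if (length(validation_hits) && length(thp1_calls$gene_id) &&
      !length(intersect(validation_hits, thp1_calls$gene_id))) {
    warning("validation and secondary screens share no genes", call. = FALSE)
  }
  confirmed <- sort(intersect(validation_hits, thp1_hits))
  res <- structure(list(
    primary_ranked = primary_ranked,
    validation_hits = validation_hits,
    tnf_excluded = tnf_excluded,
    nod1_specific = sort(setdiff(validation_hits, tnf_excluded)),
    thp1_hits = sort(thp1_hits),
    thp1_strong = sort(thp1_strong),
    confirmed_both = confirmed,
    final_shortlist = sort(setdiff(confirmed, tnf_excluded))),
    class = "triage_result")
  stopifnot(all(res$final_shortlist %in% res$confirmed_both),
            all(res$confirmed_both %in% res$validation_hits),
            all(res$thp1_strong %in% res$thp1_hits),
            !length(intersect(res$nod1_specific, res$tnf_excluded)))
  res
}

#' Per-stage gene counts of a triage result
#'
#' The flow-chart summary: how many genes survive each triage layer.
#'
#' @param triage a `triage_result`.
#' @return data.frame with `stage` and `n_genes`.
#' @export
flow_counts <- function(triage) {
  stopifnot(inherits(triage, "triage_result"))
  stages <- c("primary_ranked", "validation_hits", "nod1_specific",
              "thp1_hits", "thp1_strong", "confirmed_both", "final_shortlist")
  data.frame(stage = stages,
             n_genes = vapply(triage[stages], length, integer(1)))
}

#' @export
print.triage_result <- function(x, ...) {
  cat("Screen triage result\n")
  fc <- flow_counts(x)
  for (i in seq_len(nrow(fc))) {
    cat(sprintf("  %-16s %d\n", fc$stage[i], fc$n_genes[i]))
  }
  invisible(x)
}

#' Staged hit counts from a deposited-style siRNA-level table
#'
#' Applies the full staged rule set to an siRNA-level z-score export (such as
#' a supplementary-data sheet of a published screen): the SD-margin validation
#' rule on the stimulus arm, the analogous counter-arm rule with exclusion,
#' and the two-siRNA 1.5-SD / one-siRNA 3.0-SD secondary-screen rules. The
#' table must hold columns `gene_id`, `sirna_id`, `screen` (one of
#' `hek_validation`, `hek_counter_tnf`, `thp1`), `role` and `median_z`
#' (inhibition-oriented).
#'
#' @param sirna_table siRNA-level long table covering the three screens.
#' @param config a `screen_config`.
#' @return list with the `triage_result` and its [flow_counts()].
#' @export
stage_counts <- function(sirna_table, config = screen_config()) {
  need <- c("gene_id", "sirna_id", "screen", "role", "median_z")
  missing_cols <- setdiff(need, names(sirna_table))
  if (length(missing_cols)) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  arm <- function(s) sirna_table[sirna_table$screen == s, , drop = FALSE]
  val <- call_validation_hits(arm("hek_validation"), config)
  ctr <- call_validation_hits(arm("hek_counter_tnf"), config)
  excl <- exclude_counter_hits(val$gene_hits, ctr$gene_hits)
  thp1 <- call_thp1_hits(arm("thp1"), config)
  triage <- intersect_final(unique(arm("hek_validation")$gene_id),
                            val$gene_hits, excl$tnf_excluded, thp1)
  list(triage = triage, counts = flow_counts(triage))
}
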