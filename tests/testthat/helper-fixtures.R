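# Fixtures are built in code; no data files.

# minimal valid well row(s)
make_wells <- function(n = 1, plate_id = "P1", well = NULL, role = "sample",
                       stimulus = "TriDAP", replicate = 1L,
                       activity = 100, viability = 1,
                       sirna_id = NULL, gene_id = NULL) {
  if (is.null(well)) well <- well_names(384)[seq_len(n)]
  if (is.null(sirna_id)) sirna_id <- sprintf("s%03d", seq_len(n))
  if (is.null(gene_id)) {
    gene_id <- ifelse(rep(role, length.out = n) == "sample",
                      sprintf("g%03d", seq_len(n)), "")
  }
  data.frame(screen_id = "test", plate_id = plate_id, well = well,
             replicate = replicate, sirna_id = sirna_id, gene_id = gene_id,
             role = role, stimulus = stimulus,
             readout_activity = activity, readout_viability = viability)
}

# one plate with given negative-control viabilities plus sample wells
make_plate <- function(plate_id, neg_viability, n_sample = 6,
                       sample_viability = 1, sample_activity = 100,
                       neg_activity = 100, pos_viability = 1,
                       pos_activity = 10, replicate = 1L,
                       stimulus = "TriDAP") {
  n_neg <- length(neg_viability)
  wells <- well_names(384)
  rbind(
    make_wells(n_sample, plate_id, wells[seq_len(n_sample)], "sample",
               stimulus, replicate, sample_activity, sample_viability,
               sprintf("%s_s%02d", plate_id, seq_len(n_sample)),
               sprintf("g%03d", seq_len(n_sample))),
    make_wells(n_neg, plate_id, wells[n_sample + seq_len(n_neg)], "neg_ctrl",
               stimulus, replicate, neg_activity, neg_viability,
               sprintf("NEG_%02d", seq_len(n_neg)), ""),
    make_wells(2, plate_id, wells[n_sample + n_neg + 1:2],
               "pos_ctrl_pathway", stimulus, replicate, pos_activity,
               pos_viability, sprintf("P65_%02d", 1:2), ""))
}

# independent RSA oracle: exhaustive enumeration of all C(N, k) equally
# likely rank placements. tails[j, r] = fraction of placements with at least
# j elements at rank <= r.
oracle_tails <- function(n_total, k) {
  subsets <- utils::combn(n_total, k)
  if (k == 1) subsets <- matrix(subsets, nrow = 1)
  tails <- matrix(NA_real_, k, n_total)
  for (r in seq_len(n_total)) {
    counts <- colSums(subsets <= r)
    for (j in seq_len(k)) tails[j, r] <- mean(counts >= j)
  }
  tails
}

oracle_pmin <- function(ranks, tails) {
  r <- sort(ranks)
  min(tails[cbind(seq_along(r), r)])
}

# direct survival-sum oracle for one (ranks, N): sum of hypergeometric pmf
# terms written out with choose(), independent of phyper
oracle_pmin_choose <- function(ranks, n_total) {
  r <- sort(ranks)
  k <- length(r)
  p <- vapply(seq_len(k), function(j) {
    x <- j:k
    sum(choose(r[j], x) * choose(n_total - r[j], k - x)) /
      choose(n_total, k)
  }, numeric(1))
  list(p_min = min(p), opi = which.min(p), cutoff = r[which.min(p)])
}

tiny_preset <- function() {
  cfg <- screen_config(replicates = 2L)
  list(config = cfg,
       truth_spec = truth_spec(n_genes = 60L, n_inhibitors = 5L,
                               n_decoy_genes = 2L),
       validation_top_n = 10L,
       thp1_replicates = 2L)
}
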