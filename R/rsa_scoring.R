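# Redundant siRNA activity (RSA) gene scoring: rank all siRNAs, then score
# each gene by the minimum over rank cutoffs of an exact hypergeometric tail.

#' Rank siRNAs by oriented score
#'
#' Rank 1 is the strongest inhibition. Ties receive the worst (maximal) rank
#' of the tied block, which is conservative for the downstream hypergeometric
#' tail. siRNAs with missing scores receive `NA` ranks and are placed after
#' all ranked siRNAs in the returned table; they do not count towards `N`.
#'
#' @param scores per-siRNA score table with columns `sirna_id`, `gene_id` and
#'   `median_z` (oriented: higher = stronger inhibition). Control rows should
#'   be removed beforehand if they must not compete for ranks.
#' @return the table with a `rank` column, ordered by rank (missing scores
#'   last).
#' @export
rank_sirnas <- function(scores) {
  if (!nrow(scores)) {
    scores$rank <- integer(0)
    return(scores)
  }
  scored <- !is.na(scores$median_z)
  scores$rank <- NA_integer_
  scores$rank[scored] <- as.integer(rank(-scores$median_z[scored],
                                         ties.method = "max"))
  scores[order(scores$rank, scores$sirna_id, na.last = TRUE), , drop = FALSE]
}

#' RSA gene score: minimum hypergeometric tail over rank cutoffs
#'
#' For a gene whose `k` siRNAs hold ranks `r_1 < ... < r_k` among `N` ranked
#' siRNAs, the tail at cutoff `j` is `P(X >= j)` with
#' `X ~ Hypergeometric(N, r_j, k)`: the chance that `j` or more of `k`
#' randomly placed siRNAs land within the top `r_j`. The gene score `p_min`
#' is the minimum tail over `j = 1..k`; on ties the smallest `j` wins. The
#' gene's "OPI hits" are its siRNAs at ranks up to the optimal cutoff, i.e.
#' `j` of them.
#'
#' @param ranks integer ranks of the gene's siRNAs (any order, duplicates are
#'   a precondition error).
#' @param n_total total number of ranked siRNAs `N`.
#' @param gene_id optional label carried into the output.
#' @return one-row data.frame: `gene_id`, `k`, `ranks` (comma-joined,
#'   sorted), `p_min`, `log_p` (log10), `cutoff_rank`, `opi_hit_count`,
#'   `excluded_low_support` (`opi_hit_count < 2`).
#' @export
gene_logp <- function(ranks, n_total, gene_id = NA_character_) {
  ranks <- as.integer(ranks)
  k <- length(ranks)
  if (k == 0L) return(NULL)
  if (anyDuplicated(ranks)) {
    stop("duplicate ranks within a gene", call. = FALSE)
  }
  if (any(ranks < 1L) || any(ranks > n_total) || k > n_total) {
    stop("ranks must lie in 1..N and k <= N", call. = FALSE)
  }
  r <- sort(ranks)
  j <- seq_len(k)
  # P(X >= j) with population N, r_j marked "top" items, k draws
  p <- stats::phyper(j - 1L, m = r, n = n_total - r, k = k,
                     lower.tail = FALSE)
  best <- which.min(p)                      # smallest j on ties
  data.frame(gene_id = gene_id,
             k = k,
             ranks = paste(r, collapse = ","),
             p_min = p[best],
             log_p = log10(p[best]),
             cutoff_rank = r[best],
             opi_hit_count = best,
             excluded_low_support = best < 2L)
}

#' Score all genes of a ranked siRNA table
#'
#' Applies [gene_logp()] per gene over the ranked sample siRNAs. Control rows
#' (empty `gene_id` or `role != "sample"` when a `role` column is present) and
#' siRNAs with missing ranks are ignored; genes with no ranked siRNA are
#' omitted.
#'
#' @param ranked output of [rank_sirnas()].
#' @return data.frame of gene scores, one row per gene.
#' @export
rsa_score_genes <- function(ranked) {
  if ("role" %in% names(ranked)) ranked <- ranked[ranked$role == "sample", ]
  ranked <- ranked[!is.na(ranked$rank) & ranked$gene_id != "", ]
  if (!nrow(ranked)) {
    return(data.frame(gene_id = character(0), k = integer(0),
                      ranks = character(0), p_min = numeric(0),
                      log_p = numeric(0), cutoff_rank = integer(0),
                      opi_hit_count = integer(0),
                      excluded_low_support = logical(0)))
  }
  n_total <- nrow(ranked)
  out <- lapply(split(ranked$rank, ranked$gene_id), function(r) r)
  genes <- names(out)
  res <- do.call(rbind, Map(function(r, g) gene_logp(r, n_total, g),
                            out, genes))
  rownames(res) <- NULL
  res
}

#' Flag and drop low-support genes
#'
#' Genes whose optimal cutoff captures fewer than two of their own siRNAs
#' ("OPI hits") rest on a single-siRNA signal — the off-target signature — and
#' are removed from the ranked hit list. They remain, flagged, in the full
#' score table.
#'
#' @param gene_scores output of [rsa_score_genes()].
#' @return list with `kept` (hit-list candidates) and `all` (full table with
#'   `excluded_low_support` flags).
#' @export
filter_low_support <- function(gene_scores) {
  gene_scores$excluded_low_support <- gene_scores$opi_hit_count < 2L
  list(kept = gene_scores[!gene_scores$excluded_low_support, , drop = FALSE],
       all = gene_scores)
}

#' Order gene scores into the ranked gene list
#'
#' Ascending `log_p` (most significant first); ties broken by smaller best
#' siRNA rank, then lexicographic `gene_id`.
#'
#' @param gene_scores gene score table.
#' @return the table ordered, with a `gene_rank` column.
#' @export
rank_genes <- function(gene_scores) {
  if (!nrow(gene_scores)) {
    gene_scores$gene_rank <- integer(0)
    return(gene_scores)
  }
  best_rank <- vapply(strsplit(gene_scores$ranks, ","),
                      function(r) min(as.integer(r)), integer(1))
  ord <- order(gene_scores$log_p, best_rank, gene_scores$gene_id)
  out <- gene_scores[ord, , drop = FALSE]
  out$gene_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' RSA pipeline: scores to ranked gene list
#'
#' Convenience wrapper: [rank_sirnas()] on the sample siRNAs of one arm,
#' [rsa_score_genes()], [filter_low_support()], [rank_genes()].
#'
#' @param scores per-siRNA score table (one stimulus arm).
#' @return list: `sirna_ranked`, `gene_scores` (all, flagged), `ranked_genes`
#'   (low-support genes removed, ordered).
#' @export
rsa_rank <- function(scores) {
  if ("role" %in% names(scores)) scores <- scores[scores$role == "sample", ]
  ranked <- rank_sirnas(scores)
  flt <- filter_low_support(rsa_score_genes(ranked))
  list(sirna_ranked = ranked,
       gene_scores = flt$all,
       ranked_genes = rank_genes(flt$kept))
}
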