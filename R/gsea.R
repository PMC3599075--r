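# Gene set enrichment analysis on mean-centered log2 signal intensities:
# weighted Kolmogorov-Smirnov enrichment score, gene-label permutation
# null, sign-stratified NES and FDR q-values, and cross-group NES
# correlation.

#' Build a ranked gene list for one group
#'
#' Gene score = across-array mean log2 sample-channel signal minus the
#' across-gene mean (mean-centering), so scores sum to zero.  Probes
#' collapse to genes by the maximum mean signal; probes without a gene
#' symbol and control probes are dropped.  Ordering is by descending
#' score with lexicographic tie-breaking, so the list is deterministic.
#'
#' @param ns NormalizedSet.
#' @param group group label.
#' @return a `RankedList` data.frame with columns `gene`, `score`,
#'   ordered best-first.
#' @export
build_ranked_list <- function(ns, group) {
  in_g <- ns$samples$group == group & !ns$samples$qc_excluded
  if (!any(in_g)) stop(sprintf("no usable arrays in group '%s'", group),
                       call. = FALSE)
  keep <- !ns$annotation$is_control & nzchar(ns$annotation$gene_symbol)
  mean_l2 <- rowMeans(log2(ns$af3[keep, in_g, drop = FALSE]))
  sym <- ns$annotation$gene_symbol[keep]
  per_gene <- tapply(mean_l2, sym, max)
  score <- per_gene - mean(per_gene)
  ord <- order(-score, names(score), method = "radix")
  out <- data.frame(gene = names(score)[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("RankedList", "data.frame")
  out
}

# core running-sum computation on a 0/1 hit indicator
.es_core <- function(score, hit, p) {
  N <- length(score)
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no member in the ranked list", call. = FALSE)
  if (nh == N) return(list(es = 1, running = rep(1, N), arg = N))
  w <- abs(score)^p
  sw <- sum(w[hit])
  inc <- if (sw > 0) w * hit / sw else hit / nh  # all-zero hit scores: equal weights
  dec <- (!hit) / (N - nh)
  running <- cumsum(inc - dec)
  arg <- which.max(abs(running))
  list(es = running[arg], running = running, arg = arg)
}

#' GSEA enrichment score of one gene set
#'
#' Weighted Kolmogorov-Smirnov running sum down the ranked list: positions
#' holding set members increment by `|score|^p` (normalized over member
#' positions), other positions decrement by `1 / (N - N_hits)`; the
#' enrichment score is the signed extremum of the running sum.  A set
#' covering the entire list is assigned ES = +1 by convention.
#'
#' @param ranked `RankedList` from [build_ranked_list()].
#' @param gene_set a gene set (list with `members`) or character vector.
#' @param p weight exponent (0 = classic unweighted KS, 1 = default).
#' @return list with `es`, `running` (the running sum), `arg` (extremum
#'   position), `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  members <- if (is.list(gene_set)) gene_set$members else gene_set
  hit <- ranked$gene %in% members
  r <- .es_core(ranked$score, hit, p)
  list(es = r$es, running = r$running, arg = r$arg, n_hits = sum(hit))
}

#' Permutation NES and FDR q-values for a gene-set collection
#'
#' Null enrichment scores are generated by gene-label permutation (for
#' each permutation, each set's member positions are redrawn uniformly),
#' appropriate when each group contributes a single ranked list.
#' NES = ES divided by the mean |null ES| of matching sign; the nominal p
#' is the same-sign tail proportion; FDR q follows the sign-stratified
#' ratio of null to observed NES tail proportions, clipped to [0, 1].
#'
#' @param ranked `RankedList`.
#' @param sets collection from [read_gmt()] (named list with `members`).
#' @param n_perm number of permutations (default 1000).
#' @param p weight exponent.
#' @param seed integer seed; results are fully determined by it.
#' @param min_size sets with fewer list members are dropped.
#' @return a `GseaResult` data.frame: `name`, `size`, `es`, `nes`,
#'   `p_value`, `q_value`, `arg`; attribute `n_perm`.
#' @export
nes_and_fdr <- function(ranked, sets, n_perm = 1000, p = 1, seed = 1L,
                        min_size = 2) {
  set.seed(seed)
  N <- nrow(ranked)
  score <- ranked$score
  genes <- ranked$gene
  sizes <- vapply(sets, function(s) sum(genes %in% s$members), 0L)
  keep <- sizes >= min_size & sizes < N
  sets <- sets[keep]; sizes <- sizes[keep]
  if (!length(sets)) stop("no gene set with enough members in the list", call. = FALSE)
  obs <- vapply(sets, function(s) enrichment_score(ranked, s, p)$es, 0)
  # one permutation = one relabeling; reuse it for all sets of a given size
  null_es <- matrix(0, n_perm, length(sets),
                    dimnames = list(NULL, names(sets)))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(N)
    for (k in seq_along(sets)) {
      hit <- logical(N)
      hit[perm[seq_len(sizes[k])]] <- TRUE
      null_es[b, k] <- .es_core(score, hit, p)$es
    }
  }
  pos_mean <- apply(null_es, 2, function(v) mean(v[v >= 0]))
  neg_mean <- apply(null_es, 2, function(v) mean(abs(v[v < 0])))
  norm_one <- function(e, k) {
    if (e >= 0) e / pos_mean[k] else e / neg_mean[k]
  }
  nes <- vapply(seq_along(obs), function(k) norm_one(obs[k], k), 0)
  null_nes <- null_es
  for (k in seq_along(sets)) {
    v <- null_es[, k]
    null_nes[, k] <- ifelse(v >= 0, v / pos_mean[k], v / neg_mean[k])
  }
  p_value <- vapply(seq_along(obs), function(k) {
    v <- null_es[, k]
    if (obs[k] >= 0) {
      vp <- v[v >= 0]
      if (!length(vp)) 0 else mean(vp >= obs[k])
    } else {
      vn <- v[v < 0]
      if (!length(vn)) 0 else mean(vn <= obs[k])
    }
  }, 0)
  all_null <- as.vector(null_nes)
  q_value <- vapply(seq_along(obs), function(k) {
    s <- nes[k]
    if (s >= 0) {
      denom_null <- all_null[all_null >= 0]
      num <- if (length(denom_null)) mean(denom_null >= s) else 0
      den <- mean(nes[nes >= 0] >= s)
    } else {
      denom_null <- all_null[all_null < 0]
      num <- if (length(denom_null)) mean(denom_null <= s) else 0
      den <- mean(nes[nes < 0] <= s)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)
  out <- data.frame(name = names(sets), size = as.integer(sizes), es = obs,
                    nes = nes, p_value = p_value, q_value = q_value,
                    arg = vapply(sets, function(s)
                      enrichment_score(ranked, s, p)$arg, 0L),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("GseaResult", "data.frame")
  out
}

#' Pearson correlation of NES between two result collections
#'
#' @param a,b `GseaResult`s sharing >= 3 gene-set names.
#' @return the Pearson coefficient over matched NES pairs.
#' @export
correlate_nes <- function(a, b) {
  shared <- intersect(a$name, b$name)
  if (length(shared) < 3)
    stop("correlate_nes: need >= 3 shared gene sets", call. = FALSE)
  stats::cor(a$nes[match(shared, a$name)], b$nes[match(shared, b$name)])
}
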