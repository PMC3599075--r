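# RT-qPCR validation arm: triplicate Cq aggregation, delta-Cq
# normalization to a reference housekeeping gene, detection calls, and
# housekeeping-based sample failure identification.

#' Read a qPCR plate from TSV
#'
#' Expected columns: `sample_id`, `group`, `gene`, `rep`, `cq` (a cycle
#' number, or `NA`/empty for no amplification within `max_cycles`).
#'
#' @param path input path.
#' @param max_cycles assay cycle limit (default 46).
#' @return a `QPCRPlate` data.frame.
#' @export
read_qpcr_plate <- function(path, max_cycles = 46L) {
  plate <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "rep", "cq")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("qPCR table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  plate$cq <- suppressWarnings(as.numeric(plate$cq))
  if (any(plate$cq <= 0 | plate$cq > max_cycles, na.rm = TRUE))
    stop("Cq values must be positive and <= max_cycles", call. = FALSE)
  attr(plate, "max_cycles") <- as.integer(max_cycles)
  class(plate) <- c("QPCRPlate", "data.frame")
  plate
}

#' Summarize a qPCR plate into expression calls
#'
#' Per (sample, gene): the mean Cq over amplified triplicates, the
#' delta-Cq versus the reference housekeeping gene, and the relative
#' expression `2^(-delta Cq)`.  A gene is called detected in a sample
#' when at least `min_amplified` of its three replicates amplified; when
#' the reference gene itself is undetected, the sample's ratios are
#' undefined (`NA`).
#'
#' @param plate `QPCRPlate`.
#' @param reference_gene housekeeping reference (default `"RPL13A"`).
#' @param min_amplified replicates required for a detection call
#'   (default 2 of 3).
#' @return an `ExpressionCall` data.frame: `sample_id`, `group`, `gene`,
#'   `n_amplified`, `mean_cq`, `detected`, `delta_cq`, `rel_expression`.
#' @export
summarize_plate <- function(plate, reference_gene = "RPL13A",
                            min_amplified = 2L) {
  stopifnot(reference_gene %in% plate$gene)
  key <- interaction(plate$sample_id, plate$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(plate, key), function(d) {
    amp <- sum(!is.na(d$cq))
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               gene = d$gene[1], n_amplified = amp,
               mean_cq = if (amp > 0) mean(d$cq, na.rm = TRUE) else NA_real_,
               detected = amp >= min_amplified, stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  ref <- agg[agg$gene == reference_gene, ]
  ref_cq <- stats::setNames(ifelse(ref$detected, ref$mean_cq, NA_real_),
                            ref$sample_id)
  agg$delta_cq <- agg$mean_cq - ref_cq[agg$sample_id]
  agg$delta_cq[!agg$detected] <- NA_real_
  agg$rel_expression <- 2^(-agg$delta_cq)
  class(agg) <- c("ExpressionCall", "data.frame")
  agg
}

#' Flag failed qPCR samples from housekeeping Cq
#'
#' Per comparison group, applies Dixon's Q test (see [dixon_q()]) to each
#' sample's mean Cq over the housekeeping panel; flagged samples are
#' marked failed.
#'
#' @param calls `ExpressionCall` table from [summarize_plate()].
#' @param housekeeping housekeeping panel (default ACTB, RPL13A, YWHAZ,
#'   GAPDH).
#' @param alpha Dixon significance level.
#' @param seed Monte-Carlo null seed.
#' @return a `QCReport` for the criterion `"housekeeping_cq"`.
#' @export
flag_failed_samples <- function(calls,
                                housekeeping = c("ACTB", "RPL13A",
                                                 "YWHAZ", "GAPDH"),
                                alpha = 0.05, seed = 1L) {
  hk <- calls[calls$gene %in% housekeeping, ]
  if (!nrow(hk)) stop("no housekeeping genes in the calls", call. = FALSE)
  means <- do.call(rbind, lapply(split(hk, hk$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               criterion = "housekeeping_cq",
               value = mean(d$mean_cq, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  means$value[is.nan(means$value)] <- NA_real_
  if (anyNA(means$value)) {
    # samples with no amplified housekeeping gene at all fail outright
    failed <- means$sample_id[is.na(means$value)]
    means <- means[!is.na(means$value), ]
    rep <- flag_outlier_samples(means, alpha = alpha, seed = seed)
    rep$exclusions <- rbind(rep$exclusions,
                            data.frame(sample_id = failed, excluded = TRUE,
                                       reason = "no housekeeping amplification",
                                       stringsAsFactors = FALSE))
    return(rep)
  }
  flag_outlier_samples(means, alpha = alpha, seed = seed)
}

#' Detected-sample counts per gene and group
#'
#' @param calls `ExpressionCall` table.
#' @param genes genes of interest (rows).
#' @param groups group labels (columns; default all in `calls`).
#' @return gene x group integer matrix of samples with a positive
#'   detection call.
#' @export
detection_count_table <- function(calls, genes, groups = NULL) {
  if (is.null(groups)) groups <- unique(calls$group)
  out <- matrix(0L, length(genes), length(groups),
                dimnames = list(genes, groups))
  for (g in genes) for (gr in groups) {
    sub <- calls[calls$gene == g & calls$group == gr, ]
    out[g, gr] <- sum(sub$detected)
  }
  out
}
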