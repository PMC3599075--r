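# Containers and tabular IO for two-color array experiments.
#
# All tables are tab-separated UTF-8 with a header row.  The signal table
# carries one probe per row: columns `probe_id`, optional `gene_symbol` and
# `is_control`, then one `<sample>_AF3` / `<sample>_AF5` column pair per
# array (sample channel and shared reference channel, linear scale).

#' Construct an ExperimentSet
#'
#' An `ExperimentSet` bundles the probe annotation, the per-array sample
#' metadata and the two signal matrices of a two-color array experiment:
#' `af3` holds the sample-channel signal and `af5` the reference-channel
#' signal, both probe x sample on the linear scale.
#'
#' @param annotation data.frame with columns `probe_id`, `gene_symbol`,
#'   `is_control`.  `gene_symbol` may be empty; `is_control` defaults to
#'   `FALSE` when absent.
#' @param samples data.frame with columns `sample_id`, `group`, `day`,
#'   `replicate` and optionally `qc_excluded` (logical) and `qc_reason`.
#' @param af3,af5 numeric matrices, probes x samples, finite and
#'   non-negative, with dimensions matching `annotation` and `samples`.
#' @param truth optional simulation ground truth (see [simulate_experiment()]).
#' @return object of class `ExperimentSet`.
#' @export
experiment_set <- function(annotation, samples, af3, af5, truth = NULL) {
  annotation <- .complete_annotation(annotation)
  samples <- .complete_samples(samples)
  af3 <- as.matrix(af3)
  af5 <- as.matrix(af5)
  storage.mode(af3) <- "double"
  storage.mode(af5) <- "double"
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe_id in annotation", call. = FALSE)
  if (anyDuplicated(paste(samples$group, samples$replicate, sep = "\r")))
    stop("(group, replicate) pairs must be unique", call. = FALSE)
  for (nm in c("af3", "af5")) {
    m <- get(nm)
    if (nrow(m) != nrow(annotation) || ncol(m) != nrow(samples))
      stop(sprintf("dimension mismatch: %s is %dx%d but annotation has %d probes and metadata %d samples",
                   nm, nrow(m), ncol(m), nrow(annotation), nrow(samples)),
           call. = FALSE)
    if (any(!is.finite(m)))
      stop(sprintf("non-finite signal in %s", nm), call. = FALSE)
    if (any(m < 0))
      stop(sprintf("negative signal in %s", nm), call. = FALSE)
  }
  dimnames(af3) <- dimnames(af5) <- list(annotation$probe_id, samples$sample_id)
  structure(list(annotation = annotation, samples = samples,
                 af3 = af3, af5 = af5, truth = truth),
            class = "ExperimentSet")
}

.complete_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (is.null(annotation$probe_id)) stop("annotation needs probe_id", call. = FALSE)
  annotation$probe_id <- as.character(annotation$probe_id)
  if (is.null(annotation$gene_symbol)) annotation$gene_symbol <- ""
  annotation$gene_symbol[is.na(annotation$gene_symbol)] <- ""
  if (is.null(annotation$is_control)) annotation$is_control <- FALSE
  annotation$is_control <- as.logical(annotation$is_control)
  rownames(annotation) <- NULL
  annotation[c("probe_id", "gene_symbol", "is_control")]
}

.complete_samples <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "day", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  samples$day <- as.character(samples$day)
  samples$replicate <- as.integer(samples$replicate)
  if (any(samples$replicate < 1L)) stop("replicate must be >= 1", call. = FALSE)
  if (is.null(samples$qc_excluded)) samples$qc_excluded <- FALSE
  if (is.null(samples$qc_reason)) samples$qc_reason <- ""
  samples$qc_reason[is.na(samples$qc_reason)] <- ""
  if (any(samples$qc_excluded & !nzchar(samples$qc_reason)))
    stop("excluded samples must carry a non-empty qc_reason", call. = FALSE)
  rownames(samples) <- NULL
  samples[c("sample_id", "group", "day", "replicate", "qc_excluded", "qc_reason")]
}

#' @export
print.ExperimentSet <- function(x, ...) {
  cat(sprintf("ExperimentSet: %d probes x %d samples (%d control probes)\n",
              nrow(x$af3), ncol(x$af3), sum(x$annotation$is_control)))
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  if (!is.null(x$truth)) cat("simulation truth attached\n")
  invisible(x)
}

# full-precision numeric formatting so write/read round-trips are exact
.fmt_num <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Read a two-color array experiment from TSV tables
#'
#' @param signal_path path to the signal table: `probe_id`, optional
#'   `gene_symbol` / `is_control`, then `<sample>_AF3` and `<sample>_AF5`
#'   column pairs.  Probe and sample order are preserved as written.
#' @param meta_path path to the sample metadata table, one row per sample.
#' @return an [experiment_set()].
#' @export
read_experiment <- function(signal_path, meta_path) {
  sig <- utils::read.delim(signal_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(sig))
    stop("signal table lacks probe_id column", call. = FALSE)
  if (anyDuplicated(sig$probe_id))
    stop("duplicate probe_id in signal table", call. = FALSE)
  af3_cols <- grep("_AF3$", names(sig), value = TRUE)
  af5_cols <- grep("_AF5$", names(sig), value = TRUE)
  s3 <- sub("_AF3$", "", af3_cols)
  s5 <- sub("_AF5$", "", af5_cols)
  if (!setequal(s3, s5))
    stop("unpaired AF3/AF5 columns: ", paste(c(setdiff(s3, s5), setdiff(s5, s3)),
                                             collapse = ", "), call. = FALSE)
  unknown <- setdiff(s3, meta$sample_id)
  if (length(unknown))
    stop("samples in signal table missing from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing_sig <- setdiff(meta$sample_id, s3)
  if (length(missing_sig))
    stop("samples in metadata missing from signal table: ",
         paste(missing_sig, collapse = ", "), call. = FALSE)
  meta <- meta[match(s3, meta$sample_id), , drop = FALSE]  # signal-table order
  af3 <- as.matrix(sig[paste0(s3, "_AF3")])
  af5 <- as.matrix(sig[paste0(s3, "_AF5")])
  ann <- sig[intersect(c("probe_id", "gene_symbol", "is_control"), names(sig))]
  experiment_set(ann, meta, af3, af5)
}

#' Write an ExperimentSet as TSV tables
#'
#' Inverse of [read_experiment()]; signals are written at full precision so
#' the round-trip reproduces every value exactly.
#'
#' @param es ExperimentSet.
#' @param signal_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_experiment <- function(es, signal_path, meta_path) {
  stopifnot(inherits(es, "ExperimentSet"))
  sam <- es$samples$sample_id
  tab <- es$annotation
  for (s in sam) {
    tab[[paste0(s, "_AF3")]] <- .fmt_num(es$af3[, s])
    tab[[paste0(s, "_AF5")]] <- .fmt_num(es$af5[, s])
  }
  utils::write.table(tab, signal_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(es$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(signal_path, meta_path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' member...`.  Duplicate member symbols within a line are collapsed.
#'
#' @param path path to the GMT file.
#' @return named list of gene sets, each a list with elements `name`,
#'   `description` and `members` (character vector, unique).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields", i),
           call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT parse error at line %d: gene set has no members", i),
           call. = FALSE)
    sets[[i]] <- list(name = f[[1]], description = f[[2]], members = members)
    nm[i] <- f[[1]]
  }
  if (anyDuplicated(nm))
    stop("duplicate gene-set names in GMT file", call. = FALSE)
  names(sets) <- nm
  sets
}

#' Write a matrix as a TSV report at full numeric precision
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_name header for the row-name column.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_name = "probe_id") {
  df <- data.frame(rownames(m), apply(m, 2, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_name, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
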