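# Shared fixtures: reduced-size simulation configs and hand-built
# normalized sets, so tests stay fast (<= 2000 probes).

tiny_config <- function(n_probes = 400, seed = 1L, ...) {
  sim_config(n_probes = n_probes,
             groups = data.frame(cell_count = c(1L, 5L, 10L),
                                 n_replicates = 4L),
             seed = seed, ...)
}

# noise-free world: every captured transcript is individually detectable
# (gain above the 300 detection threshold) and the background floor is off
noise_free_config <- function(n_probes = 400, seed = 1L, ...) {
  sim_config(n_probes = n_probes,
             groups = data.frame(cell_count = c(1L, 10L),
                                 n_replicates = 4L),
             capture_prob = 1, noise_logsd = 0,
             nonspecific_floor_mean = 0, nonspecific_floor_sd = 0,
             day_shift_af3 = 0, day_shift_af5 = 0,
             gain = 1000, abundance_logmean = log(20), abundance_logsd = 1,
             seed = seed, ...)
}

# build a NormalizedSet-shaped object directly from an af3/af5 pair, for
# unit tests that target the statistics rather than the normalization
manual_ns <- function(af3, af5 = NULL, groups = NULL, gene_symbol = NULL,
                      is_control = NULL) {
  P <- nrow(af3); S <- ncol(af3)
  if (is.null(af5)) af5 <- matrix(100, P, S)
  if (is.null(groups)) groups <- rep("g", S)
  probe_id <- if (is.null(rownames(af3))) sprintf("P%03d", seq_len(P)) else rownames(af3)
  sample_id <- if (is.null(colnames(af3))) sprintf("s%02d", seq_len(S)) else colnames(af3)
  if (is.null(gene_symbol)) gene_symbol <- paste0("G_", probe_id)
  if (is.null(is_control)) is_control <- rep(FALSE, P)
  dimnames(af3) <- dimnames(af5) <- list(probe_id, sample_id)
  structure(list(
    annotation = data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                            is_control = is_control, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_id, group = groups,
                         day = "1", replicate = seq_len(S),
                         qc_excluded = FALSE, qc_reason = "",
                         stringsAsFactors = FALSE),
    af3 = af3, af5 = af5,
    M = log2(af3) - log2(af5), A = 0.5 * (log2(af3) + log2(af5)),
    truth = NULL, provenance = list()), class = "NormalizedSet")
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

local_gmt_for <- function(es, n_sets = 3, size = 15, env = parent.frame()) {
  genes <- es$annotation$gene_symbol[nzchar(es$annotation$gene_symbol)]
  set.seed(1)
  lines <- vapply(seq_len(n_sets), function(i)
    paste(c(sprintf("set%d", i), "toy", sample(genes, size)), collapse = "\t"),
    "")
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = env)
  writeLines(lines, path)
  path
}
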