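# Seeded generators for synthetic low-input amplification experiments:
# two-color array sets with ground truth, triplicate qPCR plates, and toy
# Bioanalyzer electropherogram traces.

#' Simulation configuration
#'
#' Describes the generative model for a low-input two-color array
#' experiment.  Each truly expressed probe g has a reference abundance
#' lambda_g drawn log-normally; a sample amplified from k cells draws a
#' transcript count ~ Poisson(k * lambda_g * 2^delta_g) — delta_g being
#' the probe's true log2 sample-vs-reference ratio — each transcript survives
#' capture/amplification independently with probability `capture_prob`,
#' and the sample-channel signal is
#' `gain * captured_count * lognormal_noise + background_floor + day_shift`.
#' Unexpressed probes receive floor-only signal, so dropout worsens as the
#' number of input cells decreases and low-abundance transcripts drop out
#' first.  The reference channel measures the pooled reference
#' (`gain * lambda_g * noise + floor`) and is shared across arrays.
#'
#' Defaults target the scale of a 4x44K array study: 38,695 probes,
#' ten replicates each of 1-, 5- and 10-cell pools split over two
#' experimental days, with a background floor well below the detection
#' threshold of 300 and roughly two thirds of probes expressed.
#'
#' @param n_probes number of probes on the platform.
#' @param groups data.frame with columns `cell_count`, `n_replicates`.
#' @param days function mapping replicate index and group size to a day
#'   label, or NULL for the default (first half day "1", rest day "2").
#' @param abundance_logmean,abundance_logsd log-normal parameters of
#'   per-probe reference abundance (transcripts per cell).
#' @param frac_expressed fraction of probes truly expressed.
#' @param sample_ratio_log2sd sd of the per-probe true log2
#'   sample-vs-reference expression ratio.  The sampled cells are not the
#'   reference pool, so each expressed probe carries a true M-ratio
#'   delta_g ~ N(0, sd), shared by every cell-count group; this is the
#'   structure the M-ratio concordance statistics measure.
#' @param capture_prob per-transcript capture probability per cell.
#' @param gain linear signal units per captured transcript.
#' @param nonspecific_floor_mean,nonspecific_floor_sd additive background
#'   signal (truncated at 0).
#' @param day_shift_af3,day_shift_af5 additive signal offsets applied to
#'   day-2 arrays, per channel.
#' @param noise_logsd sd of multiplicative lognormal measurement noise.
#' @param frac_control fraction of probes annotated as controls.
#' @param seed integer; fully determines the output.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_probes = 38695L,
                       groups = data.frame(cell_count = c(1L, 5L, 10L),
                                           n_replicates = 10L),
                       days = NULL,
                       abundance_logmean = log(10),
                       abundance_logsd = 1.6,
                       frac_expressed = 0.64,
                       sample_ratio_log2sd = 1.0,
                       capture_prob = 0.3,
                       gain = 100,
                       nonspecific_floor_mean = 50,
                       nonspecific_floor_sd = 15,
                       day_shift_af3 = 30,
                       day_shift_af5 = 20,
                       noise_logsd = 0.25,
                       frac_control = 0.01,
                       seed = 1L) {
  stopifnot(n_probes >= 1, nrow(groups) >= 1,
            all(groups$cell_count >= 1), all(groups$n_replicates >= 1),
            frac_expressed >= 0, frac_expressed <= 1,
            sample_ratio_log2sd >= 0,
            capture_prob >= 0, capture_prob <= 1,
            frac_control >= 0, frac_control < 1,
            gain > 0, noise_logsd >= 0,
            nonspecific_floor_mean >= 0, nonspecific_floor_sd >= 0)
  structure(list(n_probes = as.integer(n_probes), groups = groups, days = days,
                 abundance_logmean = abundance_logmean,
                 abundance_logsd = abundance_logsd,
                 frac_expressed = frac_expressed,
                 sample_ratio_log2sd = sample_ratio_log2sd,
                 capture_prob = capture_prob,
                 gain = gain,
                 nonspecific_floor_mean = nonspecific_floor_mean,
                 nonspecific_floor_sd = nonspecific_floor_sd,
                 day_shift_af3 = day_shift_af3, day_shift_af5 = day_shift_af5,
                 noise_logsd = noise_logsd, frac_control = frac_control,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

.default_days <- function(rep_idx, n_rep) {
  ifelse(rep_idx <= ceiling(n_rep / 2), "1", "2")
}

#' Simulate a two-color array experiment with ground truth
#'
#' See [sim_config()] for the generative model.  The returned
#' `ExperimentSet` carries a `truth` element with `expressed`
#' (probe x group), `captured` (probe x sample, TRUE when at least one
#' transcript survived capture), `true_abundance` (per-probe lambda,
#' 0 for unexpressed probes) and `true_m` (per-probe true log2
#' sample-vs-reference ratio).
#'
#' @param config a [sim_config()].
#' @return an [experiment_set()] with simulation truth attached.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  P <- config$n_probes
  probe_id <- sprintf("P%05d", seq_len(P))
  n_ctrl <- floor(config$frac_control * P)
  is_control <- rep(FALSE, P)
  if (n_ctrl > 0) is_control[sample.int(P, n_ctrl)] <- TRUE
  gene_symbol <- ifelse(is_control, "", sprintf("GENE%05d", seq_len(P)))

  expressed_vec <- rep(FALSE, P)
  candidates <- which(!is_control)
  n_expr <- round(config$frac_expressed * length(candidates))
  if (n_expr > 0) expressed_vec[sample(candidates, n_expr)] <- TRUE
  lambda <- numeric(P)
  lambda[expressed_vec] <- stats::rlnorm(n_expr, config$abundance_logmean,
                                         config$abundance_logsd)
  # true per-probe log2 sample-vs-reference ratio, shared across groups
  delta <- numeric(P)
  delta[expressed_vec] <- stats::rnorm(n_expr, 0, config$sample_ratio_log2sd)
  lambda_sample <- lambda * 2^delta

  groups <- config$groups
  day_fun <- if (is.null(config$days)) .default_days else config$days
  meta <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    k <- groups$cell_count[i]; R <- groups$n_replicates[i]
    data.frame(sample_id = sprintf("c%d_r%02d", k, seq_len(R)),
               group = as.character(k), day = day_fun(seq_len(R), R),
               replicate = seq_len(R), stringsAsFactors = FALSE)
  }))
  S <- nrow(meta)

  af3 <- matrix(0, P, S)
  af5 <- matrix(0, P, S)
  captured <- matrix(FALSE, P, S)
  floor_draw <- function(n) pmax(0, stats::rnorm(n, config$nonspecific_floor_mean,
                                                 config$nonspecific_floor_sd))
  lnoise <- function(n) {
    if (config$noise_logsd == 0) rep(1, n)
    else stats::rlnorm(n, 0, config$noise_logsd)
  }
  for (j in seq_len(S)) {
    k <- as.integer(meta$group[j])
    counts <- integer(P)
    idx <- which(expressed_vec)
    raw <- stats::rpois(length(idx), k * lambda_sample[idx])
    kept <- if (config$capture_prob >= 1) raw
            else stats::rbinom(length(idx), raw, config$capture_prob)
    counts[idx] <- kept
    captured[idx, j] <- kept > 0
    shift <- if (meta$day[j] == "2") config$day_shift_af3 else 0
    af3[, j] <- config$gain * counts * lnoise(P) + floor_draw(P) + shift
  }
  # shared reference channel: pooled reference abundance, same for every array
  for (j in seq_len(S)) {
    shift5 <- if (meta$day[j] == "2") config$day_shift_af5 else 0
    af5[, j] <- config$gain * lambda * lnoise(P) + floor_draw(P) + shift5
  }

  expressed <- matrix(expressed_vec, P, nrow(groups),
                      dimnames = list(probe_id, as.character(groups$cell_count)))
  dimnames(captured) <- list(probe_id, meta$sample_id)
  truth <- list(expressed = expressed, captured = captured,
                true_abundance = stats::setNames(lambda, probe_id),
                true_m = stats::setNames(delta, probe_id))
  experiment_set(data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                            is_control = is_control, stringsAsFactors = FALSE),
                 meta, af3, af5, truth = truth)
}

#' Simulate a triplicate qPCR plate
#'
#' Each (sample, gene) gets three Cq draws,
#' `Cq = cq_base - log2(captured abundance) + N(0, cq_noise_sd)`, where
#' the captured abundance is `cell_count * abundance * capture_prob`
#' (so with zero noise, halving the abundance raises Cq by exactly one
#' cycle).  Whether a reaction amplifies at all is stochastic: a
#' Poisson-binomial capture draw of zero transcripts, or a Cq beyond
#' `max_cycles`, is marked not-amplified (`NA`).
#'
#' @param config a [sim_config()]; its groups define the samples and its
#'   capture model the per-sample captured abundance.
#' @param genes character vector of gene names; must include the reference
#'   housekeeping gene `RPL13A`.
#' @param seed integer seed.
#' @param abundance optional named per-gene abundance (transcripts per
#'   cell); defaults to log-normal draws from the config parameters.
#' @param cq_base Cq of one captured transcript unit.
#' @param cq_noise_sd replicate noise sd in cycles.
#' @param max_cycles reactions are called not-amplified beyond this cycle.
#' @return a `QPCRPlate` data.frame (sample_id, group, gene, rep, cq) with
#'   `NA` cq meaning no amplification; attribute `max_cycles`.
#' @export
simulate_qpcr <- function(config, genes, seed = config$seed,
                          abundance = NULL, cq_base = 30,
                          cq_noise_sd = 0.2, max_cycles = 46L) {
  stopifnot(inherits(config, "SimConfig"), "RPL13A" %in% genes)
  set.seed(seed)
  if (is.null(abundance)) {
    abundance <- stats::setNames(
      stats::rlnorm(length(genes), config$abundance_logmean,
                    config$abundance_logsd), genes)
  }
  stopifnot(all(genes %in% names(abundance)))
  groups <- config$groups
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    k <- groups$cell_count[i]
    for (r in seq_len(groups$n_replicates[i])) {
      sample_id <- sprintf("c%d_r%02d", k, r)
      for (g in genes) {
        raw <- stats::rpois(1, k * abundance[[g]])
        kept <- stats::rbinom(1, raw, config$capture_prob)
        if (kept == 0) {
          cq <- rep(NA_real_, 3)
        } else {
          cq <- cq_base - log2(k * abundance[[g]] * config$capture_prob) +
            (if (cq_noise_sd == 0) rep(0, 3) else stats::rnorm(3, 0, cq_noise_sd))
          cq[cq > max_cycles] <- NA_real_
        }
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = sample_id, group = as.character(k),
                     gene = g, rep = 1:3, cq = cq, stringsAsFactors = FALSE)
      }
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  attr(plate, "max_cycles") <- as.integer(max_cycles)
  class(plate) <- c("QPCRPlate", "data.frame")
  plate
}

#' Simulate a Bioanalyzer electropherogram trace
#'
#' Produces a smooth unimodal fluorescence trace over a fragment-size (nt)
#' grid: a Gaussian bump centred near `mean_nt` with a small seeded
#' asymmetry, suitable as input for [mean_fragment_size()].
#'
#' @param mean_nt centre of the fragment-size distribution (nt), > 0.
#' @param spread_nt spread of the bump (nt).
#' @param seed integer seed (controls the slight asymmetry).
#' @return list with `size_nt` (increasing grid) and `fluorescence`,
#'   class `Electropherogram`.
#' @export
simulate_electropherogram <- function(mean_nt, spread_nt = mean_nt / 4,
                                      seed = 1L) {
  stopifnot(mean_nt > 0, spread_nt > 0)
  set.seed(seed)
  skew <- stats::runif(1, -0.3, 0.3)
  grid <- seq(max(1, mean_nt - 5 * spread_nt), mean_nt + 5 * spread_nt,
              length.out = 512)
  z <- (grid - mean_nt) / spread_nt
  fl <- exp(-z^2 / 2) * (1 + skew * tanh(z / 2))
  fl[fl < 0] <- 0
  structure(list(size_nt = grid, fluorescence = fl),
            class = "Electropherogram")
}
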