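#' Synthetic luminometer and RNA-seq generators
#'
#' The generators in this file emulate the statistical structure of the raw
#' inputs the analysis pipeline consumes: oscillatory reporter traces with
#' drift, damping and noise; biphasic protein-decay traces (a transient
#' plateau from residual mRNA followed by single-exponential decay); dual
#' phase-shifted reporter pairs; and a multi-species negative-binomial count
#' matrix with planted period-correlated gene modules. Every generator is
#' deterministic under a fixed seed, and in the noiseless limit is exactly
#' recovered by its matched estimator (up to grid resolution), which is the
#' basis of the closed-loop tests.
#'
#' @name synthetic
NULL

# run expr under a temporary, isolated RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Specification of a synthetic oscillation trace
#'
#' Parameters of a damped, drifting, noisy cosine emulating a normalized HES7
#' reporter recording. The duration must span at least three full cycles and
#' the sampling interval must resolve the period with a Nyquist margin
#' (`dt <= period / 6`).
#'
#' @param period Oscillation period in minutes (> 0).
#' @param duration Total recording length in minutes.
#' @param dt Sampling interval in minutes; 10 by default (plate-luminometer
#'   cadence, >12 samples per cycle even at the fastest 122-min clock).
#' @param amplitude Oscillation amplitude in arbitrary units.
#' @param baseline Constant signal offset.
#' @param drift_slope Linear trend, units per minute.
#' @param damping_rate Exponential envelope decay, 1/min (>= 0).
#' @param noise_sd Additive Gaussian noise SD as a fraction of `amplitude`.
#' @param phase0 Initial phase in radians.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `osc_trace_spec`.
#' @export
osc_trace_spec <- function(period, duration, dt = 10, amplitude = 1,
                           baseline = 0, drift_slope = 0, damping_rate = 0,
                           noise_sd = 0, phase0 = 0, seed = 0L) {
  if (!is.finite(period) || period <= 0) stop("`period` must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (duration < 3 * period) stop("`duration` must cover at least 3 periods", call. = FALSE)
  if (dt > period / 6) stop("`dt` must be <= period / 6", call. = FALSE)
  if (damping_rate < 0 || noise_sd < 0) stop("rates and noise must be >= 0", call. = FALSE)
  structure(
    list(
      period = period, duration = duration, dt = dt, amplitude = amplitude,
      baseline = baseline, drift_slope = drift_slope,
      damping_rate = damping_rate, noise_sd = noise_sd, phase0 = phase0,
      seed = seed
    ),
    class = "osc_trace_spec"
  )
}

osc_deterministic <- function(spec, time, lag = 0) {
  t0 <- time - lag
  spec$baseline + spec$drift_slope * t0 +
    spec$amplitude * exp(-spec$damping_rate * t0) *
      cos(2 * pi * t0 / spec$period + spec$phase0)
}

#' Generate a synthetic oscillation trace
#'
#' @param spec An [osc_trace_spec()].
#' @return A [lum_trace()].
#' @export
#' @examples
#' tr <- gen_oscillation_trace(osc_trace_spec(period = 153, duration = 2880))
gen_oscillation_trace <- function(spec) {
  stopifnot(inherits(spec, "osc_trace_spec"))
  time <- seq(0, spec$duration, by = spec$dt)
  det <- osc_deterministic(spec, time)
  noise <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, stats::rnorm(length(time), 0, spec$noise_sd * spec$amplitude))
  } else {
    0
  }
  lum_trace(time, det + noise)
}

#' Specification of a synthetic biphasic decay trace
#'
#' Models the protein-degradation assay readout: the reporter signal holds a
#' plateau while residual mRNA is still translated, then decays as a single
#' exponential once translation stops. Noise is multiplicative lognormal
#' because luminescence is strictly positive. The observable decay phase must
#' span at least four half-lives.
#'
#' @param halflife Protein half-life in minutes (> 0).
#' @param duration Total recording length in minutes.
#' @param plateau_min Pre-decay plateau length in minutes.
#' @param dt Sampling interval in minutes.
#' @param s0 Plateau signal level.
#' @param noise_sd Lognormal sigma (multiplicative noise fraction).
#' @param seed Integer seed.
#' @return A list of class `decay_trace_spec`.
#' @export
decay_trace_spec <- function(halflife, duration, plateau_min = 0, dt = 10,
                             s0 = 1000, noise_sd = 0, seed = 0L) {
  if (!is.finite(halflife) || halflife <= 0) stop("`halflife` must be > 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (duration - plateau_min < 4 * halflife) {
    stop("decay phase must span at least 4 half-lives", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(
      halflife = halflife, duration = duration, plateau_min = plateau_min,
      dt = dt, s0 = s0, noise_sd = noise_sd, seed = seed
    ),
    class = "decay_trace_spec"
  )
}

#' Generate a synthetic biphasic decay trace
#'
#' @param spec A [decay_trace_spec()].
#' @return A strictly positive [lum_trace()].
#' @export
gen_decay_trace <- function(spec) {
  stopifnot(inherits(spec, "decay_trace_spec"))
  time <- seq(0, spec$duration, by = spec$dt)
  det <- ifelse(
    time <= spec$plateau_min,
    spec$s0,
    spec$s0 * 2^(-(time - spec$plateau_min) / spec$halflife)
  )
  mult <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, stats::rlnorm(length(time), 0, spec$noise_sd))
  } else {
    1
  }
  lum_trace(time, det * mult)
}

#' Specification of a dual-reporter (intron delay) trace pair
#'
#' Emulates simultaneous recording of an intronless and an intron-containing
#' clock reporter: channel B equals channel A's deterministic part shifted
#' later by `lag` minutes, with independent noise per channel. The lag must be
#' smaller than the period so the delay is identifiable without phase
#' wrapping.
#'
#' @param period,duration,dt,amplitude,baseline,drift_slope,damping_rate,noise_sd,phase0
#'   As in [osc_trace_spec()].
#' @param lag Phase delay of channel B in minutes (>= 0, < period).
#' @param seed Integer seed (channel noise draws derive from it).
#' @return A list of class `dual_reporter_spec`.
#' @export
dual_reporter_spec <- function(period, duration, lag, dt = 10, amplitude = 1,
                               baseline = 0, drift_slope = 0,
                               damping_rate = 0, noise_sd = 0, phase0 = 0,
                               seed = 0L) {
  if (lag < 0) stop("`lag` must be >= 0", call. = FALSE)
  if (lag >= period) stop("`lag` must be < period (identifiability)", call. = FALSE)
  base <- osc_trace_spec(
    period = period, duration = duration, dt = dt, amplitude = amplitude,
    baseline = baseline, drift_slope = drift_slope,
    damping_rate = damping_rate, noise_sd = noise_sd, phase0 = phase0,
    seed = seed
  )
  base$lag <- lag
  class(base) <- c("dual_reporter_spec", "osc_trace_spec")
  base
}

#' Generate a dual-reporter trace pair
#'
#' @param spec A [dual_reporter_spec()].
#' @return A list with elements `without_intron` and `with_intron`, both
#'   [lum_trace()] objects on the same time grid.
#' @export
gen_dual_reporter <- function(spec) {
  stopifnot(inherits(spec, "dual_reporter_spec"))
  time <- seq(0, spec$duration, by = spec$dt)
  det_a <- osc_deterministic(spec, time)
  det_b <- osc_deterministic(spec, time, lag = spec$lag)
  if (spec$noise_sd > 0) {
    noise <- with_seed(
      spec$seed,
      matrix(stats::rnorm(2L * length(time), 0, spec$noise_sd * spec$amplitude), ncol = 2L)
    )
    det_a <- det_a + noise[, 1L]
    det_b <- det_b + noise[, 2L]
  }
  list(
    without_intron = lum_trace(time, det_a),
    with_intron = lum_trace(time, det_b)
  )
}

#' Specification of a planted cross-species expression simulation
#'
#' Generates gene-level negative-binomial counts for `n_species` species
#' (2 tissues x `n_replicates` each by default, mirroring a PSC/iPSM bulk
#' design) with a one-to-one ortholog map. A subset of genes is planted with
#' log2 mean expression strictly monotone in the species' clock-period rank:
#' `n_neg_corr` decreasing (higher in faster species) and `n_pos_corr`
#' increasing. `effect_size` is the log2 fold-change between adjacent period
#' ranks, so a planted gene spans `effect_size * (n_species - 1)` log2 units
#' overall. Remaining genes are period-independent.
#'
#' @param periods Numeric vector of species clock periods (minutes); its
#'   length sets the number of species.
#' @param n_genes Total number of orthologous genes.
#' @param n_neg_corr,n_pos_corr Numbers of planted anticorrelated /
#'   correlated genes.
#' @param effect_size Log2 fold-change per adjacent period rank (> 0 when any
#'   genes are planted).
#' @param dispersion Negative-binomial dispersion (edgeR parameterization;
#'   variance = mu + dispersion * mu^2).
#' @param gene_length_range Range of simulated gene lengths in bp.
#' @param libsize_range Range of per-sample library-size factors (relative).
#' @param n_replicates Replicates per species per tissue.
#' @param tissues Tissue labels.
#' @param base_log2_range Range of baseline log2 mean counts per gene.
#' @param seed Integer seed.
#' @return A list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(periods = c(
                                  mouse = 122, rabbit = 153, rhinoceros = 236,
                                  cattle = 238, human = 322, marmoset = 388
                                ),
                                n_genes = 2000, n_neg_corr = 100,
                                n_pos_corr = 100, effect_size = 2,
                                dispersion = 0.1,
                                gene_length_range = c(500, 10000),
                                libsize_range = c(0.7, 1.3),
                                n_replicates = 2,
                                tissues = c("iPSM", "PSC"),
                                base_log2_range = c(4, 10),
                                seed = 0L) {
  if (n_neg_corr + n_pos_corr > n_genes) {
    stop("planted genes cannot exceed `n_genes`", call. = FALSE)
  }
  if ((n_neg_corr + n_pos_corr) > 0 && effect_size <= 0) {
    stop("`effect_size` must be > 0 when planted genes are requested", call. = FALSE)
  }
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)
  if (is.null(names(periods))) {
    names(periods) <- paste0("species", seq_along(periods))
  }
  structure(
    list(
      periods = periods, n_species = length(periods), n_genes = n_genes,
      n_neg_corr = n_neg_corr, n_pos_corr = n_pos_corr,
      effect_size = effect_size, dispersion = dispersion,
      gene_length_range = gene_length_range, libsize_range = libsize_range,
      n_replicates = n_replicates, tissues = tissues,
      base_log2_range = base_log2_range, seed = seed
    ),
    class = "expression_sim_spec"
  )
}

#' Generate a planted multi-species count matrix
#'
#' @param spec An [expression_sim_spec()].
#' @return A list with:
#'   \describe{
#'     \item{counts}{integer matrix, genes (human anchor ids) x samples}
#'     \item{lengths}{named vector of gene lengths (bp)}
#'     \item{metadata}{data frame of sample, species, tissue, replicate,
#'       period}
#'     \item{ortholog_map}{data frame (species, gene_id, human_anchor_id),
#'       one-to-one across all species}
#'     \item{truth}{data frame (gene, class) with class in
#'       negative/positive/null}
#'   }
#' @export
gen_expression_matrix <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_species
    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    cls <- rep("null", spec$n_genes)
    if (spec$n_neg_corr > 0) cls[seq_len(spec$n_neg_corr)] <- "negative"
    if (spec$n_pos_corr > 0) {
      cls[spec$n_neg_corr + seq_len(spec$n_pos_corr)] <- "positive"
    }
    # period rank 1 = fastest species; planted effects are linear in rank
    rnk <- rank(spec$periods, ties.method = "first")
    base <- stats::runif(spec$n_genes, spec$base_log2_range[1L], spec$base_log2_range[2L])
    # genes x species log2 mean expression, centered on the baseline
    eff <- matrix(0, spec$n_genes, ns)
    centered <- (rnk - mean(rnk)) * spec$effect_size
    if (any(cls == "negative")) {
      eff[cls == "negative", ] <- matrix(-centered, sum(cls == "negative"), ns, byrow = TRUE)
    }
    if (any(cls == "positive")) {
      eff[cls == "positive", ] <- matrix(centered, sum(cls == "positive"), ns, byrow = TRUE)
    }
    log2mu <- base + eff

    lengths <- round(stats::runif(spec$n_genes, spec$gene_length_range[1L], spec$gene_length_range[2L]))
    names(lengths) <- genes

    meta <- expand.grid(
      replicate = seq_len(spec$n_replicates),
      tissue = spec$tissues,
      species = names(spec$periods),
      stringsAsFactors = FALSE
    )
    meta$period <- spec$periods[meta$species]
    meta$sample <- sprintf("%s_%s_r%d", meta$species, meta$tissue, meta$replicate)
    meta <- meta[, c("sample", "species", "tissue", "replicate", "period")]

    libfac <- stats::runif(nrow(meta), spec$libsize_range[1L], spec$libsize_range[2L])
    counts <- matrix(0L, spec$n_genes, nrow(meta), dimnames = list(genes, meta$sample))
    for (j in seq_len(nrow(meta))) {
      sp_idx <- match(meta$species[j], names(spec$periods))
      # expected count ~ expression x gene length x sequencing depth
      mu <- 2^log2mu[, sp_idx] * (lengths / 1000) * libfac[j]
      counts[, j] <- if (spec$dispersion > 0) {
        stats::rnbinom(spec$n_genes, mu = mu, size = 1 / spec$dispersion)
      } else {
        stats::rpois(spec$n_genes, mu)
      }
    }

    omap <- do.call(rbind, lapply(names(spec$periods), function(sp) {
      data.frame(
        species = sp,
        gene_id = paste0(substr(sp, 1L, 3L), "_", genes),
        human_anchor_id = genes,
        stringsAsFactors = FALSE
      )
    }))

    list(
      counts = counts,
      lengths = lengths,
      metadata = meta,
      ortholog_map = omap,
      truth = data.frame(gene = genes, class = cls, stringsAsFactors = FALSE)
    )
  })
}
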