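#' Glue per-species count matrices by one-to-one human-anchored orthology
#'
#' Assembles a single cross-species count matrix keyed by human anchor gene
#' ids. Only genes with a one-to-one ortholog in every species survive: an
#' anchor appearing more than once within a species violates the map, and an
#' anchor missing from any species' counts is dropped (and counted).
#'
#' @param counts_by_species Named list (species -> count matrix with
#'   species-local gene ids as rownames).
#' @param map Ortholog map data frame with columns `species`, `gene_id`,
#'   `human_anchor_id`, and optionally `relationship`; when the relationship
#'   column is present, rows not labelled `"one2one"` (e.g. one-to-many) are
#'   discarded before gluing.
#' @return A matrix of counts, rows = human anchor ids shared by all
#'   species, columns = all samples; attribute `n_dropped` records anchors
#'   lost to incomplete orthology.
#' @export
glue_orthologs <- function(counts_by_species, map) {
  stopifnot(all(c("species", "gene_id", "human_anchor_id") %in% names(map)))
  if ("relationship" %in% names(map)) {
    map <- map[map$relationship == "one2one", , drop = FALSE]
  }
  species <- names(counts_by_species)
  if (is.null(species) || !all(species %in% map$species)) {
    stop("every species in `counts_by_species` must appear in the map", call. = FALSE)
  }
  per_species <- lapply(species, function(sp) {
    sub <- map[map$species == sp, , drop = FALSE]
    if (anyDuplicated(sub$human_anchor_id)) {
      stop(sprintf("ortholog map violation: duplicate anchor within species '%s'", sp),
           call. = FALSE)
    }
    cm <- counts_by_species[[sp]]
    sub <- sub[sub$gene_id %in% rownames(cm), , drop = FALSE]
    block <- cm[sub$gene_id, , drop = FALSE]
    rownames(block) <- sub$human_anchor_id
    block
  })
  shared <- Reduce(intersect, lapply(per_species, rownames))
  all_anchors <- unique(map$human_anchor_id)
  n_dropped <- length(all_anchors) - length(shared)
  if (!length(shared)) {
    warning("no anchors shared across all species; empty matrix returned")
    out <- matrix(0L, 0L, sum(vapply(per_species, ncol, integer(1L))))
  } else {
    out <- do.call(cbind, lapply(per_species, function(b) b[shared, , drop = FALSE]))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Reads per kilobase
#'
#' Divides each gene's counts by its length in kilobases.
#'
#' @param counts Count matrix (genes x samples).
#' @param lengths Gene lengths in bp, named by gene or in row order.
#' @return RPK matrix.
#' @export
rpk <- function(counts, lengths) {
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) {
    stop("`lengths` must match the rows of `counts`", call. = FALSE)
  }
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  counts / (lengths / 1000)
}

#' Trimmed mean of M-values scaling factors
#'
#' Per-sample TMM normalization factors computed against a reference sample
#' (the sample whose upper-quartile expression is closest to the mean upper
#' quartile). For each sample, gene-wise log2 expression ratios M (of
#' library-size-scaled proportions) and average log2 abundances A are
#' computed on genes expressed in both; the 30% most extreme M values and 5%
#' most extreme A values on each side are trimmed, and the factor is 2 to
#' the mean of the surviving M values. Factors are renormalized to geometric
#' mean 1.
#'
#' By default the trimmed mean is unweighted, which makes the factors — and
#' hence the whole GeTMM pipeline — exactly invariant to rescaling any
#' sample's library (proportions, M, A and the trim set are all unchanged).
#' `weighted = TRUE` switches to the precision-weighted mean (inverse
#' delta-method asymptotic variance of M), reproducing
#' `edgeR::calcNormFactors()` to machine precision; because those weights
#' depend on absolute counts, the weighted factors shift slightly (order
#' 0.5-1%) when a library is rescaled.
#'
#' @param x Matrix of non-negative expression values (counts or RPK), genes
#'   x samples, >= 2 samples.
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @param weighted Use delta-method precision weights (edgeR-compatible)
#'   instead of the unweighted trimmed mean.
#' @return Named vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05, weighted = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  lib <- colSums(x)
  if (any(lib == 0)) stop("all-zero sample encountered", call. = FALSE)
  uq <- apply(x, 2L, function(col) stats::quantile(col[col > 0], 0.75)) / lib
  ref_j <- which.min(abs(uq - mean(uq)))
  ref <- x[, ref_j]
  f <- vapply(seq_len(ncol(x)), function(j) {
    obs <- x[, j]
    ok <- obs > 0 & ref > 0
    if (!any(ok)) return(NA_real_)
    p_o <- obs[ok] / lib[j]
    p_r <- ref[ok] / lib[ref_j]
    m <- log2(p_o / p_r)
    a <- 0.5 * log2(p_o * p_r)
    # asymptotic (delta-method) variance of M for count data
    w <- (lib[j] - obs[ok]) / (lib[j] * obs[ok]) +
      (lib[ref_j] - ref[ok]) / (lib[ref_j] * ref[ok])
    keep_m <- m >= stats::quantile(m, trim_m) & m <= stats::quantile(m, 1 - trim_m)
    keep_a <- a >= stats::quantile(a, trim_a) & a <= stats::quantile(a, 1 - trim_a)
    keep <- keep_m & keep_a & is.finite(m) & is.finite(w) & w > 0
    if (!any(keep)) {
      warning("no genes survive TMM trimming; factor set to 1")
      return(1)
    }
    if (weighted) {
      2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
    } else {
      2^mean(m[keep])
    }
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

#' Gene-length-corrected TMM (GeTMM) normalization
#'
#' Converts counts to reads per kilobase, computes TMM scaling factors on
#' the RPK matrix, and rescales each sample to an effective library of one
#' million: `GeTMM = RPK / (colSums(RPK) * factor) * 1e6`. The result is
#' comparable both across samples (TMM) and across genes within a sample
#' (length correction).
#'
#' @param counts Count matrix (genes x samples).
#' @param lengths Gene lengths in bp.
#' @return GeTMM matrix with attribute `tmm_factors`.
#' @export
getmm <- function(counts, lengths) {
  r <- rpk(counts, lengths)
  f <- tmm_factors(r)
  out <- sweep(r, 2L, colSums(r) * f, "/") * 1e6
  attr(out, "tmm_factors") <- f
  out
}

#' Discard genes below an expression floor
#'
#' Keeps a gene if its normalized expression reaches `floor` in at least one
#' sample (`>=` semantics: a gene touching the floor exactly is kept).
#'
#' @param expr Normalized expression matrix.
#' @param floor Expression floor (default 10 GeTMM units).
#' @return Filtered matrix; warns if empty.
#' @export
filter_low_expression <- function(expr, floor = 10) {
  keep <- apply(expr, 1L, max) >= floor
  out <- expr[keep, , drop = FALSE]
  if (!nrow(out)) warning("no genes pass the expression floor")
  out
}

# all permutations of seq_len(n) as an n! x n matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  }))
}

#' Per-gene Spearman correlation with the clock period (exact p-values)
#'
#' For each gene: replicates are averaged within species (iPSM samples by
#' default), the species means are rank-correlated with the species' clock
#' periods, and a two-sided p-value is computed by full enumeration of all
#' n! rank permutations of the period vector (720 at n = 6) — the exact
#' null, since large-sample approximations are invalid at n = 6. Ties are
#' mid-ranked. Genes with constant expression across species have undefined
#' rho and are flagged, not ranked.
#'
#' @param expr Normalized expression matrix (genes x samples).
#' @param metadata Data frame with columns `sample`, `species`, `tissue`
#'   matching `colnames(expr)`.
#' @param periods Named vector of clock periods per species (minutes).
#' @param tissue Tissue to profile (default `"iPSM"`; use `NULL` for all
#'   samples).
#' @return A data frame of class `correlation_profile`: `gene`, `rho`,
#'   `p_value`, `defined`, plus one `mean_<species>` column per species.
#' @export
spearman_profile <- function(expr, metadata, periods, tissue = "iPSM") {
  if (!is.null(tissue)) {
    metadata <- metadata[metadata$tissue == tissue, , drop = FALSE]
  }
  metadata <- metadata[metadata$sample %in% colnames(expr), , drop = FALSE]
  sp <- intersect(names(periods), unique(metadata$species))
  if (length(sp) < 4L) stop("need at least 4 species with samples and periods", call. = FALSE)

  means <- vapply(sp, function(s) {
    cols <- metadata$sample[metadata$species == s]
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  pvec <- periods[sp]
  n <- length(sp)

  expr_ranks <- t(apply(means, 1L, rank))
  defined <- apply(expr_ranks, 1L, function(r) stats::sd(r) > 0)

  p_ranks <- rank(pvec)
  perms <- permutations_of(n)
  perm_ranks <- matrix(p_ranks[perms], nrow(perms), n)

  std <- function(m) {
    c_m <- m - rowMeans(m)
    sw <- sqrt(rowSums(c_m^2))
    c_m / ifelse(sw == 0, 1, sw)
  }
  e_std <- std(expr_ranks)
  p_std <- std(perm_ranks)
  # rho of every gene against every permutation of the period ranks
  rho_all <- e_std %*% t(p_std) # genes x n!
  identity_row <- which(apply(perms, 1L, function(p) all(p == seq_len(n))))
  rho <- rho_all[, identity_row]
  p_value <- rowMeans(abs(rho_all) >= abs(rho) - 1e-12)

  out <- data.frame(
    gene = rownames(expr),
    rho = ifelse(defined, rho, NA_real_),
    p_value = ifelse(defined, p_value, NA_real_),
    defined = defined,
    stringsAsFactors = FALSE
  )
  colnames(means) <- paste0("mean_", sp)
  out <- cbind(out, means)
  rownames(out) <- NULL
  attr(out, "periods") <- pvec
  attr(out, "n_permutations") <- nrow(perms)
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Select the tempo gene set by a Spearman threshold
#'
#' Genes whose correlation with the clock period is strictly below
#' `rho_cut` (default -0.8: the strongest anticorrelated genes, expressed
#' higher in faster species).
#'
#' @param profile A `correlation_profile` from [spearman_profile()].
#' @param rho_cut Threshold (strict `<`).
#' @return A list of class `gene_set_selection`: `rho_cut`, `genes`, `size`,
#'   and `ranked` (gene, rho sorted ascending — the pre-ranked export).
#' @export
select_tempo_genes <- function(profile, rho_cut = -0.8) {
  ok <- profile$defined & profile$rho < rho_cut
  ranked <- profile[profile$defined, c("gene", "rho")]
  ranked <- ranked[order(ranked$rho), , drop = FALSE]
  rownames(ranked) <- NULL
  res <- list(
    rho_cut = rho_cut,
    genes = profile$gene[ok],
    size = sum(ok),
    ranked = ranked
  )
  class(res) <- "gene_set_selection"
  res
}

#' Export a pre-ranked gene list for external enrichment tools
#'
#' Writes the two-column tab-delimited (gene, rho) list, sorted ascending,
#' in the `.rnk` convention consumed by pre-ranked GSEA.
#'
#' @param selection A `gene_set_selection` (or `correlation_profile`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preranked <- function(selection, path) {
  ranked <- if (inherits(selection, "gene_set_selection")) {
    selection$ranked
  } else {
    r <- selection[selection$defined, c("gene", "rho")]
    r[order(r$rho), ]
  }
  utils::write.table(ranked, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tempo-gene-set expression ratio between two conditions
#'
#' Compares the per-gene log2 expression ratio A/B of the selected tempo
#' genes against a size-matched random gene set (seeded), as in the
#' fast-versus-slow progenitor comparison: if the selection tracks tempo,
#' its median log2 ratio separates from the random set's. A rank-based
#' two-sample test (Wilcoxon) quantifies the separation.
#'
#' @param selection A `gene_set_selection`.
#' @param expr_a,expr_b Named numeric vectors (or 1-column matrices) of
#'   expression in conditions A and B, sharing gene ids with the selection.
#' @param n_random Size of the random comparison set (default: selection
#'   size).
#' @param seed Integer seed for the random draw.
#' @param pseudo Pseudocount guarding log2 of zero.
#' @return A list of class `ratio_comparison`: `median_selected`,
#'   `median_random`, `wilcoxon_p`, `n_selected`, `random_genes`, `seed`.
#' @export
ratio_comparison <- function(selection, expr_a, expr_b, n_random = NULL,
                             seed = 0L, pseudo = 0.5) {
  a <- drop(as.matrix(expr_a))
  b <- drop(as.matrix(expr_b))
  shared <- intersect(names(a), names(b))
  sel <- intersect(selection$genes, shared)
  if (length(sel) < 10L) {
    stop("insufficient overlap: fewer than 10 selected genes in both tables",
         call. = FALSE)
  }
  if (is.null(n_random)) n_random <- length(sel)
  ratio <- log2((a[shared] + pseudo) / (b[shared] + pseudo))
  rnd <- with_seed(seed, sample(shared, n_random))
  # normal approximation: tied ratios are common and the exact test warns
  w <- stats::wilcox.test(ratio[sel], ratio[rnd], exact = FALSE)
  res <- list(
    median_selected = stats::median(ratio[sel]),
    median_random = stats::median(ratio[rnd]),
    wilcoxon_p = w$p.value,
    n_selected = length(sel),
    random_genes = rnd,
    seed = seed
  )
  class(res) <- "ratio_comparison"
  res
}
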