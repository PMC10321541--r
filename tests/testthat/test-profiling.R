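make_counts <- function(genes, samples, fill) {
  matrix(fill, length(genes), samples, dimnames = list(genes, NULL))
}

test_that("ortholog gluing keeps only complete one-to-one anchors", {
  genes <- sprintf("G%03d", 1:10)
  counts <- list(
    mouse = make_counts(paste0("mmu_", genes), 2, 5L),
    human = make_counts(paste0("hsa_", genes), 2, 7L),
    rabbit = make_counts(paste0("ocu_", genes), 2, 9L)
  )
  map <- do.call(rbind, list(
    data.frame(species = "mouse", gene_id = paste0("mmu_", genes), human_anchor_id = genes),
    data.frame(species = "human", gene_id = paste0("hsa_", genes), human_anchor_id = genes),
    data.frame(species = "rabbit", gene_id = paste0("ocu_", genes), human_anchor_id = genes)
  ))
  map$relationship <- "one2one"
  glued <- glue_orthologs(counts, map)
  expect_equal(nrow(glued), 10)
  expect_equal(ncol(glued), 6)
  expect_equal(attr(glued, "n_dropped"), 0)

  # one-to-many rows (flagged by relationship type) drop their anchors
  map2 <- map
  map2$relationship[map2$species == "mouse" & map2$human_anchor_id %in% genes[1:2]] <- "one2many"
  glued2 <- glue_orthologs(counts, map2)
  expect_false(any(genes[1:2] %in% rownames(glued2)))
  expect_equal(nrow(glued2), 8)
  expect_equal(attr(glued2, "n_dropped"), 2)

  # a duplicated anchor within one species is a map violation
  map3 <- rbind(map, data.frame(species = "mouse", gene_id = "mmu_X",
                                human_anchor_id = genes[1], relationship = "one2one"))
  expect_error(glue_orthologs(counts, map3), "map violation")

  # disjoint gene sets leave nothing to glue
  counts4 <- counts
  rownames(counts4$mouse) <- paste0("mmu_Z", 1:10)
  expect_warning(glued4 <- glue_orthologs(counts4, map), "no anchors")
  expect_equal(nrow(glued4), 0)
})

test_that("RPK divides counts by gene length in kilobases", {
  m <- matrix(c(100, 0, 10, 100, 0, 10), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  lens <- c(a = 2000, b = 1500, c = 500)
  r <- rpk(m, lens)
  expect_equal(unname(r["a", 1]), 50)
  expect_equal(unname(r["b", 1]), 0)
  expect_equal(unname(r["c", 1]), 20)
  expect_error(rpk(m, c(a = 2000, b = 0, c = 500)), "positive")
})

test_that("TMM factors are unity for proportional or identical samples", {
  set.seed(5)
  base <- stats::rpois(500, 100) + 1
  prop <- cbind(a = base, b = 3L * base)
  expect_equal(unname(tmm_factors(prop)), c(1, 1), tolerance = 1e-9)
  ident <- cbind(a = base, b = base, c = base)
  expect_equal(unname(tmm_factors(ident)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("TMM factors track the reference implementation on asymmetric data", {
  set.seed(7)
  mu <- stats::rexp(1000, 1 / 200)
  s1 <- stats::rpois(1000, mu)
  s2 <- stats::rpois(1000, mu)
  up <- sample(1000, 50)
  s2[up] <- stats::rpois(50, mu[up] * 8)
  m <- cbind(a = s1, b = s2)
  oracle <- edgeR::calcNormFactors(edgeR::DGEList(counts = m))$samples$norm.factors
  # default (unweighted) factors agree with the reference within 2%
  mine <- tmm_factors(m)
  expect_lt(max(abs(mine - oracle) / oracle), 0.02)
  # the precision-weighted variant reproduces the reference almost exactly
  # (residual differences come from quantile- versus rank-based trimming)
  mine_w <- tmm_factors(m, weighted = TRUE)
  expect_equal(unname(mine_w), oracle, tolerance = 1e-3)
})

test_that("GeTMM arithmetic behaves as a length-corrected per-million scale", {
  genes <- sprintf("g%02d", 1:40)
  set.seed(9)
  counts <- matrix(stats::rpois(40 * 4, 200), 40, 4,
                   dimnames = list(genes, paste0("s", 1:4)))
  lens <- stats::setNames(rep(1000, 40), genes)

  # single gene, equal counts and lengths: everything normalizes to 1e6
  one <- matrix(50, 1, 3, dimnames = list("g", NULL))
  suppressWarnings(g1 <- getmm(one, c(g = 1000)))
  expect_true(all(g1 == 1e6))

  # doubling one gene's length halves its value, others nearly unchanged
  g_a <- getmm(counts, lens)
  lens2 <- lens
  lens2["g01"] <- 2000
  g_b <- getmm(counts, lens2)
  expect_equal(unname(g_b["g01", ] / g_a["g01", ]), rep(0.5, 4), tolerance = 0.03)
  expect_equal(g_b["g20", ], g_a["g20", ], tolerance = 0.03)

  # null data at realistic matrix size: column sums agree within 1%
  set.seed(17)
  big <- matrix(stats::rpois(2000 * 6, 150), 2000, 6,
                dimnames = list(sprintf("n%04d", 1:2000), paste0("s", 1:6)))
  cs <- colSums(getmm(big, stats::setNames(rep(1500, 2000), rownames(big))))
  expect_lt((max(cs) - min(cs)) / mean(cs), 0.01)
})

test_that("the GeTMM pipeline is invariant to library-size rescaling", {
  sim <- small_planted_sim(n_genes = 400, n_neg = 20, n_pos = 0, seed = 15)
  base <- getmm(sim$counts, sim$lengths)
  scaled_counts <- sim$counts
  scaled_counts[, 3] <- scaled_counts[, 3] * 5L
  scaled <- getmm(scaled_counts, sim$lengths)
  nonzero <- base[, 3] > 0
  expect_lt(max(abs(scaled[nonzero, 3] - base[nonzero, 3]) / base[nonzero, 3]), 0.001)
})

test_that("expression floor keeps genes reaching 10 in any sample", {
  m <- rbind(
    low = rep(9.9, 4),
    edge = c(10, 0, 0, 0),
    high = rep(50, 4)
  )
  out <- filter_low_expression(m, floor = 10)
  expect_equal(rownames(out), c("edge", "high"))
  expect_warning(filter_low_expression(m[1, , drop = FALSE]), "no genes")
})

test_that("exact Spearman p-values match the independent exact test", {
  sim <- small_planted_sim(n_genes = 80, n_neg = 5, n_pos = 5, seed = 2)
  norm <- getmm(sim$counts, sim$lengths)
  prof <- spearman_profile(norm, sim$metadata, zoo_periods())
  expect_equal(attr(prof, "n_permutations"), 720)
  mean_cols <- grep("^mean_", names(prof), value = TRUE)
  sp <- sub("^mean_", "", mean_cols)
  for (i in which(prof$defined)[1:10]) {
    ct <- suppressWarnings(stats::cor.test(
      unlist(prof[i, mean_cols]), zoo_periods()[sp],
      method = "spearman", exact = TRUE
    ))
    expect_equal(prof$rho[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(prof$p_value[i], ct$p.value, tolerance = 1e-9)
  }
  # perfectly monotone gene: the exact two-sided tail is 2/720
  planted <- match(sim$truth$gene[sim$truth$class == "negative"], prof$gene)
  perfect <- planted[which(prof$rho[planted] < -1 + 1e-9)][1]
  expect_false(is.na(perfect))
  expect_equal(prof$p_value[perfect], 2 / 720, tolerance = 1e-9)
})

test_that("Spearman profile is invariant under monotone transforms and flags ties", {
  # single replicate per species: species means equal sample values, so a
  # monotone transform of the matrix is a monotone transform of the means
  sim <- gen_expression_matrix(expression_sim_spec(
    periods = zoo_periods(), n_genes = 60, n_neg_corr = 5, n_pos_corr = 0,
    n_replicates = 1, seed = 4
  ))
  norm <- getmm(sim$counts, sim$lengths)
  prof_a <- spearman_profile(norm, sim$metadata, zoo_periods())
  prof_b <- spearman_profile(sqrt(norm), sim$metadata, zoo_periods())
  expect_equal(prof_a$rho, prof_b$rho, tolerance = 1e-12)

  flatm <- rbind(norm, flat_gene = rep(3, ncol(norm)))
  prof_c <- spearman_profile(flatm, sim$metadata, zoo_periods())
  expect_false(prof_c$defined[prof_c$gene == "flat_gene"])
  expect_true(is.na(prof_c$rho[prof_c$gene == "flat_gene"]))
})

test_that("tempo gene selection uses a strict threshold and exports ranked lists", {
  profile <- structure(
    data.frame(gene = c("a", "b", "c"), rho = c(-0.9, -0.8, -0.7),
               p_value = c(0.01, 0.02, 0.1), defined = TRUE),
    class = c("correlation_profile", "data.frame")
  )
  sel <- select_tempo_genes(profile, rho_cut = -0.8)
  expect_equal(sel$genes, "a")
  expect_equal(sel$size, 1)
  expect_equal(sel$ranked$gene, c("a", "b", "c"))

  path <- tempfile(fileext = ".rnk")
  write_preranked(sel, path)
  rnk <- utils::read.table(path, sep = "\t")
  expect_equal(rnk[[1]], c("a", "b", "c"))
  expect_equal(rnk[[2]], c(-0.9, -0.8, -0.7))

  # empty selections are allowed
  none <- select_tempo_genes(profile, rho_cut = -0.95)
  expect_equal(none$size, 0)
})

test_that("ratio comparison separates planted fold-changes from random genes", {
  genes <- sprintf("g%03d", 1:200)
  set.seed(31)
  b <- stats::setNames(stats::rlnorm(200, 5, 0.2), genes)
  sel <- structure(list(genes = genes[1:40]), class = "gene_set_selection")

  # A identical to B: both medians zero
  eq <- ratio_comparison(sel, b, b, seed = 1)
  expect_equal(eq$median_selected, 0)
  expect_equal(eq$median_random, 0)

  # selected genes doubled in A
  a <- b
  a[genes[1:40]] <- a[genes[1:40]] * 2
  r <- ratio_comparison(sel, a, b, seed = 1)
  expect_equal(r$median_selected, 1, tolerance = 0.05)
  expect_lt(abs(r$median_random), 0.3)
  expect_lt(r$wilcoxon_p, 0.01)

  # seeded random draw is reproducible
  r2 <- ratio_comparison(sel, a, b, seed = 1)
  expect_identical(r$random_genes, r2$random_genes)

  few <- structure(list(genes = genes[1:5]), class = "gene_set_selection")
  expect_error(ratio_comparison(few, a, b), "insufficient overlap")
})
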