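# shared fixtures for the suite

zoo_periods <- function() {
  st <- species_zoo_table()
  stats::setNames(st$period, st$species)
}

# measured kinetics of the four species assayed for degradation and delay
zoo_kinetics <- function() {
  data.frame(
    species = c("rabbit", "cattle", "rhinoceros", "marmoset"),
    period = c(153, 238, 236, 388),
    halflife = c(24, 33, 32, 46),
    delay = c(24, 37, 36, 54)
  )
}

# period-scan grid step used throughout (linear 100-500 grid, 200 points)
grid_step <- function() (500 - 100) / 199

# small planted expression simulation shared by profiling tests
small_planted_sim <- function(n_genes = 600, n_neg = 50, n_pos = 20,
                              dispersion = 0.1, seed = 11) {
  gen_expression_matrix(expression_sim_spec(
    periods = zoo_periods(), n_genes = n_genes, n_neg_corr = n_neg,
    n_pos_corr = n_pos, dispersion = dispersion, seed = seed
  ))
}
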