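test_that("bulk simulation is deterministic and respects zero noise", {
  cfg <- bulk_sim_config(n_samples = 8, noise_sd = 0, n_background_genes = 5,
                         seed = 13)
  sim <- simulate_bulk_cohort(cfg)
  expect_identical(names(sim$labels), colnames(sim$expr))
  # zero noise: samples of one cluster are identical on signature genes
  sig <- compendium_universe(cfg$compendium)
  for (cl in unique(sim$labels)) {
    cols <- sim$expr[sig, sim$labels == cl, drop = FALSE]
    expect_lt(max(abs(cols - cols[, 1])), 1e-12)
  }
  # same seed reproduces byte-identical output
  expect_identical(simulate_bulk_cohort(cfg), sim)
  # different seed does not
  cfg2 <- cfg; cfg2$seed <- 14L
  expect_false(identical(simulate_bulk_cohort(cfg2)$expr, sim$expr))

  bad <- infiltration_profiles(names(cfg$compendium), 2)
  bad[[1]][1] <- -0.5
  expect_error(bulk_sim_config(n_samples = 8, clusters = bad), "negative infiltration")
  expect_error(bulk_sim_config(n_samples = 1), ">= number of clusters")
})

test_that("held-out classification recovers bulk cluster labels", {
  accs <- vapply(1:3, function(seed) {
    sim <- simulate_bulk_cohort(bulk_sim_config(n_samples = 40, noise_sd = 0.2,
                                                seed = seed))
    tr <- 1:20; te <- 21:40
    cent <- compute_centroids(sim$expr[, tr], sim$labels[tr],
                              gene_subset = compendium_universe(synthetic_compendium()))
    res <- classify_nearest_centroid(sim$expr[, te], cent)
    mean(res$assigned_cluster == sim$labels[te])
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("classification accuracy degrades monotonically with noise", {
  grid <- c(0.1, 1.0, 3.0)
  mean_acc <- vapply(grid, function(ns) {
    mean(vapply(1:10, function(seed) {
      sim <- simulate_bulk_cohort(bulk_sim_config(n_samples = 20, noise_sd = ns,
                                                  seed = seed))
      tr <- 1:10; te <- 11:20
      cent <- compute_centroids(sim$expr[, tr], sim$labels[tr])
      res <- classify_nearest_centroid(sim$expr[, te], cent)
      mean(res$assigned_cluster == sim$labels[te])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_acc) <= 0))
  expect_lt(mean_acc[3], mean_acc[1])
})

test_that("single-cell simulation honours proportions, dropout and seed", {
  cfg <- sc_sim_config(n_cells = 1000, seed = 17)
  sim <- simulate_single_cells(cfg)
  expect_identical(names(sim$labels), colnames(sim$expr))
  expect_true(all(sim$expr >= 0))
  expect_identical(simulate_single_cells(cfg), sim)

  # realized counts inside the binomial 99% envelope of the proportions
  props <- vapply(cfg$populations, `[[`, numeric(1), "proportion")
  for (p in cfg$populations) {
    n_obs <- sum(sim$labels == p$label)
    bounds <- qbinom(c(0.005, 0.995), 1000, p$proportion)
    expect_gte(n_obs, bounds[1]); expect_lte(n_obs, bounds[2])
  }

  # dropout zero + unit marker rates: every tumour cell classifies tumour
  ann <- classify_cells(sim$expr, marker_rules_preset("sox9_egfr"))
  tum <- sim$labels == "tumour"
  expect_true(all(ann$compartment[tum] == "tumour"))
  imm <- sim$labels == "immune"
  expect_true(all(ann$compartment[imm] == "immune"))

  # heavy dropout breaks joint marker positivity for some tumour cells
  drop <- simulate_single_cells(sc_sim_config(n_cells = 500, dropout_rate = 0.4,
                                              seed = 18))
  ann_d <- classify_cells(drop$expr, marker_rules_preset("sox9_egfr"))
  expect_lt(mean(ann_d$compartment[drop$labels == "tumour"] == "tumour"), 1)
})

test_that("immune cells carry a higher immunosuppressive burden than tumour cells", {
  wins <- vapply(1:10, function(seed) {
    sim <- simulate_single_cells(sc_sim_config(n_cells = 600, seed = 300 + seed))
    burden <- burden_count(sim$expr, immunosuppressive_panel())
    mean(burden[sim$labels == "immune"]) > mean(burden[sim$labels == "tumour"])
  }, logical(1))
  expect_true(all(wins))
})

test_that("pair configuration is validated", {
  pops <- list(list(label = "only", proportion = 1,
                    markers = c(PTPRC = 1, SOX9 = 0, EGFR = 0),
                    panel = c(X = 0.5),
                    pairs = list(list(genes = c("A", "B"),
                                      p_either = 0.5, p_both = 0.7))))
  expect_error(sc_sim_config(populations = pops), "p_both <= p_either")
  pops[[1]]$pairs <- list()
  pops[[1]]$proportion <- 0.9
  expect_error(sc_sim_config(populations = pops), "sum to 1")
})
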