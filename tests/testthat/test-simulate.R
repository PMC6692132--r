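test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(dfe_mixture = list(tail_tau = -1)), "GPD")
  expect_error(sim_config(dfe_mixture = list(p_beneficial = 1.2)))
  expect_error(sim_config(assay = list(colonies_sampled = 0L)))
  expect_error(sim_config(n_syn = -1L))
  expect_error(sim_config(tree = list(n_tips = 2L)))
})

test_that("degenerate mixtures behave as configured", {
  cfg0 <- sim_config(seed = 51, dfe_mixture = list(p_beneficial = 0))
  td0 <- simulate_true_dfe(cfg0)
  expect_true(all(td0$true_w <= 1))
  expect_equal(nrow(td0), 39 + 65 + 6)

  # kappa = -1 tail is uniform on [0, tau]
  cfgu <- sim_config(seed = 52, n_syn = 5000L, n_nonsyn = 0L, n_nonsense = 0L,
                     dfe_mixture = list(p_beneficial = 1, tail_kappa = -1,
                                        tail_tau = 0.1))
  su <- simulate_true_dfe(cfgu)$true_w - 1
  expect_lte(max(su), 0.1)
  expect_gte(min(su), 0)

  # nonsense mutations are strongly deleterious
  cfg <- sim_config(seed = 53)
  td <- simulate_true_dfe(cfg)
  expect_lt(max(td$true_w[td$class == "nonsense"]), 0.7)
  expect_gt(min(td$true_w), 0)
})

test_that("beneficial tail draws follow the configured GPD", {
  cfg <- sim_config(seed = 54, n_syn = 10000L, n_nonsyn = 0L, n_nonsense = 0L,
                    dfe_mixture = list(p_beneficial = 1, tail_kappa = -0.35,
                                       tail_tau = 0.05))
  s <- simulate_true_dfe(cfg)$true_w - 1
  # GPD mean formula tau/(1 - kappa) as oracle, Monte-Carlo tolerance 3 SE
  mean_expected <- 0.05 / (1 - (-0.35))
  sd_theory <- 0.05 / ((1 - (-0.35)) * sqrt(1 - 2 * (-0.35)))
  expect_lt(abs(mean(s) - mean_expected), 3 * sd_theory / sqrt(10000))
  # distributional recovery: refit within +-0.1 shape / +-15% scale
  f <- fit_gpd(s)
  expect_lt(abs(f$kappa + 0.35), 0.1)
  expect_lt(abs(f$tau - 0.05) / 0.05, 0.15)
})

test_that("competition counts conserve plate totals and expected frequency", {
  cfg <- sim_config(seed = 55)
  td <- simulate_true_dfe(cfg)
  comps <- simulate_competitions(td, cfg)
  n_col <- cfg$assay$colonies_sampled
  expect_true(all(comps$mutant_initial + comps$ref_initial == n_col))
  # final plate totals never fall below the configured depth, and both
  # strains stay countable even for strongly deleterious mutants
  expect_true(all(comps$mutant_final + comps$ref_final >= n_col))

  # expected final frequency for w = 1.1, d = 6.7, f0 = 0.5
  one <- data.frame(mutation_id = "x", class = "synonymous", true_w = 1.1)
  big <- sim_config(seed = 56, assay = list(colonies_sampled = 1000000L,
                                            n_replicates = 1L))
  cc <- simulate_competitions(one, big)
  expect_equal(cc$mutant_final / (cc$mutant_final + cc$ref_final),
               0.654432, tolerance = 2e-3)

  # neutral: expected final frequency one half
  cn <- simulate_competitions(
    data.frame(mutation_id = "n", true_w = 1), big)
  # at a balanced outcome the final plate total equals the configured depth
  expect_equal(cn$mutant_final + cn$ref_final, 1e6)
  expect_equal(cn$mutant_final / 1e6, 0.5, tolerance = 2e-3)

  # huge plates: plug-in inversion recovers true w to 3 decimals
  w_hat <- replicate_fitness(cc$mutant_initial, cc$ref_initial,
                             cc$mutant_final, cc$ref_final, cc$doublings)
  expect_equal(w_hat, 1.1, tolerance = 5e-4)
})

test_that("noiseless expression reproduces the linear relation exactly", {
  cfg <- sim_config(seed = 57,
                    expression = list(slope = 1, intercept = 0, noise_sd = 0))
  td <- simulate_true_dfe(cfg)
  ex <- simulate_expression(td, cfg)
  d <- merge(td, ex)
  expect_equal(d$relative_expression, d$true_w)
  expect_equal(suppressWarnings(summary(lm(true_w ~ relative_expression,
                                           d))$r.squared), 1)
})

test_that("simulated gene and mutation list are mutually consistent", {
  cfg <- sim_config(seed = 58)
  td <- simulate_true_dfe(cfg)
  gm <- simulate_gene_and_mutations(cfg, td)
  expect_equal(nchar(gm$cds$nucleotides), 3 * cfg$gene_length_codons)
  for (i in seq_len(nrow(gm$mutations))) {
    m <- gm$mutations[i, ]
    got <- classify_mutation(gm$cds, point_mutation(m$cds_position,
                                                    m$ref_base, m$alt_base))
    expect_identical(got, m$class)
  }
})

test_that("tree simulation honours the polytomy setting and state model", {
  cfg0 <- sim_config(seed = 59, tree = list(polytomy_fraction = 0))
  td <- simulate_true_dfe(cfg0)
  ts0 <- simulate_tree_and_states(td, cfg0)
  expect_true(ape::is.binary(ts0$tree))
  expect_equal(sort(rownames(ts0$states)), sort(td$mutation_id))
  expect_equal(ncol(ts0$states), cfg0$tree$n_tips)

  cfg <- sim_config(seed = 60, tree = list(polytomy_fraction = 0.3))
  ts <- simulate_tree_and_states(td, cfg)
  expect_false(ape::is.binary(ts$tree))
  expect_setequal(unique(as.integer(ts$states)), c(0L, 1L))

  # flat presence model: occurrence unrelated to fitness
  cfgf <- sim_config(seed = 61, n_syn = 200L,
                     tree = list(presence_logit_slope = 0,
                                 presence_logit_intercept = 0))
  tdf <- simulate_true_dfe(cfgf)
  tsf <- simulate_tree_and_states(tdf, cfgf)
  pres <- as.integer(rowSums(tsf$states) > 0)
  fit <- glm(pres ~ log(tdf$true_w), family = binomial())
  expect_gt(summary(fit)$coefficients[2, 4], 0.01)
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- sim_config(seed = 62, tree = list(n_tips = 12L))
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_simulated_data(cfg, d1)
  write_simulated_data(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_setequal(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("hash of", f))
  # a different seed changes the data
  d3 <- file.path(tempdir(), "simC")
  write_simulated_data(sim_config(seed = 63, tree = list(n_tips = 12L)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "competitions.csv"))),
                         unname(tools::md5sum(file.path(d3, "competitions.csv")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
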