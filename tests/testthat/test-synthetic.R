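test_that("gene_spec and generator_config enforce their invariants", {
  expect_error(gene_spec("G", "housekeeping", 1.2, 0, 0.5), "p_on")
  expect_error(gene_spec("G", "negative_control", 0.1, 0, 0.5), "negative control")
  expect_error(gene_spec("G", "housekeeping", 0.5, 0, -1), "burst_log_sd")
  expect_error(tiny_config(n_cells = 0), "n_cells")
  expect_error(tiny_config(capture_efficiency = 0), "capture_efficiency")
  expect_error(tiny_config(protein_decoupling = 2), "protein_decoupling")
  cfg <- tiny_config()
  expect_error(simulate_fish(cfg, "anoxia", "NTC"), "unknown condition")
  expect_error(simulate_fish(cfg, "hypoxia", "TP53_KO"), "unknown genotype")
})

test_that("resolve_p_on applies key precedence and mutual inhibition", {
  g <- gene_spec("T", "hif2_target",
                 c(default = 0.1, hypoxia = 0.3, "hypoxia:EPAS1_KO" = 0.01),
                 log(100), 0.5)
  expect_equal(resolve_p_on(g, "normoxia", "NTC"), 0.1)
  expect_equal(resolve_p_on(g, "hypoxia", "NTC"), 0.3)
  expect_equal(resolve_p_on(g, "hypoxia", "EPAS1_KO"), 0.01)
  # losing HIF-1 boosts HIF-2 targets, capped at 1
  expect_equal(resolve_p_on(g, "hypoxia", "HIF1A_KO", mutual_inhibition = 2), 0.6)
  expect_equal(resolve_p_on(g, "hypoxia", "HIF1A_KO", mutual_inhibition = 10), 1)
  g1 <- gene_spec("T1", "hif1_target", c(hypoxia = 0.4, normoxia = 0.02), log(100), 0.5)
  expect_equal(resolve_p_on(g1, "hypoxia", "EPAS1_KO", mutual_inhibition = 2), 0.8)
})

test_that("fixing the seed fixes every emitted table bit-for-bit", {
  cfg <- tiny_config(n_cells = 300)
  a <- simulate_fish(cfg, "hypoxia", "NTC")
  # simulating other samples in between must not perturb this one
  simulate_fish(cfg, "normoxia", "HIF1A_KO")
  simulate_scrnaseq(cfg, "hypoxia", "EPAS1_KO")
  b <- simulate_fish(cfg, "hypoxia", "NTC")
  expect_identical(a$table, b$table)
  expect_identical(a$truth$on, b$truth$on)

  sc1 <- simulate_scrnaseq(cfg, "hypoxia", "NTC")
  sc2 <- simulate_scrnaseq(cfg, "hypoxia", "NTC")
  expect_identical(as.matrix(sc1$counts$counts), as.matrix(sc2$counts$counts))

  # a different seed changes the draw
  c2 <- simulate_fish(tiny_config(n_cells = 300, seed = 43L), "hypoxia", "NTC")
  expect_false(identical(a$table, c2$table))
})

test_that("degenerate no-noise simulation gives h_i = 0 and pure background stays negative", {
  cfg <- generator_config(
    n_cells = 100,
    genes = list(gene_spec("G", "housekeeping", 1, log(100), 0),
                 gene_spec("NEG", "negative_control", 0, 0, 0)),
    size_factor_log_sd = 0, background_log_mean = -Inf, seed = 1L
  )
  sim <- simulate_fish(cfg, "hypoxia", "NTC")
  v <- sim$table$`G@Opal570`
  expect_true(all(v == v[1]) && v[1] > 0)
  expect_equal(heterogeneity_index(v), 0)

  # p_on = 0 channel is background only; at the background's 100th percentile
  # no cell is called positive (strict rule)
  cfg_bg <- tiny_config(n_cells = 2000)
  tab <- simulate_fish(cfg_bg, "hypoxia", "NTC")$table
  thr <- detection_threshold(tab, "NEG@Opal570", quantile = 1)
  expect_equal(mean(call_positive(tab$`NEG@Opal570`, thr)), 0)
})

test_that("realized expressing fraction recovers p_on within binomial error", {
  p <- 0.05; n <- 20000
  cfg <- generator_config(
    n_cells = n,
    genes = list(gene_spec("S", "hif2_target", p, log(1000), 0.8)),
    seed = 7L
  )
  truth <- simulate_truth(cfg, "hypoxia", "NTC")
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(truth$realized_fraction[["S"]] - p), 3 * se)
})

test_that("scRNA-seq rendering obeys thinning monotonicity and the Poisson zero law", {
  # all-zero gene when never on
  cfg0 <- tiny_config(n_cells = 200, capture_efficiency = 1)
  sc <- simulate_scrnaseq(cfg0, "hypoxia", "NTC")
  neg_row <- sc$counts$counts[match("NEG", sc$counts$gene_info$gene), ]
  expect_true(all(neg_row == 0))

  # same latent truth at efficiency 1 vs 0.05: positivity strictly drops
  genes <- list(gene_spec("L1", "housekeeping", 0.9, log(3), 0.2),
                gene_spec("L2", "hif2_target", 0.2, log(1), 0.2))
  cfg1 <- generator_config(n_cells = 3000, genes = genes,
                           capture_efficiency = 1, seed = 5L)
  cfg2 <- generator_config(n_cells = 3000, genes = genes,
                           capture_efficiency = 0.05, seed = 5L)
  truth <- simulate_truth(cfg1, "hypoxia", "NTC")
  hi <- simulate_scrnaseq(cfg1, "hypoxia", "NTC", truth = truth)
  lo <- simulate_scrnaseq(cfg2, "hypoxia", "NTC", truth = truth)
  for (g in c("L1", "L2")) {
    expect_lt(positive_cell_fraction(lo$counts, g),
              positive_cell_fraction(hi$counts, g))
  }

  # lambda = 2, efficiency 0.05: positive fraction ~ 1 - exp(-0.1)
  n <- 10000
  cfgp <- generator_config(
    n_cells = n,
    genes = list(gene_spec("L", "housekeeping", 1, log(2), 0)),
    size_factor_log_sd = 0, capture_efficiency = 0.05, seed = 9L
  )
  scp <- simulate_scrnaseq(cfgp, "hypoxia", "NTC")
  p_expect <- 1 - exp(-0.1)
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(positive_cell_fraction(scp$counts, "L") / 100 - p_expect), 3 * se)
})

test_that("paired protein channel honors the decoupling contract", {
  base_genes <- list(gene_spec("P", "hif2a_mrna", 0.5, log(500), 0.6))

  # fully coupled, no background: identical positive sets
  cfg0 <- generator_config(n_cells = 2000, genes = base_genes,
                           protein_decoupling = 0, background_log_mean = -Inf,
                           seed = 3L)
  tab0 <- simulate_paired_protein(cfg0, "hypoxia", "NTC", "P")
  expect_equal(tab0$`P_mRNA@Opal570` > 0, tab0$`P_protein@Opal570` > 0)

  # fully decoupled: correlation within sampling error of zero
  cfg1 <- generator_config(n_cells = 10000, genes = base_genes,
                           protein_decoupling = 1, background_log_mean = -Inf,
                           seed = 3L)
  tab1 <- simulate_paired_protein(cfg1, "hypoxia", "NTC", "P")
  r <- spearman_rho(tab1$`P_mRNA@Opal570`, tab1$`P_protein@Opal570`)
  expect_lt(abs(r$rho), 3 / sqrt(10000))

  # half decoupled: overlap matches the 2x2 latent mixture expectation
  # P(both on) = (1 - d) p + d p^2 = 0.375 at d = 0.5, p = 0.5
  cfg2 <- generator_config(n_cells = 20000, genes = base_genes,
                           protein_decoupling = 0.5, background_log_mean = -Inf,
                           seed = 11L)
  tab2 <- simulate_paired_protein(cfg2, "hypoxia", "NTC", "P")
  pt <- positivity_table(tab2$`P_mRNA@Opal570`, tab2$`P_protein@Opal570`, 0, 0)
  se <- sqrt(0.375 * 0.625 / 20000)
  expect_lt(abs(pt$n_pp / pt$n - 0.375), 3 * se)
})

test_that("housekeeping channels correlate through the shared size factor", {
  rhos <- vapply(c(0.1, 0.6), function(sd) {
    cfg <- tiny_config(n_cells = 4000, size_factor_log_sd = sd, seed = 13L)
    tab <- simulate_fish(cfg, "hypoxia", "NTC")$table
    spearman_rho(tab$`HK1@Opal570`, tab$`HK2@Opal650`)$rho
  }, numeric(1))
  expect_gt(rhos[1], 0)
  expect_gt(rhos[2], rhos[1])
})
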