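# synthetic-data generators: attachment, fluorescence, lineage, height maps

test_that("phenotype_mix validates its invariants", {
  m <- phenotype_mix(c(0.8, 0.2), c(5.45e-3, 2.52e-4))
  expect_s3_class(m, "phenotype_mix")
  expect_error(phenotype_mix(c(0.8, 0.3), c(1e-2, 1e-3)), "sum to 1")
  expect_error(phenotype_mix(c(0.5, 0.5), c(1e-3, 1e-2)), "decreasing")
  expect_error(phenotype_mix(c(0.5, 0.5), c(1e-2, -1e-3)), ">= 0")
  expect_error(phenotype_mix(1, 1e-3, detach_rates = -1), ">= 0")
})

test_that("zero attachment rate means no cell ever attaches", {
  trk <- simulate_attachment(phenotype_mix(1, 0),
                             sim_config(n_cells = 50, duration = 600, seed = 1))
  s <- count_series(trk)
  expect_true(all(s$n_surface == 0))
  expect_true(all(s$n_bulk == 50))
})

test_that("half of the cells attach by the half-life of a single phenotype", {
  alpha <- log(2) / 300
  n <- 1e4
  trk <- simulate_attachment(phenotype_mix(1, alpha),
                             sim_config(n_cells = n, duration = 600, seed = 7))
  s <- count_series(trk)
  frac_att <- s$n_surface[s$time_s == 300] / n
  expect_lt(abs(frac_att - 0.5), 3 * sqrt(0.25 / n))
})

test_that("ensemble mean of the simulator matches the closed-form mixture decay", {
  # The bulk fraction is an ECDF of the attach times, so the exact
  # every-frame Monte-Carlo band is the Kolmogorov-Smirnov band
  # (sqrt(n) * sup|dev| <= 1.95 at the 99.9% level); pointwise, nearly all
  # frames must also sit inside 3 per-frame SE.
  cases <- list(
    list(mix = mix_late_exponential(), n = 10000),
    list(mix = phenotype_mix(c(0.5, 0.3, 0.2), c(1e-2, 1e-3, 1e-4)), n = 5000)
  )
  for (cs in cases) {
    trk <- simulate_attachment(cs$mix, sim_config(cs$n, duration = 3600,
                                                  seed = 101))
    s <- count_series(trk)
    p <- model_nb(s$time_s, cs$mix$fractions, cs$mix$attach_rates)
    dev <- abs(s$n_bulk / cs$n - p)
    expect_lt(sqrt(cs$n) * max(dev), 1.95)
    se <- sqrt(p * (1 - p) / cs$n)
    expect_gte(mean(dev <= 3 * se + 1e-12), 0.99)
  }
})

test_that("attached state is monotone non-decreasing when detachment is off", {
  trk <- simulate_attachment(mix_late_exponential(),
                             sim_config(n_cells = 100, duration = 1200, seed = 3))
  tab <- track_table(trk)
  for (d in split(tab$attached, tab$cell_id)) {
    expect_true(all(diff(d) >= 0))
  }
  # and each cell has at most one mobile->attached switch
  expect_true(all(lengths(trk$events) <= 1))
})

test_that("same seed reproduces the simulation bit-identically, different seeds differ", {
  cfg <- sim_config(n_cells = 200, duration = 900, seed = 5)
  a <- simulate_attachment(mix_late_exponential(), cfg)
  b <- simulate_attachment(mix_late_exponential(), cfg)
  expect_identical(a$events, b$events)
  expect_identical(track_table(a), track_table(b))
  cfg2 <- sim_config(n_cells = 200, duration = 900, seed = 6)
  c2 <- simulate_attachment(mix_late_exponential(), cfg2)
  expect_false(identical(a$events, c2$events))
})

test_that("empirical phenotype fractions obey the law of large numbers", {
  mix <- mix_late_exponential()
  trk <- simulate_attachment(mix, sim_config(n_cells = 1e4, duration = 30,
                                             seed = 9))
  emp <- tabulate(trk$cells$phenotype, 2) / 1e4
  se <- sqrt(mix$fractions * (1 - mix$fractions) / 1e4)
  expect_true(all(abs(emp - mix$fractions) <= 3 * se))
})

test_that("detachment-enabled simulation produces alternating events", {
  mix <- phenotype_mix(1, 1e-2, detach_rates = 1e-3)
  trk <- simulate_attachment(mix, sim_config(n_cells = 300, duration = 3600,
                                             seed = 13))
  expect_true(any(lengths(trk$events) >= 2))
  fx <- flux_check(trk)
  expect_gt(fx$n_detach_events, 0)
})

# ---- fluorescence ----

test_that("noise-free anti-monotone channels give Spearman -1", {
  cfg <- fluor_config(n_cells = 500,
                      egfp = channel_map("decreasing", scale = 300, noise_sd = 0),
                      lectin = channel_map("increasing", scale = 500, noise_sd = 0),
                      copula_rho = 1, seed = 2)
  tab <- simulate_fluorescence(cfg)
  expect_equal(cor(tab$egfp_au, tab$lectin_au, method = "spearman"), -1)
  expect_lt(cor(tab$egfp_au, tab$lectin_au), 0)
})

test_that("copula calibration hits the reported -0.45 reporter/stain correlation", {
  tab <- simulate_fluorescence(fluor_config(n_cells = 2000, seed = 7))
  r <- channel_correlation(tab, "egfp_au", "lectin_au")$estimate
  expect_gte(r, -0.50)
  expect_lte(r, -0.40)
  expect_true(all(tab$egfp_au > 0))
  expect_true(all(tab$lectin_au > 0))
})

test_that("degenerate sample size skips the calibration check with a flag", {
  cfg <- fluor_config(n_cells = 2, seed = 1)
  expect_warning(tab <- simulate_fluorescence(cfg), "flagged")
  expect_false(attr(tab, "calibration_checked"))
  expect_equal(nrow(tab), 2)
})

test_that("unattainable correlation targets raise a parameter error", {
  expect_error(fluor_config(10, target_pearson = -1.2), "in \\(-1, 1\\)")
  # heavy-skew marginals cap the attainable anticorrelation
  cfg <- fluor_config(1000, latent_logsd = 1.6, target_pearson = -0.45)
  expect_error(simulate_fluorescence(cfg), "not attainable")
})

test_that("bulk and surface presets reproduce the reported threshold proportions", {
  n <- 5000
  bulk <- simulate_fluorescence(fluor_presets("bulk", n_cells = n, seed = 3))
  p500 <- fraction_above(bulk$egfp_au, 500)
  p1000 <- fraction_above(bulk$egfp_au, 1000)
  expect_lt(abs(p500$prop - 0.20), 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(abs(p1000$prop - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  surf <- simulate_fluorescence(fluor_presets("surface", n_cells = n, seed = 4),
                                population = "surface")
  expect_lt(abs(fraction_above(surf$egfp_au, 500)$prop - 0.02),
            3 * sqrt(0.02 * 0.98 / n))
})

# ---- lineage ----

test_that("degenerate fate distributions behave as expected", {
  # everyone stays: tree grows geometrically, no leave events
  f <- simulate_lineage(lineage_config(n_founders = 5,
                                       fate_probs = c(1, 0, 0),
                                       mean_division_interval = 1000,
                                       duration = 6000, seed = 1))
  expect_true(all(f$nodes$fate != "leave"))
  expect_gt(sum(!is.na(f$nodes$t_division_s)), 5)
  # both always leave: each founder divides exactly once, all lineages end
  g <- simulate_lineage(lineage_config(n_founders = 50,
                                       fate_probs = c(0, 0, 1),
                                       mean_division_interval = 500,
                                       duration = 1e5, seed = 2))
  cnt <- classify_fates(g)
  expect_equal(cnt$n_both_leave, cnt$n_div)
  expect_equal(cnt$n_div, 50)  # every founder divides once, daughters leave
})

test_that("empirical fate frequencies match the generating distribution", {
  probs <- c(0.1, 0.3, 0.6)
  f <- simulate_lineage(lineage_config(n_founders = 400, fate_probs = probs,
                                       seed = 21))
  cnt <- classify_fates(f)
  expect_gte(cnt$n_div, 300)
  est <- fate_probabilities(cnt)
  for (i in 1:3) {
    se <- sqrt(probs[i] * (1 - probs[i]) / cnt$n_div)
    expect_lt(abs(est$p[i] - probs[i]), 3 * se)
  }
})

test_that("a duration shorter than any division interval yields zero divisions", {
  f <- simulate_lineage(lineage_config(n_founders = 10,
                                       fate_probs = c(0.2, 0.4, 0.4),
                                       mean_division_interval = 1e6,
                                       duration = 10, seed = 3))
  cnt <- classify_fates(f)
  expect_equal(cnt$n_div, 0)
  est <- fate_probabilities(cnt)
  expect_false(est$available)
})

test_that("leave events always fall inside the observation window", {
  f <- simulate_lineage(lineage_config(n_founders = 100,
                                       fate_probs = fate_presets("PAOYs1"),
                                       seed = 4))
  leavers <- f$nodes[f$nodes$fate == "leave", ]
  expect_true(all(leavers$t_end_s <= f$config$duration))
  expect_true(all(leavers$t_end_s >= leavers$t_birth_s))
})

# ---- height maps ----

test_that("zero roughness target yields a constant map with exact mean", {
  hm <- simulate_heightmap(10, 0, grid = c(16, 16), seed = 1)
  expect_true(all(hm$grid == 10))
  expect_identical(mean_thickness(hm), 10)
  expect_equal(roughness_coefficient(hm), 0)
})

test_that("calibrated generator hits the roughness target within 10%", {
  for (target in c(0.3, 0.5, 0.9)) {
    hm <- simulate_heightmap(10, target, grid = c(64, 64), seed = 11)
    ra <- roughness_coefficient(hm)
    expect_lt(abs(ra - target) / target, 0.10)
  }
  hm <- simulate_heightmap(10, 0.5, grid = c(64, 64), seed = 11)
  expect_lt(abs(mean_thickness(hm) - 10) / 10, 0.10)
  expect_true(all(hm$grid >= 0))
})

test_that("impossible roughness targets are rejected", {
  expect_error(simulate_heightmap(10, 2.0), "unattainable")
  expect_error(simulate_heightmap(-1, 0.5), "> 0")
})
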