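test_that("Dirichlet CLR instances are positive, closed, and reproducible", {
  counts <- matrix(c(10L, 0L, 5L, 40L, 2L, 0L, 30L, 8L), 2L, 4L,
                   dimnames = list(c("s1", "s2"), letters[1:4]))
  inst <- mc_clr_instances(counts, n_mc = 16L, seed = 5L)
  expect_length(inst$instances, 16L)
  for (m in inst$instances[1:3]) {
    expect_lt(max(abs(rowSums(m))), 1e-8)      # CLR rows sum to 0
    expect_true(all(is.finite(m)))             # zeros imputed by the prior
  }
  inst2 <- mc_clr_instances(counts, n_mc = 16L, seed = 5L)
  expect_identical(inst$instances, inst2$instances)
  inst3 <- mc_clr_instances(counts, n_mc = 16L, seed = 6L)
  expect_false(identical(inst$instances[[1L]], inst3$instances[[1L]]))

  expect_error(mc_clr_instances(counts, n_mc = 8L), "at least 16")
})

test_that("mean CLR over instances converges with n_mc", {
  set.seed(41)
  counts <- matrix(rpois(20L * 6L, 60L) + 10L, 20L, 6L,
                   dimnames = list(paste0("s", 1:20), letters[1:6]))
  m128 <- Reduce(`+`, mc_clr_instances(counts, 128L, seed = 1L)$instances) / 128
  m512 <- Reduce(`+`, mc_clr_instances(counts, 512L, seed = 2L)$instances) / 512
  expect_lt(max(abs(m128 - m512)), 0.05)
})

test_that("null label splits give centred effects, large q, no calls", {
  # Arbitrary label splits of i.i.d. samples: the effect distribution is
  # centred at zero (its spread reflects the n = 20/20 sampling floor),
  # expected adjusted p-values stay high, and nothing is classified.
  effects <- c()
  qs <- c()
  for (s in 1:3) {
    sim <- simulate_cohort(sim_config(n_samples = 40L, seed = 540L + s))
    inst <- mc_clr_instances(sim$counts, n_mc = 32L, seed = 540L + s)
    res <- aldex_da(inst, rep(c("g1", "g2"), 20L))
    effects <- c(effects, res$effect)
    qs <- c(qs, res$q_expected)
    expect_true(all(classify_da(res)$class == "unchanged"))
  }
  expect_lt(abs(median(effects)), 0.1)     # centred at zero
  expect_lt(median(abs(effects)), 0.25)    # typical spread well under 0.5
  expect_gt(median(qs), 0.5)               # q mostly far from significance
  expect_gt(min(qs), 0.01)                 # never close to the 0.001 gate
})

test_that("swapping group labels negates effects within MC error", {
  set.seed(53)
  sim <- simulate_cohort(sim_config(n_samples = 30L, seed = 77L))
  inst <- mc_clr_instances(sim$counts, n_mc = 128L, seed = 77L)
  g <- rep(c("g1", "g2"), 15L)
  fwd <- aldex_da(inst, factor(g, levels = c("g1", "g2")))
  rev <- aldex_da(inst, factor(g, levels = c("g2", "g1")))
  expect_lt(max(abs(fwd$effect + rev$effect)), 1e-10)
  expect_equal(fwd$q_expected, rev$q_expected, tolerance = 1e-12)
  expect_equal(fwd$median_clr_diff, -rev$median_clr_diff, tolerance = 1e-12)
})

test_that("effect sign matches the median CLR difference", {
  shift <- numeric(30L)
  shift[c(3L, 9L)] <- c(1.5, -1.5)
  sim <- simulate_circumcision_pair(sim_config(n_samples = 30L,
                                               post_shift = shift,
                                               seed = 61L))
  inst <- mc_clr_instances(sim$counts, n_mc = 64L, seed = 61L)
  res <- aldex_da(inst, factor(sim$metadata$timepoint,
                               levels = c("pre", "post")))
  strong <- abs(res$effect) > 0.05
  expect_true(all(sign(res$effect[strong]) ==
                    sign(res$median_clr_diff[strong])))
  expect_gt(res$effect[res$taxon == colnames(sim$counts)[3L]], 0)
  expect_lt(res$effect[res$taxon == colnames(sim$counts)[9L]], 0)
})

test_that("classification applies the strict effect and q rule", {
  res <- data.frame(taxon = c("up", "edge", "weak", "down"),
                    effect = c(0.87, 0.5, -0.49, -0.9),
                    q_expected = c(1e-5, 1e-5, 1e-4, 1e-4),
                    median_clr_diff = c(1, 0.5, -0.5, -1),
                    prevalence_1 = 0.5, prevalence_2 = 0.5,
                    median_prop_1 = 0.1, median_prop_2 = 0.1)
  cl <- classify_da(res)
  expect_equal(cl$class[cl$taxon == "up"], "increased")
  expect_equal(cl$class[cl$taxon == "edge"], "unchanged")   # strict > 0.5
  expect_equal(cl$class[cl$taxon == "weak"], "unchanged")   # |effect| < 0.5
  expect_equal(cl$class[cl$taxon == "down"], "decreased")
  expect_equal(cl$taxon, cl$taxon[order(-cl$effect)])       # sorted by effect

  hi_q <- res
  hi_q$q_expected <- 0.5
  expect_true(all(classify_da(hi_q)$class == "unchanged"))
})

test_that("MC correlation recovers self- and planted correlations", {
  # counts from the community simulator, so between-sample CLR variation
  # dominates the Dirichlet resampling noise
  sim <- simulate_cohort(sim_config(n_samples = 30L, seed = 67L))
  inst <- mc_clr_instances(sim$counts, n_mc = 32L, seed = 67L)
  mean_clr <- Reduce(`+`, inst$instances) / 32
  taxon <- colnames(sim$counts)[4L]
  marker <- mean_clr[, taxon]
  res <- aldex_corr(inst, marker)
  expect_gt(res$rho_expected[res$taxon == taxon], 0.95)

  dec <- aldex_corr(inst, -marker)
  expect_lt(dec$rho_expected[dec$taxon == taxon], -0.95)

  expect_error(aldex_corr(inst, rep(1, 30L)), "constant")
  expect_error(aldex_corr(inst, marker[-1L]), "one value per sample")
})

test_that("q_expected is invariant to taxon order", {
  set.seed(71)
  counts <- matrix(rpois(20L * 5L, 80L) + 5L, 20L, 5L,
                   dimnames = list(paste0("s", 1:20), letters[1:5]))
  g <- rep(c("a", "b"), 10L)
  inst <- mc_clr_instances(counts, 16L, seed = 2L)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  inst_perm <- inst
  inst_perm$instances <- lapply(inst$instances,
                                function(m) m[, perm, drop = FALSE])
  inst_perm$counts <- inst$counts[, perm, drop = FALSE]
  r1 <- aldex_da(inst, g)
  r2 <- aldex_da(inst_perm, g)
  expect_equal(r1$q_expected[match(r2$taxon, r1$taxon)], r2$q_expected,
               tolerance = 1e-12)
  expect_equal(r1$effect[match(r2$taxon, r1$taxon)], r2$effect,
               tolerance = 1e-12)
})
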