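test_that("simulation is deterministic given the seed and conserves depth", {
  cfg <- sim_config(n_samples = 12L, seed = 42L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$sigma, b$truth$sigma)
  # count rows sum exactly to the drawn depth (multinomial closure)
  expect_identical(unname(rowSums(a$counts)), unname(a$truth$depth))

  c_ <- simulate_cohort(cfg, seed = 43L)
  expect_false(identical(a$counts, c_$counts))
})

test_that("empty cohort request yields an empty table, not an error", {
  sim <- simulate_cohort(sim_config(n_samples = 0L, seed = 1L))
  expect_equal(nrow(sim$counts), 0L)
  expect_equal(ncol(sim$counts), 30L)
  expect_equal(nrow(sim$metadata), 0L)
})

test_that("block covariance plants guild structure; no blocks stay diffuse", {
  # Monte-Carlo over 20 seeds: median within/between-block Spearman rho.
  blocks <- preset_config("adult-like")$guild_blocks
  names(blocks) <- c("a", "b")
  within_med <- between_med <- diffuse_med <- numeric(20L)
  for (s in seq_len(20L)) {
    str_cfg <- sim_config(n_samples = 60L, guild_blocks = blocks,
                          within_block_cov = 0.7, between_block_cov = -0.5,
                          seed = 100L + s)
    sim <- simulate_cohort(str_cfg)
    rel <- relative_abundance(sim$counts)
    rho <- suppressWarnings(stats::cor(apply(rel, 2L, rank)))
    in_a <- blocks$a
    in_b <- blocks$b
    w <- c(rho[in_a, in_a][upper.tri(diag(length(in_a)))],
           rho[in_b, in_b][upper.tri(diag(length(in_b)))])
    within_med[s] <- median(w)
    between_med[s] <- median(rho[in_a, in_b])

    dif <- simulate_cohort(sim_config(n_samples = 60L, seed = 100L + s))
    rd <- relative_abundance(dif$counts)
    rhod <- suppressWarnings(stats::cor(apply(rd, 2L, rank)))
    diffuse_med[s] <- median(abs(rhod[upper.tri(rhod)]))
  }
  expect_gt(median(within_med), 0.3)
  expect_lt(median(between_med), -0.2)
  expect_lt(median(diffuse_med), 0.15)
})

test_that("paired generator carries subject pairing and shift sign symmetry", {
  shift <- numeric(30L)
  shift[5L] <- 2
  cfg_up <- sim_config(n_samples = 20L, post_shift = shift, seed = 8L)
  cfg_dn <- sim_config(n_samples = 20L, post_shift = -shift, seed = 8L)
  up <- simulate_circumcision_pair(cfg_up)
  dn <- simulate_circumcision_pair(cfg_dn)
  md <- up$metadata
  expect_setequal(md$timepoint, c("pre", "post"))
  expect_equal(sort(md$subject_id[md$timepoint == "pre"]),
               sort(md$subject_id[md$timepoint == "post"]))
  # the same subjects latent CLR shifts up in one config, down in the other
  taxon <- colnames(up$counts)[5L]
  d_up <- up$truth$latent_clr[md$timepoint == "post", taxon] -
    up$truth$latent_clr[md$timepoint == "pre", taxon]
  d_dn <- dn$truth$latent_clr[md$timepoint == "post", taxon] -
    dn$truth$latent_clr[md$timepoint == "pre", taxon]
  expect_true(all(d_up > 0))
  expect_true(all(d_dn < 0))
  expect_equal(mean(d_up), -mean(d_dn), tolerance = 1e-8)
})

test_that("spiked negatives are contaminant-dominated and dna_conc coupled", {
  cfg <- sim_config(n_samples = 40L, contaminant_taxa = c("ContamX", "ContamY"),
                    n_negatives = 5L, seed = 21L)
  sim <- simulate_cohort(cfg)
  sp <- spike_negatives(sim$counts, sim$metadata, cfg)
  negs <- sp$metadata$is_negative_control
  expect_equal(sum(negs), 5L)
  neg_counts <- sp$counts[sp$metadata$sample_id[negs], , drop = FALSE]
  cont_frac <- rowSums(neg_counts[, c("ContamX", "ContamY")]) /
    rowSums(neg_counts)
  expect_true(all(cont_frac > 0.9))
  expect_true(all(!is.na(sp$metadata$dna_conc[!negs])))

  # zero negatives requested: identity
  cfg0 <- sim_config(n_samples = 10L, n_negatives = 0L, seed = 3L)
  sim0 <- simulate_cohort(cfg0)
  sp0 <- spike_negatives(sim0$counts, sim0$metadata, cfg0)
  expect_identical(sp0$counts, sim0$counts)
})

test_that("marker links reject unknown taxa and respect the compartment", {
  links <- data.frame(taxon = "NotATaxon", marker = "CD11c",
                      strength = 0.8, sign = -1)
  cfg <- sim_config(n_samples = 15L, marker_links = links, seed = 2L)
  sim <- simulate_cohort(sim_config(n_samples = 15L, seed = 2L))
  expect_error(simulate_markers(sim$counts, sim$truth, cfg, sim$metadata),
               "unknown taxa")

  links2 <- data.frame(taxon = "Mobiluncus", marker = "CD11c",
                       strength = 1.2, sign = -1)
  cfg2 <- sim_config(n_samples = 40L, marker_links = links2,
                     marker_noise_sd = 0.2, seed = 2L)
  sim2 <- simulate_cohort(cfg2)
  dens <- simulate_markers(sim2$counts, sim2$truth, cfg2, sim2$metadata)
  expect_true(all(dens$density > 0))
  clr_mob <- sim2$truth$latent_clr[, "Mobiluncus"]
  get_cor <- function(aspect, layer) {
    sub <- dens[dens$aspect == aspect & dens$layer == layer &
                  dens$marker == "CD11c", ]
    cor(log(sub$density[match(rownames(sim2$counts),
                              sub$participant_id)]), clr_mob)
  }
  expect_lt(get_cor("inner", "dermis"), -0.7)   # linked compartment
  expect_lt(abs(get_cor("outer", "dermis")), 0.5)  # unlinked: noise only
})
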