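# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.default_taxa <- c(
  "Peptoniphilus", "Hoylesella", "Varibaculum", "Ezakiella", "Porphyromonas",
  "Campylobacter", "Negativicoccus", "Fastidiosipila", "Arcanobacterium",
  "Actinotignum", "Staphylococcus", "Corynebacterium", "Finegoldia",
  "Anaerococcus", "Prevotella", "Dialister", "Mobiluncus",
  "Propionimicrobium", "Peptostreptococcus", "Murdochiella", "Fenollaria",
  "Lactobacillus", "Streptococcus", "Actinomyces", "Veillonella",
  "Gardnerella", "Atopobium", "Micrococcus", "Cutibacterium", "Escherichia")

# The two guilds observed in adult penile communities: a skin-associated
# gram-positive cluster and an anaerobe cluster, mutually exclusive.
.adult_blocks <- list(
  skin     = c("Finegoldia", "Corynebacterium", "Anaerococcus",
               "Staphylococcus", "Cutibacterium", "Micrococcus",
               "Lactobacillus", "Streptococcus"),
  anaerobe = c("Prevotella", "Hoylesella", "Peptoniphilus", "Porphyromonas",
               "Campylobacter", "Dialister", "Ezakiella", "Mobiluncus"))

# Baseline log-median immune-cell densities (cells/mm^2) by marker and layer,
# on the scale reported for pediatric foreskin tissue.
.marker_baselines <- list(
  dermis    = c(CD3 = 470, CD4 = 460, CD56 = 130, CD11c = 860, CD207 = 97,
                CD68 = 2700, CD117 = 120, tryptase = 130),
  epidermis = c(CD3 = 80, CD4 = 60, CD56 = 45, CD11c = 130, CD207 = 570,
                CD68 = 150, CD117 = 25, tryptase = 30))

#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set of the logistic-normal-multinomial
#' generative model: a latent log-abundance vector per sample is drawn from a
#' multivariate normal with block-structured covariance (the "guild" blocks),
#' mapped to proportions by softmax, and counts are drawn multinomially at a
#' lognormal sequencing depth.
#'
#' @param n_taxa Number of taxa.
#' @param taxon_names Taxon names (defaults to 30 genera typical of the
#'   uncircumcised penile microbiota).
#' @param guild_blocks List of character vectors partitioning (a subset of)
#'   taxa into covariance blocks; empty list means diagonal covariance.
#' @param within_block_cov Latent covariance between taxa in the same block,
#'   in (0, 1).
#' @param between_block_cov Latent covariance between taxa of different
#'   blocks, in (-1, 0].
#' @param baseline_logmean Latent mean log abundance per taxon; default is a
#'   graded series giving a realistic rank-abundance curve.
#' @param n_samples Number of samples (subjects).
#' @param depth_logmean,depth_logsd Lognormal sequencing-depth parameters.
#' @param post_shift Latent log-abundance shift applied at the post timepoint
#'   (named or positional numeric of length n_taxa).
#' @param marker_links data.frame(taxon, marker, strength, sign) of planted
#'   monotone links between taxon CLR and immune-marker density.
#' @param group_effect Named numeric of multiplicative density factors applied
#'   to the pathological-phimosis group (names are markers).
#' @param marker_noise_sd Lognormal noise SD for densities.
#' @param link_aspect,link_layer Tissue compartment in which marker links and
#'   group effects act (other compartments receive pure noise).
#' @param contaminant_taxa Names of taxa treated as reagent contaminants by
#'   [spike_negatives()].
#' @param n_negatives Number of negative-control samples to append.
#' @param contaminant_rate Baseline contaminant proportion at DNA
#'   concentration 1 ng/uL.
#' @param contaminant_freq_coupled If TRUE (default) contaminant load in true
#'   samples scales as 1/dna_conc; if FALSE it is constant (frequency-mode
#'   null).
#' @param prop_phimosis Fraction of subjects labelled pathological phimosis.
#' @param cohort Cohort label written into metadata.
#' @param seed Integer seed; every draw is deterministic given it.
#' @return A list of class "sim_config".
#' @export
sim_config <- function(n_taxa = 30L,
                       taxon_names = .default_taxa[seq_len(n_taxa)],
                       guild_blocks = list(),
                       within_block_cov = 0.6,
                       between_block_cov = -0.4,
                       baseline_logmean = seq(2.5, -2.5,
                                              length.out = n_taxa),
                       n_samples = 60L,
                       depth_logmean = log(47743) - 0.08,
                       depth_logsd = 0.4,
                       post_shift = numeric(n_taxa),
                       marker_links = NULL,
                       group_effect = NULL,
                       marker_noise_sd = 0.5,
                       link_aspect = "inner",
                       link_layer = "dermis",
                       contaminant_taxa = character(0),
                       n_negatives = 0L,
                       contaminant_rate = 0.02,
                       contaminant_freq_coupled = TRUE,
                       prop_phimosis = 0.4,
                       cohort = "pediatric",
                       seed = 1L) {
  if (n_taxa < 1L) stop("n_taxa must be >= 1")
  if (length(taxon_names) != n_taxa) {
    stop("taxon_names must have length n_taxa")
  }
  stray <- setdiff(unlist(guild_blocks), taxon_names)
  if (length(stray) > 0L) {
    stop("guild_blocks name unknown taxa: ", paste(stray, collapse = ", "))
  }
  if (within_block_cov <= 0 || within_block_cov >= 1) {
    stop("within_block_cov must be in (0, 1)")
  }
  if (between_block_cov > 0 || between_block_cov <= -1) {
    stop("between_block_cov must be in (-1, 0]")
  }
  if (length(post_shift) != n_taxa) stop("post_shift must have length n_taxa")
  names(post_shift) <- taxon_names
  structure(list(
    n_taxa = as.integer(n_taxa), taxon_names = taxon_names,
    guild_blocks = guild_blocks, within_block_cov = within_block_cov,
    between_block_cov = between_block_cov,
    baseline_logmean = stats::setNames(baseline_logmean, taxon_names),
    n_samples = as.integer(n_samples),
    depth_logmean = depth_logmean, depth_logsd = depth_logsd,
    post_shift = post_shift, marker_links = marker_links,
    group_effect = group_effect, marker_noise_sd = marker_noise_sd,
    link_aspect = link_aspect, link_layer = link_layer,
    contaminant_taxa = contaminant_taxa,
    n_negatives = as.integer(n_negatives),
    contaminant_rate = contaminant_rate,
    contaminant_freq_coupled = contaminant_freq_coupled,
    prop_phimosis = prop_phimosis, cohort = cohort,
    seed = as.integer(seed)), class = "sim_config")
}

#' Named simulator presets
#'
#' "pediatric-like": no covariance blocks (diffuse correlation structure,
#' moderate sequencing depth). "adult-like": two anti-correlated guild blocks
#' (within 0.6, between -0.4) and deeper sequencing, emulating the structured
#' adult penile community.
#'
#' @param name "pediatric-like" or "adult-like".
#' @param ... Overrides passed on to [sim_config()].
#' @return A "sim_config" object.
#' @export
preset_config <- function(name = c("pediatric-like", "adult-like"), ...) {
  name <- match.arg(name)
  if (name == "pediatric-like") {
    sim_config(guild_blocks = list(), cohort = "pediatric", ...)
  } else {
    sim_config(guild_blocks = .adult_blocks,
               within_block_cov = 0.6, between_block_cov = -0.4,
               depth_logmean = log(190591) - 0.08,
               cohort = "adult", ...)
  }
}

#' Assemble the latent covariance matrix from guild blocks
#'
#' Unit diagonal; `within_block_cov` between members of the same block;
#' `between_block_cov` between members of different blocks; zero elsewhere.
#' Projected to the nearest positive semi-definite matrix by eigenvalue
#' clipping at 1e-10 if needed.
#'
#' @param config A "sim_config".
#' @return Covariance matrix (n_taxa x n_taxa) with taxon dimnames.
#' @export
build_sigma <- function(config) {
  p <- config$n_taxa
  sigma <- diag(p)
  dimnames(sigma) <- list(config$taxon_names, config$taxon_names)
  blocks <- config$guild_blocks
  if (length(blocks) > 0L) {
    for (b in blocks) {
      sigma[b, b] <- config$within_block_cov
    }
    if (length(blocks) > 1L) {
      for (i in seq_along(blocks)) {
        for (j in seq_along(blocks)) {
          if (i != j) sigma[blocks[[i]], blocks[[j]]] <- config$between_block_cov
        }
      }
    }
    diag(sigma) <- 1
  }
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 1e-10)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    sigma <- (sigma + t(sigma)) / 2
    dimnames(sigma) <- list(config$taxon_names, config$taxon_names)
    if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
        < -1e-8) {
      stop("covariance not positive semi-definite after repair")
    }
  }
  sigma
}

# Draw one multivariate-normal matrix (n x p) given a pre-factored sigma.
rmvn <- function(n, mu, chol_sigma) {
  p <- length(mu)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol_sigma
  sweep(z, 2L, mu, "+")
}

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

# Core sampler shared by the cohort and paired generators. Returns latent
# z, proportions, depths and counts for n samples.
draw_samples <- function(config, n, z = NULL) {
  sigma <- build_sigma(config)
  if (is.null(z)) {
    ch <- chol(sigma + diag(1e-10, config$n_taxa))
    z <- rmvn(n, config$baseline_logmean, ch)
    colnames(z) <- config$taxon_names
  }
  props <- softmax_rows(z)
  depth <- pmax(1, round(stats::rlnorm(n, config$depth_logmean,
                                       config$depth_logsd)))
  counts <- matrix(0L, n, config$n_taxa,
                   dimnames = list(NULL, config$taxon_names))
  for (i in seq_len(n)) {
    counts[i, ] <- stats::rmultinom(1L, depth[i], props[i, ])[, 1L]
  }
  list(z = z, props = props, depth = depth, counts = counts, sigma = sigma)
}

make_metadata <- function(sample_ids, subject_ids, config, timepoint = "none",
                          indication = NULL) {
  n <- length(sample_ids)
  if (is.null(indication)) indication <- rep("none", n)
  data.frame(sample_id = sample_ids, cohort = rep(config$cohort, n),
             subject_id = subject_ids,
             timepoint = rep(timepoint, length.out = n),
             indication = indication,
             age_years = if (n > 0L) round(stats::runif(n, 0.5, 17.5), 1)
                         else numeric(0),
             ethnicity = if (n > 0L)
               sample(c("caucasian", "middle_eastern", "asian",
                        "african_american", "other"), n, replace = TRUE,
                      prob = c(0.6, 0.15, 0.12, 0.07, 0.06))
               else character(0),
             dna_conc = rep(NA_real_, n),
             is_negative_control = rep(FALSE, n),
             stringsAsFactors = FALSE)
}

#' Simulate a single-timepoint cohort
#'
#' Draws `n_samples` independent communities from the logistic-normal-
#' multinomial model defined by `config`. Indication labels are assigned
#' with `prop_phimosis` pathological-phimosis subjects, the remainder split
#' between elective and non-elective.
#'
#' @param config A "sim_config".
#' @param seed Seed; defaults to `config$seed`.
#' @return List with `counts` (integer matrix), `metadata` (data.frame) and
#'   `truth` (latent covariance, latent CLR matrix, planted parameters).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  with_seed(seed, {
    n <- config$n_samples
    d <- draw_samples(config, n)
    ids <- if (n > 0L) sprintf("%s_S%03d", substr(config$cohort, 1L, 3L),
                               seq_len(n)) else character(0)
    rownames(d$counts) <- ids
    indication <- if (n > 0L) {
      k <- round(n * config$prop_phimosis)
      sample(c(rep("pathological_phimosis", k),
               rep(c("elective", "non_elective"), length.out = n - k)))
    } else character(0)
    md <- make_metadata(ids, ids, config, timepoint = "none",
                        indication = indication)
    truth <- list(sigma = d$sigma, post_shift = config$post_shift,
                  marker_links = config$marker_links,
                  contaminants = config$contaminant_taxa,
                  group_effect = config$group_effect,
                  latent_clr = clr_from_latent(d$z, ids),
                  depth = stats::setNames(d$depth, ids))
    list(counts = d$counts, metadata = md, truth = truth)
  })
}

clr_from_latent <- function(z, ids) {
  out <- z - rowMeans(z)
  rownames(out) <- ids
  out
}

#' Simulate paired pre/post-circumcision samples
#'
#' Each subject gets a latent community z; the pre sample is a multinomial
#' draw from softmax(z) and the post sample from softmax(z + post_shift), so
#' the pairing carries subject-level community structure and the planted
#' shift is the only systematic pre/post difference.
#'
#' @param config A "sim_config" (its `post_shift` is the planted effect and
#'   `n_samples` the number of subjects).
#' @param seed Seed; defaults to `config$seed`.
#' @return List with `counts`, `metadata` (subject pairing in `subject_id`,
#'   timepoint pre/post) and `truth`.
#' @export
simulate_circumcision_pair <- function(config, seed = config$seed) {
  with_seed(seed, {
    n <- config$n_samples
    pre <- draw_samples(config, n)
    z_post <- sweep(pre$z, 2L, config$post_shift, "+")
    post <- draw_samples(config, n, z = z_post)
    subj <- sprintf("P%03d", seq_len(n))
    ids <- c(paste0(subj, "_pre"), paste0(subj, "_post"))
    counts <- rbind(pre$counts, post$counts)
    rownames(counts) <- ids
    indication <- sample(c(rep("pathological_phimosis",
                               round(n * config$prop_phimosis)),
                           rep(c("elective", "non_elective"),
                               length.out = n - round(n * config$prop_phimosis))))
    md <- make_metadata(ids, c(subj, subj), config,
                        timepoint = rep(c("pre", "post"), each = n),
                        indication = c(indication, indication))
    md$age_years[(n + 1L):(2L * n)] <- md$age_years[seq_len(n)]
    md$ethnicity[(n + 1L):(2L * n)] <- md$ethnicity[seq_len(n)]
    truth <- list(sigma = pre$sigma, post_shift = config$post_shift,
                  marker_links = config$marker_links,
                  contaminants = config$contaminant_taxa,
                  group_effect = config$group_effect,
                  latent_clr = clr_from_latent(rbind(pre$z, z_post), ids),
                  depth = stats::setNames(c(pre$depth, post$depth), ids))
    list(counts = counts, metadata = md, truth = truth)
  })
}

#' Simulate immune-cell density tables with planted taxon links
#'
#' Densities follow a log-linear model on the latent CLR scale:
#' `density = exp(a + sum(sign * strength * CLR(taxon)) + noise)` in the
#' linked compartment (`link_aspect`/`link_layer`), multiplied by
#' `group_effect[marker]` for pathological-phimosis subjects. All other
#' compartments receive pure lognormal noise around marker- and
#' layer-specific baselines, so links and group effects are compartment
#' specific, as in foreskin tissue where dermal and epidermal infiltrates
#' differ.
#'
#' @param counts Count matrix from the simulator (defines the participants:
#'   one density record set per pre-timepoint or unpaired sample).
#' @param truth Ground-truth list from the simulator (its `latent_clr` drives
#'   the links).
#' @param config The "sim_config" used to generate `counts`.
#' @param metadata Metadata from the simulator (for phimosis labels).
#' @param seed Seed; defaults to `config$seed + 1`.
#' @return A density data.frame (participant_id, aspect, layer, marker,
#'   density).
#' @export
simulate_markers <- function(counts, truth, config, metadata,
                             seed = config$seed + 1L) {
  links <- config$marker_links
  if (!is.null(links)) {
    bad <- setdiff(links$taxon, colnames(counts))
    if (length(bad) > 0L) {
      stop("marker_links reference unknown taxa: ", paste(bad, collapse = ", "))
    }
    bad_m <- setdiff(links$marker, .density_markers)
    if (length(bad_m) > 0L) {
      stop("marker_links reference unknown markers: ",
           paste(bad_m, collapse = ", "))
    }
  }
  keep <- metadata$timepoint %in% c("pre", "none") &
    !metadata$is_negative_control
  md <- metadata[keep, , drop = FALSE]
  with_seed(seed, {
    rows <- vector("list", 0L)
    for (aspect in c("inner", "outer")) {
      for (layer in c("epidermis", "dermis")) {
        base <- log(.marker_baselines[[layer]])
        linked <- aspect == config$link_aspect && layer == config$link_layer
        for (marker in .density_markers) {
          mu <- rep(base[[marker]], nrow(md))
          if (linked && !is.null(links)) {
            li <- links[links$marker == marker, , drop = FALSE]
            for (k in seq_len(nrow(li))) {
              mu <- mu + li$sign[k] * li$strength[k] *
                truth$latent_clr[md$sample_id, li$taxon[k]]
            }
          }
          dens <- exp(mu + stats::rnorm(nrow(md), 0, config$marker_noise_sd))
          if (linked && !is.null(config$group_effect) &&
              marker %in% names(config$group_effect)) {
            phim <- md$indication == "pathological_phimosis"
            dens[phim] <- dens[phim] * config$group_effect[[marker]]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = md$subject_id, aspect = aspect, layer = layer,
            marker = marker, density = dens, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_densities(out)
    out
  })
}

#' Append spiked negative controls and DNA concentrations
#'
#' Negative-control samples concentrated on `contaminant_taxa` are appended
#' to the count table, and every true sample receives a DNA concentration
#' plus added contaminant reads whose proportion scales as 1/dna_conc (the
#' frequency-mode signature) and whose presence is sparse across true
#' samples (the prevalence-mode signature). With
#' `contaminant_freq_coupled = FALSE` the contaminant proportion is constant
#' in dna_conc, a frequency-mode null.
#'
#' @param counts Count matrix of true samples.
#' @param metadata Matching metadata.
#' @param config A "sim_config" with nonempty `contaminant_taxa` (taxa are
#'   added as new columns if absent) and `n_negatives`.
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return List with augmented `counts` and `metadata`.
#' @export
spike_negatives <- function(counts, metadata, config,
                            seed = config$seed + 2L) {
  if (config$n_negatives == 0L) {
    return(list(counts = counts, metadata = metadata))
  }
  if (length(config$contaminant_taxa) == 0L) {
    stop("contaminant_taxa must be nonempty to spike negatives")
  }
  cont <- config$contaminant_taxa
  new_taxa <- setdiff(cont, colnames(counts))
  if (length(new_taxa) > 0L) {
    counts <- cbind(counts, matrix(0L, nrow(counts), length(new_taxa),
                                   dimnames = list(rownames(counts),
                                                   new_taxa)))
  }
  with_seed(seed, {
    n <- nrow(counts)
    dna <- stats::rlnorm(n, 0, 0.8)
    target <- if (config$contaminant_freq_coupled) {
      pmin(0.4, config$contaminant_rate / dna)
    } else {
      rep(config$contaminant_rate, n)
    }
    present <- stats::runif(n) < 0.2
    depth <- rowSums(counts)
    for (i in seq_len(n)) {
      if (!present[i] || depth[i] == 0L) next
      extra <- round(depth[i] * target[i] / (1 - min(target[i], 0.5)))
      if (extra < 1L) next
      add <- stats::rmultinom(1L, extra, rep(1, length(cont)))[, 1L]
      counts[i, cont] <- counts[i, cont] + add
    }
    neg_ids <- sprintf("NEG%02d", seq_len(config$n_negatives))
    neg_depth <- pmax(50L, round(stats::rlnorm(config$n_negatives,
                                               log(3000), 0.5)))
    base_prop <- rep(1e-4, ncol(counts))
    names(base_prop) <- colnames(counts)
    base_prop[cont] <- 1 / length(cont)
    neg <- t(vapply(seq_len(config$n_negatives), function(i) {
      stats::rmultinom(1L, neg_depth[i], base_prop)[, 1L]
    }, integer(ncol(counts))))
    rownames(neg) <- neg_ids
    out_counts <- rbind(counts, neg)
    storage.mode(out_counts) <- "integer"
    neg_md <- make_metadata(neg_ids, neg_ids, config)
    neg_md$is_negative_control <- TRUE
    neg_md$dna_conc <- NA_real_
    metadata$dna_conc <- dna
    out_md <- rbind(metadata, neg_md)
    rownames(out_md) <- NULL
    list(counts = out_counts, metadata = out_md)
  })
}
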