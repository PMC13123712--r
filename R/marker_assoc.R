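#' Penalized-spline regression of CLR abundance on a marker density
#'
#' Fits `clr ~ s(marker, k = 3, bs = "cs")` with mgcv: a cubic regression
#' spline with shrinkage penalty and basis dimension 3, smoothing parameter
#' chosen by restricted maximum likelihood, with additional null-space
#' shrinkage (`select = TRUE`) so the smooth can be penalized to effectively
#' zero. Reports the smooth's effective degrees of freedom, the model's
#' adjusted R-squared, the smooth's p-value, the sign of the fitted
#' end-to-end trend, and basis-adequacy diagnostics (k-index and its p),
#' which are informational only.
#'
#' @param clr_values CLR values for one taxon, one per sample.
#' @param marker Marker density per sample (same order).
#' @return List of class "spline_fit": edf, adj_r2, p, trend_sign, k_index,
#'   k_p, n.
#' @export
spline_assoc <- function(clr_values, marker) {
  ok <- !is.na(clr_values) & !is.na(marker)
  if (sum(ok) < 10L) {
    stop("at least 10 complete (clr, marker) pairs are required")
  }
  y <- clr_values[ok]
  x <- marker[ok]
  if (length(unique(x)) == 1L) stop("marker is constant")
  fit <- mgcv::gam(y ~ s(x, k = 3, bs = "cs"), method = "REML",
                   select = TRUE)
  sm <- summary(fit)
  kc <- tryCatch(mgcv::k.check(fit), error = function(e) NULL)
  fitted_ends <- stats::predict(fit, newdata = data.frame(x = range(x)))
  trend <- sign(fitted_ends[2L] - fitted_ends[1L])
  structure(list(edf = unname(sm$s.table[1L, "edf"]),
                 adj_r2 = unname(sm$r.sq),
                 p = unname(sm$s.table[1L, "p-value"]),
                 trend_sign = unname(trend),
                 k_index = if (is.null(kc)) NA_real_ else
                   unname(kc[1L, "k-index"]),
                 k_p = if (is.null(kc)) NA_real_ else
                   unname(kc[1L, "p-value"]),
                 n = length(y)),
            class = "spline_fit")
}

#' Concordant associations between two analysis arms
#'
#' BH adjustment is applied within each arm across the full taxon x marker
#' grid; a pair is reported iff both adjusted values fall at or below
#' `q_threshold` and (by default) the response directions agree (sign of the
#' MC correlation vs sign of the spline's fitted end-to-end trend).
#'
#' @param spline_fits data.frame with columns taxon, marker, edf, adj_r2, p,
#'   trend_sign.
#' @param corr_results data.frame with columns taxon, marker, rho_expected,
#'   p_expected.
#' @param q_threshold FDR threshold applied to both arms (default 0.05).
#' @param require_sign_agreement Drop pairs whose arms disagree in direction
#'   (default TRUE).
#' @return data.frame of concordant pairs: taxon, marker, edf, adj_r2,
#'   spline_p_adj, rho_expected, corr_p_adj, direction.
#' @export
concordance <- function(spline_fits, corr_results, q_threshold = 0.05,
                        require_sign_agreement = TRUE) {
  if (nrow(spline_fits) == 0L && nrow(corr_results) == 0L) {
    return(data.frame(taxon = character(0), marker = character(0),
                      edf = numeric(0), adj_r2 = numeric(0),
                      spline_p_adj = numeric(0), rho_expected = numeric(0),
                      corr_p_adj = numeric(0), direction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key_s <- paste(spline_fits$taxon, spline_fits$marker)
  key_c <- paste(corr_results$taxon, corr_results$marker)
  miss <- c(setdiff(key_s, key_c), setdiff(key_c, key_s))
  if (length(miss) > 0L) {
    stop("arms computed on different grids; unmatched pair(s): ",
         paste(utils::head(miss, 5L), collapse = "; "))
  }
  corr_results <- corr_results[match(key_s, key_c), , drop = FALSE]
  spline_q <- stats::p.adjust(spline_fits$p, method = "BH")
  corr_q <- stats::p.adjust(corr_results$p_expected, method = "BH")
  hit <- spline_q <= q_threshold & corr_q <= q_threshold
  if (require_sign_agreement) {
    hit <- hit & sign(corr_results$rho_expected) == spline_fits$trend_sign
  }
  out <- data.frame(taxon = spline_fits$taxon[hit],
                    marker = spline_fits$marker[hit],
                    edf = spline_fits$edf[hit],
                    adj_r2 = spline_fits$adj_r2[hit],
                    spline_p_adj = spline_q[hit],
                    rho_expected = corr_results$rho_expected[hit],
                    corr_p_adj = corr_q[hit],
                    direction = sign(corr_results$rho_expected[hit]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Dual-arm microbe-immune association pipeline
#'
#' Runs both analysis arms over the taxa detected in at least
#' `min_detection_prev` of samples and the markers measured in one tissue
#' compartment: (i) a penalized-spline fit of CZM/CLR abundance on each
#' marker density and (ii) Monte-Carlo Dirichlet CLR Spearman correlation;
#' then reports the concordant associations.
#'
#' @param counts Count matrix (baseline samples).
#' @param metadata Metadata mapping sample_id to subject_id (participants).
#' @param densities Density data.frame (participant_id, aspect, layer,
#'   marker, density).
#' @param aspect,layer Tissue compartment to analyse.
#' @param markers Markers to test (default: all present in the compartment).
#' @param min_detection_prev Minimum fraction of samples in which a taxon is
#'   detected (> 0 reads) to be tested (default 0.3).
#' @param n_mc,prior,seed Passed to [mc_clr_instances()].
#' @param q_threshold,require_sign_agreement Passed to [concordance()].
#' @return List with `spline` and `corr` grids and the `concordant` table.
#' @export
assoc_pipeline <- function(counts, metadata, densities,
                           aspect = "inner", layer = "dermis",
                           markers = NULL, min_detection_prev = 0.3,
                           n_mc = 128L, prior = 0.5, seed = 1L,
                           q_threshold = 0.05,
                           require_sign_agreement = TRUE) {
  md <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  keep <- !(md$is_negative_control %in% TRUE) &
    md$timepoint %in% c("pre", "none")
  counts <- counts[keep, , drop = FALSE]
  md <- md[keep, , drop = FALSE]
  dd <- densities[densities$aspect == aspect & densities$layer == layer, ,
                  drop = FALSE]
  if (is.null(markers)) markers <- unique(dd$marker)
  dens_mat <- vapply(markers, function(m) {
    sub <- dd[dd$marker == m, , drop = FALSE]
    sub$density[match(md$subject_id, sub$participant_id)]
  }, numeric(nrow(md)))
  complete <- stats::complete.cases(dens_mat)
  if (sum(complete) < 10L) {
    stop("fewer than 10 samples with complete densities in ", aspect, " ",
         layer)
  }
  counts <- counts[complete, , drop = FALSE]
  dens_mat <- dens_mat[complete, , drop = FALSE]
  detected <- colMeans(counts > 0) >= min_detection_prev
  counts <- counts[, detected, drop = FALSE]
  clr <- clr_transform(czm_replace(relative_abundance(counts)))
  instances <- mc_clr_instances(counts, n_mc = n_mc, prior = prior,
                                seed = seed)
  spline_rows <- list()
  corr_rows <- list()
  for (m in markers) {
    mv <- dens_mat[, m]
    cr <- aldex_corr(instances, mv)
    cr$marker <- m
    corr_rows[[m]] <- cr
    for (taxon in colnames(counts)) {
      sf <- spline_assoc(clr[, taxon], mv)
      spline_rows[[paste(taxon, m)]] <- data.frame(
        taxon = taxon, marker = m, edf = sf$edf, adj_r2 = sf$adj_r2,
        p = sf$p, trend_sign = sf$trend_sign, stringsAsFactors = FALSE)
    }
  }
  spline_fits <- do.call(rbind, spline_rows)
  rownames(spline_fits) <- NULL
  corr_results <- do.call(rbind, corr_rows)
  rownames(corr_results) <- NULL
  list(spline = spline_fits, corr = corr_results,
       concordant = concordance(spline_fits, corr_results,
                                q_threshold = q_threshold,
                                require_sign_agreement =
                                  require_sign_agreement))
}
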