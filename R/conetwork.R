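#' Most abundant taxa by mean relative abundance
#'
#' @param rel Proportion matrix.
#' @param n Number of taxa to return (default 30).
#' @return Character vector of taxon ids, ranked by mean relative abundance
#'   (descending), ties broken lexicographically.
#' @export
top_taxa <- function(rel, n = 30L) {
  if (n > ncol(rel)) {
    stop("requested ", n, " taxa but only ", ncol(rel), " available")
  }
  means <- colMeans(rel)
  ord <- order(-means, colnames(rel))
  colnames(rel)[ord][seq_len(n)]
}

# Spearman rho matrix (average ranks for ties) with two-sided p-values from
# the asymptotic t approximation; matches cor.test(..., method = "spearman",
# exact = FALSE).
spearman_matrix <- function(x) {
  n <- nrow(x)
  r <- apply(x, 2L, rank)
  constant <- apply(x, 2L, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(r))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  tt <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[rho^2 >= 1] <- 0
  diag(p) <- 0
  list(rho = rho, p = p)
}

#' Spearman co-occurrence network over a fixed taxon set
#'
#' Pairwise Spearman correlations (average ranks for ties) between the given
#' taxa across samples, with two-sided p-values BH-adjusted over the
#' n(n-1)/2 upper-triangle tests only. Pairs involving a zero-variance taxon
#' get rho = NA and are excluded from the BH family (their count is
#' reported). A hierarchical-clustering order (average linkage on 1 - rho)
#' is included for heatmap display.
#'
#' @param rel Proportion (or CLR, via `scale`) matrix.
#' @param taxa Taxon ids to include, e.g. from [top_taxa()].
#' @return List of class "co_network": `taxa`, `rho`, `q`, `n_na_pairs`,
#'   `cluster_order`, `n_samples`.
#' @export
correlation_network <- function(rel, taxa = colnames(rel)) {
  missing_taxa <- setdiff(taxa, colnames(rel))
  if (length(missing_taxa) > 0L) {
    stop("taxa not in table: ", paste(missing_taxa, collapse = ", "))
  }
  x <- rel[, taxa, drop = FALSE]
  if (nrow(x) < 4L) stop("at least 4 samples are required")
  sp <- spearman_matrix(x)
  ut <- upper.tri(sp$rho)
  pvec <- sp$p[ut]
  ok <- !is.na(pvec)
  q <- matrix(NA_real_, length(taxa), length(taxa),
              dimnames = dimnames(sp$rho))
  qvec <- rep(NA_real_, length(pvec))
  qvec[ok] <- stats::p.adjust(pvec[ok], method = "BH")
  q[ut] <- qvec
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  d <- 1 - sp$rho
  d[is.na(d)] <- 1
  ord <- if (length(taxa) > 2L) {
    stats::hclust(stats::as.dist(d), method = "average")$order
  } else seq_along(taxa)
  structure(list(taxa = taxa, rho = sp$rho, q = q,
                 n_na_pairs = sum(!ok), cluster_order = ord,
                 n_samples = nrow(x)),
            class = "co_network")
}

#' Cross-cohort correlation shifts (delta rho)
#'
#' On the taxa shared by two networks: delta rho = rho_a - rho_b per pair;
#' the |rho| distributions (upper triangles) compared by two-sided Wilcoxon
#' rank-sum; median |rho| per network; pairs ranked by |delta rho|.
#'
#' @param net_a,net_b "co_network" objects (a is conventionally the adult
#'   cohort, so positive shifts are correlations strengthening into
#'   adulthood).
#' @return List of class "network_comparison": `shared_taxa`, `delta_rho`
#'   matrix, `median_abs_rho` (named a/b), `wilcoxon_abs_rho`,
#'   `wilcoxon_delta` (one-sample test of delta rho against zero),
#'   `top_shifts` data.frame.
#' @export
delta_rho <- function(net_a, net_b) {
  shared <- intersect(net_a$taxa, net_b$taxa)
  if (length(shared) < 3L) stop("fewer than 3 shared taxa")
  ra <- net_a$rho[shared, shared]
  rb <- net_b$rho[shared, shared]
  d <- ra - rb
  ut <- upper.tri(d)
  abs_a <- abs(net_a$rho[upper.tri(net_a$rho)])
  abs_b <- abs(net_b$rho[upper.tri(net_b$rho)])
  w_abs <- suppressWarnings(stats::wilcox.test(abs_a, abs_b, exact = FALSE))
  dvec <- d[ut]
  w_d <- suppressWarnings(stats::wilcox.test(dvec[!is.na(dvec)],
                                             exact = FALSE))
  pairs <- which(ut, arr.ind = TRUE)
  ts <- data.frame(taxon_1 = shared[pairs[, 1L]],
                   taxon_2 = shared[pairs[, 2L]],
                   rho_a = ra[ut], rho_b = rb[ut], delta_rho = dvec,
                   stringsAsFactors = FALSE)
  ts <- ts[order(-abs(ts$delta_rho)), ]
  rownames(ts) <- NULL
  structure(list(shared_taxa = shared, delta_rho = d,
                 median_abs_rho = c(a = stats::median(abs_a, na.rm = TRUE),
                                    b = stats::median(abs_b, na.rm = TRUE)),
                 wilcoxon_abs_rho = list(statistic = unname(w_abs$statistic),
                                         p = w_abs$p.value),
                 wilcoxon_delta = list(statistic = unname(w_d$statistic),
                                       p = w_d$p.value),
                 top_shifts = ts),
            class = "network_comparison")
}

#' Per-taxon positive and negative connectedness
#'
#' kappa_pos(j) is the mean of taxon j's positive off-diagonal correlations
#' (0 if none); kappa_neg(j) the mean of its negative ones (0 if none).
#'
#' @param net A "co_network".
#' @return data.frame with taxon, connectedness_pos, connectedness_neg.
#' @export
connectedness <- function(net) {
  rho <- net$rho
  if (nrow(rho) < 2L) stop("at least 2 taxa are required")
  diag(rho) <- NA
  kpos <- apply(rho, 1L, function(r) {
    v <- r[!is.na(r) & r > 0]
    if (length(v) == 0L) 0 else mean(v)
  })
  kneg <- apply(rho, 1L, function(r) {
    v <- r[!is.na(r) & r < 0]
    if (length(v) == 0L) 0 else mean(v)
  })
  data.frame(taxon = net$taxa, connectedness_pos = unname(kpos),
             connectedness_neg = unname(kneg), stringsAsFactors = FALSE)
}

#' Per-sample positive and negative cohesion
#'
#' Cohesion is the abundance-weighted sum of connectedness over the
#' network's taxa: C_pos(i) = sum_j x_ij kappa_pos(j) (and likewise for the
#' negative part), with x the relative abundances re-closed over the network
#' taxa.
#'
#' @param rel Proportion matrix covering the network taxa.
#' @param conn Connectedness data.frame from [connectedness()].
#' @return data.frame with sample_id, cohesion_pos, cohesion_neg (NA with a
#'   warning for samples with zero total abundance over network taxa).
#' @export
cohesion <- function(rel, conn) {
  missing_taxa <- setdiff(conn$taxon, colnames(rel))
  if (length(missing_taxa) > 0L) {
    stop("rel lacks network taxa: ", paste(missing_taxa, collapse = ", "))
  }
  x <- rel[, conn$taxon, drop = FALSE]
  tot <- rowSums(x)
  empty <- tot == 0
  if (any(empty)) {
    warning("sample(s) with zero abundance over network taxa: ",
            paste(rownames(x)[empty], collapse = ", "))
  }
  xr <- x / ifelse(tot == 0, NA, tot)
  data.frame(sample_id = rownames(x),
             cohesion_pos = as.vector(xr %*% conn$connectedness_pos),
             cohesion_neg = as.vector(xr %*% conn$connectedness_neg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare cohesion and connectedness between two cohorts
#'
#' Two-sided Wilcoxon rank-sum tests on positive/negative cohesion (per
#' sample) and positive/negative connectedness (per taxon), with medians and
#' means per cohort.
#'
#' @param coh_a,coh_b Cohesion data.frames from [cohesion()].
#' @param conn_a,conn_b Connectedness data.frames from [connectedness()].
#' @return data.frame: one row per quantity with statistic, p, and per-cohort
#'   median and mean.
#' @export
compare_cohesion <- function(coh_a, coh_b, conn_a, conn_b) {
  quantities <- list(
    cohesion_pos = list(coh_a$cohesion_pos, coh_b$cohesion_pos),
    cohesion_neg = list(coh_a$cohesion_neg, coh_b$cohesion_neg),
    connectedness_pos = list(conn_a$connectedness_pos,
                             conn_b$connectedness_pos),
    connectedness_neg = list(conn_a$connectedness_neg,
                             conn_b$connectedness_neg))
  out <- lapply(names(quantities), function(nm) {
    a <- quantities[[nm]][[1L]]
    b <- quantities[[nm]][[2L]]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(quantity = nm, statistic = unname(ht$statistic),
               p = ht$p.value,
               median_a = stats::median(a), median_b = stats::median(b),
               mean_a = mean(a), mean_b = mean(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
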