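#' Multiplicative (CZM-style) zero replacement
#'
#' Each zero in sample i is replaced by delta_i = fraction / (N_i + 1),
#' where N_i is the sample's total count (the detection limit); nonzero
#' entries are multiplicatively rescaled by (1 - sum of imputed deltas) so
#' the row still sums to one. Rows without zeros are returned unchanged.
#'
#' @param rel Proportion matrix (rows sum to 1), e.g. from
#'   [relative_abundance()].
#' @param totals Per-sample total counts; defaults to the `totals` attribute
#'   carried by [relative_abundance()].
#' @param fraction Fraction of the detection limit used for imputation
#'   (default 0.65).
#' @return Strictly positive proportion matrix, rows summing to 1.
#' @export
czm_replace <- function(rel, totals = attr(rel, "totals"), fraction = 0.65) {
  if (is.null(totals)) {
    stop("per-sample totals are required (pass counts through ",
         "relative_abundance, or supply totals=)")
  }
  if (length(totals) != nrow(rel)) stop("totals must match rows of rel")
  out <- rel
  for (i in seq_len(nrow(rel))) {
    z <- rel[i, ] == 0
    if (!any(z)) next
    if (all(z)) stop("row '", rownames(rel)[i], "' is entirely zero")
    delta <- fraction / (totals[i] + 1)
    if (delta >= min(rel[i, !z])) {
      warning("imputed delta exceeds smallest observed proportion in row '",
              rownames(rel)[i], "'")
    }
    imputed <- sum(z) * delta
    out[i, z] <- delta
    out[i, !z] <- rel[i, !z] * (1 - imputed)
  }
  attr(out, "totals") <- totals
  out
}

#' Centered log-ratio transform
#'
#' clr_j = ln(x_j) - mean_k ln(x_k) per row; rows of the result sum to zero.
#'
#' @param rel Strictly positive proportion (or count) matrix.
#' @return CLR matrix with the same dimnames.
#' @export
clr_transform <- function(rel) {
  if (any(rel <= 0)) {
    stop("clr_transform requires strictly positive entries; ",
         "apply czm_replace first")
  }
  lx <- log(rel)
  out <- lx - rowMeans(lx)
  attr(out, "totals") <- NULL
  out
}

#' Principal-component analysis in Aitchison geometry
#'
#' PCA of the column-centered CLR matrix via singular value decomposition;
#' equivalent to principal coordinates on Aitchison distances, but also
#' yields taxon loadings. Euclidean distances between full score rows equal
#' the Aitchison distances between samples.
#'
#' @param clr CLR matrix (samples x taxa), e.g. from [clr_transform()].
#' @param groups Optional group labels (length = samples) for centroid
#'   computation.
#' @return List of class "aitchison_pca": `scores` (samples x components),
#'   `variance_explained`, `loadings` (taxa x components), `centroids`
#'   (group means of the first two score columns), `groups`.
#' @export
aitchison_pca <- function(clr, groups = NULL) {
  if (nrow(clr) < 3L) stop("at least 3 samples are required for ordination")
  centered <- sweep(clr, 2L, colMeans(clr), "-")
  sv <- svd(centered)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, nrow = length(d))
  dimnames(scores) <- list(rownames(clr),
                           paste0("PC", seq_along(d)))
  loadings <- sv$v[, keep, drop = FALSE]
  dimnames(loadings) <- list(colnames(clr), colnames(scores))
  ve <- d^2 / sum(d^2)
  centroids <- NULL
  if (!is.null(groups)) {
    groups <- as.character(groups)
    pc12 <- scores[, seq_len(min(2L, ncol(scores))), drop = FALSE]
    centroids <- do.call(rbind, lapply(split(seq_len(nrow(pc12)), groups),
                                       function(ix) colMeans(pc12[ix, ,
                                                                  drop = FALSE])))
  }
  structure(list(scores = scores, variance_explained = ve,
                 loadings = loadings, centroids = centroids, groups = groups),
            class = "aitchison_pca")
}

#' Pairwise Aitchison distances
#'
#' Euclidean distances between CLR rows.
#'
#' @param clr CLR matrix.
#' @return A "dist" object.
#' @export
aitchison_dist <- function(clr) stats::dist(clr)

#' Permutation test of group separation in ordination space
#'
#' Factor fitting on the first two principal components (the plotted space):
#' r2 = 1 - SS_within / SS_total of the 2-D scores under the grouping, with
#' the p-value from seeded label permutations,
#' p = (1 + #permuted r2 >= observed) / (n_perm + 1).
#'
#' @param ordination An "aitchison_pca" object (or any list with `scores`).
#' @param labels Group labels, one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `r2`, `p`, `n_perm`.
#' @export
envfit_factor <- function(ordination, labels, n_perm = 999L, seed = 1L) {
  scores <- ordination$scores[, seq_len(min(2L, ncol(ordination$scores))),
                              drop = FALSE]
  labels <- as.character(labels)
  if (length(labels) != nrow(scores)) stop("labels must match samples")
  tab <- table(labels)
  if (length(tab) < 2L) stop("at least 2 groups are required")
  if (any(tab < 2L)) stop("every group needs at least 2 members")
  obs <- envfit_r2(scores, labels)
  perm_r2 <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      envfit_r2(scores, sample(labels))
    }, numeric(1L))
  })
  p <- (1 + sum(perm_r2 >= obs)) / (n_perm + 1)
  list(r2 = obs, p = p, n_perm = n_perm)
}

envfit_r2 <- function(scores, labels) {
  center <- colMeans(scores)
  ss_tot <- sum(sweep(scores, 2L, center, "-")^2)
  if (ss_tot == 0) return(0)
  gm <- rowsum(scores, labels) / as.vector(table(labels)[sort(unique(labels))])
  # rowsum orders groups by sort(unique); align counts accordingly
  ss_w <- 0
  for (g in rownames(gm)) {
    rows <- scores[labels == g, , drop = FALSE]
    ss_w <- ss_w + sum(sweep(rows, 2L, gm[g, ], "-")^2)
  }
  1 - ss_w / ss_tot
}
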