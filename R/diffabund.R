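#' Monte-Carlo Dirichlet CLR instances
#'
#' For each of `n_mc` instances and each sample, proportions are drawn from
#' Dirichlet(counts + prior) and CLR-transformed. The count prior keeps zero
#' counts strictly positive. All draws are deterministic given `seed`.
#'
#' @param counts Count matrix with positive row sums.
#' @param n_mc Number of Monte-Carlo instances (>= 16; default 128).
#' @param prior Dirichlet count offset (default 0.5).
#' @param seed Integer seed.
#' @return List of class "mc_clr": `instances` (list of CLR matrices,
#'   samples x taxa), `counts`, `prior`, `seed`.
#' @export
mc_clr_instances <- function(counts, n_mc = 128L, prior = 0.5, seed = 1L) {
  if (n_mc < 16L) stop("n_mc must be at least 16")
  if (any(rowSums(counts) <= 0)) stop("all samples must have reads")
  n <- nrow(counts)
  p <- ncol(counts)
  shape <- counts + prior
  instances <- with_seed(seed, {
    lapply(seq_len(n_mc), function(m) {
      g <- matrix(stats::rgamma(n * p, shape = shape), n, p)
      lg <- log(g)
      out <- lg - rowMeans(lg)
      dimnames(out) <- dimnames(counts)
      out
    })
  })
  structure(list(instances = instances, counts = counts, prior = prior,
                 seed = as.integer(seed)), class = "mc_clr")
}

group_levels <- function(groups) {
  if (is.factor(groups)) levels(droplevels(groups)) else sort(unique(as.character(groups)))
}

# Two-sided Wilcoxon p per taxon (columns of clr) for one instance.
wilcox_p_cols <- function(clr, ia, ib, paired) {
  vapply(seq_len(ncol(clr)), function(j) {
    suppressWarnings(stats::wilcox.test(clr[ia, j], clr[ib, j],
                                        paired = paired,
                                        exact = FALSE)$p.value)
  }, numeric(1L))
}

#' Monte-Carlo CLR differential abundance
#'
#' Per instance, a two-sided Wilcoxon test (rank-sum, or signed-rank when
#' `paired`) compares CLR values between the two groups for every taxon and
#' the p-values are BH-adjusted across taxa; `q_expected` is the mean
#' adjusted p over instances. The standardized effect size per taxon is the
#' median, pooled over instances, of (between-group difference) /
#' max(within-group difference dispersion), computed from random pairings of
#' group values (min(group sizes) pairings per instance). Positive effects
#' mean higher CLR abundance in the *second* group level (factor order is
#' respected; character labels are sorted).
#'
#' @param instances "mc_clr" object from [mc_clr_instances()].
#' @param groups Two-level factor or character vector, one per sample.
#' @param paired Use signed-rank on subject pairs (samples must be ordered
#'   identically within each group level).
#' @return data.frame per taxon: effect, q_expected, median_clr_diff,
#'   prevalence and median proportion per group (prevalence = fraction of
#'   samples with > 1% proportional abundance).
#' @export
aldex_da <- function(instances, groups, paired = FALSE) {
  clr_list <- instances$instances
  counts <- instances$counts
  lev <- group_levels(groups)
  if (length(lev) != 2L) stop("groups must have exactly two levels")
  g <- as.character(groups)
  ia <- which(g == lev[1L])
  ib <- which(g == lev[2L])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both groups need at least 2 samples")
  }
  if (paired && length(ia) != length(ib)) {
    stop("paired test requires equal group sizes (complete pairs)")
  }
  n_mc <- length(clr_list)
  p <- ncol(counts)
  npair <- min(length(ia), length(ib))
  q_sum <- numeric(p)
  diff_sum <- numeric(p)
  ratios <- vector("list", n_mc)
  with_seed(instances$seed + 7L, {
    for (m in seq_len(n_mc)) {
      clr <- clr_list[[m]]
      pv <- wilcox_p_cols(clr, ia, ib, paired)
      q_sum <- q_sum + stats::p.adjust(pv, method = "BH")
      diff_sum <- diff_sum +
        (apply(clr[ib, , drop = FALSE], 2L, stats::median) -
         apply(clr[ia, , drop = FALSE], 2L, stats::median))
      # pairing indices are drawn in a label-order-independent way so that
      # swapping the group levels negates every effect exactly
      first_is_a <- min(ia) < min(ib)
      s1 <- if (first_is_a) ia else ib
      s2 <- if (first_is_a) ib else ia
      d1 <- sample(s1, npair)
      d2 <- sample(s2, npair)
      w1 <- clr[sample(s1, npair, replace = TRUE), , drop = FALSE] -
        clr[sample(s1, npair, replace = TRUE), , drop = FALSE]
      w2 <- clr[sample(s2, npair, replace = TRUE), , drop = FALSE] -
        clr[sample(s2, npair, replace = TRUE), , drop = FALSE]
      pa <- if (first_is_a) d1 else d2
      pb <- if (first_is_a) d2 else d1
      btw <- clr[pb, , drop = FALSE] - clr[pa, , drop = FALSE]
      denom <- pmax(abs(w1), abs(w2), 1e-12)
      ratios[[m]] <- btw / denom
    }
  })
  pooled <- do.call(rbind, ratios)
  effect <- apply(pooled, 2L, stats::median)
  rel <- counts / rowSums(counts)
  prev <- function(ix) colMeans(rel[ix, , drop = FALSE] > 0.01)
  mprop <- function(ix) apply(rel[ix, , drop = FALSE], 2L, stats::median)
  data.frame(taxon = colnames(counts),
             effect = unname(effect),
             q_expected = unname(q_sum / n_mc),
             median_clr_diff = unname(diff_sum / n_mc),
             prevalence_1 = unname(prev(ia)), prevalence_2 = unname(prev(ib)),
             median_prop_1 = unname(mprop(ia)),
             median_prop_2 = unname(mprop(ib)),
             stringsAsFactors = FALSE)
}

#' Classify differential-abundance results
#'
#' A taxon is "increased" (in the second group level) when effect >
#' `effect_min` and q_expected <= `q_max`; "decreased" symmetrically;
#' otherwise "unchanged". Both inequalities on the effect are strict, so an
#' effect of exactly `effect_min` is unchanged.
#'
#' @param results data.frame from [aldex_da()].
#' @param effect_min Minimum |effect| (strict; default 0.5).
#' @param q_max Maximum expected BH-adjusted p (inclusive; default 0.001).
#' @return The input with a `class` column, sorted by effect (descending).
#' @export
classify_da <- function(results, effect_min = 0.5, q_max = 0.001) {
  cls <- rep("unchanged", nrow(results))
  sig <- results$q_expected <= q_max
  cls[sig & results$effect > effect_min] <- "increased"
  cls[sig & results$effect < -effect_min] <- "decreased"
  out <- results
  out$class <- cls
  out <- out[order(-out$effect), ]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo CLR correlation with a continuous marker
#'
#' Per instance, Spearman correlation between each taxon's CLR values and
#' the marker, with two-sided p-values from the asymptotic t approximation,
#' BH-adjusted across taxa; reported values are means over instances.
#'
#' @param instances "mc_clr" object.
#' @param marker Numeric marker value per sample (no missing values).
#' @return data.frame per taxon: rho_expected, p_expected, q_expected.
#' @export
aldex_corr <- function(instances, marker) {
  clr_list <- instances$instances
  n <- nrow(instances$counts)
  if (length(marker) != n) stop("marker must have one value per sample")
  if (anyNA(marker)) stop("marker contains missing values")
  if (length(unique(marker)) == 1L) stop("marker is constant")
  rm_ <- rank(marker)
  p <- ncol(instances$counts)
  rho_sum <- numeric(p)
  p_sum <- numeric(p)
  q_sum <- numeric(p)
  for (clr in clr_list) {
    rcl <- apply(clr, 2L, rank)
    rho <- suppressWarnings(stats::cor(rcl, rm_))[, 1L]
    tt <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
    pv <- 2 * stats::pt(-abs(tt), df = n - 2)
    pv[rho^2 >= 1] <- 0
    rho_sum <- rho_sum + rho
    p_sum <- p_sum + pv
    q_sum <- q_sum + stats::p.adjust(pv, method = "BH")
  }
  n_mc <- length(clr_list)
  data.frame(taxon = colnames(instances$counts),
             rho_expected = unname(rho_sum / n_mc),
             p_expected = unname(p_sum / n_mc),
             q_expected = unname(q_sum / n_mc), stringsAsFactors = FALSE)
}
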