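#' Alpha diversity and evenness per sample
#'
#' Shannon diversity H = -sum p_j ln p_j over nonzero proportions (natural
#' log), observed richness S, and Pielou evenness J = H / ln S (NA when only
#' one taxon is observed).
#'
#' @param counts Count matrix with positive row sums.
#' @return data.frame with sample_id, richness, shannon, pielou.
#' @export
alpha_diversity <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop("zero-sum sample(s): ",
         paste(rownames(counts)[totals <= 0], collapse = ", "))
  }
  rel <- counts / totals
  shannon <- apply(rel, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  richness <- rowSums(counts > 0)
  pielou <- ifelse(richness > 1L, shannon / log(richness), NA_real_)
  data.frame(sample_id = rownames(counts), richness = as.integer(richness),
             shannon = shannon, pielou = pielou, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Core taxa by detection and prevalence
#'
#' A taxon is in the core iff its proportional abundance exceeds `detection`
#' (strictly) in at least a `prevalence` fraction of samples. A
#' prevalence-by-detection grid over `detection_grid` supports core heatmaps.
#'
#' @param rel Proportion matrix.
#' @param detection Detection threshold in (0, 1), strict (default 0.01).
#' @param prevalence Minimum fraction of samples (default 0.5, inclusive).
#' @param detection_grid Optional vector of detection thresholds for the
#'   grid.
#' @return List: `core` (character vector of core taxa), `prevalence` (named
#'   fraction of samples above `detection` per taxon), `grid` (taxa x
#'   thresholds matrix of those fractions, or NULL).
#' @export
core_taxa <- function(rel, detection = 0.01, prevalence = 0.5,
                      detection_grid = NULL) {
  if (detection <= 0 || detection >= 1) stop("detection must be in (0, 1)")
  frac_above <- function(d) colMeans(rel > d)
  prev <- frac_above(detection)
  core <- colnames(rel)[prev >= prevalence]
  grid <- NULL
  if (!is.null(detection_grid)) {
    grid <- vapply(detection_grid, frac_above, numeric(ncol(rel)))
    dimnames(grid) <- list(colnames(rel), as.character(detection_grid))
  }
  list(core = core, prevalence = prev, grid = grid)
}

#' Compare a per-sample metric between two groups with a normality gate
#'
#' The default gate runs Shapiro-Wilk per group at alpha = 0.05 and uses
#' Student's t (paired when requested) when neither group rejects normality,
#' falling back to the (paired) Wilcoxon test otherwise. `gate = "wilcoxon"`
#' or `gate = "t"` forces the respective test. Group medians are always
#' reported.
#'
#' @param values Numeric metric, one per sample.
#' @param groups Two-level labels aligned with `values`.
#' @param paired Paired comparison; requires `subjects` and complete pairs.
#' @param subjects Subject ids for pairing (required when `paired`).
#' @param gate "shapiro_then_t", "wilcoxon", or "t".
#' @return List with `test` (test used), `statistic`, `p`, `medians` (named
#'   per group), `shapiro_p` (per group, NA unless gated).
#' @export
compare_alpha <- function(values, groups, paired = FALSE, subjects = NULL,
                          gate = c("shapiro_then_t", "wilcoxon", "t")) {
  gate <- match.arg(gate)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  if (paired) {
    if (is.null(subjects)) stop("paired comparison requires subjects")
    wide <- split(stats::setNames(values, subjects), groups)
    common <- intersect(names(wide[[1L]]), names(wide[[2L]]))
    incomplete <- union(setdiff(names(wide[[1L]]), common),
                        setdiff(names(wide[[2L]]), common))
    if (length(incomplete) > 0L) {
      stop("incomplete pairs for subject(s): ",
           paste(incomplete, collapse = ", "))
    }
    x <- wide[[1L]][common]
    y <- wide[[2L]][common]
  } else {
    x <- values[groups == lev[1L]]
    y <- values[groups == lev[2L]]
  }
  shapiro_p <- c(NA_real_, NA_real_)
  use_t <- gate == "t"
  if (gate == "shapiro_then_t") {
    shapiro_p <- c(stats::shapiro.test(x)$p.value,
                   stats::shapiro.test(y)$p.value)
    use_t <- all(shapiro_p > 0.05)
  }
  if (use_t) {
    ht <- stats::t.test(x, y, paired = paired)
    test <- if (paired) "paired t" else "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                              exact = FALSE))
    test <- if (paired) "wilcoxon signed-rank" else "wilcoxon rank-sum"
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       medians = stats::setNames(c(stats::median(x), stats::median(y)), lev),
       shapiro_p = stats::setNames(shapiro_p, lev))
}
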