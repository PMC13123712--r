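#' Immune-cell density from a count and tissue area
#'
#' @param count Nonnegative cell count.
#' @param area_mm2 Tissue area in mm^2 (> 0).
#' @return Density in cells/mm^2.
#' @export
cell_density <- function(count, area_mm2) {
  if (any(count < 0)) stop("count must be nonnegative")
  if (any(area_mm2 <= 0)) stop("area_mm2 must be positive")
  count / area_mm2
}

#' Compare immune-cell densities between layers or indication groups
#'
#' `"epidermis_vs_dermis"`: paired Wilcoxon signed-rank per (marker, aspect)
#' across participants measured in both layers (participants missing a layer
#' are excluded from that test, with a message). `"elective_vs_phimosis"`:
#' unpaired Wilcoxon rank-sum per (marker, aspect, layer) between
#' indication groups. Within each comparison, p-values are BH-adjusted
#' across the whole marker x compartment family.
#'
#' @param densities Density data.frame (participant_id, aspect, layer,
#'   marker, density).
#' @param metadata Metadata with subject_id and indication (required for the
#'   group comparison).
#' @param comparison "epidermis_vs_dermis" or "elective_vs_phimosis".
#' @return data.frame: marker, aspect, layer, statistic, p, p_adj, group
#'   medians and sizes.
#' @export
compare_densities <- function(densities, metadata = NULL,
                              comparison = c("epidermis_vs_dermis",
                                             "elective_vs_phimosis")) {
  comparison <- match.arg(comparison)
  rows <- list()
  if (comparison == "epidermis_vs_dermis") {
    for (m in unique(densities$marker)) {
      for (a in unique(densities$aspect)) {
        epi <- densities[densities$marker == m & densities$aspect == a &
                           densities$layer == "epidermis", , drop = FALSE]
        der <- densities[densities$marker == m & densities$aspect == a &
                           densities$layer == "dermis", , drop = FALSE]
        common <- intersect(epi$participant_id, der$participant_id)
        dropped <- length(union(epi$participant_id, der$participant_id)) -
          length(common)
        if (dropped > 0L) {
          message(dropped, " participant(s) missing a layer for ", m, "/",
                  a, "; excluded from the paired test")
        }
        if (length(common) < 2L) next
        x <- epi$density[match(common, epi$participant_id)]
        y <- der$density[match(common, der$participant_id)]
        ht <- if (all(x == y)) {
          list(statistic = 0, p.value = 1)   # no nonzero pairs to rank
        } else {
          suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE))
        }
        rows[[paste(m, a)]] <- data.frame(
          marker = m, aspect = a, layer = "epidermis_vs_dermis",
          statistic = unname(ht$statistic), p = ht$p.value,
          median_1 = stats::median(x), median_2 = stats::median(y),
          n_1 = length(x), n_2 = length(y), stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) stop("no complete epidermis/dermis pairs")
  } else {
    if (is.null(metadata)) stop("metadata with indication labels is required")
    ind <- metadata$indication[match(densities$participant_id,
                                     metadata$subject_id)]
    densities$group <- ifelse(ind == "elective", "elective",
                              ifelse(ind == "pathological_phimosis",
                                     "phimosis", NA))
    dd <- densities[!is.na(densities$group), , drop = FALSE]
    for (m in unique(dd$marker)) {
      for (a in unique(dd$aspect)) {
        for (l in unique(dd$layer)) {
          sub <- dd[dd$marker == m & dd$aspect == a & dd$layer == l, ,
                    drop = FALSE]
          x <- sub$density[sub$group == "elective"]
          y <- sub$density[sub$group == "phimosis"]
          if (length(x) < 2L || length(y) < 2L) next
          ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
          rows[[paste(m, a, l)]] <- data.frame(
            marker = m, aspect = a, layer = l,
            statistic = unname(ht$statistic), p = ht$p.value,
            median_1 = stats::median(x), median_2 = stats::median(y),
            n_1 = length(x), n_2 = length(y), stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0L) stop("no testable marker/compartment groups")
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for r x c tables with Monte-Carlo fallback
#'
#' Exact enumeration (network algorithm) when feasible; otherwise a seeded
#' Monte-Carlo estimate over at least `B` tables with its standard error.
#'
#' @param tab Contingency table (matrix of counts).
#' @param B Monte-Carlo sample size for the fallback (default 1e5).
#' @param seed Seed for the fallback.
#' @return List: `p`, `method` ("exact" or "monte_carlo"), `mc_se` (0 for
#'   exact), `table`.
#' @export
fisher_exact <- function(tab, B = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  res <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                  error = function(e) NULL)
  if (!is.null(res)) {
    return(list(p = res$p.value, method = "exact", mc_se = 0, table = tab))
  }
  p <- with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE,
                                          B = B)$p.value)
  list(p = p, method = "monte_carlo", mc_se = sqrt(p * (1 - p) / B),
       table = tab)
}

#' Demographic tests across indication groups
#'
#' Kruskal-Wallis on age and Fisher's exact test on the group x ethnicity
#' contingency table.
#'
#' @param metadata Metadata with age_years and ethnicity; one row per
#'   participant (pass baseline samples only).
#' @param groups Group labels, one per metadata row (defaults to
#'   `metadata$indication`).
#' @return List: `kw_age` (statistic, df, p), `fisher_ethnicity` (p, method,
#'   mc_se, table).
#' @export
demographic_tests <- function(metadata, groups = metadata$indication) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("at least 2 groups are required")
  kw <- stats::kruskal.test(metadata$age_years, factor(groups))
  tab <- table(groups, metadata$ethnicity)
  fe <- fisher_exact(tab)
  list(kw_age = list(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p = kw$p.value),
       fisher_ethnicity = fe)
}
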