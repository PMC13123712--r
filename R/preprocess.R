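#' Flag putative reagent contaminants
#'
#' Two complementary scores, mirroring the standard frequency/prevalence
#' decision structure for amplicon contaminant removal. Frequency mode: for
#' each taxon, over the true (non-control) samples where it is present, the
#' contaminant model log(relative abundance) = intercept - log(dna_conc)
#' (slope fixed at 1 on the 1/concentration scale) is compared against the
#' constant model log(relative abundance) = intercept by the ratio of
#' residual sums of squares; the score is the one-sided F probability
#' favouring the contaminant model. Prevalence mode: a 2x2
#' presence/absence-by-control-status table scored by one-sided chi-squared,
#' favouring higher prevalence in negative controls. A taxon is flagged in a
#' mode when its score is below `threshold`.
#'
#' @param counts Count matrix including negative-control samples.
#' @param metadata Metadata with `is_negative_control` and `dna_conc`.
#' @param mode "frequency", "prevalence", or "both".
#' @param threshold Flagging threshold on the score (default 0.1).
#' @return data.frame with columns taxon_id, freq_p, prev_p, flagged_freq,
#'   flagged_prev, flagged_both (NA score in a mode never flags).
#' @export
flag_contaminants <- function(counts, metadata,
                              mode = c("both", "frequency", "prevalence"),
                              threshold = 0.1) {
  mode <- match.arg(mode)
  md <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) {
    stop("metadata missing for sample(s): ",
         paste(setdiff(rownames(counts), metadata$sample_id), collapse = ", "))
  }
  is_neg <- md$is_negative_control %in% TRUE
  true_counts <- counts[!is_neg, , drop = FALSE]
  freq_p <- rep(NA_real_, ncol(counts))
  prev_p <- rep(NA_real_, ncol(counts))
  if (mode %in% c("both", "frequency")) {
    dna <- md$dna_conc[!is_neg]
    if (all(is.na(dna))) {
      stop("frequency mode requires dna_conc on true samples")
    }
    rel <- true_counts / pmax(1, rowSums(true_counts))
    for (j in seq_len(ncol(counts))) {
      freq_p[j] <- freq_score(rel[, j], dna)
    }
  }
  if (mode %in% c("both", "prevalence")) {
    if (!any(is_neg)) {
      stop("prevalence mode requires at least one negative-control sample")
    }
    pres_neg <- colSums(counts[is_neg, , drop = FALSE] > 0)
    pres_tru <- colSums(true_counts > 0)
    n_neg <- sum(is_neg)
    n_tru <- sum(!is_neg)
    for (j in seq_len(ncol(counts))) {
      prev_p[j] <- prev_score(pres_neg[j], n_neg, pres_tru[j], n_tru)
    }
  }
  flagged_freq <- !is.na(freq_p) & freq_p < threshold
  flagged_prev <- !is.na(prev_p) & prev_p < threshold
  data.frame(taxon_id = colnames(counts), freq_p = freq_p, prev_p = prev_p,
             flagged_freq = flagged_freq, flagged_prev = flagged_prev,
             flagged_both = flagged_freq & flagged_prev,
             stringsAsFactors = FALSE)
}

# One-sided F score: contaminant model (slope 1 in log(1/dna), free
# intercept) vs constant model, over samples where the taxon is present and
# dna_conc known. Small values favour the contaminant model.
freq_score <- function(rel, dna) {
  ok <- rel > 0 & !is.na(dna) & dna > 0
  n <- sum(ok)
  if (n < 3L) return(NA_real_)
  y <- log(rel[ok])
  x <- log(1 / dna[ok])
  if (stats::var(x) == 0) return(NA_real_)
  rss_cont <- sum((y - x - mean(y - x))^2)   # slope fixed at 1
  rss_null <- sum((y - mean(y))^2)
  df <- n - 1L
  if (rss_null == 0 && rss_cont == 0) return(1)
  if (rss_null == 0) return(1)
  stats::pf(rss_cont / rss_null, df, df)
}

# One-sided chi-squared score on the 2x2 presence x control-status table;
# small values favour higher prevalence in negatives.
prev_score <- function(k_neg, n_neg, k_tru, n_tru) {
  tab <- matrix(c(k_neg, n_neg - k_neg, k_tru, n_tru - k_tru), 2L, 2L)
  if (k_neg + k_tru == 0L) return(NA_real_)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd == 0)) return(1)
  stat <- sum((tab - expd)^2 / expd)
  p2 <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  if (k_neg / n_neg >= k_tru / n_tru) p2 / 2 else 1 - p2 / 2
}

#' Remove contaminant and organelle taxa
#'
#' Drops taxa flagged by *both* contaminant modes (a taxon flagged by only
#' one mode is retained), and, when taxonomy is supplied, taxa assigned to
#' kingdom Eukaryota, order Chloroplast(s), or family Mitochondria.
#'
#' @param counts Count matrix.
#' @param flags Output of [flag_contaminants()] covering every taxon.
#' @param taxonomy Optional data.frame with column `taxon_id` and rank
#'   columns (kingdom...genus).
#' @return Count matrix without the removed taxa.
#' @export
remove_contaminants <- function(counts, flags, taxonomy = NULL) {
  missing_taxa <- setdiff(colnames(counts), flags$taxon_id)
  if (length(missing_taxa) > 0L) {
    stop("flags missing for taxa: ", paste(missing_taxa, collapse = ", "))
  }
  drop <- flags$taxon_id[flags$flagged_both %in% TRUE]
  if (!is.null(taxonomy)) {
    org <- organelle_taxa(taxonomy)
    drop <- union(drop, org)
  }
  counts[, setdiff(colnames(counts), drop), drop = FALSE]
}

organelle_taxa <- function(taxonomy) {
  hit <- rep(FALSE, nrow(taxonomy))
  if ("kingdom" %in% names(taxonomy)) {
    hit <- hit | tolower(taxonomy$kingdom) %in% "eukaryota"
  }
  if ("order" %in% names(taxonomy)) {
    hit <- hit | tolower(taxonomy$order) %in% c("chloroplast", "chloroplasts")
  }
  if ("family" %in% names(taxonomy)) {
    hit <- hit | tolower(taxonomy$family) %in% "mitochondria"
  }
  taxonomy$taxon_id[hit]
}

#' Prune low-read samples and low-abundance taxa
#'
#' Samples with fewer than `min_reads` total reads are dropped first; then
#' taxa whose per-sample proportional abundance never reaches `min_max_prop`
#' in any retained sample are dropped. The order (samples first) matters
#' because proportions are computed on retained samples only.
#'
#' @param counts Count matrix.
#' @param min_reads Minimum reads per retained sample (default 1000).
#' @param min_max_prop A taxon is retained iff its proportion reaches at
#'   least this value in some retained sample (default 0.01).
#' @return Pruned count matrix.
#' @export
prune <- function(counts, min_reads = 1000L, min_max_prop = 0.01) {
  keep_s <- rowSums(counts) >= min_reads
  if (!any(keep_s)) stop("all samples fall below min_reads = ", min_reads)
  counts <- counts[keep_s, , drop = FALSE]
  rel <- counts / rowSums(counts)
  keep_t <- apply(rel, 2L, max) >= min_max_prop
  counts[, keep_t, drop = FALSE]
}

#' Agglomerate counts to a taxonomic rank
#'
#' Counts are summed over taxa sharing the lineage down to `rank`. Taxa with
#' no assignment at `rank` are pooled per parent into
#' "unclassified_<parent>", where the parent is the most specific assigned
#' rank above. Idempotent: agglomerating an already-agglomerated table at
#' the same rank is the identity (up to column order, which is first-seen).
#'
#' @param counts Count matrix (columns are e.g. ASV ids).
#' @param taxonomy data.frame with `taxon_id` and ordered rank columns
#'   (kingdom, phylum, class, order, family, genus).
#' @param rank Rank to agglomerate to (default "genus").
#' @return Count matrix with one column per rank-level group; per-sample
#'   totals are conserved.
#' @export
agglomerate <- function(counts, taxonomy, rank = "genus") {
  if (is.null(taxonomy)) stop("taxonomy is required to agglomerate")
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  if (!rank %in% names(taxonomy)) stop("taxonomy lacks a '", rank, "' column")
  idx <- match(colnames(counts), taxonomy$taxon_id)
  if (anyNA(idx)) {
    stop("taxonomy missing for taxa: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  }
  tax <- taxonomy[idx, , drop = FALSE]
  label <- as.character(tax[[rank]])
  unassigned <- is.na(label) | label == ""
  if (any(unassigned)) {
    above <- rev(ranks[seq_len(match(rank, ranks) - 1L)])
    parent <- rep("root", sum(unassigned))
    sub <- tax[unassigned, , drop = FALSE]
    for (r in above) {
      if (!r %in% names(sub)) next
      v <- as.character(sub[[r]])
      fill <- parent == "root" & !is.na(v) & v != ""
      parent[fill] <- v[fill]
    }
    label[unassigned] <- paste0("unclassified_", parent)
  }
  groups <- unique(label)
  out <- matrix(0L, nrow(counts), length(groups),
                dimnames = list(rownames(counts), groups))
  for (g in groups) {
    out[, g] <- as.integer(rowSums(counts[, label == g, drop = FALSE]))
  }
  out
}

#' Convert counts to relative abundances
#'
#' Each row is divided by its total. The per-sample totals are kept in the
#' `"totals"` attribute, which downstream zero replacement uses as the
#' detection limit.
#'
#' @param counts Count matrix with positive row sums.
#' @return Matrix of proportions (rows sum to 1) with attribute `totals`.
#' @export
relative_abundance <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop("zero-sum sample(s): ",
         paste(rownames(counts)[totals <= 0], collapse = ", "),
         " (prune first)")
  }
  rel <- counts / totals
  attr(rel, "totals") <- totals
  rel
}
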