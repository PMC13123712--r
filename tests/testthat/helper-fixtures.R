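# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  matrix(c(5L, 0L, 3L,
           3L, 7L, 2L,
           10L, 1L, 0L,
           2L, 2L, 4L),
         nrow = 4L, byrow = TRUE,
         dimnames = list(paste0("S", 1:4), c("taxA", "taxB", "taxC")))
}

tiny_taxonomy <- function() {
  data.frame(taxon_id = c("asv1", "asv2", "asv3", "asv4"),
             kingdom = c("Bacteria", "Bacteria", "Bacteria", "Eukaryota"),
             phylum = "P", class = "C", order = "O",
             family = c("F1", "F1", "Lachnospiraceae", "F2"),
             genus = c("Peptoniphilus", "Peptoniphilus", NA, "G2"),
             stringsAsFactors = FALSE)
}

write_counts_tsv <- function(counts, path = tempfile(fileext = ".tsv")) {
  write_table(counts, path)
  path
}

tiny_metadata <- function(sample_ids, ...) {
  n <- length(sample_ids)
  out <- data.frame(sample_id = sample_ids, cohort = "pediatric",
                    subject_id = sample_ids, timepoint = "none",
                    indication = "elective", age_years = 8.5,
                    ethnicity = "caucasian", dna_conc = NA_real_,
                    is_negative_control = FALSE, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# Brute-force Spearman: average ranks computed by hand, Pearson formula by
# explicit loops. Independent oracle for correlation_network.
brute_spearman <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  rk <- x
  for (j in seq_len(p)) {
    v <- x[, j]
    r <- numeric(n)
    for (i in seq_len(n)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    rk[, j] <- r
  }
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      xa <- rk[, a] - mean(rk[, a])
      xb <- rk[, b] - mean(rk[, b])
      rho[a, b] <- sum(xa * xb) / sqrt(sum(xa^2) * sum(xb^2))
    }
  }
  rho
}
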