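test_that("frequency mode flags 1/dna_conc-proportional taxa only", {
  # Construct a table from the contaminant model itself: relative abundance
  # exactly proportional to 1/dna_conc, plus a constant-proportion taxon.
  dna <- c(0.25, 0.5, 1, 2, 4, 8)
  depth <- 20000L
  contam_prop <- 0.02 / dna
  filler <- 1 - contam_prop - 0.05
  counts <- cbind(contam = round(depth * contam_prop),
                  steady = round(depth * 0.05),
                  filler = round(depth * filler))
  rownames(counts) <- paste0("S", seq_along(dna))
  storage.mode(counts) <- "integer"
  md <- tiny_metadata(rownames(counts), dna_conc = dna)
  flags <- flag_contaminants(counts, md, mode = "frequency")
  expect_lt(flags$freq_p[flags$taxon_id == "contam"], 0.1)
  expect_true(flags$flagged_freq[flags$taxon_id == "contam"])
  expect_gt(flags$freq_p[flags$taxon_id == "steady"], 0.1)
  expect_false(flags$flagged_freq[flags$taxon_id == "steady"])
})

test_that("prevalence mode flags negatives-only taxa near zero", {
  counts <- rbind(
    matrix(c(0L, 1000L), 8L, 2L, byrow = TRUE,
           dimnames = list(paste0("S", 1:8), c("negonly", "real"))),
    matrix(c(500L, 10L), 4L, 2L, byrow = TRUE,
           dimnames = list(paste0("N", 1:4), c("negonly", "real"))))
  md <- tiny_metadata(rownames(counts),
                      is_negative_control = grepl("^N", rownames(counts)),
                      indication = ifelse(grepl("^N", rownames(counts)),
                                          "none", "elective"))
  flags <- flag_contaminants(counts, md, mode = "prevalence")
  expect_lt(flags$prev_p[flags$taxon_id == "negonly"], 0.01)
  expect_true(flags$flagged_prev[flags$taxon_id == "negonly"])
  expect_false(isTRUE(flags$flagged_prev[flags$taxon_id == "real"]))
})

test_that("mode preconditions produce informative errors", {
  counts <- tiny_counts()
  md <- tiny_metadata(rownames(counts))  # no dna_conc, no negatives
  expect_error(flag_contaminants(counts, md, mode = "frequency"), "dna_conc")
  expect_error(flag_contaminants(counts, md, mode = "prevalence"),
               "negative-control")
})

test_that("removal requires both modes; organelle lineages always drop", {
  counts <- tiny_counts()
  flags <- data.frame(taxon_id = colnames(counts),
                      freq_p = c(0.01, 0.01, 0.5),
                      prev_p = c(0.5, 0.01, 0.5),
                      flagged_freq = c(TRUE, TRUE, FALSE),
                      flagged_prev = c(FALSE, TRUE, FALSE),
                      flagged_both = c(FALSE, TRUE, FALSE))
  out <- remove_contaminants(counts, flags)
  expect_true("taxA" %in% colnames(out))   # one mode only: retained
  expect_false("taxB" %in% colnames(out))  # both modes: removed
  expect_true("taxC" %in% colnames(out))

  tax <- data.frame(taxon_id = colnames(counts),
                    kingdom = c("Bacteria", "Bacteria", "Bacteria"),
                    order = c("O", "O", "O"),
                    family = c("F", "F", "Mitochondria"))
  flags$flagged_both <- FALSE
  out2 <- remove_contaminants(counts, flags, taxonomy = tax)
  expect_false("taxC" %in% colnames(out2)) # organelle, regardless of flags
})

test_that("pruning drops shallow samples first, then rare taxa; idempotent", {
  counts <- rbind(
    deep1 = c(a = 800L, b = 150L, c = 50L, d = 0L),
    deep2 = c(a = 1500L, b = 0L, c = 8L, d = 2L),
    deep3 = c(a = 1200L, b = 100L, c = 0L, d = 5L),
    shallow = c(a = 0L, b = 999L, c = 0L, d = 0L))
  pruned <- prune(counts)
  expect_false("shallow" %in% rownames(pruned))   # 999 < 1000 reads
  # taxon b: 15% in deep1 -> retained; taxon d peaks at 5/1305 < 1% -> dropped
  expect_true("b" %in% colnames(pruned))
  expect_false("d" %in% colnames(pruned))
  # a taxon at 5% in one sample and absent elsewhere is retained (max rule)
  counts2 <- rbind(s1 = c(x = 1900L, y = 100L), s2 = c(x = 2000L, y = 0L))
  expect_true("y" %in% colnames(prune(counts2)))

  expect_identical(prune(pruned), pruned)
  expect_error(prune(counts, min_reads = 10000L), "all samples")
})

test_that("agglomeration sums lineage groups and conserves totals", {
  counts <- matrix(c(3L, 4L, 2L, 1L,
                     0L, 5L, 7L, 2L),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(c("S1", "S2"),
                                   c("asv1", "asv2", "asv3", "asv4")))
  tax <- tiny_taxonomy()
  out <- agglomerate(counts, tax)
  expect_equal(out[, "Peptoniphilus"], c(S1 = 7L, S2 = 5L))
  expect_true("unclassified_Lachnospiraceae" %in% colnames(out))
  expect_equal(rowSums(out), rowSums(counts))   # reads conserved

  # idempotent at the same rank
  tax2 <- data.frame(taxon_id = colnames(out), kingdom = "Bacteria",
                     phylum = "P", class = "C", order = "O", family = "F",
                     genus = colnames(out))
  again <- agglomerate(out, tax2)
  expect_equal(again[, colnames(out)], out)

  expect_error(agglomerate(counts, NULL), "taxonomy")
})

test_that("relative abundance closes rows and is scale invariant", {
  counts <- rbind(s1 = c(a = 2L, b = 2L, c = 4L))
  rel <- relative_abundance(counts)
  expect_equal(as.vector(rel), c(0.25, 0.25, 0.5))
  expect_equal(unname(rowSums(rel)), 1)

  scaled <- relative_abundance(counts * 10L)
  expect_equal(as.vector(scaled), as.vector(rel))

  bad <- rbind(s1 = c(a = 0L, b = 0L))
  expect_error(relative_abundance(bad), "zero-sum")
})
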