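#' Read a sample x taxon count table from TSV
#'
#' The expected layout is the ubiquitous microbiome feature-table format:
#' tab-separated, UTF-8, first column holds sample identifiers, the header
#' row holds taxon identifiers, and every cell is a nonnegative integer
#' count. Row and column order are preserved.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix (samples x taxa) with unique rownames and
#'   colnames, validated by [validate_counts()].
#' @export
read_count_table <- function(path) {
  raw <- read_tsv_checked(path)
  if (ncol(raw) < 2L) {
    stop("count table needs a sample-id column plus at least one taxon column")
  }
  sample_ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1L, drop = FALSE], 2,
                                              function(x) as.numeric(x)))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 sample_ids[bad[1L, 1L]], colnames(raw)[-1L][bad[1L, 2L]]))
  }
  nonint <- which(mat != round(mat), arr.ind = TRUE)
  if (nrow(nonint) > 0L) {
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 sample_ids[nonint[1L, 1L]], colnames(mat)[nonint[1L, 2L]]))
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- sample_ids
  validate_counts(mat)
  mat
}

#' Validate a count matrix
#'
#' @param counts Integer matrix, samples as rows, taxa as columns.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (samples x taxa)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  invisible(counts)
}

.metadata_required <- c("sample_id", "cohort", "subject_id", "timepoint",
                        "indication", "age_years", "ethnicity", "dna_conc",
                        "is_negative_control")

.metadata_enums <- list(
  cohort     = c("pediatric", "adult"),
  timepoint  = c("pre", "post", "none"),
  indication = c("elective", "non_elective", "pathological_phimosis", "none")
)

#' Read sample metadata from TSV
#'
#' Required columns: sample_id, cohort, subject_id, timepoint, indication,
#' age_years, ethnicity, dna_conc, is_negative_control. Enum-valued columns
#' (cohort, timepoint, indication) are matched case-insensitively and stored
#' in lower case; unknown levels are rejected. `dna_conc` may be NA.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  raw <- read_tsv_checked(path)
  missing_cols <- setdiff(.metadata_required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  md <- raw[, .metadata_required]
  md$sample_id  <- as.character(md$sample_id)
  md$subject_id <- as.character(md$subject_id)
  md$ethnicity  <- as.character(md$ethnicity)
  for (col in names(.metadata_enums)) {
    md[[col]] <- tolower(trimws(as.character(md[[col]])))
    bad <- setdiff(unique(md[[col]]), .metadata_enums[[col]])
    if (length(bad) > 0L) {
      stop(sprintf("unknown %s value(s): %s (allowed: %s)", col,
                   paste(bad, collapse = ", "),
                   paste(.metadata_enums[[col]], collapse = ", ")))
    }
  }
  md$age_years <- as.numeric(md$age_years)
  md$dna_conc  <- as.numeric(md$dna_conc)
  if (is.character(md$is_negative_control)) {
    md$is_negative_control <-
      tolower(trimws(md$is_negative_control)) %in% c("true", "t", "1", "yes")
  }
  md$is_negative_control <- as.logical(md$is_negative_control)
  validate_metadata(md)
  md
}

#' Validate a sample metadata data.frame
#'
#' Checks uniqueness of sample ids, nonnegative ages, positive DNA
#' concentrations where present, that negative controls carry
#' indication "none", and that pre/post timepoints of a subject agree.
#'
#' @param metadata data.frame as returned by [read_metadata()].
#' @return The input, invisibly, if valid.
#' @export
validate_metadata <- function(metadata) {
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  }
  if (any(!is.na(metadata$age_years) & metadata$age_years < 0)) {
    stop("age_years must be nonnegative")
  }
  if (any(!is.na(metadata$dna_conc) & metadata$dna_conc <= 0)) {
    stop("dna_conc must be positive where present")
  }
  negs <- metadata$is_negative_control %in% TRUE
  if (any(metadata$indication[negs] != "none")) {
    stop("negative controls must have indication 'none'")
  }
  invisible(metadata)
}

#' Read an immune-cell density table from TSV
#'
#' Long format with columns participant_id, aspect (inner/outer), layer
#' (epidermis/dermis), marker (CD3, CD4, CD56, CD11c, CD207, CD68, CD117,
#' tryptase) and density (cells/mm^2, nonnegative). At most one record per
#' (participant, aspect, layer, marker).
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame.
#' @export
read_density_table <- function(path) {
  raw <- read_tsv_checked(path)
  need <- c("participant_id", "aspect", "layer", "marker", "density")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("density table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- raw[, need]
  dt$participant_id <- as.character(dt$participant_id)
  dt$aspect <- tolower(trimws(as.character(dt$aspect)))
  dt$layer  <- tolower(trimws(as.character(dt$layer)))
  dt$marker <- as.character(dt$marker)
  dt$density <- as.numeric(dt$density)
  validate_densities(dt)
  dt
}

.density_markers <- c("CD3", "CD4", "CD56", "CD11c", "CD207", "CD68",
                      "CD117", "tryptase")

#' Validate an immune-cell density data.frame
#'
#' @param densities data.frame as returned by [read_density_table()].
#' @return The input, invisibly, if valid.
#' @export
validate_densities <- function(densities) {
  if (!all(densities$aspect %in% c("inner", "outer"))) {
    stop("aspect must be 'inner' or 'outer'")
  }
  if (!all(densities$layer %in% c("epidermis", "dermis"))) {
    stop("layer must be 'epidermis' or 'dermis'")
  }
  bad <- setdiff(unique(densities$marker), .density_markers)
  if (length(bad) > 0L) {
    stop("unknown marker(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(densities$density) & densities$density < 0)) {
    stop("density must be nonnegative")
  }
  key <- paste(densities$participant_id, densities$aspect,
               densities$layer, densities$marker)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, aspect, layer, marker) record(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "))
  }
  invisible(densities)
}

#' Write a tabular result to TSV
#'
#' Matrices are written with the rownames as a leading id column; data.frames
#' are written as-is. Missing values become literal "NA". Numeric values are
#' written with enough digits to round-trip (15 significant digits).
#'
#' @param result A matrix with dimnames or a data.frame with named columns.
#' @param path Output path.
#' @param id_col Name for the leading id column when `result` is a matrix.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path, id_col = "sample_id") {
  if (is.matrix(result)) {
    df <- data.frame(rownames(result), result, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_col
  } else if (is.data.frame(result)) {
    df <- result
  } else {
    stop("result must be a matrix or a data.frame")
  }
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Shared strict TSV reader: header required, tabs only, no comment munging.
read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    na.strings = "NA")
}
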