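#' Read a gene-by-sample expression matrix from TSV
#'
#' Reads a tab-separated text file whose first column holds gene (or probe)
#' identifiers and whose header row holds sample identifiers. Values are log2
#' expression intensities.
#'
#' @param path Path to a TSV file. Row 1 is `gene_id` followed by sample ids.
#' @return A numeric matrix with genes as rows; `rownames` are gene ids and
#'   `colnames` are sample ids, both in file order.
#' @details Duplicate gene or sample identifiers and non-numeric cells are
#'   hard errors; the offending identifier or cell coordinate is named in the
#'   error message. Missing values are not permitted in an analysis matrix.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) {
    stop("expression matrix must have a gene id column plus >= 1 sample column")
  }
  sample_ids <- colnames(raw)[-1L]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample identifier(s) in header: ",
         paste(dup_s, collapse = ", "))
  }
  gene_ids <- raw[[1L]]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value '%s' at data line %d (gene '%s'), sample '%s'",
        col[bad[1L]], bad[1L], gene_ids[bad[1L]], sample_ids[j]))
    }
    vals[, j] <- num
  }
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: writes a `gene_id` column followed
#' by one column per sample, at full double precision so that a read/write
#' round trip preserves values.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  m <- validate_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric matrix, unique non-missing gene
#' and sample identifiers, all values finite.
#'
#' @param m Candidate matrix.
#' @return The matrix, invisibly unchanged, for call chaining.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene identifier(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (!all(is.finite(m))) {
    stop("expression matrix contains non-finite values; ",
         "missing values are not supported")
  }
  m
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `cancer_type`, `location`,
#'   `group`, `center`, `rin`.
#' @return A data.frame, validated by [validate_sample_metadata()].
#' @export
read_sample_sheet <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' Write a sample sheet
#' @param meta Sample metadata data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CANCER_TYPES <- c("breast", "melanoma", "lymphoma")

#' Validate sample metadata
#'
#' Enforces the cohort design invariants: cancer type one of breast,
#' melanoma, lymphoma; location brain or extra_cerebral; group 1 samples are
#' exactly the brain samples and groups 2/3 the extra-cerebral ones; RIN in
#' `[1, 10]`.
#'
#' @param meta data.frame with columns `sample_id`, `cancer_type`,
#'   `location`, `group`, `center`, `rin`.
#' @param m Optional expression matrix; if given, every matrix sample must
#'   have exactly one metadata row.
#' @return The validated data.frame.
#' @export
validate_sample_metadata <- function(meta, m = NULL) {
  needed <- c("sample_id", "cancer_type", "location", "group", "center", "rin")
  missing_cols <- setdiff(needed, colnames(meta))
  if (length(missing_cols)) {
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  if (!all(meta$cancer_type %in% CANCER_TYPES)) {
    stop("cancer_type must be one of: ", paste(CANCER_TYPES, collapse = ", "))
  }
  if (!all(meta$location %in% c("brain", "extra_cerebral"))) {
    stop("location must be 'brain' or 'extra_cerebral'")
  }
  if (!all(meta$group %in% 1:3)) {
    stop("group must be 1, 2 or 3")
  }
  bad <- (meta$group == 1L) != (meta$location == "brain")
  if (any(bad)) {
    stop("group/location mismatch for sample(s): ",
         paste(meta$sample_id[bad], collapse = ", "),
         " (group 1 must be brain; groups 2/3 extra-cerebral)")
  }
  if (!is.numeric(meta$rin) || any(meta$rin < 1 | meta$rin > 10)) {
    stop("rin must be numeric in [1, 10]")
  }
  if (!is.null(m)) {
    absent <- setdiff(colnames(m), meta$sample_id)
    if (length(absent)) {
      stop("matrix sample(s) missing from sample sheet: ",
           paste(absent, collapse = ", "))
    }
  }
  meta
}

#' Read a probe-to-gene map
#'
#' @param path Two-column TSV `probe_id`, `gene_id`. Each probe maps to
#'   exactly one gene.
#' @return data.frame with columns `probe_id` and `gene_id`.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% colnames(pm))) {
    stop("probe map must have columns probe_id, gene_id")
  }
  if (anyDuplicated(pm$probe_id)) {
    stop("probe map assigns some probe(s) to more than one gene: ",
         paste(unique(pm$probe_id[duplicated(pm$probe_id)]), collapse = ", "))
  }
  pm
}

#' Collapse probe-level rows to gene level
#'
#' Summarizes all probes of a gene by their per-sample median, yielding one
#' row per gene. The median is robust to a single aberrant probe.
#'
#' @param m Probe-level expression matrix (probes as rows).
#' @param probe_map data.frame with columns `probe_id`, `gene_id` covering
#'   every row of `m`.
#' @return Gene-level expression matrix; genes ordered by first appearance of
#'   their probes in `m`.
#' @export
collapse_probes_to_genes <- function(m, probe_map) {
  m <- validate_expression_matrix(m)
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probe map assigns some probe(s) to more than one gene")
  }
  unmapped <- setdiff(rownames(m), probe_map$probe_id)
  if (length(unmapped)) {
    stop("unmapped probe(s): ", paste(unmapped, collapse = ", "))
  }
  gene_of <- probe_map$gene_id[match(rownames(m), probe_map$probe_id)]
  genes <- unique(gene_of)
  idx <- split(seq_len(nrow(m)), factor(gene_of, levels = genes))
  out <- t(vapply(idx, function(i) {
    if (length(i) == 1L) m[i, ] else apply(m[i, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(m))))
  dimnames(out) <- list(genes, colnames(m))
  out
}
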