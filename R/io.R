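#' Anatomical regions analysed by the pipeline
#'
#' The four brain areas affected during the limbic stage of Alzheimer's
#' disease, in the anatomical progression order used throughout the package
#' (hippocampus, CA1 subfield, entorhinal cortex, perirhinal cortex).
#' Trajectory shapes and fold-change profiles always follow this order.
#'
#' @return Character vector `c("HP", "CA1", "EC", "PRC")`.
#' @export
brain_regions <- function() c("HP", "CA1", "EC", "PRC")

.LAYERS <- c("protein", "phosphopeptide", "acetyl", "phospho_state")
.GROUPS <- c("AD", "control")

#' Construct an intensity matrix
#'
#' A features x samples abundance table for one omic layer. Missingness is
#' encoded as `NA`, never as zero; on the raw scale all present values must
#' be strictly positive so that the log2 transform is invertible.
#'
#' @param values Numeric matrix with feature row names and sample column
#'   names.
#' @param layer One of `"protein"`, `"phosphopeptide"`, `"acetyl"`,
#'   `"phospho_state"`.
#' @param scale `"raw"` or `"log2"`.
#' @return The matrix with class `intensity_matrix` and attributes `layer`
#'   and `scale`.
#' @export
intensity_matrix <- function(values, layer = .LAYERS, scale = c("raw", "log2")) {
  layer <- match.arg(layer)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature id: ", dup[1])
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    stop("raw-scale intensities must be strictly positive; ",
         "encode missing values as NA, never as 0")
  structure(values, layer = layer, scale = scale,
            class = c("intensity_matrix", "matrix", "array"))
}

#' @export
`[.intensity_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    attr(out, "layer") <- attr(x, "layer")
    attr(out, "scale") <- attr(x, "scale")
    class(out) <- class(x)
  }
  out
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix [%s, %s scale]: %d features x %d samples, %.1f%% missing\n",
              attr(x, "layer"), attr(x, "scale"), nrow(x), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Scale of an intensity matrix
#' @param x An `intensity_matrix`.
#' @return `"raw"` or `"log2"`.
#' @export
im_scale <- function(x) attr(x, "scale")

#' Omic layer of an intensity matrix
#' @param x An `intensity_matrix`.
#' @return Layer label.
#' @export
im_layer <- function(x) attr(x, "layer")

#' Read an intensity matrix from a tab-separated file
#'
#' Expects the first column to hold feature identifiers and the header row
#' to hold sample identifiers. Empty cells and the literal string `NA` are
#' read as missing.
#'
#' @param path Path to a TSV file.
#' @param layer Omic layer of the table (see [intensity_matrix()]).
#' @param scale Scale of the stored values, default `"raw"`.
#' @param samples Optional sample table; when given, all matrix columns must
#'   be known sample ids.
#' @return An [intensity_matrix()].
#' @export
read_intensity_matrix <- function(path, layer = .LAYERS, scale = c("raw", "log2"),
                                  samples = NULL) {
  layer <- match.arg(layer)
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2) stop("intensity table must have a feature-id column and at least one sample column")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate feature id: ", dup[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE))
    stop("negative intensity value encountered in ", path)
  if (scale == "raw" && any(m == 0, na.rm = TRUE))
    stop("zero intensity encountered in ", path,
         ": missing values must be empty or NA, never 0")
  if (!is.null(samples)) {
    unknown <- setdiff(colnames(m), samples$sample_id)
    if (length(unknown))
      stop("sample ids not present in sample table: ",
           paste(unknown, collapse = ", "))
  }
  intensity_matrix(m, layer = layer, scale = scale)
}

#' Write an intensity matrix to a tab-separated file
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip reproduces the matrix exactly; missing cells are written as
#' `NA`.
#'
#' @param x An [intensity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(x, path) {
  ch <- matrix("NA", nrow(x), ncol(x))
  ok <- !is.na(x)
  ch[ok] <- sprintf("%.17g", x[ok])
  df <- data.frame(feature_id = rownames(x), ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.SAMPLE_COLUMNS <- c("sample_id", "brain_id", "region", "group", "sex",
                     "age", "pmi", "tech_rep")

#' Validate a sample (design) table
#'
#' Checks the invariants of the study design: unique sample ids, unique
#' (brain, region, technical replicate) combinations, valid region/group/sex
#' labels, positive age and postmortem interval, and brain-level consistency
#' of all subject covariates.
#'
#' @param df A data frame with columns `sample_id`, `brain_id`, `region`,
#'   `group`, `sex`, `age`, `pmi`, `tech_rep`.
#' @return The validated data frame (character columns, integer `tech_rep`).
#' @export
validate_sample_table <- function(df) {
  missing_cols <- setdiff(.SAMPLE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("sample table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, .SAMPLE_COLUMNS]
  for (col in c("sample_id", "brain_id", "region", "group", "sex"))
    df[[col]] <- as.character(df[[col]])
  df$age <- as.numeric(df$age)
  df$pmi <- as.numeric(df$pmi)
  df$tech_rep <- as.integer(df$tech_rep)

  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", dup[1])
  bad_region <- setdiff(unique(df$region), brain_regions())
  if (length(bad_region)) stop("unknown region label: ", bad_region[1])
  bad_group <- setdiff(unique(df$group), .GROUPS)
  if (length(bad_group)) stop("unknown group label: ", bad_group[1])
  bad_sex <- setdiff(unique(df$sex), c("M", "F"))
  if (length(bad_sex)) stop("unknown sex label: ", bad_sex[1])
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("age must be a positive number of years")
  if (any(!is.finite(df$pmi)) || any(df$pmi <= 0)) stop("pmi must be a positive number of hours")
  if (any(df$tech_rep < 1L)) stop("tech_rep must be >= 1")

  key <- paste(df$brain_id, df$region, df$tech_rep, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (brain_id, region, tech_rep) combination: ",
         gsub("\r", "/", key[duplicated(key)][1]))

  for (col in c("group", "sex", "age", "pmi")) {
    n_per_brain <- tapply(df[[col]], df$brain_id, function(v) length(unique(v)))
    if (any(n_per_brain > 1))
      stop("brain ", names(n_per_brain)[n_per_brain > 1][1],
           " has inconsistent ", col, " across rows")
  }
  rownames(df) <- NULL
  df
}

#' Read a sample table from a tab-separated file
#'
#' @param path Path to a TSV file with the columns described in
#'   [validate_sample_table()].
#' @return A validated sample table.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Write a sample table
#' @param df Sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member identifiers. Duplicate members within a
#' set are removed.
#'
#' @param path Path to a GMT file.
#' @return Named list of unique member-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file contains no gene sets: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name: ", names(sets)[duplicated(names(sets))][1])
  empty <- which(lengths(sets) == 0L)
  if (length(empty)) stop("gene set '", names(sets)[empty[1]], "' has no members")
  sets
}

#' Read a plain accession list
#'
#' One identifier per line; blank lines and surrounding whitespace are
#' dropped. Used for AMP and kinase annotation lists.
#'
#' @param path Path to a text file.
#' @return Character vector of unique identifiers.
#' @export
read_accession_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (!length(ids)) stop("accession list is empty: ", path)
  ids
}
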