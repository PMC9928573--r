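# Central genotype container.  Genotypes are stored as an integer matrix
# (markers x individuals) with codes 0 = aa, 1 = ab, 2 = bb, NA = missing;
# "aa" is the maternal (parent-1) homozygote, "bb" the paternal (parent-2)
# homozygote.  Per-marker metadata travels in a parallel data frame.

GENO_CODES <- c("aa", "ab", "bb")
MISSING_CODE <- "--"

#' Construct a genotype matrix object
#'
#' Bundles an integer genotype matrix (markers x individuals; 0 = aa,
#' 1 = ab, 2 = bb, `NA` = missing) with per-marker metadata.  The metadata
#' data frame must contain a `marker_id` column matching the matrix row
#' names; typical further columns are `lg_truth`, `pos_truth_cM` (simulation
#' ground truth), `allele_p1`, `allele_p2` (parental calls), `snp_count`,
#' `depth_p1`, `depth_p2`.
#'
#' @param geno integer matrix, markers in rows, individuals in columns, with
#'   row and column names.  Character matrices with codes
#'   `"aa"/"ab"/"bb"/"--"` are converted.
#' @param info data frame of per-marker metadata with a `marker_id` column.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, info = NULL) {
  if (is.character(geno)) {
    codes <- match(geno, GENO_CODES) - 1L
    bad <- !is.na(geno) & geno != MISSING_CODE & is.na(codes)
    if (any(bad)) stop("unknown genotype codes: ",
                       paste(unique(geno[bad]), collapse = ", "))
    geno <- matrix(codes, nrow = nrow(geno), dimnames = dimnames(geno))
  }
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("M%04d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("F2-%03d", seq_len(ncol(geno)))
  if (any(geno < 0L | geno > 2L, na.rm = TRUE))
    stop("genotype codes must be 0 (aa), 1 (ab), 2 (bb) or NA")
  if (is.null(info)) {
    info <- data.frame(marker_id = rownames(geno), stringsAsFactors = FALSE)
  }
  if (!"marker_id" %in% names(info)) stop("info must have a marker_id column")
  if (nrow(geno) > 0 &&
      !identical(as.character(info$marker_id), rownames(geno)))
    stop("info$marker_id must match rownames(geno) in order")
  structure(list(geno = geno, info = info), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers x %d individuals\n",
              nrow(x$geno), ncol(x$geno)))
  nm <- sum(is.na(x$geno))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              100 * nm / length(x$geno)))
  cat("  metadata: ", paste(names(x$info), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by marker and/or individual
#'
#' @param x a [geno_matrix()].
#' @param markers marker ids or indices (default all).
#' @param individuals individual ids or indices (default all).
#' @return a `geno_matrix` restricted to the selection.
#' @export
subset_markers <- function(x, markers = NULL, individuals = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  if (is.null(markers)) markers <- seq_len(nrow(x$geno))
  if (is.character(markers)) markers <- match(markers, rownames(x$geno))
  if (anyNA(markers)) stop("unknown marker ids")
  if (is.null(individuals)) individuals <- seq_len(ncol(x$geno))
  geno_matrix(x$geno[markers, individuals, drop = FALSE],
              x$info[markers, , drop = FALSE])
}

code_to_char <- function(g) {
  out <- matrix(MISSING_CODE, nrow(g), ncol(g), dimnames = dimnames(g))
  out[!is.na(g)] <- GENO_CODES[g[!is.na(g)] + 1L]
  out
}

#' Write / read the native tab-separated genotype format
#'
#' Rows are markers; the leading columns are the metadata columns of the
#' object's `info` slot (always starting with `marker_id`), followed by one
#' column per individual holding `aa`, `ab`, `bb` or `--` (missing).
#' Missing numeric metadata is written as `.`.
#'
#' @param x a [geno_matrix()].
#' @param path file path.
#' @return `write_genotype_tsv()` returns `path` invisibly;
#'   `read_genotype_tsv()` returns a `geno_matrix`.
#' @export
write_genotype_tsv <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  chars <- code_to_char(x$geno)
  df <- cbind(x$info, as.data.frame(chars, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = ".",
                   stringsAsFactors = FALSE)
  if (!"marker_id" %in% names(df))
    stop("genotype TSV ", path, " lacks a marker_id column")
  is_geno <- vapply(df, function(col)
    is.character(col) && all(col %in% c(GENO_CODES, MISSING_CODE, NA)),
    logical(1))
  is_geno["marker_id"] <- FALSE
  # genotype columns are the trailing block of pure-code columns
  geno_cols <- names(df)[is_geno]
  if (length(geno_cols) == 0) stop("no genotype columns found in ", path)
  g <- as.matrix(df[, geno_cols, drop = FALSE])
  g[is.na(g)] <- MISSING_CODE
  rownames(g) <- df$marker_id
  info <- df[, setdiff(names(df), geno_cols), drop = FALSE]
  rownames(info) <- NULL
  geno_matrix(g, info)
}

#' Write / read phenotype tables
#'
#' Tab-separated with columns `individual_id`, then one column per trait
#' (`fsh_cm` continuous, `fertility` categorical); missing values written
#' as `.`.
#'
#' @param pheno data frame with an `individual_id` column.
#' @param path file path.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  stopifnot(is.data.frame(pheno), "individual_id" %in% names(pheno))
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  read.delim(path, check.names = FALSE, na.strings = ".",
             stringsAsFactors = FALSE)
}
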