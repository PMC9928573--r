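# Optional VCF bridge.  The native interchange is the TSV genotype format;
# VCF emission/ingest lets the pipeline exchange SNP genotypes with
# standard variant tooling.  Reading uses vcfR (suggested dependency).

#' Write a genotype matrix as a (sites-only) VCF
#'
#' One record per SNP: a marker with `snp_count = s` emits `s` records
#' with ids `<marker>.<k>` sharing the marker's genotypes.  Samples are
#' the two parents (always `0/0` and `1/1` — the aa x bb design) followed
#' by the progeny, coded `0/0` (aa), `0/1` (ab), `1/1` (bb), `./.`
#' (missing).  CHROM is the true linkage group when available, POS a
#' 1-based coordinate derived from the cM position (x 10000) or the row
#' index.
#'
#' @param x a [geno_matrix()].
#' @param path output path (plain text).
#' @param parent1,parent2 sample names for the parents.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(x, path, parent1 = "DH-1", parent2 = "DH-17") {
  stopifnot(inherits(x, "geno_matrix"))
  info <- x$info
  m <- nrow(x$geno)
  chrom <- if ("lg_truth" %in% names(info)) paste0("LG", info$lg_truth)
           else rep("LG0", m)
  pos <- if ("pos_truth_cM" %in% names(info))
    as.integer(round(info$pos_truth_cM * 10000)) + 1L else seq_len(m)
  ref <- if ("allele_p1" %in% names(info)) info$allele_p1 else rep("A", m)
  alt <- if ("allele_p2" %in% names(info)) info$allele_p2 else rep("G", m)
  snp <- if ("snp_count" %in% names(info)) info$snp_count else rep(1L, m)
  gt <- matrix("./.", m, ncol(x$geno))
  gt[!is.na(x$geno)] <- c("0/0", "0/1", "1/1")[x$geno[!is.na(x$geno)] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=slafmap",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", parent1, parent2,
                      colnames(x$geno)), collapse = "\t"))
  rows <- character(sum(snp))
  ri <- 0L
  for (i in seq_len(m)) {
    for (k in seq_len(snp[i])) {
      ri <- ri + 1L
      rows[ri] <- paste(c(chrom[i], pos[i] + k - 1L,
                          paste0(rownames(x$geno)[i], ".", k),
                          ref[i], alt[i], ".", "PASS", ".", "GT",
                          "0/0", "1/1", gt[i, ]), collapse = "\t")
    }
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read progeny genotypes from a VCF relative to two parents
#'
#' Each biallelic record becomes one marker.  Progeny genotypes are
#' recoded to aa / ab / bb relative to the parental homozygous states
#' (`aa` = parent-1 allele); half calls and missing calls become missing.
#' Records where either parent is heterozygous or missing are routed to
#' the segregation-pattern classifier and excluded from the aa x bb
#' output; multi-allelic records are skipped and counted.
#'
#' @param path VCF file path.
#' @param parent1,parent2 parent sample names.
#' @return list with `matrix` (aa x bb [geno_matrix()]), `excluded` (data
#'   frame `marker_id`, `pattern`), `n_multiallelic`.
#' @export
read_vcf_genotypes <- function(path, parent1 = "DH-1", parent2 = "DH-17") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    warning("empty VCF: ", path)
    return(list(matrix = geno_matrix(matrix(NA_integer_, 0, 0,
                                            dimnames = list(NULL, NULL)),
                                     data.frame(marker_id = character(0))),
                excluded = data.frame(marker_id = character(0),
                                      pattern = character(0)),
                n_multiallelic = 0L))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!all(c(parent1, parent2) %in% colnames(gt)))
    stop("parent samples not found in VCF: ", parent1, ", ", parent2)
  multi <- grepl(",", fix[, "ALT"])
  prog_cols <- setdiff(colnames(gt), c(parent1, parent2))
  code_gt <- function(s) {
    s <- gsub("\\|", "/", s)
    out <- rep(NA_integer_, length(s))
    out[s %in% "0/0"] <- 0L
    out[s %in% c("0/1", "1/0")] <- 1L
    out[s %in% "1/1"] <- 2L
    out
  }
  parent_alleles <- function(code, ref, alt) {
    if (is.na(code)) return(NA_character_)
    c(ref, paste0(ref, "/", alt), alt)[code + 1L]
  }
  keep <- excl_id <- excl_pat <- character(0)
  geno_rows <- list()
  info_rows <- list()
  for (i in which(!multi)) {
    p1 <- code_gt(gt[i, parent1])
    p2 <- code_gt(gt[i, parent2])
    id <- unname(fix[i, "ID"])
    if (is.na(id) || id == ".") id <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
    ref <- unname(fix[i, "REF"]); alt <- unname(fix[i, "ALT"])
    a1 <- parent_alleles(p1, ref, alt)
    a2 <- parent_alleles(p2, ref, alt)
    pat <- if (is.na(p1) || is.na(p2)) "missing_parent"
           else classify_segregation_pattern(a1, a2)
    if (identical(pat, "aaxbb")) {
      g <- code_gt(gt[i, prog_cols])
      if (p1 == 2L) g <- 2L - g   # orient so aa = parent-1 allele
      geno_rows[[length(geno_rows) + 1]] <- g
      info_rows[[length(info_rows) + 1]] <- data.frame(
        marker_id = id, allele_p1 = if (p1 == 0L) ref else alt,
        allele_p2 = if (p2 == 0L) ref else alt, stringsAsFactors = FALSE)
      keep <- c(keep, id)
    } else {
      excl_id <- c(excl_id, id)
      excl_pat <- c(excl_pat, pat)
    }
  }
  geno <- if (length(geno_rows))
    matrix(unlist(geno_rows), nrow = length(geno_rows), byrow = TRUE,
           dimnames = list(keep, prog_cols))
  else matrix(NA_integer_, 0, length(prog_cols),
              dimnames = list(NULL, prog_cols))
  info <- if (length(info_rows)) do.call(rbind, info_rows)
          else data.frame(marker_id = character(0))
  list(matrix = geno_matrix(geno, info),
       excluded = data.frame(marker_id = excl_id, pattern = excl_pat,
                             stringsAsFactors = FALSE),
       n_multiallelic = sum(multi))
}
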