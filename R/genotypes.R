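#' Construct a genotype matrix
#'
#' Container for diploid SNP dosages (0/1/2, `NA` allowed) for individuals by
#' loci, with per-sample population labels and a set label recording which SNP
#' set (full, neutral, candidate, custom) the matrix represents.
#'
#' @param dosages Integer matrix, individuals in rows, SNPs in columns, values
#'   in `{0, 1, 2, NA}`. Row names are sample ids, column names SNP ids (both
#'   filled in from `sample_ids`/`snp_ids` when given).
#' @param sample_ids,snp_ids Optional identifier vectors (unique).
#' @param population_ids Per-sample provenance labels (recycled if length 1).
#' @param set_label One of `"full"`, `"neutral"`, `"candidate"`, `"custom"`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            snp_ids = colnames(dosages),
                            population_ids = "pop_1",
                            set_label = c("custom", "full", "neutral", "candidate")) {
  set_label <- match.arg(set_label)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(sample_ids)) sample_ids <- sprintf("ind_%04d", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%05d", seq_len(ncol(dosages)))
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length does not match dosage rows", call. = FALSE)
  }
  if (length(snp_ids) != ncol(dosages)) {
    stop("snp_ids length does not match dosage columns", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique", call. = FALSE)
  bad <- dosages[!is.na(dosages)]
  if (length(bad) > 0 && !all(bad %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA (diploid biallelic coding)", call. = FALSE)
  }
  population_ids <- rep_len(as.character(population_ids), nrow(dosages))
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(
    list(dosages = dosages, population_ids = population_ids,
         set_label = set_label),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (set: %s, %d populations)\n",
              nrow(x$dosages), ncol(x$dosages), x$set_label,
              length(unique(x$population_ids))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Sample and SNP identifiers of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(g) rownames(g$dosages)

#' @rdname sample_ids
#' @export
snp_ids <- function(g) colnames(g$dosages)

#' Read genotypes from a 012 dosage table or a VCF
#'
#' The canonical exchange format is a TSV with columns `sample_id`,
#' `population_id`, then one column per SNP holding 0/1/2 dosages (`NA` or
#' empty for missing). VCF (v4.x, diploid `GT` field) is supported as a
#' convenience; multiallelic records are dropped with a logged count.
#'
#' @param path File path.
#' @param format `"matrix-012"` (default) or `"vcf"`.
#' @param set_label Set label stored on the result.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("matrix-012", "vcf"),
                           set_label = "custom") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "matrix-012") {
    read_genotypes_012(path, set_label)
  } else {
    read_genotypes_vcf(path, set_label)
  }
}

read_genotypes_012 <- function(path, set_label) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  need <- c("sample_id", "population_id")
  if (!all(need %in% names(df))) {
    stop(sprintf("parse error in %s line 1: header must start with sample_id, population_id",
                 path), call. = FALSE)
  }
  snp_cols <- setdiff(names(df), need)
  dos <- as.matrix(df[snp_cols])
  if (!is.numeric(dos)) {
    bad_line <- which(apply(df[snp_cols], 1, function(r) {
      any(!is.na(r) & is.na(suppressWarnings(as.numeric(r))))
    }))[1]
    stop(sprintf("parse error in %s line %d: non-numeric dosage", path,
                 bad_line + 1L), call. = FALSE)
  }
  vals <- dos[!is.na(dos)]
  if (length(vals) > 0 && !all(vals %in% 0:2)) {
    stop("non-diploid dosage call (value outside 0/1/2) in genotype table",
         call. = FALSE)
  }
  genotype_matrix(dos, sample_ids = as.character(df$sample_id),
                  snp_ids = snp_cols,
                  population_ids = as.character(df$population_id),
                  set_label = set_label)
}

read_genotypes_vcf <- function(path, set_label) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    gf_log("dropped %d multiallelic VCF record(s)", sum(multi))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids)) {
    ids <- sprintf("%s_%s", vcfR::getCHROM(v), vcfR::getPOS(v))
  }
  alleles <- function(x) {
    x <- sub("\\|", "/", x)
    parts <- strsplit(x, "/", fixed = TRUE)
    vapply(parts, function(a) {
      if (length(a) != 2 || any(a == ".") || anyNA(a)) return(NA_integer_)
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a) || any(a > 1)) stop("non-diploid or non-biallelic GT call",
                                       call. = FALSE)
      sum(a)
    }, integer(1))
  }
  # apply over VCF rows yields one column per record: samples x snps
  dos <- apply(gt, 1, alleles)
  dos <- matrix(as.integer(dos), nrow = ncol(gt),
                dimnames = list(colnames(gt), ids))
  genotype_matrix(dos, set_label = set_label)
}

#' Write a genotype matrix as a 012 TSV
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(sample_id = sample_ids(g), population_id = g$population_ids,
                   g$dosages, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-SNP minor allele frequency
#'
#' For each locus the alternate-allele frequency is `p = sum(dosages) /
#' (2 * n_non_missing)` and the minor allele frequency is `min(p, 1 - p)`,
#' computed over all individuals pooled.
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector of MAF values in `[0, 0.5]`, one per SNP.
#' @export
minor_allele_frequency <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_called <- colSums(!is.na(g$dosages))
  if (any(n_called == 0)) {
    stop(sprintf("SNP(s) with all calls missing: %s",
                 paste(snp_ids(g)[n_called == 0], collapse = ", ")),
         call. = FALSE)
  }
  p <- colSums(g$dosages, na.rm = TRUE) / (2 * n_called)
  pmin(p, 1 - p)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains exactly the loci whose pooled-sample MAF is strictly greater than
#' `threshold` (default 0.05, the conventional rare-allele cutoff). The filter
#' is idempotent.
#'
#' @param g A [genotype_matrix()].
#' @param threshold MAF cutoff in `[0, 0.5)`; strict inequality.
#' @return The filtered `genotype_matrix`.
#' @export
filter_maf <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 0.5) {
    stop("threshold must be a single value in [0, 0.5)", call. = FALSE)
  }
  maf <- minor_allele_frequency(g)
  keep <- maf > threshold
  gf_log("MAF filter (> %g): retained %d of %d SNPs", threshold,
         sum(keep), length(keep))
  out <- g
  out$dosages <- g$dosages[, keep, drop = FALSE]
  out
}

#' Drop SNPs with excessive missingness
#'
#' Loci whose per-SNP missing-call fraction exceeds `ceiling` are removed with
#' a log entry. Remaining missing calls are left in place: each SNP's forest is
#' later fit on its complete cases.
#'
#' @param g A [genotype_matrix()].
#' @param ceiling Maximum tolerated per-SNP missing fraction (default 0.2).
#' @return The filtered `genotype_matrix`.
#' @export
filter_missingness <- function(g, ceiling = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"))
  miss <- colMeans(is.na(g$dosages))
  keep <- miss <= ceiling
  if (any(!keep)) {
    gf_log("missingness filter (> %g): dropped %d SNP(s)", ceiling, sum(!keep))
  }
  out <- g
  out$dosages <- g$dosages[, keep, drop = FALSE]
  out
}

#' Assemble a candidate SNP set from association-scan hits
#'
#' Unions the locus ids nominated by a genotype-environment association scan
#' with those from a genotype-phenotype scan. Ids present in both contribute
#' once: `|union| = |gea| + |gpa| - |intersection|`.
#'
#' @param gea_ids,gpa_ids Character vectors of SNP ids (no duplicates within
#'   either set).
#' @return Character vector of the union, in first-appearance order.
#' @export
#' @examples
#' assemble_candidate_set(c("a", "b"), c("b", "c"))
assemble_candidate_set <- function(gea_ids, gpa_ids) {
  if (anyDuplicated(gea_ids)) stop("duplicate ids in gea_ids", call. = FALSE)
  if (anyDuplicated(gpa_ids)) stop("duplicate ids in gpa_ids", call. = FALSE)
  union(gea_ids, gpa_ids)
}

#' Subset a genotype matrix by SNP ids
#' @param g A [genotype_matrix()].
#' @param ids SNP ids to keep (all must be present).
#' @param set_label Optional new set label.
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_snps <- function(g, ids, set_label = g$set_label) {
  stopifnot(inherits(g, "genotype_matrix"))
  missing <- setdiff(ids, snp_ids(g))
  if (length(missing) > 0) {
    stop(sprintf("unknown SNP id(s): %s", paste(utils::head(missing, 5),
                                                collapse = ", ")), call. = FALSE)
  }
  out <- g
  out$dosages <- g$dosages[, ids, drop = FALSE]
  out$set_label <- set_label
  out
}
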