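#' Genotype dosage matrix with variant metadata
#'
#' The container all scan stages operate on: a subjects-by-variants matrix of
#' expected allele-count dosages in `[0, 2]` plus a variant information table.
#'
#' @param dosage numeric matrix, subjects in rows (rownames = subject ids),
#'   variants in columns; values in `[0, 2]` or NA.
#' @param info data.frame with one row per variant: `chr`, `pos` (1-based),
#'   `rsid`, `a1` (effect allele), `a2` (reference allele), `maf`, `r2`
#'   (imputation accuracy); extra columns are kept.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, info) {
  dosage <- as.matrix(dosage)
  info <- as.data.frame(info)
  stopifnot(ncol(dosage) == nrow(info))
  need <- c("chr", "pos", "rsid", "a1", "a2", "maf", "r2")
  miss <- setdiff(need, names(info))
  if (length(miss)) stop("variant info lacks columns: ", paste(miss, collapse = ", "))
  if (any(info$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (anyDuplicated(paste(info$chr, info$pos, info$rsid))) stop("duplicate variant keys")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  colnames(dosage) <- info$rsid
  structure(list(dosage = dosage, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  print(utils::head(x$info, 3))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read dosages from a VCF with MAF and imputation-quality filters
#'
#' Parses a VCF (v4.2+) whose FORMAT carries a `DS` dosage field, applies the
#' record filters — minor allele frequency strictly greater than `maf_min` and
#' imputation R-squared strictly greater than `r2_min` — and returns a
#' [genotype_matrix()]. MAF is computed from the dosages when no allele
#' frequency INFO field is present; R-squared is read from the INFO key
#' `r2_key` (variants lacking it are treated as R2 = 1, i.e. genotyped).
#' Multi-allelic records are skipped with a warning. Per-filter drop counts
#' are logged.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param maf_min strict lower MAF bound (default 0.01).
#' @param r2_min strict lower imputation-R2 bound (default 0.8).
#' @param r2_key INFO key holding imputation accuracy (default `"R2"`).
#' @return a [genotype_matrix()].
#' @export
read_vcf_dosages <- function(path, maf_min = 0.01, r2_min = 0.8, r2_key = "R2") {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("no variant records in ", path)
  fixed <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fixed$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  fmt <- v@gt[, 1L]
  if (!all(grepl("(^|:)DS(:|$)", fmt))) {
    bad <- which(!grepl("(^|:)DS(:|$)", fmt))[1L]
    stop("FORMAT lacks DS dosage field at record ", fixed$CHROM[bad], ":",
         fixed$POS[bad])
  }
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  ds <- t(ds)  # subjects x variants
  r2 <- extract_info_key(fixed$INFO, r2_key)
  r2[is.na(r2)] <- 1
  af <- colMeans(ds, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep_multi <- !multi
  keep_r2 <- r2 > r2_min
  keep_maf <- maf > maf_min
  keep <- keep_multi & keep_r2 & keep_maf
  gxewas_log("read_vcf", sprintf(
    "%d records; dropped %d multi-allelic, %d at R2 <= %g, %d at MAF <= %g; %d retained",
    nrow(fixed), sum(multi), sum(keep_multi & !keep_r2), r2_min,
    sum(keep_multi & keep_r2 & !keep_maf), maf_min, sum(keep)))
  if (!any(keep)) stop("no variants survive the MAF/R2 filters")
  info <- data.frame(
    chr = fixed$CHROM[keep], pos = as.integer(fixed$POS[keep]),
    rsid = fixed$ID[keep], a1 = fixed$ALT[keep], a2 = fixed$REF[keep],
    maf = maf[keep], r2 = r2[keep], stringsAsFactors = FALSE
  )
  genotype_matrix(ds[, keep, drop = FALSE], info)
}

extract_info_key <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  out <- rep(NA_real_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- as.numeric(sub(paste0("^;?", key, "="), "", m))
  out
}

#' Write a genotype matrix as a VCF v4.2 with FORMAT DS
#'
#' Emits one dosage value per subject per variant under the `DS` FORMAT key,
#' with `AF` and the imputation accuracy in INFO, so that simulated data
#' round-trip through [read_vcf_dosages()].
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @param r2_key INFO key for imputation accuracy (default `"R2"`).
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(geno, path, r2_key = "R2") {
  stopifnot(inherits(geno, "genotype_matrix"))
  ids <- rownames(geno$dosage)
  info <- geno$info
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gxewas",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Imputation accuracy">', r2_key),
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alternate allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  af <- colMeans(geno$dosage, na.rm = TRUE) / 2
  body <- vapply(seq_len(nrow(info)), function(j) {
    ds <- formatC(geno$dosage[, j], digits = 6, format = "g")
    ds[is.na(geno$dosage[, j])] <- "."
    paste(c(sub("^chr", "", info$chr[j]), info$pos[j], info$rsid[j],
            info$a2[j], info$a1[j], ".", "PASS",
            sprintf("AF=%s;%s=%s", formatC(af[j], digits = 6, format = "g"),
                    r2_key, formatC(info$r2[j], digits = 6, format = "g")),
            "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with a header row and `NA` as the missing-value token.
#' Mandatory columns: `subject_id`, `outcome` (strictly 0/1), `study`. All
#' other columns are preserved, typed by [utils::read.delim()].
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ph <- utils::read.delim(path, sep = "\t", na.strings = "NA",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "outcome", "study")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks mandatory columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ph$subject_id)) {
    stop("duplicate subject ids: ",
         paste(utils::head(ph$subject_id[duplicated(ph$subject_id)], 5), collapse = ", "))
  }
  if (!all(ph$outcome %in% c(0L, 1L))) {
    stop("outcome must be strictly 0/1; offending values: ",
         paste(utils::head(setdiff(unique(ph$outcome), c(0L, 1L)), 5), collapse = ", "))
  }
  gxewas_log("read_phenotypes", nrow(ph), " subjects read")
  ph
}

#' Write a phenotype table as TSV
#' @param pheno data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a results table with run provenance
#'
#' Deterministic column order and row sort (by `chr`, `pos` when present).
#' Floats are formatted to 6 significant digits; p-value columns switch to
#' scientific notation below 1e-4. Every row carries the producing config
#' hash and seed.
#'
#' @param results data.frame of per-variant or per-analysis results.
#' @param path output path.
#' @param config object hashed into the provenance column (any R object).
#' @param seed integer seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = NULL, seed = NA_integer_) {
  results <- as.data.frame(results)
  if (all(c("chr", "pos") %in% names(results)) && nrow(results) > 1L) {
    results <- results[order(results$chr, results$pos), , drop = FALSE]
  }
  results$config_hash <- rep(config_hash(config), nrow(results))
  results$seed <- rep(seed, nrow(results))
  results$timestamp <- rep(format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                           nrow(results))
  out <- results
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      if (grepl("^p($|_)|_p$|^p\\.", nm)) {
        out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                            ifelse(out[[nm]] < 1e-4 & out[[nm]] > 0,
                                   formatC(out[[nm]], digits = 6, format = "e"),
                                   formatC(out[[nm]], digits = 6, format = "g")))
      } else {
        out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                            formatC(out[[nm]], digits = 6, format = "g"))
      }
    }
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  gxewas_log("write_results", nrow(out), " rows -> ", path)
  invisible(path)
}

#' Align a genotype matrix and phenotype table by subject id
#'
#' Matching is by identifier, never by row order; unmatched ids on either side
#' are reported.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno phenotype data.frame with `subject_id`.
#' @return list with the aligned `genotypes` and `phenotypes`.
#' @export
align_subjects <- function(geno, pheno) {
  gid <- rownames(geno$dosage)
  common <- intersect(gid, pheno$subject_id)
  if (!length(common)) stop("no subject ids shared between genotypes and phenotypes")
  only_g <- setdiff(gid, common)
  only_p <- setdiff(pheno$subject_id, common)
  if (length(only_g) || length(only_p)) {
    gxewas_log("align", length(only_g), " genotype-only and ", length(only_p),
               " phenotype-only subjects dropped")
  }
  ph <- pheno[match(common, pheno$subject_id), , drop = FALSE]
  rownames(ph) <- NULL
  list(genotypes = genotype_matrix(geno$dosage[common, , drop = FALSE], geno$info),
       phenotypes = ph)
}
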