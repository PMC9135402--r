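#' Read a VCF file into a 012 genotype matrix
#'
#' Parses a VCF (v4.x) with diploid GT calls and converts each biallelic SNP
#' record to the dosage of the alternate allele: 0 = homozygous reference,
#' 1 = heterozygote, 2 = homozygous alternate; missing genotypes (`./.`)
#' become `NA`. Multiallelic records and indels are rejected with a warning
#' giving the count. Per-call DP is retained when the FORMAT field carries it,
#' so mean-depth filters can be applied downstream.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param samples optional sample metadata data frame (see
#'   [genotype_matrix()]); matched to VCF samples by `sample_id`.
#' @param loci optional locus annotation data frame; matched to retained
#'   records by `(scaffold, position)`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, samples = NULL, loci = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) stop("VCF contains no records", call. = FALSE)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_rejected <- sum(!snp)
  if (n_rejected > 0)
    warning(n_rejected, " non-biallelic-SNP record(s) rejected", call. = FALSE)
  if (!any(snp)) stop("no biallelic SNP records in VCF", call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")[snp, , drop = FALSE]
  calls <- gt_to_dosage(gt)                     # loci x samples
  calls <- t(calls)

  depth <- NULL
  fmt <- vcf@gt[, 1]
  if (any(grepl("DP", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    depth <- t(dp[snp, , drop = FALSE])
  }

  loci_df <- data.frame(
    scaffold = fix[snp, "CHROM"],
    position = as.integer(fix[snp, "POS"]),
    ref = ref[snp], alt = alt[snp],
    swept_in = "none", source = "unknown", fst = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(loci)) loci_df <- merge_locus_annotation(loci_df, loci)

  ids <- rownames(calls)
  samp_df <- default_sample_meta(ids, length(ids))
  if (!is.null(samples)) {
    idx <- match(ids, samples$sample_id)
    if (anyNA(idx))
      stop("sample metadata missing for: ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
    samp_df <- as.data.frame(samples[idx, , drop = FALSE])
    rownames(samp_df) <- NULL
  }

  genotype_matrix(calls, samples = samp_df, loci = loci_df, depth = depth)
}

gt_to_dosage <- function(gt) {
  core <- sub(":.*$", "", gt)
  core <- gsub("\\|", "/", core)
  out <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  out[core %in% c("0/0")] <- 0L
  out[core %in% c("0/1", "1/0")] <- 1L
  out[core %in% c("1/1")] <- 2L
  out
}

merge_locus_annotation <- function(loci_df, ann) {
  key <- paste(loci_df$scaffold, loci_df$position)
  akey <- paste(ann$scaffold, ann$position)
  idx <- match(key, akey)
  for (col in intersect(c("swept_in", "source", "fst", "ref", "alt"), names(ann))) {
    hit <- !is.na(idx)
    loci_df[[col]][hit] <- ann[[col]][idx[hit]]
  }
  loci_df
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT (dosage 0 -> `0/0`,
#' 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`), suitable for round-tripping
#' through [read_vcf()].
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- gm$calls
  body <- vapply(seq_len(ncol(calls)), function(j) {
    g <- calls[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    paste(c(gm$loci$scaffold[j], gm$loci$position[j], ".",
            gm$loci$ref[j], gm$loci$alt[j], ".", "PASS", ".", "GT", cells),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write a genotype matrix as a 012 TSV
#'
#' One row per sample; columns `sample_id` then one per locus named
#' `scaffold:position`; missing calls written as `NA`.
#'
#' @inheritParams write_vcf
#' @return `path`, invisibly.
#' @export
write_012 <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- as.data.frame(gm$calls)
  names(df) <- paste0(gm$loci$scaffold, ":", gm$loci$position)
  df <- cbind(sample_id = gm$samples$sample_id, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter loci by minor allele frequency, call rate and mean depth
#'
#' VCFtools-style site filters. Minor allele frequency is computed from
#' allele counts over non-missing diploid calls and retained when
#' `>= maf_min` (ties kept). Call rate follows the VCFtools `--max-missing`
#' convention: the fraction of non-missing genotypes must be `>= max_missing`.
#' When the matrix carries depth and `mean_dp_range` is given, per-site mean
#' depth must fall inside the closed interval.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]` (default 0.05).
#' @param max_missing minimum fraction of non-missing genotypes in `[0, 1]`
#'   (default 0.85).
#' @param mean_dp_range optional length-2 numeric `c(min, max)` of mean depth
#'   bounds (e.g. `c(7, 100)`); ignored with a warning when the matrix has no
#'   depth information.
#' @return A filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, maf_min = 0.05, max_missing = 0.85,
                         mean_dp_range = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]", call. = FALSE)
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0, 1]", call. = FALSE)

  calls <- gm$calls
  n_nonmiss <- colSums(!is.na(calls))
  call_rate <- n_nonmiss / nrow(calls)
  alt_count <- colSums(calls, na.rm = TRUE)
  p_alt <- ifelse(n_nonmiss > 0, alt_count / (2 * n_nonmiss), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)

  keep <- !is.na(maf) & maf >= maf_min & call_rate >= max_missing
  if (!is.null(mean_dp_range)) {
    if (is.null(gm$depth)) {
      warning("no depth information; mean-depth filter skipped", call. = FALSE)
    } else {
      mdp <- colMeans(gm$depth, na.rm = TRUE)
      keep <- keep & !is.na(mdp) & mdp >= mean_dp_range[1] & mdp <= mean_dp_range[2]
    }
  }
  if (!any(keep)) stop("all loci removed by filters", call. = FALSE)
  subset_genotypes(gm, loci = keep)
}

#' Select candidate adaptive loci by specialist and source of variation
#'
#' Returns the column indices of loci annotated as sweeping in the requested
#' specialist whose source of adaptive variation falls in `sources`, in stable
#' (scaffold, position) order. These indices form the pool from which the
#' resampling engines draw SNP sets.
#'
#' @param gm a [genotype_matrix()].
#' @param specialist `"molluscivore"` or `"scale_eater"`.
#' @param sources non-empty subset of `c("SGV", "introgression", "de_novo")`.
#' @return Integer vector of locus indices.
#' @export
select_adaptive_loci <- function(gm, specialist,
                                 sources = c("SGV", "introgression", "de_novo")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  specialist <- match.arg(specialist, c("molluscivore", "scale_eater"))
  if (length(sources) == 0) stop("sources must be non-empty", call. = FALSE)
  check_level(sources, SOURCE_LEVELS, "source")
  idx <- which(gm$loci$swept_in == specialist & gm$loci$source %in% sources)
  if (length(idx) == 0)
    stop("empty adaptive-locus pool for ", specialist, " with sources {",
         paste(sources, collapse = ", "), "}", call. = FALSE)
  idx[order(gm$loci$scaffold[idx], gm$loci$position[idx])]
}

#' Read sample metadata or locus annotations from CSV/TSV
#'
#' `read_sample_metadata()` expects columns `sample_id, species, lake,
#' experiment, role`; `read_locus_annotations()` expects `scaffold, position,
#' swept_in, source` and optionally `ref, alt, fst`.
#'
#' @param path CSV (or TSV when the extension is `.tsv`) file path.
#' @return A data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read_delim_auto(path)
  need <- c("sample_id", "species", "lake", "experiment", "role")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("sample metadata missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_sample_metadata
#' @export
read_locus_annotations <- function(path) {
  df <- read_delim_auto(path)
  need <- c("scaffold", "position", "swept_in", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("locus annotation missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
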