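#' @keywords internal
SPECIES_LEVELS <- c("generalist", "molluscivore", "scale_eater", "hybrid")
LAKE_LEVELS <- c("crescent_pond", "little_lake")
EXPERIMENT_LEVELS <- c("exp2011", "exp2014", "none")
ROLE_LEVELS <- c("parental", "hybrid")
SWEPT_LEVELS <- c("molluscivore", "scale_eater", "none")
SOURCE_LEVELS <- c("SGV", "introgression", "de_novo", "unknown")

#' Construct a diploid 012 genotype matrix with sample and locus metadata
#'
#' The central container of the package: a samples-by-loci matrix of diploid
#' genotype dosages (0 = homozygous reference, 1 = heterozygote, 2 = homozygous
#' alternate, `NA` = missing call) together with per-sample metadata (species,
#' lake, experiment, parental/hybrid role) and per-locus annotation (scaffold,
#' position, alleles, which specialist the allele swept in, source of adaptive
#' variation, F_ST).
#'
#' @param calls integer matrix (samples x loci) with entries in \{0, 1, 2, NA\}.
#'   Row names, when present, must agree with `samples$sample_id`.
#' @param samples data frame with columns `sample_id`, `species`, `lake`,
#'   `experiment`, `role`; one row per row of `calls`. Missing columns are
#'   filled with permissive defaults.
#' @param loci data frame with columns `scaffold`, `position`, `ref`, `alt`,
#'   `swept_in`, `source`, `fst`; one row per column of `calls`.
#' @param depth optional numeric matrix of per-call sequencing depth, same
#'   dimensions as `calls` (used by [filter_sites()] mean-depth bounds).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples = NULL, loci = NULL, depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- default_sample_meta(rownames(calls), nrow(calls))
  if (is.null(loci)) loci <- default_locus_annotation(ncol(calls))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)

  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  if (nrow(samples) != nrow(calls))
    stop("samples metadata rows (", nrow(samples), ") != genotype rows (", nrow(calls), ")", call. = FALSE)
  if (nrow(loci) != ncol(calls))
    stop("locus annotation rows (", nrow(loci), ") != genotype columns (", ncol(calls), ")", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("sample_id values must be unique", call. = FALSE)
  if (anyDuplicated(paste(loci$scaffold, loci$position)))
    stop("(scaffold, position) pairs must be unique", call. = FALSE)
  if (any(loci$position < 1))
    stop("locus positions are 1-based and must be >= 1", call. = FALSE)
  check_level(samples$species, SPECIES_LEVELS, "species")
  check_level(samples$experiment, EXPERIMENT_LEVELS, "experiment")
  check_level(samples$role, ROLE_LEVELS, "role")
  check_level(loci$swept_in, SWEPT_LEVELS, "swept_in")
  check_level(loci$source, SOURCE_LEVELS, "source")
  if (any(samples$role == "hybrid" & samples$experiment == "none"))
    stop("hybrid samples must belong to an experiment", call. = FALSE)
  if (any(loci$source == "de_novo" & loci$swept_in != "scale_eater"))
    stop("de novo loci are only annotated for the scale-eater lineage", call. = FALSE)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(calls)))
      stop("depth matrix must match calls dimensions", call. = FALSE)
  }

  rownames(calls) <- samples$sample_id
  structure(
    list(calls = calls, samples = samples, loci = loci, depth = depth),
    class = "genotype_matrix"
  )
}

check_level <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad))
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

default_sample_meta <- function(ids, n) {
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(n))
  data.frame(
    sample_id = ids,
    species = rep("hybrid", n),
    lake = rep(NA_character_, n),
    experiment = rep("exp2011", n),
    role = rep("hybrid", n),
    stringsAsFactors = FALSE
  )
}

default_locus_annotation <- function(m) {
  data.frame(
    scaffold = rep("scaffold1", m),
    position = seq_len(m),
    ref = rep("A", m),
    alt = rep("T", m),
    swept_in = rep("none", m),
    source = rep("unknown", m),
    fst = rep(NA_real_, m),
    stringsAsFactors = FALSE
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "loci\n")
  cat("  species:", paste(sprintf("%s=%d", names(table(x$samples$species)),
                                  as.integer(table(x$samples$species))), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a [genotype_matrix()].
#' @param samples row selector (indices, logical, or sample ids).
#' @param loci column selector (indices or logical).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- seq_len(nrow(gm$calls))
  li <- seq_len(ncol(gm$calls))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples$sample_id) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)", call. = FALSE)
  }
  if (!is.null(loci)) li <- li[loci]
  genotype_matrix(
    gm$calls[si, li, drop = FALSE],
    samples = gm$samples[si, , drop = FALSE],
    loci = gm$loci[li, , drop = FALSE],
    depth = if (!is.null(gm$depth)) gm$depth[si, li, drop = FALSE]
  )
}

#' Combine two genotype matrices over the same loci
#'
#' Used to stack parental and hybrid cohorts that share a locus panel.
#'
#' @param a,b `genotype_matrix` objects with identical locus annotation.
#' @return A `genotype_matrix` with the rows of `a` followed by the rows of `b`.
#' @export
bind_genotypes <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  if (!identical(a$loci[c("scaffold", "position")], b$loci[c("scaffold", "position")]))
    stop("locus panels differ; cannot bind", call. = FALSE)
  depth <- NULL
  if (!is.null(a$depth) && !is.null(b$depth)) depth <- rbind(a$depth, b$depth)
  genotype_matrix(rbind(a$calls, b$calls),
                  samples = rbind(a$samples, b$samples),
                  loci = a$loci, depth = depth)
}
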