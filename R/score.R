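#' Reference metadata for the 32-SNP adult-BMI panel
#'
#' The fixed panel of 32 single nucleotide polymorphisms associated with
#' adult BMI in large GWAS, with effect (BMI-increasing) allele, non-effect
#' allele, published per-allele effect on adult BMI (kg/m^2) and the effect
#' allele frequency observed in each of the two reference cohorts.
#'
#' @return Data frame with one row per SNP: `chr`, `gene`, `snp`,
#'   `effect_allele`, `other_allele`, `gwas_effect`, `eaf_alspac`,
#'   `eaf_raine`.
#' @export
bmi_snp_panel <- function() {
  path <- system.file("extdata", "bmi_snp_panel.csv", package = "bmigrowth")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Dosage panel constructor
#'
#' Holds an individuals-by-SNPs matrix of effect-allele dosages (expected
#' allele counts from imputation, each in `[0, 2]`) together with per-SNP
#' metadata.  Missing dosages are replaced by the SNP-wise mean dosage (and
#' the count of imputed entries recorded), so that downstream allelic
#' scores keep their scale.
#'
#' @param dosages Numeric matrix, individuals in rows (rownames are
#'   individual ids), SNPs in columns (colnames are SNP ids).
#' @param snps Optional per-SNP metadata data frame with at least column
#'   `snp`; defaults to the packaged panel restricted to the dosage
#'   columns.
#' @return Object of class `dosage_panel`.
#' @export
dosage_panel <- function(dosages, snps = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- as.character(seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    stop("dosage matrix must have SNP ids as column names")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages outside [0, 2] found (range ",
         paste(signif(rng, 4), collapse = " to "), ")")
  n_imputed <- 0L
  if (anyNA(dosages)) {
    for (j in seq_len(ncol(dosages))) {
      miss <- is.na(dosages[, j])
      if (any(miss)) {
        dosages[miss, j] <- mean(dosages[, j], na.rm = TRUE)
        n_imputed <- n_imputed + sum(miss)
      }
    }
    message("dosage_panel: mean-imputed ", n_imputed, " missing dosages")
  }
  if (is.null(snps)) {
    ref <- bmi_snp_panel()
    snps <- ref[match(colnames(dosages), ref$snp), , drop = FALSE]
    snps$snp <- colnames(dosages)
  }
  stopifnot(nrow(snps) == ncol(dosages))
  structure(list(dosages = dosages, snps = snps, n_imputed = n_imputed),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat("Dosage panel:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs\n")
  cat("  mean dosage:", signif(mean(x$dosages), 4), "\n")
  invisible(x)
}

#' @export
dim.dosage_panel <- function(x) dim(x$dosages)

#' Allelic score from a dosage panel
#'
#' The unweighted allelic score of an individual is the sum of effect
#' allele dosages across the panel, so with 32 SNPs it lies in `[0, 64]`.
#' Supplying per-SNP weights (for instance the published adult-BMI effect
#' sizes) gives the weighted sensitivity score `sum_j w_j d_ij`.
#'
#' @param panel A [dosage_panel()].
#' @param weights `NULL` for the unweighted score, `"published"` for the
#'   packaged GWAS effect sizes, or a numeric vector with one weight per
#'   SNP in panel column order.
#' @return Named numeric vector of scores (names are individual ids), with
#'   attribute `weighted` flagging the variant.
#' @export
compute_allelic_score <- function(panel, weights = NULL) {
  stopifnot(inherits(panel, "dosage_panel"))
  weighted <- !is.null(weights)
  if (identical(weights, "published")) {
    weights <- panel$snps$gwas_effect
    if (anyNA(weights))
      stop("published weights unavailable for some panel SNPs")
  }
  if (is.null(weights)) weights <- rep(1, ncol(panel$dosages))
  if (length(weights) != ncol(panel$dosages))
    stop("need exactly one weight per SNP (",
         ncol(panel$dosages), "), got ", length(weights))
  score <- drop(panel$dosages %*% weights)
  names(score) <- rownames(panel$dosages)
  attr(score, "weighted") <- weighted
  score
}

#' Effect allele frequency
#'
#' Estimated as half the mean dosage per SNP.
#'
#' @param panel A [dosage_panel()].
#' @param snp Optional SNP id (or vector); default all panel SNPs.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
effect_allele_frequency <- function(panel, snp = NULL) {
  stopifnot(inherits(panel, "dosage_panel"), nrow(panel$dosages) >= 1)
  eaf <- colMeans(panel$dosages) / 2
  if (!is.null(snp)) {
    if (!all(snp %in% names(eaf))) stop("unknown SNP id(s)")
    eaf <- eaf[snp]
  }
  eaf
}

is_ambiguous_pair <- function(a, b) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(a) & !is.na(b) & comp[a] == b
}

#' Harmonise user-supplied dosages to the reference effect alleles
#'
#' Compares the panel's declared effect/other alleles against the packaged
#' reference.  Where the user's effect allele equals the reference
#' non-effect allele (and vice versa) the dosage is flipped to `2 - d`.
#' Strand-ambiguous A/T or C/G sites that do not match the reference
#' orientation raise an error, since a silent flip could not be
#' distinguished from a strand difference.  SNPs absent from the reference
#' are dropped with a warning.
#'
#' @param panel A [dosage_panel()] whose `snps` metadata carries
#'   `effect_allele` and `other_allele` as supplied by the user.
#' @param reference Reference metadata, default [bmi_snp_panel()].
#' @return A harmonised [dosage_panel()]; attribute `flipped` lists SNP ids
#'   whose dosages were flipped.
#' @export
harmonise_dosages <- function(panel, reference = bmi_snp_panel()) {
  stopifnot(inherits(panel, "dosage_panel"))
  ids <- panel$snps$snp
  m <- match(ids, reference$snp)
  if (anyNA(m)) {
    warning("dropping SNPs not in the reference panel: ",
            paste(ids[is.na(m)], collapse = ", "))
    keep <- !is.na(m)
    panel$dosages <- panel$dosages[, keep, drop = FALSE]
    panel$snps <- panel$snps[keep, , drop = FALSE]
    m <- m[keep]
  }
  ea <- toupper(panel$snps$effect_allele)
  oa <- toupper(panel$snps$other_allele)
  rea <- toupper(reference$effect_allele[m])
  roa <- toupper(reference$other_allele[m])
  same <- ea == rea & oa == roa
  flip <- ea == roa & oa == rea
  bad <- !(same | flip)
  if (any(bad))
    stop("allele labels incompatible with the reference for: ",
         paste(panel$snps$snp[bad], collapse = ", "))
  ambiguous <- is_ambiguous_pair(ea, oa)
  if (any(flip & ambiguous))
    stop("refusing to flip strand-ambiguous (A/T or C/G) SNPs: ",
         paste(panel$snps$snp[flip & ambiguous], collapse = ", "))
  if (any(flip)) {
    panel$dosages[, flip] <- 2 - panel$dosages[, flip]
    panel$snps$effect_allele[flip] <- rea[flip]
    panel$snps$other_allele[flip] <- roa[flip]
  }
  attr(panel, "flipped") <- panel$snps$snp[flip]
  panel
}
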