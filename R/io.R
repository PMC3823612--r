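## Delimited I/O for the pipeline's tabular formats.  Comma-separated with
## header is the default dialect; tab is accepted via `sep`.  Missing
## values are the empty field or "NA" on read and written back as "NA".

read_delim_checked <- function(path, required, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         na.strings = c("", "NA"), stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  d
}

write_delim_na <- function(d, path, sep = ",") {
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a long-format growth table
#'
#' Expected columns: `individual_id`, `sex` (`female`/`male`), `age`
#' (years), `measure` (`bmi`, `weight` or `height`), `value`, and
#' optionally `source` (`clinic`/`parental_report`) and `cohort_id`.  Rows
#' whose age or value cannot be parsed as a positive number (age zero is
#' allowed for birth weight/length records) are dropped with a message.
#'
#' @param path File path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return Data frame of typed growth records; attribute `n_dropped`
#'   counts removed rows.
#' @export
read_growth_table <- function(path, sep = ",") {
  d <- read_delim_checked(path, c("individual_id", "sex", "age",
                                  "measure", "value"), sep)
  if (is.null(d$source)) d$source <- "clinic"
  if (is.null(d$cohort_id)) d$cohort_id <- "cohort1"
  d$age <- suppressWarnings(as.numeric(d$age))
  d$value <- suppressWarnings(as.numeric(d$value))
  ok_age <- !is.na(d$age) &
    (d$age > 0 | (d$age == 0 & d$measure %in% c("weight", "height")))
  ok <- ok_age & !is.na(d$value) & d$value > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("read_growth_table: dropped ", n_dropped,
            " rows with unparseable or non-positive age/value")
  d <- d[ok, , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "n_dropped") <- n_dropped
  d
}

#' Read a per-individual covariate table
#'
#' Expected columns: `individual_id`, `sex`, and optionally `birth_weight`
#' (kg), `birth_length` (cm), `gestational_age` (weeks), ancestry principal
#' components `pc1`, `pc2`, ... and `cohort_id`.  Gestational ages outside
#' (20, 46) weeks are set to missing with a message.
#'
#' @inheritParams read_growth_table
#' @return Data frame, one row per individual.
#' @export
read_individual_table <- function(path, sep = ",") {
  d <- read_delim_checked(path, c("individual_id", "sex"), sep)
  if (!is.null(d$gestational_age)) {
    d$gestational_age <- suppressWarnings(as.numeric(d$gestational_age))
    bad <- !is.na(d$gestational_age) &
      (d$gestational_age <= 20 | d$gestational_age >= 46)
    if (any(bad)) {
      message("read_individual_table: ", sum(bad),
              " gestational ages outside (20, 46) weeks set to missing")
      d$gestational_age[bad] <- NA_real_
    }
  }
  d
}

#' Read a dosage panel from a delimited table or a VCF with DS genotypes
#'
#' The table format has individuals in rows: an `individual_id` column plus
#' one numeric column per SNP (dosage of the effect allele, in `[0, 2]`).
#' The `vcf_ds` format reads a VCF whose genotype FORMAT includes the `DS`
#' (posterior mean dosage) field, one site per panel SNP; the VCF `ID`
#' column supplies SNP ids and REF/ALT are taken as other/effect allele.
#'
#' @param path File path.
#' @param format `"table"` or `"vcf_ds"`.
#' @param sep Field separator for the table format.
#' @return A [dosage_panel()].
#' @export
read_dosage_panel <- function(path, format = c("table", "vcf_ds"),
                              sep = ",") {
  format <- match.arg(format)
  if (format == "table") {
    d <- read_delim_checked(path, "individual_id", sep)
    ids <- as.character(d$individual_id)
    mat <- as.matrix(d[setdiff(names(d), c("individual_id", "cohort_id"))])
    storage.mode(mat) <- "double"
    rownames(mat) <- ids
    return(dosage_panel(mat))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF dosages requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  snp_ids <- fix[, "ID"]
  mat <- t(ds)
  colnames(mat) <- snp_ids
  snps <- data.frame(snp = snp_ids,
                     effect_allele = fix[, "ALT"],
                     other_allele = fix[, "REF"],
                     stringsAsFactors = FALSE)
  ref <- bmi_snp_panel()
  m <- match(snp_ids, ref$snp)
  snps$gwas_effect <- ref$gwas_effect[m]
  snps$gene <- ref$gene[m]
  dosage_panel(mat, snps)
}

#' Write a dosage panel as a delimited table
#'
#' @param panel A [dosage_panel()].
#' @param path Output path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_dosage_panel <- function(panel, path, sep = ",") {
  d <- data.frame(individual_id = rownames(panel$dosages),
                  panel$dosages, check.names = FALSE)
  write_delim_na(d, path, sep)
}

#' Write a growth table
#'
#' @param growth Growth data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_growth_table <- function(growth, path, sep = ",") {
  write_delim_na(growth, path, sep)
}

#' Write association / meta-analysis results
#'
#' Writes a results table with the fixed leading column order `term`,
#' `beta`, `se`, `p`, `n`, `cohort`; any further columns follow.  An empty
#' results object produces a header-only file with a warning.
#'
#' @param results Data frame of results rows.
#' @param path Output path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_results_table <- function(results, path, sep = ",") {
  lead <- c("term", "beta", "se", "p", "n", "cohort")
  for (cn in setdiff(lead, names(results))) results[[cn]] <- NA
  results <- results[c(lead, setdiff(names(results), lead))]
  if (nrow(results) == 0L)
    warning("writing empty results table (header only): ", path)
  write_delim_na(results, path, sep)
}

#' Read back a results table written by [write_results_table()]
#'
#' @inheritParams read_growth_table
#' @return Data frame of results rows.
#' @export
read_results_table <- function(path, sep = ",") {
  read_delim_checked(path, c("term", "beta", "se", "p", "n", "cohort"), sep)
}

#' Default run configuration
#'
#' A plain list describing one pipeline run: per-measure spline settings,
#' QC thresholds, age bins, random-effect columns, per-cohort covariates,
#' meta-analysis policy and the seed.  Serialised to/from YAML by
#' [write_run_config()] and [read_run_config()].
#'
#' @param seed Non-negative integer seed.
#' @return Named list.
#' @export
default_run_config <- function(seed = 1L) {
  stopifnot(length(seed) == 1L, seed >= 0, seed == round(seed))
  list(
    seed = as.integer(seed),
    qc = list(sd_threshold = 4,
              age_breaks = c(1, 1.5, seq(2.5, 16.5, 1), 17.5)),
    spline = list(center = 8, knots = c(2, 8, 12)),
    random_effects = list(bmi = c("const", "age_c", "age_c2", "tp2_3"),
                          weight = c("const", "age_c", "tp2_2"),
                          infancy = c("const", "age_c", "age_c2")),
    covariates = list(alspac = "source01",
                      raine = c("pc1", "pc2", "pc3", "pc4", "pc5")),
    meta = list(fwer = 0.05, n_tests = 32L),
    final_bmi_window = c(15, 17.5)
  )
}

#' @rdname default_run_config
#' @param config Configuration list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop("run config must carry a non-negative integer seed")
  cfg
}
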