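panel_from <- function(mat, ids = NULL) {
  ref <- bmi_snp_panel()
  colnames(mat) <- ref$snp[seq_len(ncol(mat))]
  if (!is.null(ids)) rownames(mat) <- ids
  dosage_panel(mat)
}

test_that("unweighted score is the row sum of dosages", {
  p0 <- panel_from(matrix(0, 2, 32))
  expect_equal(as.numeric(compute_allelic_score(p0)), c(0, 0))
  p1 <- panel_from(matrix(1, 3, 32))
  expect_equal(as.numeric(compute_allelic_score(p1)), c(32, 32, 32))
  expect_false(attr(compute_allelic_score(p1), "weighted"))
})

test_that("published weights reproduce the per-SNP GWAS effects", {
  ## a homozygous carrier at the first panel SNP (NEGR1, effect 0.13) only
  m <- matrix(0, 1, 32)
  m[1, 1] <- 2
  p <- panel_from(m)
  s <- compute_allelic_score(p, weights = "published")
  expect_equal(as.numeric(s), 2 * 0.13)
  expect_true(attr(s, "weighted"))
  ## all-ones weights equal the unweighted score
  expect_equal(as.numeric(compute_allelic_score(p, weights = rep(1, 32))),
               as.numeric(compute_allelic_score(p)))
})

test_that("dosage range and weight length are enforced", {
  m <- matrix(1, 2, 32)
  m[1, 5] <- 2.3
  expect_error(panel_from(m), "outside")
  expect_error(compute_allelic_score(panel_from(matrix(1, 2, 32)),
                                     weights = rep(1, 31)),
               "one weight per SNP")
})

test_that("missing dosages are mean-imputed per SNP", {
  m <- matrix(1, 4, 32)
  m[1, 2] <- NA; m[3, 2] <- 0
  p <- suppressMessages(panel_from(m))
  expect_equal(p$n_imputed, 1L)
  expect_equal(unname(p$dosages[1, 2]), mean(c(1, 0, 1)))
})

test_that("score is linear under row concatenation", {
  set.seed(3)
  a <- matrix(stats::runif(5 * 32, 0, 2), 5, 32)
  b <- matrix(stats::runif(3 * 32, 0, 2), 3, 32)
  sa <- compute_allelic_score(panel_from(a, ids = paste0("a", 1:5)))
  sab <- compute_allelic_score(panel_from(rbind(a, b),
                                          ids = c(paste0("a", 1:5),
                                                  paste0("b", 1:3))))
  expect_equal(as.numeric(sab[1:5]), as.numeric(sa))
})

test_that("effect allele frequency is half the mean dosage", {
  m <- matrix(1, 3, 32)
  m[, 1] <- c(0, 1, 2)
  m[, 2] <- 2
  p <- panel_from(m)
  eaf <- effect_allele_frequency(p)
  expect_equal(unname(eaf[1]), 0.5)
  expect_equal(unname(eaf[2]), 1.0)
  expect_error(effect_allele_frequency(p, "rs0"), "unknown SNP")
})

test_that("simulated FTO frequency matches its target within 3 binomial SEs", {
  params <- simulation_params("alspac", n = 10000, seed = 5)
  panel <- simulate_genotypes(params)
  target <- bmi_snp_panel()$eaf_alspac[bmi_snp_panel()$snp == "rs9939609"]
  est <- effect_allele_frequency(panel, "rs9939609")
  se <- sqrt(target * (1 - target) / (2 * 10000))
  expect_lt(abs(est - target), 3 * se + 0.003) # small slack for dosage noise
})

test_that("allele harmonisation flips mismatched labels and refuses A/T-C/G", {
  ref <- bmi_snp_panel()
  m <- matrix(0.5, 2, 32)
  colnames(m) <- ref$snp
  rownames(m) <- c("i1", "i2")
  snps <- ref
  ## swap alleles at a non-ambiguous SNP (NEGR1 A/G): dosage must flip
  snps$effect_allele[1] <- ref$other_allele[1]
  snps$other_allele[1] <- ref$effect_allele[1]
  p <- dosage_panel(m, snps)
  h <- harmonise_dosages(p)
  expect_equal(unname(h$dosages[, 1]), c(1.5, 1.5))
  expect_equal(unname(h$dosages[, 2]), c(0.5, 0.5))
  expect_equal(attr(h, "flipped"), ref$snp[1])
  ## FTO is A/T: a swap there is strand-ambiguous and must error
  snps2 <- ref
  k <- which(ref$snp == "rs9939609")
  snps2$effect_allele[k] <- ref$other_allele[k]
  snps2$other_allele[k] <- ref$effect_allele[k]
  expect_error(harmonise_dosages(dosage_panel(m, snps2)), "ambiguous")
  ## unknown SNPs are dropped with a warning
  snps3 <- ref
  snps3$snp[2] <- "rs000000"
  colnames(m)[2] <- "rs000000"
  expect_warning(h3 <- harmonise_dosages(dosage_panel(m, snps3)),
                 "not in the reference")
  expect_equal(ncol(h3$dosages), 31)
})
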