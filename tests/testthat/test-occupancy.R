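# Helper: build an expression_matrix directly from a TPM-scale matrix so
# occupancy arithmetic can be checked against hand values.
make_em <- function(values, sheet) {
  structure(list(values = values,
                 spike = setNames(rep(FALSE, nrow(values)), rownames(values)),
                 normalized = TRUE, sheet = sheet),
            class = "expression_matrix")
}

two_geno_sheet <- function(n_rep = 2, genotypes = c("WT", "CompoundHet")) {
  sheet <- expand.grid(replicate = seq_len(n_rep),
                       fraction = c("total", "mRNP", "polysome"),
                       genotype = genotypes, stringsAsFactors = FALSE)[, 3:1]
  sheet$sample_id <- with(sheet, paste(genotype, fraction, replicate, sep = "_"))
  sheet[, c("sample_id", "genotype", "fraction", "replicate")]
}

test_that("the expression filter requires TPM above threshold in every total replicate of one genotype", {
  sheet <- two_geno_sheet()
  vals <- matrix(1, nrow = 3, ncol = nrow(sheet),
                 dimnames = list(c("gA", "gB", "gC"), sheet$sample_id))
  # gA: WT totals (6, 7) -> retained; gB: (4, 6) everywhere -> dropped;
  # gC: exactly (5, 5) -> dropped (strict inequality)
  vals["gA", c("WT_total_1", "WT_total_2")] <- c(6, 7)
  vals["gB", sheet$sample_id[sheet$fraction == "total"]] <- c(4, 6, 4, 6)
  vals["gC", sheet$sample_id[sheet$fraction == "total"]] <- 5
  em <- make_em(vals, sheet)
  expect_identical(filter_expressed(em), "gA")
  expect_error(filter_expressed(em, threshold = -1), class = "fracseq_config_error")
})

test_that("occupancy is the within-individual fraction/total TPM ratio with floors", {
  sheet <- two_geno_sheet(n_rep = 2)
  vals <- matrix(60, nrow = 2, ncol = nrow(sheet),
                 dimnames = list(c("gA", "gB"), sheet$sample_id))
  vals["gA", "WT_mRNP_1"] <- 30
  vals["gA", "WT_polysome_1"] <- 45
  vals["gB", "WT_total_1"] <- 0.5   # below the 1-TPM floor
  em <- make_em(vals, sheet)
  occ <- compute_occupancy(em)
  r <- occ$replicates
  expect_equal(r$occ_mRNP[r$gene_id == "gA" & r$genotype == "WT" & r$replicate == 1], 0.5)
  expect_equal(r$occ_polysome[r$gene_id == "gA" & r$genotype == "WT" & r$replicate == 1], 0.75)
  expect_true(is.na(r$occ_mRNP[r$gene_id == "gB" & r$genotype == "WT" & r$replicate == 1]))

  # multiplying one individual's libraries by a constant leaves occupancy unchanged
  vals2 <- vals
  ind_cols <- c("WT_total_1", "WT_mRNP_1", "WT_polysome_1")
  vals2[, ind_cols] <- vals2[, ind_cols] * 3
  occ2 <- compute_occupancy(make_em(vals2, sheet))
  gA1 <- occ$replicates$gene_id == "gA"
  expect_equal(occ2$replicates$occ_mRNP[gA1], occ$replicates$occ_mRNP[gA1])
  expect_equal(occ2$replicates$ratio[gA1], occ$replicates$ratio[gA1])

  # genotype means need >= 2 defined replicate values
  gB_wt <- subset(occ$genotype, gene_id == "gB" & genotype == "WT")
  expect_true(is.na(gB_wt$occ_mRNP))

  # missing matched library is a structural error naming the individual
  sheet_miss <- sheet[sheet$sample_id != "WT_polysome_2", ]
  expect_error(compute_occupancy(make_em(vals[, sheet_miss$sample_id], sheet_miss)),
               "WT.*2|2.*WT", class = "fracseq_structural_error")
})

test_that("occupancy t-test matches a hand-computed pooled t and handles degenerate groups", {
  sheet <- two_geno_sheet(n_rep = 3)
  build_occ <- function(mut_occ, wt_occ) {
    vals <- matrix(100, nrow = 1, ncol = nrow(sheet),
                   dimnames = list("gA", sheet$sample_id))
    for (i in 1:3) {
      vals["gA", paste0("WT_mRNP_", i)] <- 100 * wt_occ[i]
      vals["gA", paste0("CompoundHet_mRNP_", i)] <- 100 * mut_occ[i]
    }
    compute_occupancy(make_em(vals, sheet))
  }
  # hand-computed: pooled sd^2 = 0.01, t = -0.3/(0.1*sqrt(2/3)) = -3.674, df = 4
  tt <- occupancy_test(build_occ(c(0.4, 0.5, 0.6), c(0.7, 0.8, 0.9)), "CompoundHet", "mRNP")
  expect_equal(tt$statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0213, tolerance = 1e-3)

  # identical groups: t = 0, p = 1
  tt0 <- occupancy_test(build_occ(c(0.2, 0.25, 0.2), c(0.2, 0.25, 0.2)),
                        "CompoundHet", "mRNP")
  expect_equal(tt0$p, 1)

  # zero variance both groups: equal means p = 1; unequal means sentinel p = 0
  ttz <- occupancy_test(build_occ(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3)),
                        "CompoundHet", "mRNP")
  expect_equal(ttz$p, 1)
  expect_identical(ttz$flag, "zero_variance")
  ttz2 <- occupancy_test(build_occ(c(0.3, 0.3, 0.3), c(0.5, 0.5, 0.5)),
                         "CompoundHet", "mRNP")
  expect_equal(ttz2$p, 0)
  expect_identical(ttz2$flag, "zero_variance")

  # fewer than 2 defined values in a group -> NA with a reason
  sheet2 <- two_geno_sheet(n_rep = 2)
  vals <- matrix(100, nrow = 1, ncol = nrow(sheet2),
                 dimnames = list("gA", sheet2$sample_id))
  vals["gA", "WT_total_2"] <- 0.1  # below floor -> one WT occupancy NA
  ttn <- occupancy_test(compute_occupancy(make_em(vals, sheet2)), "CompoundHet", "mRNP")
  expect_true(is.na(ttn$p))
  expect_identical(ttn$flag, "insufficient_replicates")
})

test_that("high-confidence calls require p < alpha in both fractions", {
  p_m <- c(gA = 0.01, gB = 0.01, gC = 0.2)
  p_p <- c(gA = 0.03, gB = 0.30, gC = 0.01)
  tg <- high_confidence_targets(p_m, p_p)
  expect_identical(tg$high_confidence, c(TRUE, FALSE, FALSE))
  expect_identical(tg$significant_mRNP, c(TRUE, TRUE, FALSE))

  expect_equal(nrow(high_confidence_targets(setNames(numeric(), character()),
                                            setNames(numeric(), character()))), 0)
  expect_error(high_confidence_targets(p_m, p_p[1:2]),
               class = "fracseq_structural_error")
})

test_that("polysome:mRNP ratios aggregate per individual and equal the TPM ratio", {
  sheet <- two_geno_sheet(n_rep = 2)
  vals <- matrix(100, nrow = 1, ncol = nrow(sheet),
                 dimnames = list("gA", sheet$sample_id))
  vals["gA", "WT_mRNP_1"] <- 30;  vals["gA", "WT_polysome_1"] <- 60   # ratio 2
  vals["gA", "WT_mRNP_2"] <- 25;  vals["gA", "WT_polysome_2"] <- 100  # ratio 4
  occ <- compute_occupancy(make_em(vals, sheet))
  r <- occ$replicates
  expect_equal(r$ratio[r$genotype == "WT"], c(2, 4))
  rg <- polysome_mrnp_ratio(occ)
  expect_equal(rg$ratio[rg$genotype == "WT"], 3)

  # ratio identity: occupancy ratio equals TPM_poly / TPM_mRNP (total cancels)
  expect_equal(r$ratio[r$genotype == "WT"],
               c(60 / 30, 100 / 25), tolerance = 1e-12)

  # mRNP occupancy below the ratio floor gives NA
  vals["gA", "WT_mRNP_1"] <- 0
  occ0 <- compute_occupancy(make_em(vals, sheet))
  expect_true(is.na(occ0$replicates$ratio[1]))

  # the alternative aggregation (ratio of genotype means) is available
  occ_m <- compute_occupancy(make_em(vals, sheet), ratio_method = "of_means")
  expect_identical(occ_m$ratio_method, "of_means")
})

test_that("direction summary reports the fraction of targets translated more in the mutant", {
  tg <- high_confidence_targets(c(gA = 0.01, gB = 0.01), c(gA = 0.01, gB = 0.01))
  ratios <- data.frame(gene_id = rep(c("gA", "gB"), 2),
                       genotype = rep(c("WT", "CompoundHet"), each = 2),
                       ratio = c(1, 1, 2, 0.5))
  ds <- direction_summary(tg, ratios)
  expect_equal(ds$fraction, 0.5)
  expect_equal(ds$n_targets, 2)

  ratios$ratio <- c(1, 1, 2, 3)
  expect_equal(direction_summary(tg, ratios)$fraction, 1)

  tg0 <- high_confidence_targets(c(gA = 0.5), c(gA = 0.5))
  expect_message(ds0 <- direction_summary(tg0, ratios), "empty")
  expect_true(is.na(ds0$fraction))
})

test_that("the simplified total-RNA differential stage follows its formula", {
  sheet <- two_geno_sheet(n_rep = 2)
  vals <- matrix(100, nrow = 2, ncol = nrow(sheet),
                 dimnames = list(c("gA", "gB"), sheet$sample_id))
  tot_mut <- sheet$sample_id[sheet$fraction == "total" & sheet$genotype == "CompoundHet"]
  vals["gA", tot_mut] <- 200
  de <- differential_total(make_em(vals, sheet), genotype = "CompoundHet")
  # means 200 vs 100, pseudocount 1: LFC = log2(201/101)
  expect_equal(de$lfc[de$gene_id == "gA"], log2(201 / 101), tolerance = 1e-12)
  # identical groups: LFC 0, p 1
  expect_equal(de$lfc[de$gene_id == "gB"], 0)
  expect_equal(de$p[de$gene_id == "gB"], 1)
  expect_true(all(de$q >= de$p, na.rm = TRUE))
})

test_that("equal-abundance genes show near-zero median LFC in simulation", {
  cfg <- sim_config(n_genes = 400, genotypes = c("WT", "CompoundHet"),
                    n_replicates = 2, depth = 1e6, planted_fraction = 0.1,
                    seed = 17)
  an <- run_small_analysis(cfg)
  de <- differential_total(an$tpm, genotype = "CompoundHet", genes = an$genes)
  # planted effects move occupancy, not total abundance
  expect_lt(abs(median(de$lfc)), 0.1)
})

test_that("stronger derepression strictly increases the estimated mutant ratio of planted genes", {
  mean_ratio <- function(k) {
    cfg <- sim_config(n_genes = 400, genotypes = c("WT", "CompoundHet"),
                      n_replicates = 3, depth = 2e6, planted_fraction = 0.2,
                      effect_size = k, seed = 23)
    an <- run_small_analysis(cfg)
    rg <- polysome_mrnp_ratio(an$occ)
    planted <- intersect(an$sim$truth$planted_ids, an$genes)
    mean(rg$ratio[rg$genotype == "CompoundHet" & rg$gene_id %in% planted], na.rm = TRUE)
  }
  ratios <- vapply(c(1.5, 2, 3), mean_ratio, 0)
  expect_true(all(diff(ratios) > 0))
})
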