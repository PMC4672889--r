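# Occupancy statistics: expression filter, per-individual fraction/total
# occupancies, genotype t-tests, high-confidence target calling,
# polysome:mRNP ratios and a simplified total-RNA differential stage.
# An "individual" is a (genotype, replicate) pair: its total, mRNP and
# polysome libraries come from the same animal, so occupancy is always a
# within-individual ratio.

genotype_individuals <- function(sheet) {
  unique(sheet[, c("genotype", "replicate")])
}

sample_for <- function(sheet, genotype, fraction, replicate) {
  id <- sheet$sample_id[sheet$genotype == genotype &
                        sheet$fraction == fraction &
                        sheet$replicate == replicate]
  if (length(id) != 1)
    fs_stop(sprintf("individual %s replicate %d lacks a unique %s library",
                    genotype, replicate, fraction), "structural")
  id
}

#' Expression filter on total-RNA TPM
#'
#' A gene is retained iff, in at least one genotype, its TPM exceeds the
#' threshold (strictly) in every total-fraction replicate of that genotype.
#' Spike-in rows are never retained.
#'
#' @param tpm an `expression_matrix`.
#' @param sheet sample sheet (defaults to the one stored in `tpm`).
#' @param threshold TPM threshold, strict inequality (default 5).
#' @return character vector of retained gene IDs.
#' @export
filter_expressed <- function(tpm, sheet = tpm$sheet, threshold = 5) {
  if (threshold < 0) fs_stop("threshold must be >= 0", "config")
  tot <- sheet[sheet$fraction == "total", ]
  if (!nrow(tot)) fs_stop("no total-fraction samples", "structural")
  keep <- rep(FALSE, nrow(tpm$values))
  for (g in unique(tot$genotype)) {
    cols <- tot$sample_id[tot$genotype == g]
    keep <- keep | apply(tpm$values[, cols, drop = FALSE] > threshold, 1, all)
  }
  rownames(tpm$values)[keep & !tpm$spike]
}

#' Per-individual occupancy table
#'
#' Occupancy of gene g in fraction F for one individual is
#' `TPM_F(g) / TPM_total(g)`, i.e. the fraction signal normalized by total
#' expression within that individual before any averaging across a
#' genotype. Occupancy is NA when the individual's total TPM is below
#' `total_floor`; the per-individual polysome:mRNP ratio is NA when the
#' mRNP occupancy is below `ratio_floor`. Genotype means are taken over
#' replicates, ignoring NA only when at least two values are defined
#' (otherwise NA).
#'
#' @param tpm an `expression_matrix`.
#' @param sheet sample sheet (defaults to the one stored in `tpm`).
#' @param genes gene IDs to tabulate (default: all non-spike rows).
#' @param total_floor minimum total TPM for a defined occupancy (default 1).
#' @param ratio_floor minimum mRNP occupancy for a defined ratio
#'   (default 1e-3).
#' @param ratio_method `"per_individual"` (ratio per individual, then mean;
#'   default) or `"of_means"` (ratio of genotype-mean occupancies).
#' @return An `occupancy_table`: list with `replicates` (gene, genotype,
#'   replicate, occ_mRNP, occ_polysome, ratio) and `genotype` (genotype
#'   means of the same quantities).
#' @export
compute_occupancy <- function(tpm, sheet = tpm$sheet, genes = NULL,
                              total_floor = 1, ratio_floor = 1e-3,
                              ratio_method = c("per_individual", "of_means")) {
  ratio_method <- match.arg(ratio_method)
  if (is.null(genes)) genes <- rownames(tpm$values)[!tpm$spike]
  miss <- setdiff(genes, rownames(tpm$values))
  if (length(miss)) fs_stop("genes absent from expression matrix", "structural")
  ind <- genotype_individuals(sheet)
  reps <- vector("list", nrow(ind))
  for (i in seq_len(nrow(ind))) {
    G <- ind$genotype[i]; r <- ind$replicate[i]
    v_t <- tpm$values[genes, sample_for(sheet, G, "total", r)]
    v_m <- tpm$values[genes, sample_for(sheet, G, "mRNP", r)]
    v_p <- tpm$values[genes, sample_for(sheet, G, "polysome", r)]
    ok <- v_t >= total_floor
    occ_m <- ifelse(ok, v_m / v_t, NA_real_)
    occ_p <- ifelse(ok, v_p / v_t, NA_real_)
    ratio <- ifelse(!is.na(occ_m) & occ_m >= ratio_floor, occ_p / occ_m, NA_real_)
    reps[[i]] <- data.frame(gene_id = genes, genotype = G, replicate = r,
                            occ_mRNP = occ_m, occ_polysome = occ_p,
                            ratio = ratio, row.names = NULL)
  }
  repdf <- do.call(rbind, reps)

  mean2 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2) mean(x) else NA_real_
  }
  key <- list(gene_id = repdf$gene_id, genotype = repdf$genotype)
  gt <- aggregate(repdf[, c("occ_mRNP", "occ_polysome", "ratio")], key, mean2)
  if (ratio_method == "of_means")
    gt$ratio <- ifelse(!is.na(gt$occ_mRNP) & gt$occ_mRNP >= ratio_floor,
                       gt$occ_polysome / gt$occ_mRNP, NA_real_)
  gt <- gt[order(gt$gene_id, match(gt$genotype, GENOTYPE_LEVELS)), ]
  rownames(gt) <- NULL
  structure(list(replicates = repdf, genotype = gt,
                 total_floor = total_floor, ratio_floor = ratio_floor,
                 ratio_method = ratio_method),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("occupancy_table:", length(unique(x$replicates$gene_id)), "genes,",
      length(unique(x$replicates$genotype)), "genotypes,",
      "ratio method:", x$ratio_method, "\n")
  invisible(x)
}

# two-sample t with deterministic handling of degenerate inputs:
# both groups zero-variance -> p = 1 if means equal, else sentinel p = 0
pooled_t <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                flag = "insufficient_replicates", n1 = length(x), n2 = length(y)))
  if (sd(x) == 0 && sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2,
                p = if (eq) 1 else 0,
                flag = "zero_variance", n1 = length(x), n2 = length(y)))
  }
  tt <- t.test(x, y, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, flag = "", n1 = length(x), n2 = length(y))
}

#' Per-gene occupancy t-test for one genotype and fraction
#'
#' Two-sided two-sample t-test of mutant versus wildtype per-individual
#' occupancies. The default is the pooled-variance Student's t
#' (df = n1 + n2 - 2), which is stable at the study's N = 2; Welch's
#' t is available behind `welch`. Genes with fewer than two defined
#' occupancies in either group get NA with a flag; zero variance in both
#' groups gives p = 1 (equal means) or a flagged p = 0 sentinel.
#'
#' @param tab an `occupancy_table`.
#' @param genotype mutant genotype to compare against `ref`.
#' @param fraction `"mRNP"` or `"polysome"`.
#' @param ref reference genotype (default WT).
#' @param welch use Welch's t instead of pooled variance.
#' @return data.frame: gene_id, statistic, df, p, flag.
#' @export
occupancy_test <- function(tab, genotype, fraction = c("mRNP", "polysome"),
                           ref = "WT", welch = FALSE) {
  fraction <- match.arg(fraction)
  col <- paste0("occ_", fraction)
  rd <- tab$replicates
  genes <- unique(rd$gene_id)
  mut <- rd[rd$genotype == genotype, ]
  wt <- rd[rd$genotype == ref, ]
  if (!nrow(mut) || !nrow(wt))
    fs_stop("genotype absent from occupancy table", "structural")
  xs <- split(mut[[col]], factor(mut$gene_id, levels = genes))
  ys <- split(wt[[col]], factor(wt$gene_id, levels = genes))
  out <- mapply(function(x, y) pooled_t(x, y, welch), xs, ys, SIMPLIFY = FALSE)
  data.frame(gene_id = genes,
             statistic = vapply(out, `[[`, 0, "statistic"),
             df = vapply(out, `[[`, 0, "df"),
             p = vapply(out, `[[`, 0, "p"),
             flag = vapply(out, `[[`, "", "flag"),
             row.names = NULL)
}

#' Occupancy tests for all mutant genotypes and both fractions
#'
#' Runs [occupancy_test()] per (genotype, fraction) and appends
#' Benjamini-Hochberg q-values within each (genotype, fraction) family.
#' Target calling in this design uses the raw p at 0.05 (as in the
#' two-replicate study design); q is reported alongside.
#'
#' @inheritParams occupancy_test
#' @param genotypes mutant genotypes (default: all non-reference genotypes
#'   present).
#' @return data.frame: gene_id, genotype, fraction, statistic, df, p, q,
#'   flag.
#' @export
occupancy_tests <- function(tab, genotypes = NULL, ref = "WT", welch = FALSE) {
  present <- unique(tab$replicates$genotype)
  genotypes <- genotypes %||% setdiff(present, ref)
  out <- list()
  for (G in genotypes) for (F in c("mRNP", "polysome")) {
    tt <- occupancy_test(tab, G, F, ref = ref, welch = welch)
    tt$genotype <- G; tt$fraction <- F
    tt$q <- bh_qvalues(tt$p)
    out[[paste(G, F)]] <- tt
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("gene_id", "genotype", "fraction", "statistic", "df", "p", "q", "flag")]
}

#' Call high-confidence derepression targets
#'
#' A gene is a high-confidence target iff its occupancy differs from
#' wildtype at `p < alpha` in both the mRNP and the polysome fraction. The
#' direction flag (mutant polysome:mRNP ratio above wildtype) is recorded
#' post hoc and never used for inclusion.
#'
#' @param p_mRNP,p_polysome named per-gene p-value vectors over the same
#'   gene universe.
#' @param alpha raw p-value threshold (default 0.05, strict).
#' @param ratios optional genotype-level ratio table from
#'   [polysome_mrnp_ratio()] used for the direction flag.
#' @param mutant,ref genotypes compared in the direction flag.
#' @return data.frame (class `target_calls`): gene_id, significant_mRNP,
#'   significant_polysome, high_confidence, direction_consistent.
#' @export
high_confidence_targets <- function(p_mRNP, p_polysome, alpha = 0.05,
                                    ratios = NULL, mutant = "CompoundHet",
                                    ref = "WT") {
  if (!setequal(names(p_mRNP), names(p_polysome)))
    fs_stop("mRNP and polysome p-value maps cover different gene universes",
            "structural")
  genes <- names(p_mRNP)
  p_polysome <- p_polysome[genes]
  sig_m <- !is.na(p_mRNP) & p_mRNP < alpha
  sig_p <- !is.na(p_polysome) & p_polysome < alpha
  dirc <- rep(NA, length(genes))
  r_mut <- r_ref <- rep(NA_real_, length(genes))
  if (!is.null(ratios)) {
    rm_ <- ratios[ratios$genotype == mutant, ]
    rr_ <- ratios[ratios$genotype == ref, ]
    r_mut <- rm_$ratio[match(genes, rm_$gene_id)]
    r_ref <- rr_$ratio[match(genes, rr_$gene_id)]
    dirc <- r_mut > r_ref
  }
  out <- data.frame(gene_id = genes,
                    significant_mRNP = unname(sig_m),
                    significant_polysome = unname(sig_p),
                    high_confidence = unname(sig_m & sig_p),
                    direction_consistent = unname(dirc),
                    ratio_mutant = unname(r_mut), ratio_ref = unname(r_ref),
                    row.names = NULL)
  class(out) <- c("target_calls", "data.frame")
  out
}

#' @export
print.target_calls <- function(x, ...) {
  cat("target_calls:", nrow(x), "genes;",
      sum(x$high_confidence), "high-confidence targets\n")
  invisible(x)
}

#' Genotype-level polysome:mRNP ratios
#'
#' The per-individual ratio `occ_polysome / occ_mRNP` equals
#' `TPM_polysome / TPM_mRNP` (the total cancels) and indexes translational
#' activity: higher means more of the transcript pool is ribosome-engaged.
#' The genotype value aggregates per-individual ratios as configured in
#' [compute_occupancy()].
#'
#' @param tab an `occupancy_table`.
#' @return data.frame: gene_id, genotype, ratio (genotype-level).
#' @export
polysome_mrnp_ratio <- function(tab) {
  tab$genotype[, c("gene_id", "genotype", "ratio")]
}

#' Fraction of high-confidence targets with increased translation
#'
#' Among high-confidence targets, the fraction whose mutant polysome:mRNP
#' ratio exceeds the wildtype ratio. In a pure loss-of-repression scenario
#' this fraction is 1 ("invariably greater").
#'
#' @param targets a `target_calls` table.
#' @param ratios genotype-level ratio table from [polysome_mrnp_ratio()].
#' @param mutant,ref genotypes compared.
#' @return list with `fraction` (NA for an empty target set), `n_targets`,
#'   `per_gene` (gene_id, greater).
#' @export
direction_summary <- function(targets, ratios, mutant = "CompoundHet", ref = "WT") {
  hc <- targets$gene_id[targets$high_confidence]
  if (!length(hc)) {
    message("direction_summary: empty high-confidence target set")
    return(list(fraction = NA_real_, n_targets = 0L,
                per_gene = data.frame(gene_id = character(), greater = logical())))
  }
  rm_ <- ratios[ratios$genotype == mutant, ]
  rr_ <- ratios[ratios$genotype == ref, ]
  greater <- rm_$ratio[match(hc, rm_$gene_id)] > rr_$ratio[match(hc, rr_$gene_id)]
  list(fraction = mean(greater, na.rm = TRUE), n_targets = length(hc),
       per_gene = data.frame(gene_id = hc, greater = greater, row.names = NULL))
}

#' Simplified total-RNA differential expression stage
#'
#' A deliberately simple surrogate for a full count-model DE analysis:
#' log2 fold change of pseudocounted mean TPM in the total fraction, a
#' pooled t-test on log2(TPM + c), and BH q-values. Intended for flagging
#' gross abundance changes alongside the occupancy analysis, not as a
#' replacement for a negative-binomial DE model.
#'
#' @param tpm an `expression_matrix`.
#' @param sheet sample sheet (defaults to the one stored in `tpm`).
#' @param genotype mutant genotype.
#' @param ref reference genotype.
#' @param genes gene universe (default non-spike rows).
#' @param pseudocount c added before logs (default 1 TPM).
#' @param welch use Welch's t.
#' @return data.frame: gene_id, lfc, p, q, flag.
#' @export
differential_total <- function(tpm, sheet = tpm$sheet, genotype,
                               ref = "WT", genes = NULL, pseudocount = 1,
                               welch = FALSE) {
  if (is.null(genes)) genes <- rownames(tpm$values)[!tpm$spike]
  tot <- sheet[sheet$fraction == "total", ]
  mut_cols <- tot$sample_id[tot$genotype == genotype]
  ref_cols <- tot$sample_id[tot$genotype == ref]
  if (!length(mut_cols) || !length(ref_cols))
    fs_stop("total-fraction libraries missing for a genotype", "structural")
  m_mat <- log2(tpm$values[genes, mut_cols, drop = FALSE] + pseudocount)
  r_mat <- log2(tpm$values[genes, ref_cols, drop = FALSE] + pseudocount)
  lfc <- log2((rowMeans(tpm$values[genes, mut_cols, drop = FALSE]) + pseudocount) /
              (rowMeans(tpm$values[genes, ref_cols, drop = FALSE]) + pseudocount))
  res <- lapply(seq_along(genes),
                function(i) pooled_t(m_mat[i, ], r_mat[i, ], welch))
  data.frame(gene_id = genes, lfc = unname(lfc),
             p = vapply(res, `[[`, 0, "p"),
             q = bh_qvalues(vapply(res, `[[`, 0, "p")),
             flag = vapply(res, `[[`, "", "flag"),
             row.names = NULL)
}
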