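# Independent oracles used to check the package's computations.

# Benjamini-Hochberg step-up applied literally: q_(i) = min_{j>=i} p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) q_sorted[i] <- min(ps[i:m] * m / (i:m))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# classical BH rejection set at level alpha: reject p_(1..k) where
# k = max{ i : p_(i) <= i/m * alpha }
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0L, which(ps <= seq_len(m) / m * alpha)))
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# exhaustive-enumeration tail probabilities on the same score lattice as a
# pvalue_table: enumerate all 4^width k-mers, accumulate background mass
# per lattice score, and tail-sum from the top.
oracle_pwm_tail <- function(pv_table) {
  int <- pv_table$disc$int
  w <- ncol(int)
  bg <- as.numeric(pv_table$background)
  codes <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- integer(nrow(codes))
  probs <- rep(1, nrow(codes))
  for (j in seq_len(w)) {
    scores <- scores + int[cbind(codes[, j], j)]
    probs <- probs * bg[codes[, j]]
  }
  max_s <- length(pv_table$tail) - 1L
  mass <- tapply(probs, factor(scores, levels = 0:max_s), sum)
  mass[is.na(mass)] <- 0
  unname(rev(cumsum(rev(mass))))
}

# a random PWM of the given width (no pseudocount structure assumed)
random_pwm <- function(width) {
  prob <- matrix(rgamma(4 * width, 1), nrow = 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  prob <- sweep(prob, 2, colSums(prob), "/")
  structure(list(width = width, prob = prob,
                 consensus = paste(rep("N", width), collapse = ""),
                 eps = 0, classes = NULL),
            class = "motif_model")
}

random_background <- function() {
  p <- rgamma(4, 2) + 0.1
  fracseq::motif_background(setNames(p / sum(p), c("A", "C", "G", "T")))
}

# window-by-window class membership count for a degenerate consensus
oracle_count_canonical <- function(seq, classes) {
  chars <- strsplit(seq, "")[[1]]
  w <- length(classes)
  if (length(chars) < w) return(0L)
  n <- 0L
  for (s in seq_len(length(chars) - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) if (!(chars[s + j - 1L] %in% classes[[j]])) { ok <- FALSE; break }
    if (ok) n <- n + 1L
  }
  n
}

# small fixture: write a 3-gene experiment's TSVs into a dir
write_tiny_experiment <- function(dir, counts = NULL, spike_rows = NULL) {
  sheet <- data.frame(
    sample_id = c("WT_total_1", "WT_total_2", "CompoundHet_total_1", "CompoundHet_total_2"),
    genotype = rep(c("WT", "CompoundHet"), each = 2),
    fraction = "total",
    replicate = rep(1:2, 2))
  if (is.null(counts)) {
    counts <- matrix(c(10, 20, 30, 40,
                       5, 6, 7, 8,
                       0, 1, 2, 3), nrow = 3, byrow = TRUE,
                     dimnames = list(c("geneA", "geneB", "geneC"), sheet$sample_id))
  }
  if (!is.null(spike_rows)) counts <- rbind(counts, spike_rows)
  write.table(data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sheet, file.path(dir, "sheet.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(counts), length = 1000),
              file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  list(counts = counts, sheet = sheet, dir = dir)
}

# full small analysis: simulate -> tpm -> filter -> occupancy -> tests
run_small_analysis <- function(cfg) {
  sim <- fracseq::simulate_experiment(cfg)
  tpm <- fracseq::compute_tpm(sim$experiment)
  genes <- fracseq::filter_expressed(tpm)
  occ <- fracseq::compute_occupancy(tpm, genes = genes)
  tests <- fracseq::occupancy_tests(occ)
  list(sim = sim, tpm = tpm, genes = genes, occ = occ, tests = tests)
}
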