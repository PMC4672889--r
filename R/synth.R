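# Synthetic fractionated RNA-seq generator. Each individual contributes a
# total, an mRNP and a polysome library; per-gene fraction weights are
# w_total = 1, w_mRNP = m_g, w_polysome = p_g with m_g + p_g <= 1 (the
# remainder is a free monosome/degradation pool that is not sequenced).
# Derepression is planted in the compound heterozygote as m -> m/k together
# with p -> min(p*k, 1 - m/k), leaving total abundance untouched.

#' Default ERCC-like spike-in design
#'
#' 92 synthetic control species with nominal concentrations log-spaced over
#' the Mix-1 nominal range (0.014 to 30000 attomoles/ul).
#'
#' @param n number of controls.
#' @return A spike-in design data.frame (see [spikein_design()]).
#' @export
default_spikein_design <- function(n = 92) {
  spikein_design(sprintf("ERCC-%05d", seq_len(n)),
                 exp(seq(log(0.014), log(30000), length.out = n)))
}

#' Simulation configuration
#'
#' Describes a synthetic fractionation experiment: gene abundances are
#' log-normal, per-gene fraction partitions (mRNP, polysome, free) are
#' Dirichlet, counts are negative binomial with `variance = mu + phi * mu^2`
#' (`phi = 0` is the Poisson limit), and a chosen fraction of genes carries a
#' planted loss-of-repression effect of size `k` in the compound
#' heterozygote.
#'
#' @param n_genes number of biological genes.
#' @param genotypes genotypes to simulate (subset of [GENOTYPE_LEVELS];
#'   must include "WT").
#' @param n_replicates individuals per genotype (the study design uses
#'   biological duplicates).
#' @param depth expected biological fragments per library before scale
#'   factors.
#' @param nb_dispersion NB dispersion phi >= 0.
#' @param abundance_meanlog,abundance_sdlog log-normal baseline abundance.
#' @param partition_alpha length-3 Dirichlet concentration for
#'   (mRNP, polysome, free).
#' @param planted_fraction fraction of genes planted with the effect
#'   (count = floor(planted_fraction * n_genes)).
#' @param effect_size effect size k > 1.
#' @param scale_factors per-library true scale factors, recycled over
#'   libraries in sheet order (default 1).
#' @param spike_design spike-in design data.frame (NULL for none).
#' @param spike_mass_fraction expected spike fragments as a fraction of
#'   `depth`.
#' @param length_meanlog,length_sdlog log-normal gene length distribution.
#' @param seed integer seed; all randomness in [simulate_experiment()]
#'   derives from it.
#' @param abundance,partition_mrnp,partition_polysome,gene_lengths optional
#'   explicit per-gene values overriding the random draws (recycled).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       genotypes = GENOTYPE_LEVELS,
                       n_replicates = 2,
                       depth = 5e6,
                       nb_dispersion = 0.05,
                       abundance_meanlog = 4,
                       abundance_sdlog = 1.5,
                       partition_alpha = c(2, 2, 2),
                       planted_fraction = 0.05,
                       effect_size = 3,
                       scale_factors = 1,
                       spike_design = default_spikein_design(),
                       spike_mass_fraction = 0.05,
                       length_meanlog = log(1500),
                       length_sdlog = 0.4,
                       seed = 1,
                       abundance = NULL,
                       partition_mrnp = NULL,
                       partition_polysome = NULL,
                       gene_lengths = NULL) {
  if (n_genes < 1) fs_stop("n_genes must be >= 1", "config")
  if (!all(genotypes %in% GENOTYPE_LEVELS) || !"WT" %in% genotypes)
    fs_stop("genotypes must be a subset of GENOTYPE_LEVELS containing WT", "config")
  if (n_replicates < 1) fs_stop("n_replicates must be >= 1", "config")
  if (depth <= 0) fs_stop("depth must be > 0", "config")
  if (nb_dispersion < 0) fs_stop("nb_dispersion must be >= 0", "config")
  if (planted_fraction < 0 || planted_fraction > 1)
    fs_stop("planted_fraction must be in [0,1]", "config")
  if (effect_size <= 1) fs_stop("effect_size must be > 1", "config")
  if (any(scale_factors <= 0)) fs_stop("scale factors must be > 0", "config")
  if (length(partition_alpha) != 3 || any(partition_alpha <= 0))
    fs_stop("partition_alpha must be 3 positive concentrations", "config")
  if (spike_mass_fraction < 0) fs_stop("spike_mass_fraction must be >= 0", "config")
  pm <- partition_mrnp; pp <- partition_polysome
  if (!is.null(pm) && !is.null(pp)) {
    pm <- rep_len(pm, n_genes); pp <- rep_len(pp, n_genes)
    if (any(pm <= 0) || any(pp <= 0) || any(pm + pp > 1))
      fs_stop("explicit partitions must satisfy m, p in (0,1), m + p <= 1", "config")
  }
  structure(list(n_genes = as.integer(n_genes), genotypes = genotypes,
                 n_replicates = as.integer(n_replicates), depth = depth,
                 nb_dispersion = nb_dispersion,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 partition_alpha = partition_alpha,
                 planted_fraction = planted_fraction,
                 effect_size = effect_size, scale_factors = scale_factors,
                 spike_design = spike_design,
                 spike_mass_fraction = spike_mass_fraction,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 seed = as.integer(seed), abundance = abundance,
                 partition_mrnp = pm, partition_polysome = pp,
                 gene_lengths = gene_lengths),
            class = "sim_config")
}

# run code with a local RNG stream: the caller's .Random.seed is untouched
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

rnb <- function(n, mu, phi) {
  if (phi == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a fractionated RNA-seq experiment
#'
#' Per-gene parameters are drawn from the config seed; each library then
#' draws its counts from a sub-seed sampled from the same stream, so all
#' randomness derives from the single config seed and the caller's RNG
#' state is left untouched. For sample j (genotype G, fraction F) and gene
#' g, the expected fragment share is proportional to
#' `a_g * w_F(g, G) * L_g` and counts are NB with mean
#' `share * depth * s_j`. Spike-in rows get NB counts with mean
#' proportional to their nominal concentration times
#' `depth * spike_mass_fraction * s_j`.
#'
#' @param config a [sim_config()].
#' @return list with elements `experiment` (a [fracseq_experiment()]) and
#'   `truth` (class `fracseq_truth`): per-gene baseline abundance, lengths,
#'   per-genotype partitions, planted flags (and whether the polysome cap
#'   bound), per-sample true scale factors.
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) fs_stop("config must be a sim_config", "config")
  n <- config$n_genes
  gene_ids <- sprintf("g%06d", seq_len(n))
  sheet <- expand.grid(replicate = seq_len(config$n_replicates),
                       fraction = FRACTION_LEVELS,
                       genotype = config$genotypes,
                       stringsAsFactors = FALSE)[, 3:1]
  sheet$sample_id <- with(sheet, paste(genotype, fraction, replicate, sep = "_"))
  sheet <- sheet[, c("sample_id", "genotype", "fraction", "replicate")]
  ns <- nrow(sheet)
  sj <- rep_len(config$scale_factors, ns)

  spikes <- config$spike_design
  n_spike <- if (is.null(spikes)) 0L else nrow(spikes)

  res <- with_local_seed(config$seed, {
    a <- config$abundance %||% rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
    a <- rep_len(a, n)
    L <- config$gene_lengths %||% pmax(100, round(rlnorm(n, config$length_meanlog,
                                                         config$length_sdlog)))
    L <- rep_len(L, n)
    if (is.null(config$partition_mrnp)) {
      g1 <- rgamma(n, config$partition_alpha[1])
      g2 <- rgamma(n, config$partition_alpha[2])
      g3 <- rgamma(n, config$partition_alpha[3])
      tot <- g1 + g2 + g3
      m <- g1 / tot; p <- g2 / tot
    } else {
      m <- config$partition_mrnp; p <- config$partition_polysome
    }
    n_planted <- floor(config$planted_fraction * n)
    planted <- if (n_planted > 0) sort(sample.int(n, n_planted)) else integer()
    spike_len <- if (n_spike) round(runif(n_spike, 250, 2000)) else numeric()
    sample_seeds <- sample.int(.Machine$integer.max - 1L, ns)
    list(a = a, L = L, m = m, p = p, planted = planted,
         spike_len = spike_len, sample_seeds = sample_seeds)
  })

  k <- config$effect_size
  is_planted <- seq_len(n) %in% res$planted
  # effect applies only in the compound heterozygote
  m_eff <- res$m; p_eff <- res$p
  m_eff[is_planted] <- res$m[is_planted] / k
  p_cap <- 1 - m_eff
  p_eff[is_planted] <- pmin(res$p[is_planted] * k, p_cap[is_planted])
  cap_bound <- is_planted & (res$p * k > p_cap)
  if (any(m_eff + p_eff > 1 + 1e-12))
    fs_stop("planted effect leaves a negative free pool", "config")

  part <- function(G) {
    if (G == "CompoundHet") list(m = m_eff, p = p_eff) else list(m = res$m, p = res$p)
  }

  counts <- matrix(0, nrow = n + n_spike, ncol = ns,
                   dimnames = list(c(gene_ids, if (n_spike) spikes$control_id),
                                   sheet$sample_id))
  spike_w <- if (n_spike) spikes$concentration / sum(spikes$concentration) else numeric()
  phi <- config$nb_dispersion
  for (j in seq_len(ns)) {
    pj <- part(sheet$genotype[j])
    w <- switch(sheet$fraction[j], total = rep(1, n), mRNP = pj$m, polysome = pj$p)
    u <- res$a * w * res$L
    mu_gene <- (u / sum(u)) * config$depth * sj[j]
    mu_spk <- spike_w * config$depth * config$spike_mass_fraction * sj[j]
    counts[, j] <- with_local_seed(res$sample_seeds[j], {
      c(rnb(n, mu_gene, phi), if (n_spike) rnb(n_spike, mu_spk, phi))
    })
  }

  lengths <- setNames(c(res$L, res$spike_len),
                      c(gene_ids, if (n_spike) spikes$control_id))
  exp <- fracseq_experiment(counts, sheet, lengths,
                            spikein_ids = if (n_spike) spikes$control_id else character())

  genes_truth <- data.frame(gene_id = gene_ids, abundance = res$a, length = res$L,
                            m_baseline = res$m, p_baseline = res$p,
                            m_CompoundHet = m_eff, p_CompoundHet = p_eff,
                            is_planted = is_planted, cap_bound = cap_bound)
  truth <- structure(list(genes = genes_truth,
                          planted_ids = gene_ids[is_planted],
                          scale_factors = setNames(sj, sheet$sample_id),
                          config = config),
                     class = "fracseq_truth")
  list(experiment = exp, truth = truth)
}

#' @export
print.fracseq_truth <- function(x, ...) {
  cat("fracseq_truth:", nrow(x$genes), "genes,",
      length(x$planted_ids), "planted derepression targets\n")
  invisible(x)
}

#' Generate UTR sequences with planted consensus motif instances
#'
#' Background bases are i.i.d. from `base_composition`; each planted
#' instance overwrites a window with a 7-mer sampled uniformly from the
#' k-mers compatible with the degenerate consensus (36 of them for the
#' YRS). Planted windows never overlap.
#'
#' @param n_utrs number of sequences.
#' @param lengths sequence length(s), recycled.
#' @param planted_per_utr exact-consensus instances per sequence.
#' @param positions optional plant start positions (1-based): a vector
#'   (recycled across UTRs, one instance each unless a list) or a list of
#'   vectors per UTR; NULL draws non-overlapping positions at random.
#' @param base_composition named probabilities over A, C, G, T.
#' @param consensus degenerate consensus string (default the YRS).
#' @param seed integer seed.
#' @return list with `utrs` (a [utr_set()]) and `truth`: data.frame of
#'   transcript_id, start (1-based), planted k-mer.
#' @export
generate_utr_set <- function(n_utrs, lengths = 300, planted_per_utr = 0,
                             positions = NULL,
                             base_composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                             consensus = yrs_consensus(), seed = 1) {
  if (n_utrs < 1) fs_stop("n_utrs must be >= 1", "config")
  if (planted_per_utr < 0) fs_stop("planted_per_utr must be >= 0", "config")
  bases <- c("A", "C", "G", "T")
  if (!setequal(names(base_composition), bases))
    fs_stop("base_composition must be named over A,C,G,T", "config")
  comp <- base_composition[bases] / sum(base_composition)
  classes <- parse_consensus(consensus)
  w <- length(classes)
  kmers <- consensus_kmers(consensus)
  lens <- rep_len(as.integer(lengths), n_utrs)
  pos_list <- if (is.null(positions)) NULL
              else if (is.list(positions)) rep_len(positions, n_utrs)
              else rep_len(lapply(positions, identity), n_utrs)
  ids <- sprintf("utr%05d", seq_len(n_utrs))
  with_local_seed(seed, {
    seqs <- character(n_utrs)
    truth <- vector("list", n_utrs)
    for (i in seq_len(n_utrs)) {
      L <- lens[i]
      npl <- if (is.null(pos_list)) planted_per_utr else length(pos_list[[i]])
      if (L < w || (npl > 0 && L < npl * w))
        fs_stop("UTR length too short for requested planted instances", "config")
      s <- sample(bases, L, replace = TRUE, prob = comp)
      starts <- integer()
      if (npl > 0) {
        if (!is.null(pos_list)) {
          starts <- as.integer(pos_list[[i]])
          if (any(starts < 1 | starts > L - w + 1))
            fs_stop("plant position outside UTR bounds", "config")
          if (npl > 1 && min(diff(sort(starts))) < w)
            fs_stop("plant positions overlap", "config")
        } else {
          allowed <- rep(TRUE, L - w + 1)
          for (q in seq_len(npl)) {
            ok <- which(allowed)
            if (!length(ok))
              fs_stop("UTR length too short for requested planted instances", "config")
            st <- ok[sample.int(length(ok), 1)]
            starts <- c(starts, st)
            allowed[max(1, st - w + 1):min(L - w + 1, st + w - 1)] <- FALSE
          }
          starts <- sort(starts)
        }
        planted_kmers <- kmers[sample.int(length(kmers), npl, replace = TRUE)]
        for (q in seq_along(starts))
          s[starts[q]:(starts[q] + w - 1)] <- strsplit(planted_kmers[q], "")[[1]]
        truth[[i]] <- data.frame(transcript_id = ids[i], start = starts,
                                 kmer = planted_kmers)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    truth_df <- if (length(tdf <- Filter(Negate(is.null), truth)))
      do.call(rbind, tdf)
    else data.frame(transcript_id = character(), start = integer(), kmer = character())
    list(utrs = utr_set(setNames(seqs, ids)), truth = truth_df)
  })
}
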