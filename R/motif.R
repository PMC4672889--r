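# Degenerate motif scanner for the Y-box recognition sequence (YRS),
# built from scratch: a degenerate consensus is converted to a PWM with a
# small pseudocount, windows are scored by log2 odds against a 0-order
# background, and score p-values are exact tail probabilities obtained by
# dynamic programming over a discretized score grid (the lattice trick
# used by standard PWM scanners). Per-position scores are rounded DOWN to
# bin edges so reported p-values are conservative. Coordinates are 0-based
# half-open internally and 1-based inclusive in outputs; scanning is sense
# strand only (the YRS is an RNA element).

DNA_BASES <- c("A", "C", "G", "T")

#' The degenerate YRS consensus
#'
#' The Y-box protein recognition sequence, a degenerate 7-mer found in
#' 3'UTRs of translationally repressed spermatid mRNAs. In DNA alphabet:
#' `[TAC][CA]CA[TC]C[ACT]` (36 compatible 7-mers).
#'
#' @return The consensus string.
#' @export
yrs_consensus <- function() "[TAC][CA]CA[TC]C[ACT]"

# parse "[TAC][CA]CA[TC]C[ACT]" -> list of allowed-base character vectors
parse_consensus <- function(consensus) {
  s <- chartr("U", "T", toupper(consensus))
  classes <- list()
  i <- 1L
  chars <- strsplit(s, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      cls <- character()
      while (j <= length(chars) && chars[j] != "]") {
        cls <- c(cls, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) fs_stop("unterminated bracket class in consensus", "validation")
      if (!length(cls)) fs_stop("empty class in consensus", "validation")
      classes[[length(classes) + 1L]] <- unique(cls)
      i <- j + 1L
    } else {
      classes[[length(classes) + 1L]] <- ch
      i <- i + 1L
    }
  }
  bad <- setdiff(unlist(classes), DNA_BASES)
  if (length(bad))
    fs_stop(paste0("unknown symbol(s) in consensus: ", paste(bad, collapse = ", ")),
            "validation")
  classes
}

# all k-mers compatible with the consensus (36 for the YRS)
consensus_kmers <- function(consensus) {
  classes <- parse_consensus(consensus)
  grid <- do.call(expand.grid, c(rev(classes), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(classes)), drop = FALSE], 1, paste, collapse = "")
}

#' Convert a degenerate consensus to a PWM motif model
#'
#' Each position's probability for base b is
#' `(1[b allowed]/n_allowed + eps) / (1 + 4 eps)`, so allowed bases share
#' the mass and disallowed bases keep a small pseudocount (log-odds stay
#' finite).
#'
#' @param consensus degenerate consensus over `{A,C,G,T,U}` with optional
#'   bracket classes, e.g. `"[TAC][CA]CA[TC]C[ACT]"`.
#' @param eps pseudocount (default 1e-4).
#' @return A `motif_model`: list with `width`, `prob` (4 x width matrix,
#'   rows A,C,G,T, columns summing to 1), `consensus`, `eps`, `classes`.
#' @export
consensus_to_pwm <- function(consensus, eps = 1e-4) {
  classes <- parse_consensus(consensus)
  w <- length(classes)
  prob <- matrix(0, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(w)) {
    allowed <- DNA_BASES %in% classes[[i]]
    prob[, i] <- (allowed / sum(allowed) + eps) / (1 + 4 * eps)
  }
  structure(list(width = w, prob = prob, consensus = consensus,
                 eps = eps, classes = classes),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: width", x$width, "consensus", x$consensus, "\n")
  invisible(x)
}

#' Background base composition
#'
#' @param probs named probabilities over A, C, G, T (normalized here).
#' @return class `motif_background`: named numeric vector summing to 1.
#' @export
motif_background <- function(probs) {
  if (!setequal(names(probs), DNA_BASES))
    fs_stop("background must be named over A,C,G,T", "validation")
  probs <- probs[DNA_BASES]
  if (any(probs <= 0)) fs_stop("background probabilities must be > 0", "validation")
  structure(probs / sum(probs), class = "motif_background")
}

#' @rdname motif_background
#' @export
uniform_background <- function() motif_background(setNames(rep(0.25, 4), DNA_BASES))

#' @rdname motif_background
#' @param utrs a `utr_set`; 0-order frequencies are estimated from it with
#'   a small floor so no base has probability 0.
#' @param floor minimum probability per base before renormalization.
#' @export
estimate_background <- function(utrs, floor = 1e-6) {
  tab <- table(factor(unlist(strsplit(unclass(utrs), "")), levels = DNA_BASES))
  motif_background(pmax(as.numeric(tab) / sum(tab), floor) |> setNames(DNA_BASES))
}

# log2-odds matrix and the shared discretization used by both the DP table
# and window scoring: per-position scores are shifted to their minimum and
# floored onto an integer lattice with `scale` bins per unit score.
log_odds <- function(m, bg) log2(m$prob / as.numeric(bg))

discretize <- function(lo, n_bins) {
  mins <- apply(lo, 2, min)
  range_total <- sum(apply(lo, 2, max) - mins)
  scale <- if (range_total > 0) (n_bins - 1) / range_total else 1
  int <- floor(sweep(lo, 2, mins, "-") * scale + 1e-9)
  storage.mode(int) <- "integer"
  list(int = int, mins = mins, scale = scale, offset = sum(mins))
}

#' Exact score p-values by dynamic programming
#'
#' Discretizes per-position log-odds scores onto an `n_bins` lattice
#' (rounding down, hence conservative p), convolves the per-position score
#' distributions under the background, and tabulates the exact tail
#' probability `p(s) = P_bg(score >= s)` at every lattice point. For motif
#' widths small enough to enumerate, the table agrees with brute-force
#' enumeration of all `4^width` k-mers under the same lattice.
#'
#' @param m a `motif_model`.
#' @param bg a `motif_background`.
#' @param n_bins lattice resolution (>= 100; default 1000).
#' @return A `pvalue_table`: list with `tail` (tail probability per lattice
#'   score 0..max), `disc` (the shared discretization), `score_grid`
#'   (real score at each lattice point), plus the model and background.
#' @export
exact_pvalue_table <- function(m, bg, n_bins = 1000) {
  if (n_bins < 100) fs_stop("n_bins must be >= 100", "config")
  lo <- log_odds(m, bg)
  disc <- discretize(lo, n_bins)
  bgv <- as.numeric(bg)
  dist <- 1
  for (i in seq_len(m$width)) {
    col <- disc$int[, i]
    width_i <- max(col)
    newdist <- numeric(length(dist) + width_i)
    for (b in 1:4) {
      idx <- seq_along(dist) + col[b]
      newdist[idx] <- newdist[idx] + dist * bgv[b]
    }
    dist <- newdist
  }
  # tail from the top so p(min) = 1 exactly up to float error
  tail <- rev(cumsum(rev(dist)))
  tail[1] <- 1
  structure(list(tail = tail, disc = disc,
                 score_grid = disc$offset + (seq_along(tail) - 1) / disc$scale,
                 model = m, background = bg, n_bins = n_bins),
            class = "pvalue_table")
}

# p-value for integer lattice scores (vectorized)
lookup_p <- function(tab, int_scores) {
  p <- rep(0, length(int_scores))
  inside <- int_scores < length(tab$tail)
  p[inside] <- tab$tail[int_scores[inside] + 1L]
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * m / j`; thresholding
#' `q <= alpha` reproduces the classical BH rejection set at level alpha.
#'
#' @param pvals numeric p-values in `[0, 1]` (NA allowed, propagated).
#' @return q-values in input order.
#' @export
bh_qvalues <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    fs_stop("p-values must lie in [0, 1]", "validation")
  p.adjust(pvals, method = "BH")
}

# score all windows of one sequence; windows containing non-ACGT are NA
score_windows <- function(seq, lo, int) {
  w <- ncol(lo)
  codes <- match(strsplit(seq, "")[[1]], DNA_BASES)
  L <- length(codes)
  if (L < w) return(list(score = numeric(), int = integer(), starts = integer()))
  starts <- seq_len(L - w + 1L)
  sc <- numeric(length(starts))
  isc <- integer(length(starts))
  nas <- rep(FALSE, length(starts))
  for (j in seq_len(w)) {
    cj <- codes[starts + j - 1L]
    bad <- is.na(cj)
    nas <- nas | bad
    cj[bad] <- 1L
    sc <- sc + lo[cbind(cj, j)]
    isc <- isc + int[cbind(cj, j)]
  }
  sc[nas] <- NA_real_
  isc[nas] <- NA_integer_
  list(score = sc, int = isc, starts = starts)
}

#' Scan UTR sequences for motif hits
#'
#' Scores every window of every sequence (sense strand only), computes the
#' exact tail p-value of each window score, keeps windows with
#' `p <= report_threshold_p`, and appends BH q-values pooled over all
#' emitted positions of the run. Windows containing N are skipped.
#'
#' @param utrs a `utr_set`.
#' @param m a `motif_model` (default: the YRS).
#' @param bg a `motif_background`; NULL estimates a 0-order background from
#'   the scanned set.
#' @param report_threshold_p emit positions with p at or below this
#'   (default 1e-2).
#' @param n_bins p-value lattice resolution.
#' @param pv_table optionally a precomputed [exact_pvalue_table()] for
#'   `m`/`bg`.
#' @return data.frame of hits: transcript_id, start, end (1-based
#'   inclusive), matched, score_bits, p, q; ordered by transcript then
#'   position.
#' @export
scan_utrs <- function(utrs, m = consensus_to_pwm(yrs_consensus()), bg = NULL,
                      report_threshold_p = 1e-2, n_bins = 1000,
                      pv_table = NULL) {
  if (is.null(bg)) bg <- estimate_background(utrs)
  tab <- pv_table %||% exact_pvalue_table(m, bg, n_bins)
  lo <- log_odds(m, bg)
  int <- tab$disc$int
  hits <- vector("list", length(utrs))
  short <- 0L
  for (i in seq_along(utrs)) {
    s <- unclass(utrs)[[i]]
    if (nchar(s) < m$width) { short <- short + 1L; next }
    sw <- score_windows(s, lo, int)
    p <- rep(NA_real_, length(sw$starts))
    ok <- !is.na(sw$int)
    p[ok] <- lookup_p(tab, sw$int[ok])
    keep <- ok & p <= report_threshold_p
    if (!any(keep)) next
    st <- sw$starts[keep]
    hits[[i]] <- data.frame(transcript_id = names(utrs)[i],
                            start = st, end = st + m$width - 1L,
                            matched = substring(s, st, st + m$width - 1L),
                            score_bits = sw$score[keep], p = p[keep],
                            row.names = NULL)
  }
  if (short) message("scan_utrs: ", short, " sequence(s) shorter than motif width")
  hits <- Filter(Negate(is.null), hits)
  out <- if (length(hits)) do.call(rbind, hits)
         else data.frame(transcript_id = character(), start = integer(),
                         end = integer(), matched = character(),
                         score_bits = numeric(), p = numeric())
  out$q <- bh_qvalues(out$p)
  rownames(out) <- NULL
  out
}

#' Count exact consensus matches in a sequence
#'
#' Number of (possibly overlapping) windows exactly matching the degenerate
#' consensus classes.
#'
#' @param seq a single normalized sequence (or a `utr_set`, vectorized).
#' @param consensus degenerate consensus (default the YRS).
#' @return integer count(s).
#' @export
count_canonical <- function(seq, consensus = yrs_consensus()) {
  pat <- paste0("(?=", chartr("U", "T", toupper(consensus)), ")")
  vapply(chartr("U", "T", toupper(unclass(seq))), function(s) {
    mm <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (mm[1] == -1) 0L else length(mm)
  }, integer(1), USE.NAMES = FALSE)
}

#' Compare motif content across UTR sets
#'
#' For each labelled set: the fraction of UTRs with at least one hit at
#' `q <= q_threshold` (q-values pooled within that set's scan, mirroring a
#' per-dataset significance comparison), and the mean number of canonical
#' consensus matches among UTRs carrying at least one canonical match.
#'
#' @param sets named list of `utr_set`s.
#' @param m a `motif_model`.
#' @param bg a `motif_background`; NULL estimates per set.
#' @param q_threshold q-value threshold (default 0.2).
#' @param report_threshold_p scan emission threshold.
#' @return data.frame: set, n_utrs, frac_with_hit, mean_canonical,
#'   n_with_canonical (NA row for an empty set).
#' @export
compare_utr_sets <- function(sets, m = consensus_to_pwm(yrs_consensus()),
                             bg = NULL, q_threshold = 0.2,
                             report_threshold_p = 1e-2) {
  if (!length(sets)) fs_stop("at least one UTR set required", "config")
  rows <- lapply(names(sets), function(lbl) {
    u <- sets[[lbl]]
    if (!length(u))
      return(data.frame(set = lbl, n_utrs = 0L, frac_with_hit = NA_real_,
                        mean_canonical = NA_real_, n_with_canonical = NA_integer_))
    hits <- scan_utrs(u, m, bg, report_threshold_p)
    sig <- hits[!is.na(hits$q) & hits$q <= q_threshold, ]
    cc <- count_canonical(u, m$consensus)
    has_cc <- cc >= 1
    data.frame(set = lbl, n_utrs = length(u),
               frac_with_hit = length(unique(sig$transcript_id)) / length(u),
               mean_canonical = if (any(has_cc)) mean(cc[has_cc]) else NA_real_,
               n_with_canonical = sum(has_cc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export motif hits as GFF3 (transcript-relative coordinates)
#'
#' @param hits hit table from [scan_utrs()].
#' @param path output path.
#' @param source feature source tag.
#' @export
write_hits_gff3 <- function(hits, path, source = "fracseq") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits)) {
    attr_col <- sprintf("ID=hit%05d;matched=%s;pvalue=%.3g;qvalue=%.3g",
                        seq_len(nrow(hits)), hits$matched, hits$p, hits$q)
    df <- data.frame(hits$transcript_id, source, "nucleotide_motif",
                     hits$start, hits$end, sprintf("%.4f", hits$score_bits),
                     "+", ".", attr_col)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
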