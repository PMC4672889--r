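# Readers, validators and writers for the external tab-separated formats.
# Counts dialect: tab-separated, first column "gene_id", header row of
# sample ids, UTF-8, no quoting.

read_tsv <- function(path) {
  if (!file.exists(path)) fs_stop(paste0("file not found: ", path), "structural")
  read.delim(path, sep = "\t", header = TRUE, quote = "", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Validate a sample sheet
#'
#' A sample sheet has one row per sequencing library with columns
#' `sample_id`, `genotype`, `fraction` and `replicate`. Genotypes must be
#' drawn from [GENOTYPE_LEVELS] and fractions from [FRACTION_LEVELS];
#' replicates within each (genotype, fraction) must be numbered `1..n`
#' without gaps, so that replicate r of every fraction identifies the same
#' individual.
#'
#' @param sheet data.frame with the four columns above.
#' @return The sheet, with `replicate` coerced to integer.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "genotype", "fraction", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    fs_stop(paste0("sample sheet lacks column(s): ", paste(miss, collapse = ", ")),
            "structural")
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$genotype <- as.character(sheet$genotype)
  sheet$fraction <- as.character(sheet$fraction)
  sheet$replicate <- as.integer(sheet$replicate)
  if (anyDuplicated(sheet$sample_id))
    fs_stop("duplicate sample_id in sample sheet", "validation")
  bad_g <- setdiff(unique(sheet$genotype), GENOTYPE_LEVELS)
  if (length(bad_g))
    fs_stop(paste0("unknown genotype(s): ", paste(bad_g, collapse = ", ")), "validation")
  bad_f <- setdiff(unique(sheet$fraction), FRACTION_LEVELS)
  if (length(bad_f))
    fs_stop(paste0("unknown fraction(s): ", paste(bad_f, collapse = ", ")), "validation")
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1L))
    fs_stop("replicate numbers must be positive integers", "validation")
  for (key in split(sheet$replicate, paste(sheet$genotype, sheet$fraction))) {
    if (!identical(sort(key), seq_along(key)))
      fs_stop("replicates within a (genotype, fraction) must be numbered 1..n without gaps",
              "validation")
  }
  sheet[need]
}

#' Construct a fractionated experiment
#'
#' Bundles a gene-by-sample count matrix with its sample sheet, per-gene
#' effective lengths and the set of rows that are spike-in controls. Columns
#' are reordered to sample-sheet order and rows are sorted by ID so that
#' readers are agnostic to input permutations.
#'
#' @param counts numeric matrix, genes (and spike-ins) by samples; finite,
#'   non-negative, unique rownames, colnames = sample ids.
#' @param sheet sample sheet (see [validate_sample_sheet()]).
#' @param lengths named numeric vector of effective lengths in nucleotides
#'   covering every row of `counts`.
#' @param spikein_ids character vector of row IDs that are control species.
#' @return An object of class `fracseq_experiment` with elements `counts`,
#'   `sheet`, `lengths`, `spikein_ids`.
#' @export
fracseq_experiment <- function(counts, sheet, lengths, spikein_ids = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    fs_stop("counts must have row and column names", "structural")
  if (anyDuplicated(rownames(counts)))
    fs_stop("duplicate gene ID in counts", "validation")
  if (any(!is.finite(counts)))
    fs_stop("counts must be finite", "validation")
  if (any(counts < 0))
    fs_stop("negative count", "validation")
  sheet <- validate_sample_sheet(sheet)
  if (!setequal(colnames(counts), sheet$sample_id))
    fs_stop("counts columns and sample sheet disagree", "structural")
  counts <- counts[, sheet$sample_id, drop = FALSE]
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)))
    fs_stop("lengths missing for some rows", "structural")
  if (any(lengths <= 0))
    fs_stop("lengths must be > 0", "validation")
  names(lengths) <- rownames(counts)
  spikein_ids <- as.character(spikein_ids)
  if (!all(spikein_ids %in% rownames(counts)))
    fs_stop("spikein_ids not all present among row IDs", "structural")
  ord <- order(rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  lengths <- lengths[ord]
  structure(list(counts = counts, sheet = sheet, lengths = lengths,
                 spikein_ids = sort(spikein_ids)),
            class = "fracseq_experiment")
}

#' @export
print.fracseq_experiment <- function(x, ...) {
  cat("fracseq_experiment:", nrow(x$counts), "rows x", ncol(x$counts), "samples;",
      length(x$spikein_ids), "spike-in rows\n")
  cat("genotypes:", paste(unique(x$sheet$genotype), collapse = ", "), "\n")
  invisible(x)
}

#' Read a fractionated experiment from TSV files
#'
#' @param counts_path counts TSV: first column `gene_id`, one column per
#'   sample named by sample id.
#' @param sheet_path sample sheet TSV (`sample_id`, `genotype`, `fraction`,
#'   `replicate`).
#' @param lengths_path two-column TSV (`gene_id`, `length`) covering every
#'   counts row; effective lengths are supplied, never computed here.
#' @param spikeins either a single string, used as an ID prefix (default
#'   `"ERCC-"`), or a character vector of explicit control IDs.
#' @return A [fracseq_experiment()].
#' @export
read_experiment <- function(counts_path, sheet_path, lengths_path,
                            spikeins = "ERCC-") {
  ctab <- read_tsv(counts_path)
  if (names(ctab)[1] != "gene_id")
    fs_stop("counts TSV must have first column 'gene_id'", "structural")
  counts <- as.matrix(ctab[, -1, drop = FALSE])
  rownames(counts) <- as.character(ctab$gene_id)
  sheet <- validate_sample_sheet(read_tsv(sheet_path))
  ltab <- read_tsv(lengths_path)
  lengths <- setNames(as.numeric(ltab[[2]]), as.character(ltab[[1]]))
  ids <- rownames(counts)
  spike_ids <- if (length(spikeins) == 1L) {
    ids[startsWith(ids, spikeins)]
  } else {
    miss <- setdiff(spikeins, ids)
    if (length(miss))
      fs_stop(paste0("explicit spike-in IDs absent from counts: ",
                     paste(miss, collapse = ", ")), "structural")
    spikeins
  }
  fracseq_experiment(counts, sheet, lengths, spike_ids)
}

#' Write the count matrix of an experiment as TSV
#'
#' Inverse of the counts part of [read_experiment()]; integer counts
#' round-trip bit-exactly.
#'
#' @param exp a `fracseq_experiment`.
#' @param path output path.
#' @export
write_counts <- function(exp, path) {
  df <- data.frame(gene_id = rownames(exp$counts), exp$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spike-in design table
#'
#' Two-column TSV of control ID and nominal concentration (attomoles/ul,
#' e.g. the ERCC Mix 1 panel).
#'
#' @param path TSV path.
#' @return data.frame with columns `control_id`, `concentration`.
#' @export
read_spikein_design <- function(path) {
  tab <- read_tsv(path)
  if (ncol(tab) < 2)
    fs_stop("spike-in design must have two columns (id, concentration)", "structural")
  spikein_design(as.character(tab[[1]]), as.numeric(tab[[2]]))
}

#' @rdname read_spikein_design
#' @param control_id,concentration vectors forming the design directly.
#' @export
spikein_design <- function(control_id, concentration) {
  if (anyDuplicated(control_id))
    fs_stop("duplicate spike-in control ID", "validation")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    fs_stop("spike-in concentrations must be positive", "validation")
  data.frame(control_id = as.character(control_id),
             concentration = as.numeric(concentration))
}

#' Read a 3'UTR sequence set from FASTA
#'
#' Sequences are upper-cased and U is normalized to T; IDs are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA path.
#' @return A `utr_set`: named character vector of DNA-alphabet sequences.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  utr_set(seqs)
}

#' @rdname read_utr_fasta
#' @param seqs named character vector of sequences over `{A,C,G,T,U,N}`
#'   (any case).
#' @export
utr_set <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    fs_stop("UTR sequences must be named", "structural")
  if (anyDuplicated(names(seqs)))
    fs_stop("duplicate UTR transcript ID", "validation")
  seqs <- chartr("U", "T", toupper(seqs))
  empty <- names(seqs)[nchar(seqs) == 0]
  if (length(empty))
    fs_stop(paste0("empty sequence for: ", paste(empty, collapse = ", ")), "validation")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    fs_stop(paste0("non-ACGTUN characters in: ",
                   paste(names(seqs)[bad], collapse = ", ")), "validation")
  structure(seqs, class = "utr_set")
}

#' @export
print.utr_set <- function(x, ...) {
  cat("utr_set:", length(x), "sequences, lengths",
      min(nchar(x)), "-", max(nchar(x)), "nt\n")
  invisible(x)
}

#' Write a UTR set as FASTA
#' @param utrs a `utr_set`.
#' @param path output path.
#' @export
write_utr_fasta <- function(utrs, path) {
  writeLines(paste0(">", names(utrs), "\n", unclass(utrs)), path)
  invisible(path)
}

# shared writer for result TSVs: tagged header line plus provenance comment
write_result_tsv <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#fracseq-occupancy v1", con)
  if (!is.null(seed) || !is.null(config_hash))
    writeLines(sprintf("#seed=%s config=%s",
                       seed %||% "NA", config_hash %||% "NA"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
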