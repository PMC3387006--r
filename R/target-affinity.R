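#' Seed-match target-site motifs of a mature miRNA
#'
#' Derives the canonical 7-mer and 8-mer seed-match motifs from a mature
#' miRNA sequence. With S = positions 2-8 of the mature miRNA (the seed
#' region plus position 8):
#' \itemize{
#'   \item 7mer-m8: reverse complement of S, in DNA alphabet;
#'   \item 7mer-A1: reverse complement of positions 2-7 followed by "A";
#'   \item 8mer: reverse complement of S followed by "A".
#' }
#' Duplicate motifs are collapsed.
#'
#' @param mature_sequence Mature miRNA sequence, length >= 8, RNA alphabet
#'   (A/C/G/U; T is accepted and read as U).
#' @param mirna_id Identifier carried into the motif set.
#' @return A `SeedMotifSet`: list with `mirna_id` and `motifs`, a
#'   data.frame of (`motif`, `type`) rows.
#' @examples
#' seed_motifs("UAAAGUGCUUAUAGUGCAGGUAG", "hsa-miR-106b")$motifs
#' @export
seed_motifs <- function(mature_sequence, mirna_id = NA_character_) {
  s <- toupper(as.character(mature_sequence))
  s <- chartr("T", "U", s)
  if (nchar(s) < 8) stop("mature sequence must be at least 8 nt")
  if (grepl("[^ACGU]", s)) stop("mature sequence contains non-ACGU letters")
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chartr("U", "T", x))))
  }
  m8 <- rc(substr(s, 2, 8))
  a1 <- paste0(rc(substr(s, 2, 7)), "A")
  mer8 <- paste0(m8, "A")
  motifs <- data.frame(motif = c(m8, a1, mer8),
                       type = c("7mer-m8", "7mer-A1", "8mer"),
                       stringsAsFactors = FALSE)
  motifs <- motifs[!duplicated(motifs$motif), , drop = FALSE]
  structure(list(mirna_id = mirna_id, motifs = motifs),
            class = "SeedMotifSet")
}

#' @export
print.SeedMotifSet <- function(x, ...) {
  cat(sprintf("SeedMotifSet %s: %s\n", x$mirna_id,
              paste(sprintf("%s (%s)", x$motifs$motif, x$motifs$type),
                    collapse = ", ")))
  invisible(x)
}

# internal: coerce FASTA path / DNAStringSet / named character to
# a named character vector of uppercase DNA sequences
utr_sequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    fasta <- Biostrings::readDNAStringSet(fasta)
  if (inherits(fasta, "XStringSet")) {
    out <- as.character(fasta)
  } else if (is.character(fasta)) {
    out <- toupper(fasta)
  } else stop("expected a FASTA path, a DNAStringSet or a named character vector")
  if (is.null(names(out)) || any(names(out) == ""))
    stop("every 3'UTR sequence must carry a gene name")
  names(out) <- sub("\\s.*$", "", names(out))
  if (anyDuplicated(names(out))) stop("duplicate FASTA headers")
  out
}

#' Scan 3'UTRs for seed-match motifs: the binary affinity matrix
#'
#' Exact substring matching of each miRNA's motifs on the given (sense)
#' strand of each 3'UTR. `N` never matches. The result is the binary
#' sequence affinity matrix A with A_ij = 1 iff at least one motif of
#' miRNA j occurs anywhere in the 3'UTR of gene i (existence, not count).
#'
#' @param fasta 3'UTR sequences: FASTA path, `DNAStringSet`, or named
#'   character vector (names = unique gene symbols; alphabet A/C/G/T/N).
#' @param motif_sets List of `SeedMotifSet` objects (one per miRNA).
#' @return An `AffinityMatrix`: binary integer matrix, genes x miRNAs.
#' @export
scan_utr <- function(fasta, motif_sets) {
  seqs <- utr_sequences(fasta)
  if (any(grepl("[^ACGTN]", seqs)))
    stop("3'UTR sequences must be over the A/C/G/T/N alphabet")
  empty <- nchar(seqs) == 0
  if (any(empty))
    message(sprintf("%d empty 3'UTR sequence(s): all-zero affinity rows",
                    sum(empty)))
  mirna_ids <- vapply(motif_sets, function(ms) ms$mirna_id, character(1))
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA ids in motif sets")
  subj <- Biostrings::DNAStringSet(seqs)
  A <- matrix(0L, length(seqs), length(motif_sets),
              dimnames = list(names(seqs), mirna_ids))
  for (j in seq_along(motif_sets)) {
    hit <- rep(FALSE, length(seqs))
    for (motif in motif_sets[[j]]$motifs$motif) {
      hit <- hit | Biostrings::vcountPattern(motif, subj, fixed = TRUE) > 0
    }
    A[, j] <- as.integer(hit)
  }
  structure(A, class = c("AffinityMatrix", class(A)))
}

# internal: one-sided Fisher exact on a 2x2 table given as counts
# (a = hits in list, b = misses in list, c = hits outside, d = misses
# outside). The odds ratio uses the Haldane 0.5 correction for reporting
# only; the p-value comes from the exact test on the raw counts.
fisher_2x2 <- function(a, b, c, d, alternative = "greater") {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  list(p_value = p, odds_ratio = or)
}

#' Target-site enrichment of a gene list for one miRNA
#'
#' Tests whether the genes of a (modular) list carry target-site motifs of
#' a miRNA more often than expected, in reference to the entire gene
#' universe of the affinity matrix, with a one-sided Fisher exact test
#' (alternative "greater": enrichment, not depletion).
#'
#' @param a An `AffinityMatrix` from [scan_utr()].
#' @param gene_list Non-empty character vector of genes, a subset of the
#'   affinity matrix's gene universe.
#' @param mirna_id Column of `a` to test.
#' @param alternative Passed to the exact test (default `"greater"`).
#' @return One-row data.frame: `mirna`, the 2x2 counts
#'   (`list_targets`, `list_nontargets`, `bg_targets`, `bg_nontargets`),
#'   `odds_ratio` (Haldane-corrected, reporting only) and `p_value`.
#' @export
target_enrichment <- function(a, gene_list, mirna_id,
                              alternative = "greater") {
  stopifnot(inherits(a, "AffinityMatrix"))
  if (length(gene_list) == 0) stop("empty gene list")
  if (!all(gene_list %in% rownames(a)))
    stop("gene list contains genes outside the affinity universe")
  if (!mirna_id %in% colnames(a)) stop("unknown miRNA id")
  targ <- a[, mirna_id] == 1L
  in_list <- rownames(a) %in% gene_list
  n11 <- sum(targ & in_list)
  n12 <- sum(!targ & in_list)
  n21 <- sum(targ & !in_list)
  n22 <- sum(!targ & !in_list)
  ft <- fisher_2x2(n11, n12, n21, n22, alternative)
  data.frame(mirna = mirna_id,
             list_targets = n11, list_nontargets = n12,
             bg_targets = n21, bg_nontargets = n22,
             odds_ratio = ft$odds_ratio, p_value = ft$p_value,
             stringsAsFactors = FALSE)
}

#' Per-miRNA target-site enrichment report for a module
#'
#' Runs [target_enrichment()] for every modular miRNA against a modular
#' gene list and adjusts the p-values across those miRNAs with
#' Benjamini-Hochberg.
#'
#' @param a An `AffinityMatrix`.
#' @param gene_list Modular gene list (non-empty).
#' @param mirna_ids Modular miRNA ids (columns of `a`).
#' @param alternative Passed to the exact test.
#' @return data.frame with one row per miRNA, including `adj_p`.
#' @export
module_target_enrichment <- function(a, gene_list, mirna_ids,
                                     alternative = "greater") {
  rows <- do.call(rbind, lapply(mirna_ids, function(j)
    target_enrichment(a, gene_list, j, alternative)))
  rows$adj_p <- bh_adjust(rows$p_value)
  rows
}

#' Read mature miRNA sequences from FASTA
#'
#' Accepts RNA- or DNA-alphabet FASTA; returns uppercase RNA sequences
#' named by the first word of each header.
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return Named character vector of RNA sequences.
#' @export
read_mature_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- chartr("T", "U", toupper(as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(out))) stop("duplicate miRNA FASTA headers")
  out
}
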