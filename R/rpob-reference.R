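#' rpoB reference and RRDR coordinates
#'
#' The rifampicin resistance determining region (RRDR) of *E. coli* rpoB
#' comprises three clusters, given here in CDS coordinates:
#' cluster I (amino acids 507-533, nucleotides 1520-1598), cluster II
#' (amino acids 563-572, nucleotides 1687-1715) and cluster III (amino acid
#' 687, nucleotides 2060-2062).
#'
#' @return `rrdr_clusters()`: a data.frame with one row per cluster
#'   (`cluster`, `nt_start`, `nt_end`, `aa_start`, `aa_end`).
#' @examples
#' rrdr_clusters()
#' rrdr_cluster_of(c(1520, 1650, 1715, 2061))
#' @export
rrdr_clusters <- function() {
  data.frame(cluster = c("I", "II", "III"),
             nt_start = c(1520L, 1687L, 2060L),
             nt_end = c(1598L, 1715L, 2062L),
             aa_start = c(507L, 563L, 687L),
             aa_end = c(533L, 572L, 687L),
             stringsAsFactors = FALSE)
}

#' @rdname rrdr_clusters
#' @param cds_pos vector of 1-based CDS nucleotide positions.
#' @return `rrdr_cluster_of()`: character vector, `"I"`, `"II"`, `"III"` or
#'   `"outside"`.
#' @export
rrdr_cluster_of <- function(cds_pos) {
  cl <- rrdr_clusters()
  out <- rep("outside", length(cds_pos))
  for (i in seq_len(nrow(cl)))
    out[cds_pos >= cl$nt_start[i] & cds_pos <= cl$nt_end[i]] <- cl$cluster[i]
  out
}

#' Reference CDS container
#'
#' `rpob_reference()` builds a *synthetic* stand-in for the rpoB coding
#' sequence: a deterministic random 4029-nt CDS (1343 codons, the length of
#' the NC_000913.3 window 4181245-4185273), ATG start, single terminal stop,
#' no internal stops. It is a sequence stand-in for offline work --- all
#' positional arithmetic (RRDR clusters, codon numbering, genomic offset) is
#' identical to the real gene, but the base content is not *E. coli*'s.
#' Use [read_reference()] to load the real CDS from a FASTA file instead.
#'
#' @param seed seed for the deterministic synthetic sequence.
#' @return an object of class `rpob_reference`: `gene_id`, `cds` (character
#'   string), `genome_accession`, `genome_offset` (genomic coordinate of CDS
#'   position 1), `synthetic` flag.
#' @examples
#' ref <- rpob_reference()
#' nchar(ref$cds)  # 4029
#' @export
rpob_reference <- function(seed = 7301) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  n_codons <- 1343L
  cds <- local_seed(seed, {
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  })
  structure(list(gene_id = "rpoB_synthetic", cds = cds,
                 genome_accession = "NC_000913.3",
                 genome_offset = 4181245L, synthetic = TRUE),
            class = "rpob_reference")
}

#' @rdname rpob_reference
#' @param fasta path to a FASTA file whose first record is the CDS.
#' @param gene_id,genome_accession,genome_offset annotation carried into
#'   variant calls.
#' @export
read_reference <- function(fasta, gene_id = "rpoB",
                           genome_accession = "NC_000913.3",
                           genome_offset = 4181245L) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) < 1) stop_domain("no sequence in ", fasta)
  cds <- toupper(as.character(seqs[[1]]))
  if (nchar(cds) %% 3 != 0)
    stop_domain("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", cds))
    stop_domain("CDS must contain only A, C, G, T")
  structure(list(gene_id = gene_id, cds = cds,
                 genome_accession = genome_accession,
                 genome_offset = as.integer(genome_offset),
                 synthetic = FALSE),
            class = "rpob_reference")
}

#' @export
print.rpob_reference <- function(x, ...) {
  cat(sprintf("%s: %d nt CDS (%d codons), %s offset %d%s\n",
              x$gene_id, nchar(x$cds), nchar(x$cds) / 3,
              x$genome_accession, x$genome_offset,
              if (isTRUE(x$synthetic)) " [synthetic sequence]" else ""))
  invisible(x)
}

ref_base <- function(ref, pos) substring(ref$cds, pos, pos)

codon_of <- function(ref, codon_number) {
  substring(ref$cds, 3 * (codon_number - 1) + 1, 3 * codon_number)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) "X" else aa
}
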