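#' Call rpoB mutations for a set of isolate reads
#'
#' Runs [orient_and_align()] and [extract_variants()] on every read and
#' joins the calls with isolate metadata. Isolates whose reads align but
#' carry no call inside RRDR clusters I/II are emitted with category
#' `"none_detected"` (the paper's 214-of-274 situation: resistance may lie
#' outside the sequenced window). Unalignable reads are likewise emitted as
#' `"none_detected"` with a note. Isolates with more than one call are all
#' reported and flagged for review rather than silently reduced to one.
#'
#' @param reads a named `DNAStringSet`, a named character vector, or the
#'   path to a FASTA file; one record per isolate, names are isolate ids.
#' @param ref an `rpob_reference`.
#' @param metadata data.frame with columns `isolate_id`, `strain`,
#'   `glucose`; every read must have a metadata row.
#' @param ... alignment parameters passed to [orient_and_align()].
#' @return data.frame with one row per call (or per empty isolate):
#'   `isolate_id`, `strain`, `glucose`, `cds_pos`, `kind`, `ref_allele`,
#'   `alt_allele`, `codon_number`, `aa_change`, `cluster`, `category`,
#'   `frame_preserving`, `n_calls`, `note`.
#' @export
call_rpob_reads <- function(reads, ref, metadata, ...) {
  stopifnot(inherits(ref, "rpob_reference"))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads)
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads)) || any(names(reads) == ""))
    stop_domain("reads must be named by isolate id")
  missing_meta <- setdiff(names(reads), metadata$isolate_id)
  if (length(missing_meta) > 0)
    stop_domain("isolates missing metadata: ",
                paste(missing_meta, collapse = ", "))

  rows <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    meta <- metadata[match(id, metadata$isolate_id), , drop = FALSE]
    calls <- tryCatch({
      aln <- orient_and_align(reads[[i]], ref, ...)
      extract_variants(aln, ref)
    }, error = function(e) {
      structure(empty_calls(), note = conditionMessage(e))
    })
    note <- attr(calls, "note")
    in_rrdr <- calls$cluster %in% c("I", "II")
    if (nrow(calls) == 0 || !any(in_rrdr)) {
      rows[[i]] <- data.frame(
        isolate_id = id, strain = meta$strain, glucose = meta$glucose,
        cds_pos = NA_integer_, kind = NA_character_,
        ref_allele = NA_character_, alt_allele = NA_character_,
        codon_number = NA_integer_, aa_change = NA_character_,
        cluster = NA_character_, category = "none_detected",
        frame_preserving = NA, n_calls = nrow(calls),
        note = if (is.null(note)) "" else note,
        stringsAsFactors = FALSE)
    } else {
      calls$isolate_id <- id
      calls$strain <- meta$strain
      calls$glucose <- meta$glucose
      calls$category <- ifelse(
        calls$kind == "substitution",
        classify_substitution(calls$ref_allele, calls$alt_allele),
        calls$kind)
      calls$n_calls <- nrow(calls)
      calls$note <- if (nrow(calls) > 1) "multiple calls: review" else ""
      rows[[i]] <- calls[, c("isolate_id", "strain", "glucose", "cds_pos",
                             "kind", "ref_allele", "alt_allele",
                             "codon_number", "aa_change", "cluster",
                             "category", "frame_preserving", "n_calls",
                             "note")]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate calls per isolate and optionally write a VCF
#'
#' `calls_to_tables()` is the file-facing wrapper: it writes the calls CSV
#' and, when `vcf` is given, a minimal VCF 4.2 against the genome accession
#' of the reference (`POS = genome_offset + cds_pos - 1`; indels use the
#' usual anchor-base convention).
#'
#' @param calls call table from [call_rpob_reads()].
#' @param ref the `rpob_reference`.
#' @param csv path for the calls CSV (optional).
#' @param vcf path for a VCF 4.2 file (optional).
#' @return the calls table, invisibly if a CSV was written.
#' @export
calls_to_tables <- function(calls, ref, csv = NULL, vcf = NULL) {
  stopifnot(inherits(ref, "rpob_reference"))
  if (!is.null(csv)) utils::write.csv(calls, csv, row.names = FALSE)
  if (!is.null(vcf)) write_calls_vcf(calls, ref, vcf)
  if (is.null(csv)) calls else invisible(calls)
}

write_calls_vcf <- function(calls, ref, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##reference=", ref$genome_accession),
           paste0("##contig=<ID=", ref$genome_accession, ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  real <- calls[!is.na(calls$cds_pos), , drop = FALSE]
  for (r in seq_len(nrow(real))) {
    pos <- real$cds_pos[r]
    if (real$kind[r] == "substitution") {
      gpos <- ref$genome_offset + pos - 1L
      refa <- real$ref_allele[r]; alta <- real$alt_allele[r]
    } else if (real$kind[r] == "deletion") {
      anchor_pos <- max(1L, pos - 1L)
      gpos <- ref$genome_offset + anchor_pos - 1L
      anchor <- ref_base(ref, anchor_pos)
      refa <- paste0(anchor, real$ref_allele[r]); alta <- anchor
    } else {
      gpos <- ref$genome_offset + pos - 1L
      anchor <- ref_base(ref, pos)
      refa <- anchor; alta <- paste0(anchor, real$alt_allele[r])
    }
    body <- c(body, sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tISOLATE=%s",
                            ref$genome_accession, gpos, ".",
                            refa, alta, real$isolate_id[r]))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
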