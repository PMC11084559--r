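#' Orient and align a Sanger read against the reference CDS
#'
#' Semi-global alignment (the whole read against a window of the CDS, read
#' end-gaps free) of the read and of its reverse complement; the
#' higher-scoring strand wins. Defaults favour substitution calls over
#' spurious gaps at Sanger-scale divergence.
#'
#' @param read nucleotide string (character or `DNAString`), length >= 50,
#'   alphabet A/C/G/T/N.
#' @param ref an `rpob_reference`.
#' @param match,mismatch,gap_open,gap_ext alignment scores (gap penalties
#'   given as positive costs).
#' @param min_identity minimum fraction of matching base columns (gaps and
#'   read Ns excluded); below it the read is rejected as unalignable.
#' @return object of class `rpob_alignment`: `oriented_read`, `strand_used`
#'   (`"forward"` or `"reverse-complement"`), `score`, `identity`,
#'   `ref_window` (c(start, end), 1-based CDS), `aligned_read` and
#'   `aligned_ref` (gapped strings of equal length).
#' @examples
#' ref <- rpob_reference()
#' aln <- orient_and_align(substring(ref$cds, 1400, 1900), ref)
#' aln$ref_window
#' @export
orient_and_align <- function(read, ref, match = 2, mismatch = -3,
                             gap_open = 5, gap_ext = 2,
                             min_identity = 0.8) {
  stopifnot(inherits(ref, "rpob_reference"))
  read <- toupper(as.character(read))
  if (nchar(read) < 50) stop_domain("read shorter than 50 nt")
  if (grepl("[^ACGTN]", read))
    stop_domain("read contains characters outside A,C,G,T,N")

  bases <- c("A", "C", "G", "T", "N")
  smat <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(smat) <- match
  smat["N", ] <- 0            # N columns are uninformative, score-neutral
  smat[, "N"] <- 0

  subject <- Biostrings::DNAString(ref$cds)
  align1 <- function(r) {
    Biostrings::pairwiseAlignment(Biostrings::DNAString(r), subject,
                                  type = "global-local",
                                  substitutionMatrix = smat,
                                  gapOpening = gap_open,
                                  gapExtension = gap_ext)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  fwd <- align1(read)
  rev <- align1(rc)
  use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)
  aln <- if (use_rev) rev else fwd
  oriented <- if (use_rev) rc else read

  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(ap, "")[[1]]
  sc <- strsplit(as_, "")[[1]]
  informative <- pc != "-" & sc != "-" & pc != "N"
  n_inf <- sum(informative)
  identity <- if (n_inf == 0) 0 else
    sum(pc[informative] == sc[informative]) / n_inf
  if (identity < min_identity)
    stop_domain(sprintf(
      "unalignable read: best identity %.3f below floor %.2f",
      identity, min_identity))

  structure(list(
    oriented_read = oriented,
    strand_used = if (use_rev) "reverse-complement" else "forward",
    score = Biostrings::score(aln),
    identity = identity,
    ref_window = c(start = Biostrings::start(Biostrings::subject(aln)),
                   end = Biostrings::end(Biostrings::subject(aln))),
    aligned_read = ap,
    aligned_ref = as_),
    class = "rpob_alignment")
}

# Left-normalize an indel against the reference CDS (VCF-style): shift the
# event to the smallest CDS position that preserves the altered sequence.
# For a deletion of ref[pos .. pos+L-1] a left shift is valid when
# ref[pos-1] == ref[pos+L-1]; for an insertion of `seq` after ref[pos]
# when ref[pos] == last base of seq (the inserted string rotates).
left_normalize_indel <- function(ref, kind, cds_pos, seq) {
  L <- nchar(seq)
  if (kind == "deletion") {
    while (cds_pos > 1 &&
           ref_base(ref, cds_pos - 1) == ref_base(ref, cds_pos + L - 1)) {
      cds_pos <- cds_pos - 1
      seq <- substring(ref$cds, cds_pos, cds_pos + L - 1)
    }
  } else {
    while (cds_pos >= 1 && cds_pos <= nchar(ref$cds) &&
           ref_base(ref, cds_pos) == substring(seq, L, L)) {
      seq <- paste0(substring(ref$cds, cds_pos, cds_pos),
                    substring(seq, 1, L - 1))
      cds_pos <- cds_pos - 1
      if (cds_pos == 0) break
    }
  }
  list(cds_pos = cds_pos, seq = seq)
}

empty_calls <- function() {
  data.frame(isolate_id = character(0), cds_pos = integer(0),
             kind = character(0), ref_allele = character(0),
             alt_allele = character(0), codon_number = integer(0),
             aa_change = character(0), cluster = character(0),
             frame_preserving = logical(0), stringsAsFactors = FALSE)
}

#' Extract variant calls from an alignment
#'
#' Walks the aligned columns: each mismatching base column yields one
#' substitution call, each gap run one insertion or deletion call. Read `N`
#' columns never produce calls. Indels are left-normalized against the
#' reference. Insertions are reported at the CDS position of the base
#' immediately to their left.
#'
#' @param aln an `rpob_alignment`.
#' @param ref the `rpob_reference` used for the alignment.
#' @return data.frame of calls (possibly zero rows) with columns
#'   `cds_pos`, `kind`, `ref_allele`, `alt_allele`, plus annotation columns
#'   filled by [annotate_call()].
#' @export
extract_variants <- function(aln, ref) {
  stopifnot(inherits(aln, "rpob_alignment"), inherits(ref, "rpob_reference"))
  pc <- strsplit(aln$aligned_read, "")[[1]]
  sc <- strsplit(aln$aligned_ref, "")[[1]]
  ref_pos <- unname(aln$ref_window["start"]) - 1L

  calls <- list()
  i <- 1L
  n <- length(pc)
  while (i <= n) {
    if (sc[i] != "-" && pc[i] != "-") {
      ref_pos <- ref_pos + 1L
      if (pc[i] != sc[i] && pc[i] != "N") {
        calls[[length(calls) + 1L]] <- list(
          cds_pos = ref_pos, kind = "substitution",
          ref_allele = sc[i], alt_allele = pc[i])
      }
      i <- i + 1L
    } else if (pc[i] == "-") {            # deletion from the read
      j <- i
      while (j <= n && pc[j] == "-") j <- j + 1L
      del_start <- ref_pos + 1L
      del_seq <- paste(sc[i:(j - 1L)], collapse = "")
      ref_pos <- ref_pos + (j - i)
      nrm <- left_normalize_indel(ref, "deletion", del_start, del_seq)
      calls[[length(calls) + 1L]] <- list(
        cds_pos = nrm$cds_pos, kind = "deletion",
        ref_allele = nrm$seq, alt_allele = "")
      i <- j
    } else {                              # insertion in the read
      j <- i
      while (j <= n && sc[j] == "-") j <- j + 1L
      ins_seq <- paste(pc[i:(j - 1L)], collapse = "")
      if (!grepl("N", ins_seq)) {
        nrm <- left_normalize_indel(ref, "insertion", ref_pos, ins_seq)
        calls[[length(calls) + 1L]] <- list(
          cds_pos = nrm$cds_pos, kind = "insertion",
          ref_allele = "", alt_allele = nrm$seq)
      }
      i <- j
    }
  }
  if (length(calls) == 0) return(empty_calls())
  out <- do.call(rbind, lapply(calls, function(x)
    data.frame(isolate_id = NA_character_, cds_pos = x$cds_pos,
               kind = x$kind, ref_allele = x$ref_allele,
               alt_allele = x$alt_allele, codon_number = NA_integer_,
               aa_change = NA_character_, cluster = NA_character_,
               frame_preserving = NA, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  annotate_call(out, ref)
}

#' Annotate variant calls with codon, amino-acid change and RRDR cluster
#'
#' Codon numbering is `ceiling(cds_pos / 3)`; cluster assignment uses the
#' inclusive RRDR nucleotide ranges; substitution amino-acid changes are
#' translated under the standard (bacterial) genetic code. Indels get an
#' empty `aa_change` and a `frame_preserving` flag (allele length difference
#' divisible by 3).
#'
#' @param call data.frame of calls as produced by [extract_variants()].
#' @param ref the `rpob_reference`.
#' @return the call data.frame with `codon_number`, `aa_change`, `cluster`
#'   and `frame_preserving` filled in.
#' @examples
#' ref <- rpob_reference()
#' call <- data.frame(isolate_id = "i1", cds_pos = 1520L,
#'                    kind = "substitution", ref_allele = "A",
#'                    alt_allele = "G")
#' # any of the annotation columns may be absent; they are (re)computed
#' annotate_call(call, ref)$cluster  # "I"
#' @export
annotate_call <- function(call, ref) {
  stopifnot(inherits(ref, "rpob_reference"))
  if (nrow(call) == 0) return(call)
  if (any(call$cds_pos < 1 | call$cds_pos > nchar(ref$cds)))
    stop_domain("cds_pos outside the reference CDS")
  call$codon_number <- as.integer(ceiling(call$cds_pos / 3))
  call$cluster <- rrdr_cluster_of(call$cds_pos)
  call$frame_preserving <- NA
  call$aa_change <- ""
  for (r in seq_len(nrow(call))) {
    if (call$kind[r] != "substitution") {
      # indels: cluster by overlap of the affected interval, so that a
      # left-normalized event starting just before a cluster but deleting
      # into it (or inserting between its first bases) is still assigned
      span_end <- if (call$kind[r] == "deletion")
        call$cds_pos[r] + nchar(call$ref_allele[r]) - 1L
      else min(call$cds_pos[r] + 1L, nchar(ref$cds))
      span <- rrdr_cluster_of(seq(call$cds_pos[r], span_end))
      hit <- span[span != "outside"]
      call$cluster[r] <- if (length(hit) > 0) hit[1] else "outside"
    }
    if (call$kind[r] == "substitution") {
      cn <- call$codon_number[r]
      codon <- codon_of(ref, cn)
      off <- call$cds_pos[r] - 3 * (cn - 1)
      mut <- codon
      substring(mut, off, off) <- call$alt_allele[r]
      call$aa_change[r] <- paste0(translate_codon(codon), cn,
                                  translate_codon(mut))
    } else {
      len_diff <- abs(nchar(call$ref_allele[r]) - nchar(call$alt_allele[r]))
      call$frame_preserving[r] <- len_diff %% 3 == 0
    }
  }
  call
}
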