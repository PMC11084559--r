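ref <- rpob_reference()

test_that("RRDR coordinates reproduce the amino-acid/nucleotide pairings", {
  expect_equal(ceiling(1520 / 3), 507)
  expect_equal(ceiling(1598 / 3), 533)
  expect_equal(ceiling(1687 / 3), 563)
  expect_equal(ceiling(1715 / 3), 572)
  expect_equal(ceiling(2060 / 3), 687)
  expect_equal(ceiling(2061 / 3), 687)
  # cluster assignment follows the published inclusive nucleotide ranges
  expect_equal(rrdr_cluster_of(c(1520, 1598, 1650, 1687, 1715, 2060, 2062, 100)),
               c("I", "I", "outside", "II", "II", "III", "III", "outside"))
})

test_that("synthetic reference has the accession window geometry", {
  expect_equal(nchar(ref$cds), 4029)     # 1343 codons
  expect_equal(ref$genome_offset, 4181245L)
  expect_true(ref$synthetic)
  expect_false(grepl("[^ACGT]", ref$cds))
  # deterministic across calls and independent of the caller's RNG
  set.seed(1); a <- rpob_reference()$cds
  set.seed(2); b <- rpob_reference()$cds
  expect_identical(a, b)
})

test_that("exact substring aligns perfectly on either strand", {
  read <- substring(ref$cds, 1400, 1900)
  aln <- orient_and_align(read, ref)
  expect_equal(aln$strand_used, "forward")
  expect_equal(aln$identity, 1)
  expect_equal(aln$score, 2 * nchar(read))
  expect_equal(unname(aln$ref_window), c(1400, 1900))
  expect_equal(nrow(extract_variants(aln, ref)), 0)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  aln2 <- orient_and_align(rc, ref)
  expect_equal(aln2$strand_used, "reverse-complement")
  expect_equal(aln2$score, aln$score)
})

test_that("an all-N read is rejected as unalignable", {
  expect_error(orient_and_align(strrep("N", 300), ref), "unalignable")
})

test_that("a planted substitution is called at the planted site", {
  read <- substring(ref$cds, 1400, 1900)
  pos <- 1565; off <- pos - 1400 + 1
  rb <- substring(read, off, off)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  substring(read, off, off) <- ab
  v <- extract_variants(orient_and_align(read, ref), ref)
  expect_equal(nrow(v), 1)
  expect_equal(v$cds_pos, 1565)
  expect_equal(v$kind, "substitution")
  expect_equal(v$ref_allele, rb)
  expect_equal(v$alt_allele, ab)
  expect_equal(v$cluster, "I")
  expect_equal(v$codon_number, 522)
  # reverse-complement of the same read yields the identical call
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  v2 <- extract_variants(orient_and_align(rc, ref), ref)
  expect_equal(v[, c("cds_pos", "kind", "ref_allele", "alt_allele")],
               v2[, c("cds_pos", "kind", "ref_allele", "alt_allele")])
})

test_that("a read N position never becomes a variant call", {
  read <- substring(ref$cds, 1400, 1900)
  substring(read, 166, 166) <- "N"
  v <- extract_variants(orient_and_align(read, ref), ref)
  expect_equal(nrow(v), 0)
})

test_that("an in-frame deletion inside cluster I is called frame-preserving", {
  read <- substring(ref$cds, 1400, 1900)
  off <- 1530 - 1400 + 1
  read <- paste0(substring(read, 1, off - 1), substring(read, off + 3))
  v <- extract_variants(orient_and_align(read, ref), ref)
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "deletion")
  expect_true(v$frame_preserving)
  expect_equal(v$cluster, "I")
  expect_equal(nchar(v$ref_allele), 3)
})

test_that("indels are left-normalized against the reference", {
  # use a homopolymer context so the raw gap placement is ambiguous
  runs <- gregexpr("A{3,}", ref$cds)[[1]]
  i <- which(as.integer(runs) > 150)[1]   # interior run, window fits
  pos <- as.integer(runs)[i]
  L <- attr(runs, "match.length")[i]
  win <- c(pos - 100, pos + 100)
  read <- substring(ref$cds, win[1], win[2])
  # delete the *last* base of the run; normalized call must sit at run start
  del_at <- pos + L - 1
  off <- del_at - win[1] + 1
  read <- paste0(substring(read, 1, off - 1), substring(read, off + 1))
  v <- extract_variants(orient_and_align(read, ref), ref)
  expect_equal(nrow(v), 1)
  expect_equal(v$cds_pos, as.integer(pos))
  expect_equal(v$ref_allele, "A")
})

test_that("annotation translates codons and fills cluster labels", {
  call <- data.frame(isolate_id = "x", cds_pos = 1520L,
                     kind = "substitution",
                     ref_allele = ref_base <- substring(ref$cds, 1520, 1520),
                     alt_allele = setdiff(c("A", "C", "G", "T"), ref_base)[1],
                     stringsAsFactors = FALSE)
  ann <- annotate_call(call, ref)
  expect_equal(ann$codon_number, 507L)
  expect_equal(ann$cluster, "I")
  expect_match(ann$aa_change, "^[A-Z*]507[A-Z*]$")
  expect_error(annotate_call(transform(call, cds_pos = 99999L), ref),
               "outside")
})

test_that("per-isolate tables include none_detected and VCF positions", {
  reads <- c(i1 = substring(ref$cds, 1400, 1900),
             i2 = substring(ref$cds, 1400, 1900),
             i3 = substring(ref$cds, 1400, 1900))
  substring(reads["i1"], 166, 166) <-
    setdiff(c("A", "C", "G", "T"), substring(reads["i1"], 166, 166))[1]
  substring(reads["i2"], 300, 300) <-
    setdiff(c("A", "C", "G", "T"), substring(reads["i2"], 300, 300))[1]
  meta <- data.frame(isolate_id = c("i1", "i2", "i3"),
                     strain = "MG1655", glucose = "low",
                     stringsAsFactors = FALSE)
  calls <- call_rpob_reads(reads, ref, meta)
  expect_equal(nrow(calls), 3)
  expect_equal(sum(calls$category == "none_detected"), 1)
  expect_equal(calls$cds_pos[calls$isolate_id == "i1"], 1565)
  vcf <- tempfile(fileext = ".vcf")
  calls_to_tables(calls, ref, vcf = vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2)
  pos1 <- as.integer(strsplit(body[1], "\t")[[1]][2])
  expect_equal(pos1, 4181245L + 1565L - 1L)  # 4182809
  expect_error(call_rpob_reads(reads, ref, meta[1:2, ]), "i3")
})

test_that("calling is strand-invariant across a batch of planted reads", {
  cfg <- study_config(n_isolates = 8, detection_prob = 1)
  iso <- gen_isolate_reads(cfg, ref, seed = 77)
  rc <- vapply(iso$reads, function(r)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(r))), "")
  names(rc) <- names(iso$reads)
  c1 <- call_rpob_reads(iso$reads, ref, iso$metadata)
  c2 <- call_rpob_reads(rc, ref, iso$metadata)
  cols <- c("isolate_id", "cds_pos", "kind", "ref_allele", "alt_allele",
            "category")
  expect_equal(c1[, cols], c2[, cols])
})
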