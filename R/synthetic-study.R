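#' Configuration of a synthetic fluctuation + spectrum study
#'
#' Builds the full parameter set for a two-strain (wild-type MG1655 and a
#' luxS deletant) by two-glucose-level (low, high) study with known ground
#' truth. Defaults emulate the design of a typical rifampicin fluctuation
#' assay: 182 parallel cultures per condition, final population size 1e8
#' cells per culture estimated from 3 replicate platings (lognormal, 10%
#' CV), mutation rates around 1e-8 per cell per generation with a
#' low-to-high ratio preset of 1.60 for the wild type and 1.06 for the
#' deletant, 68 sequenced isolates per condition of which a fraction
#' 214/274 carry a detectable RRDR mutation, and condition-dependent
#' 8-category spectrum probabilities in which AT>GC transitions are
#' elevated at low glucose (0.45 vs 0.25) and GC>TA transversions are
#' elevated in the deletant.
#'
#' @param strains length-2 character vector of strain labels.
#' @param n_cultures parallel cultures per condition.
#' @param n_cfu_replicates CFU plating replicates per condition.
#' @param cfu_noise_cv lognormal coefficient of variation of CFU totals.
#' @param Nt_true final population size per culture (cells).
#' @param mu_true named list `strain -> c(low, high)` mutation rates per
#'   cell per generation.
#' @param fitness_true mutant relative fitness used by the simulator.
#' @param spectrum_probs named list `"strain.glucose" -> 8 probabilities`
#'   in canonical category order, each summing to 1.
#' @param n_isolates sequenced isolates per condition.
#' @param detection_prob probability that an isolate's mutation lies in the
#'   sequenced window.
#' @param read_window CDS interval covered by the synthetic Sanger read
#'   (default spans RRDR clusters I and II).
#' @param read_error_rate per-base substitution error rate of reads.
#' @return a list of class `study_config`.
#' @export
study_config <- function(strains = c("MG1655", "dluxS"),
                         n_cultures = 182,
                         n_cfu_replicates = 3,
                         cfu_noise_cv = 0.1,
                         Nt_true = 1e8,
                         mu_true = NULL,
                         fitness_true = 1,
                         spectrum_probs = NULL,
                         n_isolates = 68,
                         detection_prob = 214 / 274,
                         read_window = c(1400, 1900),
                         read_error_rate = 0) {
  if (is.null(mu_true))
    mu_true <- stats::setNames(
      list(c(low = 1.6e-8, high = 1.0e-8),
           c(low = 1.06e-8, high = 1.0e-8)), strains)
  if (is.null(spectrum_probs)) {
    sp <- list(
      c(0.45, 0.10, 0.10, 0.10, 0.03, 0.12, 0.04, 0.06),  # wt low
      c(0.25, 0.14, 0.12, 0.12, 0.04, 0.17, 0.06, 0.10),  # wt high
      c(0.45, 0.08, 0.09, 0.09, 0.03, 0.22, 0.02, 0.02),  # del low
      c(0.25, 0.10, 0.10, 0.10, 0.03, 0.36, 0.03, 0.03))  # del high
    spectrum_probs <- stats::setNames(sp, c(
      paste(strains[1], c("low", "high"), sep = "."),
      paste(strains[2], c("low", "high"), sep = ".")))
  }
  for (p in spectrum_probs) {
    if (length(p) != 8 || abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop_domain("each spectrum_probs entry must be 8 probabilities summing to 1")
  }
  if (detection_prob < 0 || detection_prob > 1)
    stop_domain("detection_prob must be in [0, 1]")
  structure(list(strains = strains, glucose = c("low", "high"),
                 n_cultures = n_cultures,
                 n_cfu_replicates = n_cfu_replicates,
                 cfu_noise_cv = cfu_noise_cv, Nt_true = Nt_true,
                 mu_true = mu_true, fitness_true = fitness_true,
                 spectrum_probs = spectrum_probs,
                 n_isolates = n_isolates,
                 detection_prob = detection_prob,
                 read_window = read_window,
                 read_error_rate = read_error_rate),
            class = "study_config")
}

condition_grid <- function(config) {
  expand.grid(strain = config$strains, glucose = config$glucose,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Generate fluctuation-assay counts and CFU totals with ground truth
#'
#' Mutant counts are Luria-Delbruck distributed (via [simulate_counts()])
#' with `m_true = mu_true * Nt_true` per condition; CFU replicate totals
#' are lognormal around `Nt_true` with the configured CV.
#'
#' @param config a `study_config`.
#' @param seed integer seed; the whole study is a pure function of
#'   `(config, seed)`.
#' @return list with `counts` (strain, glucose, culture_id, mutant_count),
#'   `cfu` (strain, glucose, replicate, cfu_total) and `truth`
#'   (per-condition `m_true`, `mu_true`).
#' @export
gen_fluctuation_study <- function(config, seed = 0) {
  stopifnot(inherits(config, "study_config"))
  grid <- condition_grid(config)
  cv <- config$cfu_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config$Nt_true) - sdlog^2 / 2
  counts <- list(); cfu <- list(); truth <- list()
  for (i in seq_len(nrow(grid))) {
    st <- grid$strain[i]; gl <- grid$glucose[i]
    mu <- config$mu_true[[st]][[gl]]
    m <- mu * config$Nt_true
    cts <- simulate_counts(config$n_cultures, m, config$fitness_true,
                           seed = seed * 1000L + i)
    reps <- local_seed(seed * 1000L + 500L + i,
                       stats::rlnorm(config$n_cfu_replicates, meanlog, sdlog))
    counts[[i]] <- data.frame(strain = st, glucose = gl,
                              culture_id = seq_along(cts),
                              mutant_count = cts,
                              stringsAsFactors = FALSE)
    cfu[[i]] <- data.frame(strain = st, glucose = gl,
                           replicate = seq_along(reps), cfu_total = reps,
                           stringsAsFactors = FALSE)
    truth[[paste(st, gl, sep = ".")]] <- list(m_true = m, mu_true = mu)
  }
  list(counts = do.call(rbind, counts), cfu = do.call(rbind, cfu),
       truth = truth)
}

# compatible planting sites inside RRDR clusters I/II for each category
category_sites <- function(config, ref) {
  win <- config$read_window
  cl <- rrdr_clusters()
  rrdr_pos <- unlist(lapply(1:2, function(i) {
    lo <- max(cl$nt_start[i], win[1]); hi <- min(cl$nt_end[i], win[2])
    if (lo > hi) integer(0) else seq(lo, hi)
  }))
  if (length(rrdr_pos) == 0)
    return(stats::setNames(rep(list(integer(0)), 8), mutation_categories()))
  base_at <- strsplit(ref$cds, "")[[1]][rrdr_pos]
  at_sites <- rrdr_pos[base_at %in% c("A", "T")]
  gc_sites <- rrdr_pos[base_at %in% c("G", "C")]
  # indels: whole-codon events fully inside a cluster
  codon_starts <- rrdr_pos[(rrdr_pos %% 3) == 1 &
                             (rrdr_pos + 2) %in% rrdr_pos]
  list("AT>GC" = at_sites, "AT>CG" = at_sites, "AT>TA" = at_sites,
       "GC>AT" = gc_sites, "GC>CG" = gc_sites, "GC>TA" = gc_sites,
       insertion = codon_starts, deletion = codon_starts)
}

snv_alt <- function(category, ref_base) {
  switch(category,
         "AT>GC" = c(A = "G", T = "C")[ref_base],
         "GC>AT" = c(G = "A", C = "T")[ref_base],
         "AT>CG" = c(A = "C", T = "G")[ref_base],
         "AT>TA" = c(A = "T", T = "A")[ref_base],
         "GC>CG" = c(G = "C", C = "G")[ref_base],
         "GC>TA" = c(G = "T", C = "A")[ref_base])
}

#' Generate synthetic isolate reads with planted rpoB mutations
#'
#' Each isolate is "detected" with probability `detection_prob`; detected
#' isolates get one mutation planted at a random compatible RRDR cluster
#' I/II site, with category drawn from the condition's spectrum
#' probabilities (indels are whole-codon, frame-preserving events).
#' The read is the reference window with the mutation applied, optional
#' uniform base errors, and a random strand orientation. Planted indel
#' records are left-normalized so that recovery can be compared in
#' canonical coordinates.
#'
#' @param config a `study_config`.
#' @param ref an `rpob_reference`.
#' @param seed integer seed.
#' @return list with `reads` (named character vector), `metadata`
#'   (isolate_id, strain, glucose) and `truth` (one row per isolate:
#'   planted `cds_pos`, `kind`, `ref_allele`, `alt_allele`, `category`, or
#'   `category = "none"` for undetected isolates).
#' @export
gen_isolate_reads <- function(config, ref, seed = 0) {
  stopifnot(inherits(config, "study_config"), inherits(ref, "rpob_reference"))
  sites <- category_sites(config, ref)
  cats <- mutation_categories()
  grid <- condition_grid(config)
  win <- config$read_window
  window_seq <- substring(ref$cds, win[1], win[2])

  reads <- character(0); meta <- list(); truth <- list()
  local_seed(seed, {
    for (i in seq_len(nrow(grid))) {
      st <- grid$strain[i]; gl <- grid$glucose[i]
      probs <- config$spectrum_probs[[paste(st, gl, sep = ".")]]
      active <- cats[probs > 0]
      for (a in active)
        if (length(sites[[a]]) == 0)
          stop_domain("no compatible site for category ", a)
      for (j in seq_len(config$n_isolates)) {
        id <- sprintf("%s_%s_%03d", st, gl, j)
        detected <- stats::runif(1) < config$detection_prob
        read <- window_seq
        rec <- data.frame(isolate_id = id, strain = st, glucose = gl,
                          cds_pos = NA_integer_, kind = NA_character_,
                          ref_allele = NA_character_,
                          alt_allele = NA_character_,
                          category = "none", stringsAsFactors = FALSE)
        if (detected) {
          cat_j <- sample(cats, 1, prob = probs)
          pos <- sites[[cat_j]][sample.int(length(sites[[cat_j]]), 1)]
          off <- pos - win[1] + 1
          if (cat_j %in% cats[1:6]) {
            rb <- substring(read, off, off)
            ab <- unname(snv_alt(cat_j, rb))
            substring(read, off, off) <- ab
            rec[, c("cds_pos", "kind", "ref_allele", "alt_allele",
                    "category")] <-
              list(pos, "substitution", rb, ab, cat_j)
          } else if (cat_j == "deletion") {
            del_seq <- substring(read, off, off + 2)
            read <- paste0(substring(read, 1, off - 1),
                           substring(read, off + 3))
            nrm <- left_normalize_indel(ref, "deletion", pos, del_seq)
            rec[, c("cds_pos", "kind", "ref_allele", "alt_allele",
                    "category")] <-
              list(nrm$cds_pos, "deletion", nrm$seq, "", cat_j)
          } else {
            ins_seq <- paste(sample(c("A", "C", "G", "T"), 3,
                                    replace = TRUE), collapse = "")
            read <- paste0(substring(read, 1, off),
                           ins_seq, substring(read, off + 1))
            nrm <- left_normalize_indel(ref, "insertion", pos, ins_seq)
            rec[, c("cds_pos", "kind", "ref_allele", "alt_allele",
                    "category")] <-
              list(nrm$cds_pos, "insertion", "", nrm$seq, cat_j)
          }
        }
        if (config$read_error_rate > 0) {
          nt <- strsplit(read, "")[[1]]
          err <- stats::runif(length(nt)) < config$read_error_rate
          if (any(err))
            nt[err] <- vapply(nt[err], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
          read <- paste(nt, collapse = "")
        }
        if (stats::runif(1) < 0.5)
          read <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(read)))
        reads[id] <- read
        meta[[length(meta) + 1]] <- data.frame(
          isolate_id = id, strain = st, glucose = gl,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- rec
      }
    }
  })
  list(reads = reads, metadata = do.call(rbind, meta),
       truth = do.call(rbind, truth))
}

#' Draw spectrum counts directly from the configured probabilities
#'
#' Fast path for statistical testing: per condition the categorized-isolate
#' counts are one multinomial draw, bypassing read generation.
#'
#' @param config a `study_config`.
#' @param seed integer seed.
#' @param n_isolates override of isolates per condition (defaults to the
#'   config value).
#' @return list with `table` (a `spectrum_table`) and `truth` (the
#'   probability vectors used).
#' @export
gen_spectrum_counts <- function(config, seed = 0, n_isolates = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(n_isolates)) n_isolates <- config$n_isolates
  grid <- condition_grid(config)
  cats <- mutation_categories()
  rows <- list()
  local_seed(seed, {
    for (i in seq_len(nrow(grid))) {
      st <- grid$strain[i]; gl <- grid$glucose[i]
      probs <- config$spectrum_probs[[paste(st, gl, sep = ".")]]
      cts <- as.vector(stats::rmultinom(1, n_isolates, probs))
      rows[[i]] <- data.frame(category = cats, strain = st, glucose = gl,
                              count = cts, stringsAsFactors = FALSE)
    }
  })
  list(table = as_spectrum_table(do.call(rbind, rows)),
       truth = config$spectrum_probs)
}

#' Write a generated study to disk in the formats the pipeline reads
#'
#' @param study output of [gen_fluctuation_study()].
#' @param isolates output of [gen_isolate_reads()] (optional).
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_study <- function(study, isolates = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             cfu = file.path(dir, "cfu.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(study$counts, paths["counts"], row.names = FALSE)
  utils::write.csv(study$cfu, paths["cfu"], row.names = FALSE)
  truth <- study$truth
  if (!is.null(isolates)) {
    paths <- c(paths, reads = file.path(dir, "reads.fasta"),
               metadata = file.path(dir, "metadata.csv"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(isolates$reads), paths["reads"])
    utils::write.csv(isolates$metadata, paths["metadata"],
                     row.names = FALSE)
    truth <- list(rates = truth, isolates = isolates$truth)
  }
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
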