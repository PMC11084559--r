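#' Estimate mutation rates for every condition of a study
#'
#' @param counts data.frame with columns `strain`, `glucose`, `mutant_count`
#'   (and optionally `culture_id`).
#' @param cfu data.frame with columns `strain`, `glucose`, `cfu_total`.
#' @param method `"ml"` or `"p0"`.
#' @param fitness_mode passed to [fluctuation_ml()].
#' @param winsor_cap passed to [fluctuation_ml()].
#' @return data.frame with one row per condition: `strain`, `glucose`,
#'   `n_cultures`, `m_hat`, `se_m`, `Nt`, `mu_hat`, `se_mu`, `method`,
#'   `fitness_mode`.
#' @export
estimate_rates <- function(counts, cfu, method = c("ml", "p0"),
                           fitness_mode = "fixed", winsor_cap = 1024) {
  method <- match.arg(method)
  need <- c("strain", "glucose", "mutant_count")
  if (!all(need %in% names(counts)))
    stop_domain("counts needs columns ", paste(need, collapse = ", "))
  if (!all(c("strain", "glucose", "cfu_total") %in% names(cfu)))
    stop_domain("cfu needs columns strain, glucose, cfu_total")
  grid <- unique(counts[, c("strain", "glucose")])
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    sel <- counts$strain == grid$strain[i] & counts$glucose == grid$glucose[i]
    cc <- counts$mutant_count[sel]
    fit <- if (method == "ml")
      fluctuation_ml(cc, fitness_mode = fitness_mode,
                     winsor_cap = winsor_cap)
    else fluctuation_p0(cc)
    selc <- cfu$strain == grid$strain[i] & cfu$glucose == grid$glucose[i]
    rate <- rate_from_m(fit, cfu$cfu_total[selc])
    rows[[i]] <- data.frame(
      strain = grid$strain[i], glucose = grid$glucose[i],
      n_cultures = length(cc), m_hat = rate$m_hat, se_m = rate$se_m,
      Nt = rate$Nt, mu_hat = rate$mu_hat, se_mu = rate$se_mu,
      method = method, fitness_mode = fit$fitness_mode,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare low-to-high rate ratios within and between strains
#'
#' @param rates data.frame from [estimate_rates()] with both glucose levels
#'   for each strain.
#' @param contrast_sidedness sidedness of the between-strain z-test
#'   (default one-sided, first strain's ratio hypothesised larger).
#' @return list with `ratios` (named list of `rate_ratio` + test), and
#'   `contrast` (a `ratio_contrast`).
#' @export
compare_rates <- function(rates, contrast_sidedness = "greater") {
  strains <- unique(rates$strain)
  ratios <- list()
  for (st in strains) {
    lo <- rates[rates$strain == st & rates$glucose == "low", ]
    hi <- rates[rates$strain == st & rates$glucose == "high", ]
    if (nrow(lo) != 1 || nrow(hi) != 1)
      stop_domain("strain ", st, " needs exactly one low and one high row")
    rr <- sigma_ratio(lo$mu_hat, hi$mu_hat, lo$se_mu, hi$se_mu)
    tst <- z_ratio_vs_1(rr)
    ratios[[st]] <- c(rr, tst)
  }
  contrast <- if (length(strains) == 2)
    z_ratio_diff(structure(ratios[[1]], class = "rate_ratio"),
                 structure(ratios[[2]], class = "rate_ratio"),
                 sidedness = contrast_sidedness)
  else NULL
  list(ratios = ratios, contrast = contrast)
}

#' Run the full synthetic-study pipeline
#'
#' Generates (or loads) a study, then executes estimate -> compare ->
#' call -> tabulate -> test, returning every stage's result plus a
#' provenance block. The run is a pure function of `(config, seed)`: data
#' outputs are identical across reruns (timestamps excluded).
#'
#' @param config a `study_config`, or the path to a YAML file whose keys
#'   are [study_config()] arguments, or `NULL` for defaults.
#' @param seed integer seed for all generation.
#' @param ref an `rpob_reference` (synthetic stand-in by default).
#' @param outdir if non-NULL, the report is written there as
#'   `report.json` plus CSV mirrors.
#' @return object of class `study_report`: `rates`, `comparison`,
#'   `calls`, `spectrum`, `tests`, `truth`, `provenance`.
#' @export
run_full <- function(config = NULL, seed = 0, ref = rpob_reference(),
                     outdir = NULL) {
  config <- load_config(config)
  study <- gen_fluctuation_study(config, seed = seed)
  isolates <- gen_isolate_reads(config, ref, seed = seed + 1)

  rates <- estimate_rates(study$counts, study$cfu)
  comparison <- compare_rates(rates)
  calls <- call_rpob_reads(isolates$reads, ref, isolates$metadata)
  spectrum <- relative_frequencies(tabulate_spectrum(calls))
  tests <- test_spectrum(tabulate_spectrum(calls))

  provenance <- list(
    package = "fluctspec",
    version = as.character(utils::packageVersion("fluctspec")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  rep <- structure(list(rates = rates, comparison = comparison,
                        calls = calls, spectrum = spectrum, tests = tests,
                        truth = study$truth,
                        isolate_truth = isolates$truth,
                        provenance = provenance),
                   class = "study_report")
  if (!is.null(outdir)) write_report(rep, outdir)
  rep
}

load_config <- function(config) {
  if (is.null(config)) return(study_config())
  if (inherits(config, "study_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop_domain("config file not found: ", config)
    args <- yaml::read_yaml(config)
    return(do.call(study_config, args))
  }
  if (is.list(config)) return(do.call(study_config, config))
  stop_domain("cannot interpret 'config'")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(config)),
                   collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$rates, file.path(outdir, "rates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$calls, file.path(outdir, "calls.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$spectrum),
                   file.path(outdir, "spectrum.csv"), row.names = FALSE)
  utils::write.csv(report$tests, file.path(outdir, "tests.csv"),
                   row.names = FALSE)
  json <- list(rates = report$rates,
               ratios = lapply(report$comparison$ratios, function(r)
                 r[c("R", "var_R", "ci95", "z", "p", "sidedness")]),
               contrast = unclass(report$comparison$contrast),
               tests = report$tests,
               truth = report$truth,
               provenance = report$provenance)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Fluctuation + spectrum study report ==\n\n")
  cat("Mutation rates (per cell per generation):\n")
  print(x$rates, digits = 4)
  cat("\nLow-to-high ratios:\n")
  for (st in names(x$comparison$ratios)) {
    r <- x$comparison$ratios[[st]]
    cat(sprintf("  %s: R = %.3f (95%% CI %.3f, %.3f), z = %.2f, p = %s\n",
                st, r$R, r$ci95[1], r$ci95[2], r$z, format_p(r$p)))
  }
  if (!is.null(x$comparison$contrast)) {
    ct <- x$comparison$contrast
    cat(sprintf("  contrast: Z = %.2f, P = %s (%s)\n",
                ct$z, format_p(ct$p), ct$sidedness))
  }
  n_cat <- sum(x$calls$category != "none_detected")
  cat(sprintf("\nIsolates: %d sequenced, %d with an RRDR mutation\n",
              length(unique(x$calls$isolate_id)), n_cat))
  cat("\nSpectrum tests (Type-II likelihood-ratio chi-square):\n")
  tt <- x$tests
  tt$p <- format_p(tt$p)
  print(tt, digits = 3)
  invisible(x)
}
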