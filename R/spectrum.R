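#' Mutation categories
#'
#' The eight canonical categories: the six strand-collapsed SNV classes
#' (transitions AT>GC and GC>AT; transversions AT>CG, AT>TA, GC>CG, GC>TA)
#' plus one pooled insertion and one pooled deletion category.
#'
#' @return character vector of the 8 category labels, canonical order.
#' @export
mutation_categories <- function() {
  c("AT>GC", "GC>AT", "AT>CG", "AT>TA", "GC>CG", "GC>TA",
    "insertion", "deletion")
}

#' Classify a substitution into its strand-collapsed SNV class
#'
#' A mutation and its reverse-strand complement are the same biological
#' event, so the twelve ordered base changes collapse to six classes:
#' A>G and T>C are both AT>GC, and so on.
#'
#' @param ref_base,alt_base vectors of single bases (A/C/G/T), `ref != alt`
#'   elementwise.
#' @return character vector of SNV classes.
#' @examples
#' classify_substitution(c("A", "T", "C"), c("G", "C", "A"))
#' @export
classify_substitution <- function(ref_base, alt_base) {
  map <- c("A>G" = "AT>GC", "T>C" = "AT>GC",
           "G>A" = "GC>AT", "C>T" = "GC>AT",
           "A>C" = "AT>CG", "T>G" = "AT>CG",
           "A>T" = "AT>TA", "T>A" = "AT>TA",
           "G>C" = "GC>CG", "C>G" = "GC>CG",
           "G>T" = "GC>TA", "C>A" = "GC>TA")
  key <- paste0(toupper(ref_base), ">", toupper(alt_base))
  out <- map[key]
  if (anyNA(out))
    stop_domain("invalid substitution: ",
                paste(key[is.na(out)], collapse = ", "))
  unname(out)
}

#' Tabulate the mutational spectrum
#'
#' Counts categorized isolates over category x strain x glucose. Isolates
#' with `category == "none_detected"` are excluded (they carry no observed
#' RRDR mutation).
#'
#' @param calls data.frame with columns `category`, `strain`, `glucose`
#'   (e.g. from [call_rpob_reads()]), one row per categorized isolate; or a
#'   pre-tabulated data.frame that additionally has a `count` column.
#' @return object of class `spectrum_table`: a long data.frame
#'   (`category`, `strain`, `glucose`, `count`) covering every combination,
#'   categories in canonical order.
#' @export
tabulate_spectrum <- function(calls) {
  cats <- mutation_categories()
  keep <- calls$category != "none_detected"
  calls <- calls[keep, , drop = FALSE]
  bad <- setdiff(unique(calls$category), cats)
  if (length(bad) > 0)
    stop_domain("unknown categories: ", paste(bad, collapse = ", "))
  if (nrow(calls) == 0) {
    out <- data.frame(category = factor(character(0), levels = cats),
                      strain = character(0), glucose = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("spectrum_table", "data.frame")))
  }
  strains <- sort(unique(as.character(calls$strain)))
  glucoses <- sort(unique(as.character(calls$glucose)))
  f_cat <- factor(calls$category, levels = cats)
  f_str <- factor(as.character(calls$strain), levels = strains)
  f_glu <- factor(as.character(calls$glucose), levels = glucoses)
  tab <- if ("count" %in% names(calls)) {
    stats::xtabs(count ~ f_cat + f_str + f_glu,
                 data = data.frame(count = calls$count, f_cat, f_str, f_glu))
  } else {
    table(f_cat, f_str, f_glu)
  }
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("category", "strain", "glucose", "count")
  out$category <- factor(out$category, levels = cats)
  out <- out[order(match(out$category, cats), out$strain, out$glucose), ]
  rownames(out) <- NULL
  structure(out, class = c("spectrum_table", "data.frame"))
}

#' Build a spectrum table from explicit counts
#'
#' @param counts data.frame with columns `category`, `strain`, `glucose`,
#'   `count`.
#' @return a `spectrum_table`.
#' @export
as_spectrum_table <- function(counts) {
  needed <- c("category", "strain", "glucose", "count")
  if (!all(needed %in% names(counts)))
    stop_domain("need columns ", paste(needed, collapse = ", "))
  tabulate_spectrum(counts)
}

#' Per-condition relative frequencies of the spectrum
#'
#' Because conditions yield unequal numbers of categorized isolates, the
#' spectrum is compared on relative frequencies: within each strain x
#' glucose condition the eight counts are divided by their total.
#'
#' @param table a `spectrum_table`.
#' @return the table with a `freq` column; conditions with zero isolates
#'   get `NA` frequencies and a warning.
#' @export
relative_frequencies <- function(table) {
  stopifnot(inherits(table, "spectrum_table"))
  key <- interaction(table$strain, table$glucose, drop = TRUE)
  totals <- tapply(table$count, key, sum)
  tot <- as.numeric(totals[as.character(key)])
  if (any(totals == 0))
    warning("conditions with no categorized isolates: ",
            paste(names(totals)[totals == 0], collapse = ", "),
            "; frequencies undefined there")
  table$freq <- ifelse(tot > 0, table$count / tot, NA_real_)
  table
}

#' @export
print.spectrum_table <- function(x, ...) {
  wide <- stats::xtabs(count ~ category + interaction(strain, glucose, sep = "/"),
                       data = x)
  cat("Mutational spectrum (counts):\n")
  print(wide)
  invisible(x)
}

#' Plot spectrum relative frequencies
#'
#' Minimal grouped-bar summary of per-condition category frequencies.
#'
#' @param x a `spectrum_table`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.spectrum_table <- function(x, ...) {
  ft <- relative_frequencies(x)
  m <- stats::xtabs(freq ~ interaction(strain, glucose, sep = "/") + category,
                    data = ft)
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = rownames(m),
                    ylab = "relative frequency", ...)
  invisible(x)
}
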