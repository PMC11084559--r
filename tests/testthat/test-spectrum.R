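test_that("substitution classification is total and complement-invariant", {
  expect_equal(classify_substitution("A", "G"), "AT>GC")
  expect_equal(classify_substitution("T", "C"), "AT>GC")
  expect_equal(classify_substitution("C", "A"), "GC>TA")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  for (r in bases) for (a in setdiff(bases, r)) {
    cls <- classify_substitution(r, a)
    expect_true(cls %in% mutation_categories()[1:6])
    expect_equal(classify_substitution(comp[r], comp[a]), cls)
  }
  expect_error(classify_substitution("A", "A"), "invalid")
  expect_error(classify_substitution("A", "X"), "invalid")
})

test_that("tabulation partitions categorized isolates and drops none_detected", {
  calls <- data.frame(
    category = c("AT>GC", "AT>GC", "GC>TA", "none_detected"),
    strain = "MG1655", glucose = "low", stringsAsFactors = FALSE)
  tab <- tabulate_spectrum(calls)
  expect_s3_class(tab, "spectrum_table")
  expect_equal(sum(tab$count), 3)
  expect_equal(tab$count[tab$category == "AT>GC"], 2)
  expect_equal(tab$count[tab$category == "GC>TA"], 1)
  empty <- tabulate_spectrum(calls[0, ])
  expect_equal(sum(empty$count), 0)
  expect_error(tabulate_spectrum(transform(calls, category = "weird")),
               "unknown")
})

test_that("tabulated frequencies track generator truth", {
  cfg <- study_config()
  gen <- gen_spectrum_counts(cfg, seed = 3, n_isolates = 500)
  ft <- relative_frequencies(gen$table)
  for (key in names(gen$truth)) {
    parts <- strsplit(key, "\\.")[[1]]
    sel <- ft$strain == parts[1] & ft$glucose == parts[2]
    p <- gen$truth[[key]]
    se <- sqrt(p * (1 - p) / 500)
    expect_true(all(abs(ft$freq[sel] - p) <= 3 * pmax(se, 1e-3)))
  }
})

test_that("relative frequencies sum to one per condition", {
  tab <- make_spectrum(list("A.low" = c(2, 0, 0, 0, 0, 1, 0, 0),
                            "A.high" = c(5, 1, 1, 1, 0, 0, 1, 1)))
  ft <- relative_frequencies(tab)
  expect_equal(ft$freq[ft$glucose == "low"][1], 2 / 3)
  sums <- tapply(ft$freq, interaction(ft$strain, ft$glucose), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  tab0 <- make_spectrum(list("A.low" = rep(0, 8),
                             "A.high" = c(5, 1, 1, 1, 0, 0, 1, 1)))
  expect_warning(ft0 <- relative_frequencies(tab0), "undefined")
  expect_true(all(is.na(ft0$freq[ft0$glucose == "low"])))
})

test_that("intercept-only multinomial MLE equals observed frequencies", {
  tab <- make_spectrum(list("A.low" = c(12, 5, 3, 2, 1, 6, 2, 1)))
  fit <- fit_multinomial(tab, ~ 1)
  expect_true(fit$converged)
  expect_equal(as.vector(fit$fitted[1, ]),
               c(12, 5, 3, 2, 1, 6, 2, 1) / 32, tolerance = 1e-9)
})

test_that("model nesting: richer multinomial models never lose likelihood", {
  set.seed(5)
  tab <- make_spectrum(list(
    "A.low" = as.vector(rmultinom(1, 80, rep(1 / 8, 8))),
    "A.high" = as.vector(rmultinom(1, 90, rep(1 / 8, 8))),
    "B.low" = as.vector(rmultinom(1, 70, rep(1 / 8, 8))),
    "B.high" = as.vector(rmultinom(1, 60, rep(1 / 8, 8)))))
  ll <- function(f) fit_multinomial(tab, f)$logLik
  expect_gte(ll(~ glucose + strain) + 1e-9, ll(~ glucose))
  expect_gte(ll(~ glucose * strain) + 1e-9, ll(~ glucose + strain))
})

test_that("single-predictor multinomial LR equals the classical G statistic", {
  set.seed(6)
  for (rep in 1:5) {
    c1 <- as.vector(rmultinom(1, 120, c(8, 3, 2, 2, 1, 3, 1, 2)))
    c2 <- as.vector(rmultinom(1, 140, c(4, 4, 2, 3, 1, 6, 1, 1)))
    tab <- make_spectrum(list("A.low" = c1, "A.high" = c2))
    lr <- 2 * (fit_multinomial(tab, ~ glucose)$logLik -
                 fit_multinomial(tab, ~ 1)$logLik)
    keep <- c1 + c2 > 0
    G <- oracle_g_stat(cbind(c1[keep], c2[keep]))
    expect_lt(abs(lr - G) / max(G, 1e-12), 1e-6)
  }
})

test_that("multinomial LR tests are invariant to the baseline category", {
  set.seed(8)
  counts <- lapply(1:4, function(i)
    as.vector(rmultinom(1, 100, c(5, 3, 2, 2, 1, 4, 1, 2))))
  tab <- make_spectrum(list("A.low" = counts[[1]], "A.high" = counts[[2]],
                            "B.low" = counts[[3]], "B.high" = counts[[4]]))
  t1 <- type2_tests_multinomial(tab)
  # permute the category labels: LR stats must permute-invariantly agree
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  tab2 <- make_spectrum(list("A.low" = counts[[1]][perm],
                             "A.high" = counts[[2]][perm],
                             "B.low" = counts[[3]][perm],
                             "B.high" = counts[[4]][perm]))
  t2 <- type2_tests_multinomial(tab2)
  expect_equal(t1$lr_stat, t2$lr_stat, tolerance = 1e-7)
})

test_that("Type-II multinomial tests have df 7 and detect exact null copies", {
  set.seed(9)
  low <- as.vector(rmultinom(1, 150, c(6, 3, 2, 2, 1, 4, 1, 2)))
  lowB <- as.vector(rmultinom(1, 150, c(6, 3, 2, 2, 1, 4, 1, 2)))
  tab <- make_spectrum(list("A.low" = low, "A.high" = low,
                            "B.low" = lowB, "B.high" = lowB))
  res <- type2_tests_multinomial(tab)
  expect_equal(res$df, c(7L, 7L, 7L))
  glu <- res[res$term == "glucose", ]
  expect_lt(glu$lr_stat, 1e-6)
  expect_gt(glu$p, 0.999)
})

test_that("Type-II null LR statistics have mean approximately df", {
  set.seed(10)
  probs <- c(0.25, 0.15, 0.12, 0.12, 0.05, 0.19, 0.05, 0.07)
  n_rep <- 200
  stats <- replicate(n_rep, {
    tab <- make_spectrum(list(
      "A.low" = as.vector(rmultinom(1, 200, probs)),
      "A.high" = as.vector(rmultinom(1, 200, probs)),
      "B.low" = as.vector(rmultinom(1, 200, probs)),
      "B.high" = as.vector(rmultinom(1, 200, probs))))
    suppressWarnings(type2_tests_multinomial(tab)$lr_stat)
  })
  # each term is chi-square with 7 df under the null: mean ~ 7
  for (i in 1:3)
    expect_lt(abs(mean(stats[i, ]) - 7),
              3 * sd(stats[i, ]) / sqrt(n_rep))
})

test_that("per-class binomial tests: df 1, balance, degenerate flagging", {
  bal <- make_spectrum(list("A.low" = c(10, 5, 5, 5, 5, 5, 5, 5),
                            "A.high" = c(10, 5, 5, 5, 5, 5, 5, 5),
                            "B.low" = c(10, 5, 5, 5, 5, 5, 5, 5),
                            "B.high" = c(10, 5, 5, 5, 5, 5, 5, 5)))
  res <- fit_binomial_class(bal, "AT>GC")
  expect_equal(res$df, c(1L, 1L, 1L))
  expect_true(all(res$lr_stat < 1e-6))
  zero <- make_spectrum(list("A.low" = c(10, 5, 5, 5, 5, 5, 0, 5),
                             "A.high" = c(8, 5, 5, 5, 5, 5, 0, 5),
                             "B.low" = c(9, 5, 5, 5, 5, 5, 0, 5),
                             "B.high" = c(7, 5, 5, 5, 5, 5, 0, 5)))
  expect_warning(resz <- fit_binomial_class(zero, "insertion"), "degenerate")
  expect_true(all(is.na(resz$p)))
  expect_error(fit_binomial_class(bal, "nonsense"), "unknown")
})

test_that("single-predictor binomial LR equals the 2x2 G statistic", {
  set.seed(12)
  for (rep in 1:5) {
    tot <- c(120, 140)
    s <- rbinom(2, tot, c(0.35, 0.2))
    tab <- make_spectrum(list(
      "A.low" = c(s[1], tot[1] - s[1], rep(0, 6)),
      "A.high" = c(s[2], tot[2] - s[2], rep(0, 6))))
    res <- fit_binomial_class(tab, "AT>GC")
    G <- oracle_g_stat(rbind(c(s[1], tot[1] - s[1]),
                             c(s[2], tot[2] - s[2])))
    glu <- res$lr_stat[res$term == "glucose"]
    expect_lt(abs(glu - G) / max(G, 1e-12), 1e-6)
  }
})

test_that("full test battery returns the multinomial and all per-class rows", {
  cfg <- study_config()
  tab <- gen_spectrum_counts(cfg, seed = 20, n_isolates = 150)$table
  res <- suppressWarnings(test_spectrum(tab))
  expect_equal(sum(res$model == "multinomial"), 3)
  expect_equal(nrow(res), 3 + 3 * 8)
  expect_true(all(res$p[!is.na(res$p)] >= 0 & res$p[!is.na(res$p)] <= 1))
})
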