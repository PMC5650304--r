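# Expression filtering, univariate screening and forward/stability
# selection.

test_that("the filter drops dim and flat genes per its stated rule", {
  m <- rbind(bright_flat = c(10, 10, 10),
             dim = c(1, 1, 1),
             varying = c(5, 6, 7))
  colnames(m) <- c("s1", "s2", "s3")
  # row medians (10, 1, 6): reference median 6, threshold 1.2 -> "dim" fails
  # the median criterion; the two constant rows also fail the variance one
  out <- expression_filter(m)
  expect_false("dim" %in% rownames(out))
  expect_true("varying" %in% rownames(out))

  # vacuous thresholds keep every gene of positive, non-constant data
  m2 <- matrix(abs(rnorm(20, 10)), nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  out2 <- expression_filter(m2, 1e-9, 1e-9)
  expect_identical(nrow(out2), 4L)

  expect_error(expression_filter(m, median_fraction = 1.2), "fractions")
})

test_that("every retained gene re-verifies both filter inequalities", {
  co <- simulate_cohort(simulation_config(n_samples = 60, n_genes = 500,
                                          n_signature = 4, n_positive = 3,
                                          n_negative = 1, seed = 31))
  out <- expression_filter(co$expression)
  med_thr <- attr(out, "filter")$median_threshold
  var_thr <- attr(out, "filter")$variance_threshold
  for (g in rownames(out)) {
    expect_gt(stats::median(co$expression[g, ]), med_thr)
    expect_gt(stats::var(co$expression[g, ]), var_thr)
  }
  dropped <- setdiff(rownames(co$expression), rownames(out))
  for (g in dropped) {
    expect_true(stats::median(co$expression[g, ]) <= med_thr ||
                  stats::var(co$expression[g, ]) <= var_thr)
  }
})

test_that("univariate screening flags degenerate genes and finds planted ones", {
  co <- simulate_cohort(simulation_config(n_samples = 300, n_genes = 30,
                                          n_signature = 1, n_positive = 1,
                                          n_negative = 0, beta = 1.0,
                                          seed = 17))
  m <- rbind(co$expression, CONST = rep(5, 300))
  tab <- univariate_screen(m, co$survival)
  expect_true(all(diff(tab$p) >= 0))           # sorted ascending
  expect_identical(tab$seed, tab$p < 0.05)     # seed flag definition
  cr <- tab[tab$gene == "CONST", ]
  expect_true(cr$flagged)
  expect_equal(cr$p, 1)
  expect_false(cr$seed)
  # planted beta = 1 gene at n = 300: overwhelming evidence
  expect_lt(tab$p[tab$gene == co$truth$genes], 1e-3)
})

test_that("forward selection handles one gene, is seeded-deterministic, and ranks planted genes first", {
  co <- simulate_cohort(simulation_config(n_samples = 100, n_genes = 5,
                                          n_signature = 1, n_positive = 1,
                                          n_negative = 0, seed = 23))
  one <- co$expression[co$truth$genes, , drop = FALSE]
  tr1 <- forward_select(one, co$survival, partition_spec(seed = 1))
  expect_identical(nrow(tr1), 1L)
  expect_identical(attr(tr1, "selected"), co$truth$genes)

  # determinism under an identical seed and config
  co2 <- simulate_cohort(simulation_config(n_samples = 150, n_genes = 12,
                                           n_signature = 2, n_positive = 2,
                                           n_negative = 0, seed = 29))
  a <- forward_select(co2$expression, co2$survival, partition_spec(seed = 99),
                      max_steps = 5)
  b <- forward_select(co2$expression, co2$survival, partition_spec(seed = 99),
                      max_steps = 5)
  expect_identical(a, b)

  # two strong planted genes among noise occupy the first two steps
  hits <- vapply(1:8, function(s) {
    co3 <- simulate_cohort(simulation_config(n_samples = 300, n_genes = 22,
                                             n_signature = 2, n_positive = 2,
                                             n_negative = 0,
                                             beta = c(1.0, 0.8),
                                             seed = 700 + s))
    tr <- forward_select(co3$expression, co3$survival,
                         partition_spec(seed = s), max_steps = 4)
    all(tr$gene[1:2] %in% co3$truth$genes)
  }, logical(1))
  expect_gte(sum(hits), 7)
})

test_that("the recorded full-data likelihood is monotone over nested models", {
  co <- simulate_cohort(simulation_config(n_samples = 150, n_genes = 15,
                                          n_signature = 3, n_positive = 2,
                                          n_negative = 1, seed = 37))
  tr <- forward_select(co$expression, co$survival, partition_spec(seed = 2),
                       max_steps = 10)
  expect_true(all(diff(tr$nloglik) <= 1e-8))
  expect_equal(tr$aic, 2 * tr$nloglik + 2 * tr$step, tolerance = 1e-12)
  expect_identical(tr$step, seq_len(nrow(tr)))
})

test_that("min-AIC model size matches an exhaustive scan", {
  expect_identical(select_model_size(c(5, 6, 7)), 1L)
  set.seed(41)
  for (i in 1:100) {
    a <- stats::runif(sample(1:20, 1), 0, 100)
    scan <- which(a == min(a))[1]  # brute-force first minimum
    expect_identical(select_model_size(a), scan)
  }
})

test_that("stability selection tallies sets exactly and ignores sample order", {
  co <- simulate_cohort(simulation_config(n_samples = 80, n_genes = 8,
                                          n_signature = 2, n_positive = 1,
                                          n_negative = 1, seed = 43))
  spec1 <- partition_spec(subsample = 60, n_outer = 1, seed = 5, n_inner = 3)
  st1 <- stability_select(co$expression, co$survival, spec1, max_steps = 4)
  expect_identical(length(st1$sets), 1L)
  expect_identical(unname(st1$sets), 1L)

  spec <- partition_spec(subsample = 60, n_outer = 6, seed = 5, n_inner = 3)
  st <- stability_select(co$expression, co$survival, spec, max_steps = 4)
  expect_identical(sum(st$sets), st$n_outer)
  tally <- table(st$iteration_sets)
  expect_identical(st$modal_frequency, max(as.integer(tally)))
  key <- paste(st$modal_set, collapse = "|")
  expect_identical(unname(st$sets[key]), st$modal_frequency)

  # shuffling the input sample order leaves the (id-canonicalized) result intact
  perm <- sample(ncol(co$expression))
  st_shuf <- stability_select(co$expression[, perm],
                              co$survival[perm, , drop = FALSE], spec,
                              max_steps = 4)
  expect_identical(st$sets, st_shuf$sets)
  expect_identical(st$modal_set, st_shuf$modal_set)
})

test_that("screening preconditions fail loudly", {
  co <- simulate_cohort(simulation_config(n_samples = 40, n_genes = 6,
                                          n_signature = 2, n_positive = 1,
                                          n_negative = 1, seed = 47))
  allcens <- make_surv(co$survival$time, rep(0, 40), ids = co$survival$sample_id)
  expect_error(univariate_screen(co$expression, allcens), "events")
  spec <- partition_spec(subsample = 100)
  expect_error(stability_select(co$expression, co$survival, spec), "subsample")
})
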