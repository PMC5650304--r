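# Clustering, impact signs, activation counts, the threshold sweep and
# frozen-model validation.

test_that("two well-separated blobs cluster perfectly; edge cases hold", {
  set.seed(51)
  blob <- cbind(matrix(rnorm(5 * 20, 0), nrow = 5),
                matrix(rnorm(5 * 20, 6), nrow = 5))
  dimnames(blob) <- list(paste0("g", 1:5), paste0("s", 1:40))
  cl <- cluster_samples(blob)
  expect_identical(length(unique(cl$labels[1:20])), 1L)
  expect_identical(length(unique(cl$labels[21:40])), 1L)
  expect_false(cl$labels[1] == cl$labels[21])

  two <- blob[, c(1, 21)]
  cl2 <- cluster_samples(two)
  expect_identical(sort(unname(cl2$labels)), c(1L, 2L))

  # duplicating every sample leaves the induced partition unchanged
  dup <- cbind(blob, blob)
  colnames(dup) <- paste0("s", 1:80)
  cld <- cluster_samples(dup)
  expect_identical(unname(cld$labels[1:40]), unname(cld$labels[41:80]))
})

test_that("worse-survival cluster is labelled 1 when follow-up is supplied", {
  set.seed(52)
  expr <- cbind(matrix(rnorm(3 * 25, 0), nrow = 3),
                matrix(rnorm(3 * 25, 5), nrow = 3))
  dimnames(expr) <- list(paste0("g", 1:3), paste0("s", 1:50))
  # second blob dies fast
  tm <- c(rexp(25, 0.05), rexp(25, 1))
  sv <- make_surv(tm, rep(1, 50), ids = colnames(expr))
  cl <- cluster_samples(expr, sv)
  expect_identical(cl$basis, "survival")
  expect_true(mean(cl$labels[26:50] == 1) > 0.9)
})

test_that("sign rules apply their contrasts literally", {
  expr <- rbind(up = c(8, 8, 4, 4), down = c(3, 3, 7, 7), flat = c(5, 5, 5, 5))
  colnames(expr) <- paste0("s", 1:4)
  clusters <- structure(list(labels = stats::setNames(c(1L, 1L, 2L, 2L),
                                                      colnames(expr)),
                             worse_cluster = 1L, basis = "survival",
                             linkage = "complete", distance = "euclidean"),
                        class = "cluster_assignment")
  s <- assign_signs(expr, c("up", "down"), method = "cluster-contrast",
                    clusters = clusters)
  expect_identical(unname(s), c(1L, -1L))
  expect_warning(
    s2 <- assign_signs(expr, "flat", method = "cluster-contrast",
                       clusters = clusters),
    "resolved to \\+1")
  expect_identical(unname(s2), 1L)
  expect_error(assign_signs(expr, "up", method = "cox-sign"), "survival")
})

test_that("cox-sign recovers planted directions", {
  co <- simulate_cohort(simulation_config(n_samples = 300, n_genes = 20,
                                          n_signature = 4, n_positive = 2,
                                          n_negative = 2, seed = 53))
  s <- assign_signs(co$expression, co$truth$genes, co$survival,
                    method = "cox-sign")
  expect_identical(s, co$truth$signs)
})

test_that("activation counts follow the strict-inequality rule", {
  genes <- c("a", "b", "c")
  model <- signature_model(genes, stats::setNames(c(1L, 1L, -1L), genes),
                           stats::setNames(c(5, 5, 5), genes), k = 2)
  expr <- matrix(c(6, 4, 3), ncol = 1, dimnames = list(genes, "s1"))
  expect_identical(unname(activation_scores(expr, model)), 2L)
  at_cut <- matrix(c(5, 5, 5), ncol = 1, dimnames = list(genes, "s2"))
  expect_identical(unname(activation_scores(at_cut, model)), 0L)
  expect_error(activation_scores(expr[1:2, , drop = FALSE], model), "c")
})

test_that("activation counts match an independent per-gene tally", {
  co <- simulate_cohort(simulation_config(n_samples = 100, n_genes = 12,
                                          n_signature = 5, n_positive = 3,
                                          n_negative = 2, seed = 54))
  model <- signature_model(co$truth$genes, co$truth$signs, co$expression, k = 3)
  counts <- activation_scores(co$expression, model)
  for (s in sample(colnames(co$expression), 10)) {
    tally <- 0L
    for (g in model$genes) {
      v <- co$expression[g, s]
      if (model$signs[g] > 0 && v > model$cutoffs[g]) tally <- tally + 1L
      if (model$signs[g] < 0 && v < model$cutoffs[g]) tally <- tally + 1L
    }
    expect_identical(unname(counts[s]), tally)
  }
  # invariance under a joint strictly monotone transform
  model_t <- signature_model(model$genes, model$signs, exp(model$cutoffs),
                             k = model$k)
  expect_identical(activation_scores(exp(co$expression), model_t), counts)
})

test_that("the threshold sweep picks the only informative split and degenerates loudly", {
  set.seed(55)
  n <- 100
  counts <- stats::setNames(rep(c(1L, 2L), each = n / 2), paste0("s", 1:n))
  highrisk <- counts >= 2
  tm <- rexp(n, rate = 0.05 * ifelse(highrisk, 3, 1))
  sv <- make_surv(tm, rep(1, n), ids = names(counts))
  sw <- threshold_sweep(counts, sv, n_resample = 10)
  expect_identical(sw$chosen_k, 2L)
  expect_true(is.na(sw$table$p[sw$table$k == 1]))  # k=1 leaves no low group
  expect_lt(sw$logrank$p, 0.01)
  # high-group size is non-increasing in k
  expect_true(all(diff(sw$table$n_high) <= 0))

  same <- stats::setNames(rep(3L, 10), paste0("s", 1:10))
  sv10 <- make_surv(rexp(10), rep(1, 10), ids = names(same))
  expect_error(threshold_sweep(same, sv10), "non-empty")
})

test_that("raising k never promotes a sample to high risk", {
  co <- simulate_cohort(simulation_config(n_samples = 80, n_genes = 10,
                                          n_signature = 4, n_positive = 3,
                                          n_negative = 1, seed = 56))
  model <- signature_model(co$truth$genes, co$truth$signs, co$expression, k = 1)
  prev <- rep(TRUE, 80)
  for (k in 1:4) {
    model$k <- k
    high <- classify_samples(co$expression, model)$label == "high"
    expect_true(all(high <= prev))
    prev <- high
  }
})

test_that("validation on the discovery cohort itself is idempotent", {
  co <- simulate_cohort(simulation_config(n_samples = 120, n_genes = 30,
                                          n_signature = 4, n_positive = 3,
                                          n_negative = 1, seed = 57))
  model <- signature_model(co$truth$genes, co$truth$signs, co$expression, k = 2)
  ref <- classify_samples(co$expression, model)
  val <- validate_external(co$expression, list(survival = co$survival), model)
  expect_identical(val$assignment, ref)
  expect_s3_class(val$tests$survival, "logrank_test")
  # a frozen model transfers to an independent cohort from the same truth
  vc <- simulate_validation_cohort(co, seed = 58)
  v2 <- validate_external(vc$expression,
                          list(survival = vc$survival,
                               recurrence = vc$recurrence), model)
  expect_lt(v2$tests$survival$p, 0.01)
  expect_lt(v2$tests$recurrence$p, 0.01)
  dropped <- setdiff(rownames(vc$expression), model$genes[1])
  expect_error(validate_external(vc$expression[dropped, ],
                                 list(survival = vc$survival), model),
               "missing")
})

test_that("gene correlation matrices behave at their extremes", {
  set.seed(59)
  g <- matrix(rnorm(3 * 50), nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:50)))
  m <- rbind(g, dup = g["a", ], neg = -g["a", ], flat = rep(1, 50))
  cc <- gene_correlation(m)
  expect_equal(cc["a", "dup"], 1)
  expect_equal(cc["a", "neg"], -1)
  expect_true(all(is.na(cc["flat", setdiff(rownames(m), "flat")])))
  expect_equal(unname(diag(cc)), rep(1, 6))
  expect_equal(cc, t(cc))

  big <- matrix(rnorm(6 * 1000), nrow = 6,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:1000)))
  cb <- gene_correlation(big)
  expect_lt(max(abs(cb[upper.tri(cb)])), 0.15)
})
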