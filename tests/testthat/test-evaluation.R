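# CV splitting, report aggregation, cross-KB and cross-reference analyses.

eval_dataset <- function(seed = 41, ...) {
  skb <- generate_synthetic_kb(synthetic_config(
    n_kbs = 2L, compounds_per_kb = 30L, pathways_per_kb = 6L,
    membership_noise = 0, seed = seed, ...))
  pd <- build_pair_dataset(skb$compounds, skb$pathways,
                           coloring_config(), std_config("none"))
  list(skb = skb, pd = pd)
}

quick_mlp <- function(max_epochs = 12L, ...) {
  mlp_config(hidden_sizes = c(32L, 16L), max_epochs = max_epochs,
             batch_size = 64L, early_stop_patience = Inf, ...)
}

test_that("stratified splits partition pairs and preserve the label rate", {
  pd <- eval_dataset()$pd
  n <- nrow(pd$pairs)
  splits <- stratified_cv_splits(pd, n_iterations = 4L, k = 10L, seed = 3)
  rate <- mean(pd$pairs$label)
  for (sp in splits) {
    expect_equal(sort(c(sp$train, sp$test)), seq_len(n))
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_equal(length(sp$test), round(n / 10), tolerance = 0.02)
    # stratification: test-fold positives within 1 of the proportional count
    expect_lte(abs(sum(pd$pairs$label[sp$test]) - rate * length(sp$test)), 1 + 1e-9)
  }
  # distinct iterations use distinct fold assignments
  expect_false(identical(splits[[1]]$test, splits[[2]]$test))
  expect_error(stratified_cv_splits(pd, 1L, k = 1L), "at least 2")
  few <- c(rep(1L, 3), rep(0L, 100))
  expect_error(stratified_cv_splits(few, 1L, k = 10L), "smaller k")
})

test_that("run_cv produces per-iteration rows, aggregates, and per-KB partitions", {
  pd <- eval_dataset()$pd
  rep1 <- run_cv(pd, quick_mlp(), n_iterations = 2L, k = 10L, seed = 5)
  expect_equal(nrow(rep1$per_iteration), 2L)
  agg <- rep1$aggregate
  expect_equal(agg$mean[agg$metric == "mcc"], mean(rep1$per_iteration$mcc))
  expect_equal(agg$median[agg$metric == "f1"], median(rep1$per_iteration$f1))
  expect_equal(agg$sd[agg$metric == "accuracy"], sd(rep1$per_iteration$accuracy))
  # no merged row spans KBs in this corpus: per-KB counts partition the total
  for (i in 1:2) {
    kb <- rep1$per_kb[rep1$per_kb$iteration == i, ]
    tot <- rep1$per_iteration[i, ]
    expect_equal(sum(kb$tp), tot$tp)
    expect_equal(sum(kb$tn), tot$tn)
    expect_equal(sum(kb$fp), tot$fp)
    expect_equal(sum(kb$fn), tot$fn)
  }
  # determinism
  rep2 <- run_cv(pd, quick_mlp(), n_iterations = 2L, k = 10L, seed = 5)
  expect_identical(rep1$per_iteration, rep2$per_iteration)
})

test_that("cross_kb_eval needs two knowledgebases and returns the MCC matrix", {
  d <- eval_dataset()
  res <- cross_kb_eval(d$pd, quick_mlp(), seed = 2)
  expect_equal(dim(res), c(2L, 2L))
  expect_true(all(is.finite(res)))
  single <- generate_synthetic_kb(synthetic_config(
    n_kbs = 1L, compounds_per_kb = 20L, pathways_per_kb = 4L, seed = 9))
  pds <- build_pair_dataset(single$compounds, single$pathways,
                            coloring_config(), std_config("none"))
  expect_error(cross_kb_eval(pds, quick_mlp()), "at least two")
})

test_that("an identity cross-reference yields zero MCC difference and all-identical features", {
  d <- eval_dataset()
  pd <- d$pd
  model <- train_mlp(pd, oversample_positives(pd, seq_len(nrow(pd$pairs))),
                     quick_mlp(max_epochs = 20L))
  ids <- utils::head(d$skb$annotations[!duplicated(d$skb$annotations$compound_id), ], 10)
  xref <- data.frame(kb_a = ids$kb, cid_a = ids$compound_id,
                     kb_b = ids$kb, cid_b = ids$compound_id,
                     stringsAsFactors = FALSE)
  rep <- cross_reference_analysis(model, pd, xref, pd$graphs)
  expect_equal(rep$n_pairs, nrow(xref))
  expect_equal(rep$n_identical_feature_pairs, rep$n_pairs)
  expect_equal(rep$mcc_difference, 0)
  expect_identical(unlist(rep$train_counts), unlist(rep$crossref_counts))
})

test_that("cross-reference analysis rejects an empty table and manifests skips", {
  d <- eval_dataset()
  model <- train_mlp(d$pd, oversample_positives(d$pd, seq_len(nrow(d$pd$pairs))),
                     quick_mlp(max_epochs = 2L))
  expect_error(cross_reference_analysis(model, d$pd, data.frame(), d$pd$graphs),
               "empty cross-reference")
  xref <- data.frame(kb_a = c("KB1", "KB9"), cid_a = c("KB1_C001", "ghost"),
                     kb_b = c("KB1", "KB1"), cid_b = c("KB1_C001", "KB1_C001"),
                     stringsAsFactors = FALSE)
  rep <- cross_reference_analysis(model, d$pd, xref, d$pd$graphs)
  expect_equal(rep$n_pairs, 1L)
  expect_equal(nrow(rep$skipped), 1L)
})

test_that("perturbed cross-references unify under inchi standardization only", {
  skb <- generate_synthetic_kb(synthetic_config(
    n_kbs = 2L, compounds_per_kb = 25L, pathways_per_kb = 6L,
    membership_noise = 0, crossref_fraction = 0.4,
    perturbation_mix = c(resonance_charge_form = 0.5, tautomer_swap = 0.5),
    seed = 43))
  frac <- function(std_mode) {
    pd <- build_pair_dataset(skb$compounds, skb$pathways,
                             coloring_config(), std_config(std_mode))
    model <- train_mlp(pd, oversample_positives(pd, seq_len(nrow(pd$pairs))),
                       quick_mlp(max_epochs = 2L))
    cross_reference_analysis(model, pd, skb$crossref, pd$graphs)$identical_fraction
  }
  expect_equal(frac("inchi"), 1)
  expect_lt(frac("none"), 0.2)
})
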