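# Cross-validation, per- and cross-knowledgebase evaluation, and the
# cross-reference consistency analysis.

#' Stratified cross-validation splits
#'
#' Each iteration is an independent 10-fold (by default) partition of the
#' pairs, stratified on the binary label, with exactly one fold designated
#' as the test set. Iteration `i` is seeded with `seed + i - 1`.
#'
#' @param pd A `pair_dataset` (or an integer 0/1 label vector).
#' @param n_iterations Number of CV iterations.
#' @param k Folds per iteration (test fraction = 1/k).
#' @param seed Base seed.
#' @return List of `list(train, test)` index pairs.
#' @export
stratified_cv_splits <- function(pd, n_iterations = 100L, k = 10L, seed = 1L) {
  labels <- if (inherits(pd, "pair_dataset")) pd$pairs$label else as.integer(pd)
  if (k < 2L) stop("k must be at least 2")
  if (min(table(factor(labels, levels = 0:1))) < k) {
    stop(sprintf("fewer than k = %d pairs in the rarest class; use a smaller k", k))
  }
  n <- length(labels)
  lapply(seq_len(n_iterations), function(i) {
    .with_seed(seed + i - 1L, {
      fold <- integer(n)
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      test <- which(fold == 1L)
      list(train = which(fold != 1L), test = test)
    })
  })
}

.per_kb_tallies <- function(pred, truth, kb_str) {
  kbs <- sort(unique(unlist(strsplit(kb_str, ",", fixed = TRUE))))
  out <- lapply(kbs, function(kb) {
    sel <- grepl(kb, kb_str, fixed = TRUE)
    tally_confusion(pred[sel], truth[sel])
  })
  names(out) <- kbs
  out
}

#' Run repeated stratified cross-validation
#'
#' Per iteration: oversample the training fold's positives, train the MLP,
#' predict the test fold, and tally confusion counts overall and per
#' knowledgebase (a pair witnessed by several knowledgebases counts in
#' each). Aggregates are mean/median/standard deviation over the
#' iteration-level metrics, not pooled counts.
#'
#' @param pd A `pair_dataset`.
#' @param model_config An [mlp_config()].
#' @param n_iterations,k,seed See [stratified_cv_splits()].
#' @return An `eval_report`: `per_iteration` (metric rows), `aggregate`
#'   (mean/median/sd per metric), `per_kb` (per-iteration per-KB metric
#'   rows and aggregates), and the config stamp.
#' @export
run_cv <- function(pd, model_config = mlp_config(), n_iterations = 5L,
                   k = 10L, seed = 1L) {
  splits <- stratified_cv_splits(pd, n_iterations, k, seed)
  rows <- list(); kb_rows <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    cfg <- model_config
    cfg$seed <- model_config$seed + i - 1L
    os <- oversample_positives(pd, sp$train)
    model <- tryCatch(train_mlp(pd, os, cfg), error = function(e) {
      stop(sprintf("CV iteration %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
    pred <- predict_pairs(model, pd, sp$test)
    truth <- pd$pairs$label[sp$test]
    row <- .metric_row(tally_confusion(pred$label, truth))
    row$iteration <- i
    rows[[i]] <- row
    per_kb <- .per_kb_tallies(pred$label, truth, pd$pairs$kbs[sp$test])
    for (kb in names(per_kb)) {
      kr <- .metric_row(per_kb[[kb]])
      kr$iteration <- i; kr$kb <- kb
      kb_rows[[length(kb_rows) + 1L]] <- kr
    }
  }
  per_iteration <- do.call(rbind, rows)
  per_kb <- do.call(rbind, kb_rows)
  agg <- function(df) {
    metrics <- c("mcc", "f1", "precision", "recall", "accuracy")
    data.frame(metric = metrics,
               mean = vapply(metrics, function(m) mean(df[[m]]), numeric(1)),
               median = vapply(metrics, function(m) stats::median(df[[m]]), numeric(1)),
               sd = vapply(metrics, function(m) stats::sd(df[[m]]), numeric(1)),
               row.names = NULL)
  }
  kb_agg <- do.call(rbind, lapply(split(per_kb, per_kb$kb), function(df) {
    a <- agg(df); a$kb <- df$kb[1]; a
  }))
  rownames(kb_agg) <- NULL
  structure(list(per_iteration = per_iteration, aggregate = agg(per_iteration),
                 per_kb = per_kb, per_kb_aggregate = kb_agg,
                 config = list(model = model_config, n_iterations = n_iterations,
                               k = k, seed = seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d CV iterations>\n", nrow(x$per_iteration)))
  print(x$aggregate)
  invisible(x)
}

#' Cross-knowledgebase evaluation
#'
#' For each training knowledgebase, trains a model on its pairs (with a
#' stratified fraction held out) and evaluates MCC on the held-out same-KB
#' pairs (diagonal) and on all pairs of every other knowledgebase
#' (off-diagonal).
#'
#' @param pd A multi-knowledgebase `pair_dataset`.
#' @param model_config An [mlp_config()].
#' @param heldout_fraction Same-KB held-out fraction for the diagonal.
#' @param seed Seed for the held-out splits.
#' @return Numeric matrix of MCC values, training KB in rows, test KB in
#'   columns.
#' @export
cross_kb_eval <- function(pd, model_config = mlp_config(),
                          heldout_fraction = 0.1, seed = 1L) {
  kbs <- sort(pd$blocks$kb[pd$blocks$n_compound_rows > 0 & pd$blocks$n_pathway_rows > 0])
  if (length(kbs) < 2L) stop("cross-knowledgebase evaluation needs at least two knowledgebases")
  has_kb <- function(kb) grepl(kb, pd$pairs$kbs, fixed = TRUE)
  res <- matrix(NA_real_, length(kbs), length(kbs), dimnames = list(kbs, kbs))
  for (tr in kbs) {
    idx <- which(has_kb(tr))
    lab <- pd$pairs$label[idx]
    held <- .with_seed(seed, {
      k <- max(2L, round(1 / heldout_fraction))
      fold <- integer(length(idx))
      for (cls in unique(lab)) {
        w <- which(lab == cls)
        fold[w] <- sample(rep_len(seq_len(k), length(w)))
      }
      which(fold == 1L)
    })
    train_idx <- idx[-held]
    model <- train_mlp(pd, oversample_positives(pd, train_idx), model_config)
    for (te in kbs) {
      test_idx <- if (te == tr) idx[held] else setdiff(which(has_kb(te)), idx)
      if (length(test_idx) == 0L) next
      pred <- predict_pairs(model, pd, test_idx)
      res[tr, te] <- mcc(tally_confusion(pred$label, pd$pairs$label[test_idx]))
    }
  }
  res
}

.find_compound_row <- function(fm, kb, cid) {
  for (i in seq_along(fm$row_meta)) {
    m <- fm$row_meta[[i]]
    if (any(m$kb == kb & m$id == cid)) return(i)
  }
  NA_integer_
}

#' Cross-reference consistency analysis
#'
#' For each cross-reference pair, evaluates the model twice against the
#' first (training-set) compound's knowledgebase block and labels: once with
#' the first compound's stored feature row, once with the second compound's
#' structure projected into the training feature space via
#' [project_new_compound()]. Tallies the two confusion counts, their MCCs
#' and the MCC difference, and counts pairs whose two members have
#' identical raw atom-color count vectors (after the dataset's
#' standardization mode).
#'
#' @param model A `trained_mlp` trained on all pairs of `pd`.
#' @param pd The training `pair_dataset`.
#' @param crossref Data frame `kb_a`, `cid_a`, `kb_b`, `cid_b`; the first
#'   member must be a training-set compound.
#' @param graphs_b Named list of `mol_graph`s for second members, keyed
#'   `"kb:compound_id"`.
#' @return A `crossref_report`: confusion counts and MCC for training-set
#'   compounds and for cross-references, `mcc_difference`
#'   (train - crossref), `n_pairs`, `n_identical_feature_pairs`, mean OOV
#'   fraction, and a manifest of skipped pairs.
#' @export
cross_reference_analysis <- function(model, pd, crossref, graphs_b) {
  if (is.null(crossref) || nrow(crossref) == 0L) {
    stop("empty cross-reference table")
  }
  cm <- pd$compounds
  pkbs <- .row_kbs(pd$pathways)
  cfg_col <- cm$coloring %||% coloring_config()
  cfg_std <- cm$std %||% std_config("none")
  ct_train <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  ct_xref <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  n_identical <- 0L; n_pairs <- 0L
  oov <- numeric(0)
  skipped <- data.frame(kb_a = character(), cid_a = character(),
                        reason = character(), stringsAsFactors = FALSE)
  pair_lookup <- split(seq_len(nrow(pd$pairs)), pd$pairs$ci)

  for (r in seq_len(nrow(crossref))) {
    kb_a <- crossref$kb_a[r]; cid_a <- crossref$cid_a[r]
    kb_b <- crossref$kb_b[r]; cid_b <- crossref$cid_b[r]
    ia <- .find_compound_row(cm, kb_a, cid_a)
    gb <- graphs_b[[paste(kb_b, cid_b, sep = ":")]]
    if (is.na(ia) || is.null(gb)) {
      skipped <- rbind(skipped, data.frame(
        kb_a = kb_a, cid_a = cid_a,
        reason = if (is.na(ia)) "first member not in training set"
                 else "second member structure unavailable",
        stringsAsFactors = FALSE))
      next
    }
    prs <- pair_lookup[[as.character(ia)]]
    prs <- prs[grepl(kb_a, pd$pairs$kbs[prs], fixed = TRUE)]
    if (length(prs) == 0L) next
    jj <- pd$pairs$pi[prs]
    truth <- pd$pairs$label[prs]
    comp_a <- cm$x[rep(ia, length(jj)), , drop = FALSE]
    path_rows <- pd$pathways$x[jj, , drop = FALSE]
    pred_a <- predict_rows(model, comp_a, path_rows)

    proj <- project_new_compound(gb, pd)
    comp_b <- proj$row[rep(1L, length(jj)), , drop = FALSE]
    pred_b <- predict_rows(model, comp_b, path_rows)

    add <- function(ct, pred) {
      ct + c(tp = sum(pred == 1 & truth == 1), tn = sum(pred == 0 & truth == 0),
             fp = sum(pred == 1 & truth == 0), fn = sum(pred == 0 & truth == 1))
    }
    ct_train <- add(ct_train, pred_a$label)
    ct_xref <- add(ct_xref, pred_b$label)
    oov <- c(oov, proj$oov_fraction)
    n_pairs <- n_pairs + 1L

    # identical raw atom-color counts, computed the same way for both members
    fa <- .raw_counts_for(pd, kb_a, cid_a)
    fb <- featurize(standardize(gb, cfg_std), cfg_col)
    if (!is.null(fa) && identical(fa, fb)) n_identical <- n_identical + 1L
  }
  if (n_pairs == 0L) stop("no resolvable cross-reference pairs")
  cc_train <- do.call(confusion_counts, as.list(ct_train))
  cc_xref <- do.call(confusion_counts, as.list(ct_xref))
  structure(list(
    train_counts = cc_train, train_mcc = mcc(cc_train),
    crossref_counts = cc_xref, crossref_mcc = mcc(cc_xref),
    mcc_difference = mcc(cc_train) - mcc(cc_xref),
    n_pairs = n_pairs, n_identical_feature_pairs = n_identical,
    identical_fraction = n_identical / n_pairs,
    mean_oov_fraction = mean(oov), skipped = skipped
  ), class = "crossref_report")
}

# raw standardized color counts of an original training compound, recomputed
# from its stored graph if available in the pair dataset's graph registry
.raw_counts_for <- function(pd, kb, cid) {
  reg <- pd$graphs
  if (is.null(reg)) return(NULL)
  g <- reg[[paste(kb, cid, sep = ":")]]
  if (is.null(g)) return(NULL)
  cm <- pd$compounds
  featurize(standardize(g, cm$std %||% std_config("none")),
            cm$coloring %||% coloring_config())
}

#' @export
print.crossref_report <- function(x, ...) {
  cat(sprintf("<crossref_report: %d pairs, %d with identical atom-color counts (%.1f%%)>\n",
              x$n_pairs, x$n_identical_feature_pairs, 100 * x$identical_fraction))
  cat(sprintf("  training-set MCC %.4f, cross-reference MCC %.4f, difference %.4f\n",
              x$train_mcc, x$crossref_mcc, x$mcc_difference))
  invisible(x)
}
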