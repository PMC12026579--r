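# Multi-layer perceptron over concatenated compound + pathway feature rows.
# Implemented with base matrix operations (BLAS-backed) and Adam; batches are
# gathered from the two feature matrices on the fly, so peak memory is
# O(batch_size x feature width) regardless of the total pair count.

#' MLP configuration
#'
#' @param hidden_sizes Integer vector of hidden layer widths.
#' @param activation `"relu"` or `"tanh"`.
#' @param dropout Dropout probability in `[0, 1)` applied to hidden layers
#'   during training.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Stop after this many epochs without
#'   improvement (`Inf` disables): without a validation split, improvement
#'   means training loss; with one, validation MCC.
#' @param validation_fraction Fraction of unique training pairs held out
#'   (stratified) for early stopping and best-epoch weight selection; 0
#'   disables. Validation pairs never enter the oversampled training
#'   stream, and the returned model carries the weights of the best
#'   validation epoch.
#' @param calibrate_threshold With a validation split, replace the decision
#'   threshold by the value maximizing validation MCC after training.
#' @param weight_decay Decoupled L2 weight decay applied to weight matrices
#'   each step.
#' @param l1 Proximal L1 penalty on weight matrices (soft-thresholding by
#'   `learning_rate * l1` after each Adam step); encourages sparse
#'   first-layer feature selection, the network analogue of lasso feature
#'   selection.
#' @param decision_threshold Probability cutoff; predicted label is 1 when
#'   probability >= threshold.
#' @param seed RNG seed controlling weight initialization, shuffling and
#'   dropout.
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(hidden_sizes = c(512L, 256L),
                       activation = c("relu", "tanh"),
                       dropout = 0, learning_rate = 1e-3,
                       weight_decay = 1e-4, l1 = 0,
                       batch_size = 256L, max_epochs = 50L,
                       early_stop_patience = 10L,
                       validation_fraction = 0,
                       calibrate_threshold = FALSE,
                       decision_threshold = 0.5, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(all(hidden_sizes >= 1L), dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
            weight_decay >= 0, l1 >= 0,
            validation_fraction >= 0, validation_fraction < 1,
            decision_threshold >= 0, decision_threshold <= 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, dropout = dropout,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, l1 = l1,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 validation_fraction = validation_fraction,
                 calibrate_threshold = isTRUE(calibrate_threshold),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.act <- function(z, kind) if (kind == "relu") pmax(z, 0) else tanh(z)
.act_grad <- function(a, kind) if (kind == "relu") (a > 0) * 1 else 1 - a^2

.init_mlp <- function(widths) {
  # He-style initialization; widths = c(input, hidden..., 1)
  W <- list(); b <- list()
  for (l in seq_len(length(widths) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(widths[l] * widths[l + 1L],
                                  sd = sqrt(2 / widths[l])),
                     nrow = widths[l])
    b[[l]] <- numeric(widths[l + 1L])
  }
  list(W = W, b = b)
}

.forward_mlp <- function(par, X, config, train_drop = FALSE) {
  L <- length(par$W)
  A <- list(X)
  for (l in seq_len(L - 1L)) {
    Z <- A[[l]] %*% par$W[[l]]
    Z <- sweep(Z, 2L, par$b[[l]], `+`)
    H <- .act(Z, config$activation)
    if (train_drop && config$dropout > 0) {
      mask <- matrix(stats::runif(length(H)) >= config$dropout, nrow = nrow(H))
      H <- H * mask / (1 - config$dropout)
      attr(H, "mask") <- mask
    }
    A[[l + 1L]] <- H
  }
  Z <- A[[L]] %*% par$W[[L]]
  Z <- sweep(Z, 2L, par$b[[L]], `+`)
  p <- 1 / (1 + exp(-Z))
  list(A = A, p = as.numeric(p))
}

#' Train the pair classifier
#'
#' Optimizes binary cross-entropy with Adam on minibatches drawn from the
#' (typically oversampled) training pair indices. Deterministic given the
#' config seed.
#'
#' @param pd A `pair_dataset` with normalized matrices.
#' @param train_idx Pair index multiset to train on (after
#'   [oversample_positives()]).
#' @param config An [mlp_config()].
#' @param verbose Print per-epoch loss.
#' @return A `trained_mlp`: weights, config, layer widths, the dataset
#'   fingerprint, and the training loss trace.
#' @export
train_mlp <- function(pd, train_idx, config = mlp_config(), verbose = FALSE) {
  if (length(train_idx) == 0L) stop("empty training set")
  y_all <- pd$pairs$label[train_idx]
  if (length(unique(y_all)) < 2L) {
    stop("training subset contains a single class; both labels are required")
  }
  n_in <- ncol(pd$compounds$x) + ncol(pd$pathways$x)
  widths <- c(n_in, config$hidden_sizes, 1L)

  .with_seed(config$seed, {
    vf <- config$validation_fraction %||% 0
    val_idx <- integer(0)
    if (vf > 0) {
      uniq <- unique(train_idx)
      ulab <- pd$pairs$label[uniq]
      for (cls in unique(ulab)) {
        w <- uniq[ulab == cls]
        take <- max(1L, round(vf * length(w)))
        val_idx <- c(val_idx, w[sample.int(length(w), take)])
      }
      train_idx <- train_idx[!(train_idx %in% val_idx)]
      if (length(train_idx) == 0L || length(unique(pd$pairs$label[train_idx])) < 2L) {
        stop("validation split leaves no two-class training data; lower validation_fraction")
      }
    }
    par <- .init_mlp(widths)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    n <- length(train_idx)
    best <- Inf; stale <- 0L
    best_val <- -Inf; best_par <- NULL
    val_trace <- numeric(0)
    losses <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      nb <- ceiling(n / config$batch_size)
      for (bi in seq_len(nb)) {
        sel <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
        idx <- train_idx[sel]
        X <- gather_pair_features(pd, idx)
        y <- pd$pairs$label[idx]
        fw <- .forward_mlp(par, X, config, train_drop = TRUE)
        p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
        loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
        if (!is.finite(loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d batch %d (lr=%g); aborting",
                       epoch, bi, config$learning_rate))
        }
        epoch_loss <- epoch_loss + loss * length(sel)

        # backprop
        L <- length(par$W)
        delta <- matrix((fw$p - y) / length(y), ncol = 1L)
        gW <- vector("list", L); gb <- vector("list", L)
        for (l in rev(seq_len(L))) {
          gW[[l]] <- crossprod(fw$A[[l]], delta)
          gb[[l]] <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(par$W[[l]])
            H <- fw$A[[l]]
            mask <- attr(H, "mask")
            grad <- .act_grad(H, config$activation)
            if (!is.null(mask)) grad <- grad * mask / (1 - config$dropout)
            delta <- delta * grad
          }
        }
        t_step <- t_step + 1L
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
          mhW <- mW[[l]] / (1 - beta1^t_step); vhW <- vW[[l]] / (1 - beta2^t_step)
          mhb <- mb[[l]] / (1 - beta1^t_step); vhb <- vb[[l]] / (1 - beta2^t_step)
          par$W[[l]] <- par$W[[l]] - config$learning_rate *
            (mhW / (sqrt(vhW) + eps) + (config$weight_decay %||% 0) * par$W[[l]])
          l1 <- config$l1 %||% 0
          if (l1 > 0) {
            thr <- config$learning_rate * l1
            par$W[[l]] <- sign(par$W[[l]]) * pmax(abs(par$W[[l]]) - thr, 0)
          }
          par$b[[l]] <- par$b[[l]] - config$learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      epoch_loss <- epoch_loss / n
      losses <- c(losses, epoch_loss)
      if (vf > 0) {
        Xv <- gather_pair_features(pd, val_idx)
        pv <- .forward_mlp(par, Xv, config)$p
        val_mcc <- mcc(tally_confusion(as.integer(pv >= config$decision_threshold),
                                       pd$pairs$label[val_idx]))
        val_trace <- c(val_trace, val_mcc)
        if (verbose) message(sprintf("epoch %d: loss %.5f val MCC %.4f",
                                     epoch, epoch_loss, val_mcc))
        if (val_mcc > best_val + 1e-6) {
          best_val <- val_mcc; best_par <- par; stale <- 0L
        } else {
          stale <- stale + 1L
          if (is.finite(config$early_stop_patience) &&
              stale >= config$early_stop_patience) break
        }
      } else {
        if (verbose) message(sprintf("epoch %d: loss %.5f", epoch, epoch_loss))
        if (epoch_loss < best - 1e-6) { best <- epoch_loss; stale <- 0L }
        else {
          stale <- stale + 1L
          if (is.finite(config$early_stop_patience) &&
              stale >= config$early_stop_patience) break
        }
      }
    }
    if (vf > 0 && !is.null(best_par)) par <- best_par
    if (vf > 0 && isTRUE(config$calibrate_threshold)) {
      Xv <- gather_pair_features(pd, val_idx)
      pv <- .forward_mlp(list(W = par$W, b = par$b), Xv, config)$p
      yv <- pd$pairs$label[val_idx]
      cand <- sort(unique(round(pv, 4)))
      if (length(cand) > 200L) cand <- stats::quantile(pv, seq(0.005, 0.995, length.out = 200))
      scores <- vapply(cand, function(th) {
        mcc(tally_confusion(as.integer(pv >= th), yv))
      }, numeric(1))
      config$decision_threshold <- unname(cand[which.max(scores)])
    }
    structure(list(par = par, config = config, widths = widths,
                   val_trace = if (vf > 0) val_trace else NULL,
                   best_val_mcc = if (vf > 0) best_val else NULL,
                   n_compound_cols = ncol(pd$compounds$x),
                   n_pathway_cols = ncol(pd$pathways$x),
                   fingerprint = dataset_fingerprint(pd),
                   losses = losses),
              class = "trained_mlp")
  })
}

#' Dataset fingerprint
#'
#' Digest of the color vocabulary, normalization statistics and featurization
#' configs; models refuse mismatched feature spaces unless overridden.
#'
#' @param pd A `pair_dataset`.
#' @return Hash string.
#' @export
dataset_fingerprint <- function(pd) {
  rlang::hash(list(colnames(pd$compounds$x), colnames(pd$pathways$x),
                   pd$compounds$norm_stats, pd$pathways$norm_stats,
                   pd$compounds$coloring, pd$compounds$std))
}

#' Predict pair probabilities and labels
#'
#' @param model A `trained_mlp`.
#' @param compound_rows,pathway_rows Matrices (or vectors) of normalized
#'   feature rows, one per prediction; widths must match the model.
#' @param batch_size Prediction batch size.
#' @return Data frame with `probability` and `label`
#'   (1 when probability >= the config decision threshold).
#' @export
predict_rows <- function(model, compound_rows, pathway_rows, batch_size = 4096L) {
  if (is.null(dim(compound_rows))) compound_rows <- matrix(compound_rows, nrow = 1L)
  if (is.null(dim(pathway_rows))) pathway_rows <- matrix(pathway_rows, nrow = 1L)
  if (ncol(compound_rows) != model$n_compound_cols ||
      ncol(pathway_rows) != model$n_pathway_cols) {
    stop(sprintf("feature width mismatch: model expects %d + %d columns, got %d + %d",
                 model$n_compound_cols, model$n_pathway_cols,
                 ncol(compound_rows), ncol(pathway_rows)))
  }
  stopifnot(nrow(compound_rows) == nrow(pathway_rows))
  n <- nrow(compound_rows)
  p <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    X <- cbind(as.matrix(compound_rows[sel, , drop = FALSE]),
               as.matrix(pathway_rows[sel, , drop = FALSE]))
    p[sel] <- .forward_mlp(model$par, X, model$config)$p
  }
  data.frame(probability = p,
             label = as.integer(p >= model$config$decision_threshold))
}

#' Predict on pairs of a dataset
#'
#' @param model A `trained_mlp`.
#' @param pd A `pair_dataset`.
#' @param idx Pair indices (default all).
#' @param check_fingerprint Refuse a dataset whose fingerprint differs from
#'   the training one (set `FALSE` to predict on a compatible projection).
#' @param batch_size Prediction batch size.
#' @return Data frame `probability`, `label`.
#' @export
predict_pairs <- function(model, pd, idx = seq_len(nrow(pd$pairs)),
                          check_fingerprint = TRUE, batch_size = 4096L) {
  if (check_fingerprint && !identical(model$fingerprint, dataset_fingerprint(pd))) {
    stop("dataset fingerprint mismatch; pass check_fingerprint = FALSE to override")
  }
  predict_rows(model,
               pd$compounds$x[pd$pairs$ci[idx], , drop = FALSE],
               pd$pathways$x[pd$pairs$pi[idx], , drop = FALSE],
               batch_size = batch_size)
}

#' Project a new compound into a trained feature space
#'
#' Standardizes and featurizes the compound with the dataset's configs,
#' keeps only colors in the training vocabulary (reporting the out-of-
#' vocabulary count mass), and applies the frozen softmax -> min-max
#' transform using the training matrix's per-column statistics. Projecting a
#' training compound reproduces its stored row exactly.
#'
#' @param g A `mol_graph`.
#' @param pd The training `pair_dataset`.
#' @return List with `row` (normalized feature row), `raw` (retained raw
#'   counts over the vocabulary) and `oov_fraction`.
#' @export
project_new_compound <- function(g, pd) {
  cm <- pd$compounds
  if (!cm$normalized) stop("training compound matrix must be normalized")
  gs <- standardize(g, cm$std %||% std_config("none"))
  f <- featurize(gs, cm$coloring %||% coloring_config())
  vocab <- colnames(cm$x)
  raw <- numeric(length(vocab))
  names(raw) <- vocab
  hit <- intersect(names(f), vocab)
  raw[hit] <- f[hit]
  # colors merged into a column at dedup time are still in-vocabulary;
  # only colors never seen in training count as out-of-vocabulary mass
  known <- unlist(cm$col_meta %||% as.list(vocab))
  total <- sum(f)
  oov <- if (total == 0) 0 else 1 - sum(f[names(f) %in% known]) / total
  sm <- .softmax_rows(matrix(raw, nrow = 1L))
  row <- .minmax_cols(sm, cm$norm_stats$col_min, cm$norm_stats$col_max)
  row <- matrix(row, nrow = 1L, dimnames = list(NULL, vocab))
  list(row = row, raw = raw, oov_fraction = oov)
}
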