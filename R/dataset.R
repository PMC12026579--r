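# Dataset construction: compound and pathway feature matrices, feature-wise
# and entry-wise de-duplication, softmax + min-max normalization, and the
# block-diagonal compound x pathway pair dataset.

.ann_key <- function(kb, pid) paste(kb, pid, sep = "\t")

.new_feature_matrix <- function(x, entity_class, row_meta, col_meta,
                                row_annot = NULL) {
  structure(list(
    x = x, entity_class = entity_class, row_meta = row_meta,
    col_meta = col_meta, row_annot = row_annot,
    deduped = FALSE, normalized = FALSE, norm_stats = NULL,
    coloring = NULL, std = NULL
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix [%s]: %d rows x %d cols; deduped=%s normalized=%s>\n",
              x$entity_class, nrow(x$x), ncol(x$x), x$deduped, x$normalized))
  invisible(x)
}

#' Build the compound feature matrix (raw counts)
#'
#' Standardizes each compound per `std`, featurizes it with the atom-coloring
#' configuration, and assembles the sparse count matrix with one column per
#' distinct color observed anywhere in the corpus and one row per compound
#' record (pre-deduplication). Columns are in lexicographic color order.
#'
#' @param records List of compound records spanning one or more
#'   knowledgebases.
#' @param coloring A [coloring_config()].
#' @param std A [std_config()].
#' @param on_error Standardization failure policy, see
#'   [standardize_records()].
#' @return A `feature_matrix` with `entity_class = "compound"`; the
#'   standardization manifest is attached as attribute `"manifest"`.
#' @export
build_compound_matrix <- function(records, coloring = coloring_config(),
                                  std = std_config("none"),
                                  on_error = c("fail", "skip")) {
  if (length(records) == 0L) stop("no compound records supplied")
  sr <- standardize_records(records, std, on_error = match.arg(on_error))
  records <- sr$records
  if (length(records) == 0L) stop("all compound records failed standardization")
  feats <- lapply(records, function(r) featurize(r$graph, coloring))
  colors <- sort(unique(unlist(lapply(feats, names))), method = "radix")
  ii <- integer(); jj <- integer(); vv <- integer()
  for (r in seq_along(feats)) {
    f <- feats[[r]]
    ii <- c(ii, rep.int(r, length(f)))
    jj <- c(jj, match(names(f), colors))
    vv <- c(vv, as.integer(f))
  }
  x <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(vv),
                            dims = c(length(records), length(colors)))
  rownames(x) <- vapply(records, function(r) paste(r$source_kb, r$compound_id, sep = ":"),
                        character(1))
  colnames(x) <- colors
  fm <- .new_feature_matrix(
    x, "compound",
    row_meta = lapply(records, function(r) data.frame(
      kb = r$source_kb, id = r$compound_id, stringsAsFactors = FALSE)),
    col_meta = as.list(colors),
    row_annot = lapply(records, function(r) {
      if (length(r$pathway_ids) == 0L) character() else .ann_key(r$source_kb, r$pathway_ids)
    })
  )
  fm$coloring <- coloring
  fm$std <- std
  attr(fm, "manifest") <- sr$manifest
  fm
}

#' Aggregate pathway feature vectors (raw counts)
#'
#' A pathway's feature row is the elementwise sum of the raw count rows of
#' its member compounds, i.e. the counts of the atom colors across all
#' compounds within the pathway. Pathways whose members all failed to
#' resolve in the compound matrix are dropped with a warning.
#'
#' @param pathways List of pathway records.
#' @param compound_matrix The raw (pre-dedup) compound `feature_matrix`.
#' @return A `feature_matrix` with `entity_class = "pathway"` sharing the
#'   compound matrix's column space.
#' @export
aggregate_pathway_features <- function(pathways, compound_matrix) {
  if (length(pathways) == 0L) stop("no pathway records supplied")
  if (compound_matrix$normalized) {
    stop("pathway aggregation requires raw compound counts, not normalized rows")
  }
  cx <- compound_matrix$x
  keys <- rownames(cx)
  rows <- list(); meta <- list(); dropped <- character()
  for (p in pathways) {
    mk <- paste(p$source_kb, p$member_compound_ids, sep = ":")
    hit <- mk[mk %in% keys]
    if (length(hit) == 0L) {
      dropped <- c(dropped, p$pathway_id)
      next
    }
    rows[[length(rows) + 1L]] <- Matrix::colSums(cx[hit, , drop = FALSE])
    meta[[length(meta) + 1L]] <- data.frame(kb = p$source_kb, id = p$pathway_id,
                                            stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0L) {
    warning(sprintf("dropping pathways with no resolvable members: %s",
                    paste(dropped, collapse = ", ")))
  }
  if (length(rows) == 0L) stop("no pathway has resolvable members")
  x <- Matrix::Matrix(do.call(rbind, rows), sparse = TRUE)
  rownames(x) <- vapply(meta, function(m) paste(m$kb[1], m$id[1], sep = ":"), character(1))
  colnames(x) <- colnames(cx)
  .new_feature_matrix(x, "pathway", row_meta = meta,
                      col_meta = compound_matrix$col_meta)
}

# canonical string key per row of a sparse matrix (column index:value pairs)
.row_keys <- function(x) {
  t <- methods::as(methods::as(x, "TsparseMatrix"), "generalMatrix")
  keys <- rep.int("", nrow(x))
  if (length(t@i) > 0L) {
    ord <- order(t@i, t@j)
    i <- t@i[ord] + 1L; j <- t@j[ord]; v <- t@x[ord]
    keep <- v != 0
    parts <- split(paste0(j[keep], ":", v[keep]), i[keep])
    keys[as.integer(names(parts))] <- vapply(parts, paste, character(1), collapse = ",")
  }
  keys
}

#' De-duplicate a feature matrix entry-wise and feature-wise
#'
#' Entry-wise: rows with identical count vectors are merged; the merged row
#' represents the union of entities and, for compounds, the union of their
#' pathway annotations. Feature-wise: columns identical across all rows are
#' merged, keeping the lexicographically smallest color as representative
#' with the merged color set recorded in `col_meta`.
#'
#' @param fm A raw-count `feature_matrix`.
#' @return The de-duplicated `feature_matrix` (`deduped = TRUE`).
#' @export
dedup <- function(fm) {
  if (fm$normalized) stop("dedup must run on raw counts")
  x <- fm$x
  rk <- .row_keys(x)
  rgrp <- unname(split(seq_len(nrow(x)), match(rk, unique(rk))))
  rgrp <- rgrp[order(vapply(rgrp, min, integer(1)))]
  rkeep <- vapply(rgrp, min, integer(1))
  row_meta <- lapply(rgrp, function(g) do.call(rbind, fm$row_meta[g]))
  row_annot <- if (is.null(fm$row_annot)) NULL else
    lapply(rgrp, function(g) sort(unique(unlist(fm$row_annot[g]))))
  x <- x[rkeep, , drop = FALSE]

  ck <- .row_keys(Matrix::t(x))
  cgrp <- unname(split(seq_len(ncol(x)), match(ck, unique(ck))))
  # representative: lexicographically smallest color in the group; groups
  # ordered by that representative so columns stay in lexicographic order
  col_meta <- lapply(cgrp, function(g) sort(unlist(fm$col_meta[g]), method = "radix"))
  reps <- vapply(col_meta, `[[`, character(1), 1L)
  ord <- order(reps, method = "radix")
  cgrp <- cgrp[ord]; col_meta <- col_meta[ord]; reps <- reps[ord]
  ckeep <- vapply(seq_along(cgrp), function(k) {
    g <- cgrp[[k]]
    g[match(reps[k], unlist(fm$col_meta[g]))]
  }, integer(1))
  x <- x[, ckeep, drop = FALSE]
  colnames(x) <- reps

  out <- fm
  out$x <- x
  out$row_meta <- row_meta
  out$row_annot <- row_annot
  out$col_meta <- col_meta
  out$deduped <- TRUE
  out
}

#' Normalize a feature matrix (softmax entry-wise, min-max feature-wise)
#'
#' Step 1: softmax across each row's columns (max-subtracted for numerical
#' stability). Step 2: per-column min-max scaling over this entity class's
#' rows, with constant columns mapped to 0. Not idempotent by design:
#' applying it twice is an error. The post-softmax per-column min/max are
#' stored in `norm_stats` so new compounds can be projected with the frozen
#' training transform.
#'
#' @param fm A de-duplicated raw-count `feature_matrix`.
#' @return The normalized `feature_matrix` (dense values in `[0, 1]`).
#' @export
normalize_features <- function(fm) {
  if (fm$normalized) stop("feature matrix is already normalized")
  if (!fm$deduped) stop("normalize_features expects a de-duplicated matrix")
  d <- as.matrix(fm$x)
  sm <- .softmax_rows(d)
  cmin <- apply(sm, 2L, min)
  cmax <- apply(sm, 2L, max)
  out <- .minmax_cols(sm, cmin, cmax)
  dimnames(out) <- dimnames(d)
  fm$x <- out
  fm$normalized <- TRUE
  fm$norm_stats <- list(col_min = cmin, col_max = cmax)
  fm
}

.softmax_rows <- function(d) {
  mx <- apply(d, 1L, max)
  e <- exp(d - mx)
  e / rowSums(e)
}

.minmax_cols <- function(sm, cmin, cmax) {
  rng <- cmax - cmin
  out <- sweep(sm, 2L, cmin, `-`)
  out <- sweep(out, 2L, ifelse(rng == 0, 1, rng), `/`)
  out[, rng == 0] <- 0
  out
}

.row_kbs <- function(fm) lapply(fm$row_meta, function(m) unique(m$kb))

#' Cross-join compound and pathway rows within knowledgebase blocks
#'
#' Pairs every compound row representing at least one entity of a
#' knowledgebase with every pathway row representing at least one pathway of
#' the same knowledgebase (block diagonalization); a pair appearing in
#' several blocks (merged rows spanning knowledgebases) is emitted once,
#' with every witnessing knowledgebase recorded. The label is 1 iff some
#' represented compound is annotated to some represented pathway (union
#' semantics after merging).
#'
#' @param compounds,pathways De-duplicated, normalized `feature_matrix`
#'   objects.
#' @return A `pair_dataset`: the two matrices plus a pair table
#'   (`ci`, `pi`, `label`, `kbs` comma-joined witnesses) and a block summary.
#' @export
cross_join <- function(compounds, pathways) {
  stopifnot(compounds$entity_class == "compound", pathways$entity_class == "pathway")
  if (!compounds$normalized || !pathways$normalized) {
    stop("cross_join expects de-duplicated, normalized matrices")
  }
  ckbs <- .row_kbs(compounds)
  pkbs <- .row_kbs(pathways)
  kbs <- sort(unique(c(unlist(ckbs), unlist(pkbs))))
  pkeys <- lapply(pathways$row_meta, function(m) .ann_key(m$kb, m$id))

  blocks <- data.frame(kb = character(), n_compound_rows = integer(),
                       n_pathway_rows = integer(), stringsAsFactors = FALSE)
  ci_all <- integer(); pi_all <- integer(); kb_all <- character()
  for (kb in kbs) {
    ci <- which(vapply(ckbs, function(k) kb %in% k, logical(1)))
    pi <- which(vapply(pkbs, function(k) kb %in% k, logical(1)))
    blocks <- rbind(blocks, data.frame(kb = kb, n_compound_rows = length(ci),
                                       n_pathway_rows = length(pi),
                                       stringsAsFactors = FALSE))
    if (length(ci) == 0L || length(pi) == 0L) next
    grid <- expand.grid(ci = ci, pi = pi, KEEP.OUT.ATTRS = FALSE)
    ci_all <- c(ci_all, grid$ci)
    pi_all <- c(pi_all, grid$pi)
    kb_all <- c(kb_all, rep.int(kb, nrow(grid)))
  }
  key <- paste(ci_all, pi_all)
  wit <- vapply(split(kb_all, key), paste, character(1), collapse = ",")
  first <- !duplicated(key)
  pairs <- data.frame(ci = ci_all[first], pi = pi_all[first],
                      stringsAsFactors = FALSE)
  pairs$kbs <- unname(wit[paste(pairs$ci, pairs$pi)])
  ann <- compounds$row_annot
  pairs$label <- vapply(seq_len(nrow(pairs)), function(r) {
    as.integer(any(ann[[pairs$ci[r]]] %in% pkeys[[pairs$pi[r]]]))
  }, integer(1))

  structure(list(compounds = compounds, pathways = pathways,
                 pairs = pairs, blocks = blocks),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset: %d pairs (%d positive) over %d blocks; %d compound x %d pathway rows>\n",
              nrow(x$pairs), sum(x$pairs$label), nrow(x$blocks),
              nrow(x$compounds$x), nrow(x$pathways$x)))
  invisible(x)
}

#' Pair label accessor
#'
#' @param pd A `pair_dataset`.
#' @param i Compound row index.
#' @param j Pathway row index.
#' @return 0/1 label; errors if the pair lies outside every knowledgebase
#'   block (such pairs do not exist in the dataset).
#' @export
pair_label <- function(pd, i, j) {
  hit <- which(pd$pairs$ci == i & pd$pairs$pi == j)
  if (length(hit) == 0L) stop(sprintf("pair (%d, %d) lies outside all knowledgebase blocks", i, j))
  pd$pairs$label[hit]
}

#' Oversample positive training pairs
#'
#' Duplicates each positive training pair `k = max(1, round(n_neg / n_pos))`
#' times so positive and negative counts roughly balance; negatives appear
#' once. Applied to training folds only, never to test folds.
#'
#' @param pd A `pair_dataset`.
#' @param train_idx Indices into `pd$pairs` forming the training subset.
#' @return Integer multiset of pair indices.
#' @export
oversample_positives <- function(pd, train_idx) {
  lab <- pd$pairs$label[train_idx]
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  if (n_pos == 0L) stop("degenerate split: no positive pairs in the training subset")
  k <- max(1L, as.integer(round(n_neg / n_pos)))
  c(train_idx[lab == 0L], rep(train_idx[lab == 1L], each = k))
}

#' Gather the dense feature block for a set of pairs
#'
#' Concatenates the compound row and pathway row of each requested pair.
#' This is the only place pair features materialize, so memory is bounded by
#' the batch size rather than the total pair count.
#'
#' @param pd A `pair_dataset`.
#' @param idx Pair indices.
#' @return Dense numeric matrix, `length(idx)` rows.
#' @export
gather_pair_features <- function(pd, idx) {
  cx <- pd$compounds$x
  px <- pd$pathways$x
  if (!is.matrix(cx)) cx <- as.matrix(cx)
  if (!is.matrix(px)) px <- as.matrix(px)
  cbind(cx[pd$pairs$ci[idx], , drop = FALSE],
        px[pd$pairs$pi[idx], , drop = FALSE])
}
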