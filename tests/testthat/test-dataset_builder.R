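# Dataset builder: matrices, dedup, normalization, cross-join, oversampling.
# The worked toy: 2 KBs, 5 compounds (one duplicate), 3 pathways, with
# duplicate feature columns, checked against hand-computed values.

toy_records <- function() {
  list(
    list(compound_id = "c1", source_kb = "KB1", graph = mol_methanol(),
         pathway_ids = c("p1", "p2")),
    list(compound_id = "c2", source_kb = "KB1", graph = mol_methanol(),
         pathway_ids = character()),                     # duplicate structure
    list(compound_id = "c3", source_kb = "KB1", graph = mol_methane(),
         pathway_ids = "p2"),
    list(compound_id = "c4", source_kb = "KB2", graph = mol_ethanol(),
         pathway_ids = "p3"),
    list(compound_id = "c5", source_kb = "KB2", graph = mol_ammonia(),
         pathway_ids = character())
  )
}

toy_pathways <- function() {
  list(
    list(pathway_id = "p1", source_kb = "KB1", member_compound_ids = "c1"),
    list(pathway_id = "p2", source_kb = "KB1", member_compound_ids = c("c1", "c3")),
    list(pathway_id = "p3", source_kb = "KB2", member_compound_ids = "c4")
  )
}

toy_dataset <- function() {
  cm_raw <- build_compound_matrix(toy_records(), coloring_config(max_rounds = 1),
                                  std_config("none"))
  pm_raw <- aggregate_pathway_features(toy_pathways(), cm_raw)
  list(cm_raw = cm_raw, pm_raw = pm_raw,
       cm = normalize_features(dedup(cm_raw)),
       pm = normalize_features(dedup(pm_raw)))
}

test_that("raw compound matrix has one row per record and one column per color", {
  cm <- toy_dataset()$cm_raw
  expect_equal(nrow(cm$x), 5L)
  # methanol: 2 colors; methane 1; ethanol 3; ammonia 1 -> 7 distinct colors
  expect_equal(ncol(cm$x), 7L)
  expect_identical(unname(cm$x["KB1:c1", ]), unname(cm$x["KB1:c2", ]))
  expect_equal(sum(cm$x["KB2:c4", ]), 3)   # ethanol heavy atoms
  expect_error(build_compound_matrix(list()), "no compound records")
})

test_that("pathway rows are sums of member raw rows", {
  d <- toy_dataset()
  expect_equal(unname(as.matrix(d$pm_raw$x)["KB1:p2", ]),
               unname(as.matrix(d$cm_raw$x)["KB1:c1", ] +
                      as.matrix(d$cm_raw$x)["KB1:c3", ]))
  expect_equal(unname(as.matrix(d$pm_raw$x)["KB1:p1", ]),
               unname(as.matrix(d$cm_raw$x)["KB1:c1", ]))
  ghost <- list(list(pathway_id = "px", source_kb = "KB1",
                     member_compound_ids = "nope"))
  expect_warning(expect_error(
    aggregate_pathway_features(ghost, d$cm_raw), "no pathway has"),
    "no resolvable members")
})

test_that("dedup merges identical rows and identical columns with union metadata", {
  d <- toy_dataset()
  cm <- dedup(d$cm_raw)
  expect_equal(nrow(cm$x), 4L)    # c1 and c2 merged
  merged <- which(vapply(cm$row_meta, nrow, integer(1)) == 2L)
  expect_length(merged, 1L)
  expect_setequal(cm$row_meta[[merged]]$id, c("c1", "c2"))
  # annotations of merged entities are combined (c2 contributes none)
  expect_setequal(cm$row_annot[[merged]], c("KB1\tp1", "KB1\tp2"))
  # methanol's two colors form identical columns -> merged; so do ethanol's 3
  expect_equal(ncol(cm$x), 4L)
  sizes <- sort(vapply(cm$col_meta, length, integer(1)))
  expect_equal(sizes, c(1L, 1L, 2L, 3L))
  # conservation of represented entities
  expect_equal(sum(vapply(cm$row_meta, nrow, integer(1))), 5L)
  # already-unique matrix is unchanged
  cm2 <- dedup(cm)
  expect_equal(as.matrix(cm2$x), as.matrix(cm$x))
})

test_that("normalization applies row softmax then column min-max, exactly", {
  # analytic check on a hand-built 2-column matrix: softmax of [0, ln 2]
  fm <- structure(list(
    x = Matrix::Matrix(matrix(c(0, log(2), 0, 0), 2, 2, byrow = TRUE),
                       sparse = TRUE, dimnames = list(c("K:a", "K:b"), c("x", "y"))),
    entity_class = "compound", row_meta = list(data.frame(kb = "K", id = "a"),
                                               data.frame(kb = "K", id = "b")),
    col_meta = list("x", "y"), row_annot = list(character(), character()),
    deduped = TRUE, normalized = FALSE, norm_stats = NULL,
    coloring = coloring_config(), std = std_config("none")),
    class = "feature_matrix")
  nm <- normalize_features(fm)
  # row softmaxes: [1/3, 2/3] and [1/2, 1/2]; then column min-max
  expect_equal(unname(nm$x[1, ]), c(0, 1))
  expect_equal(unname(nm$x[2, ]), c(1, 0))
  sm <- pathcolor:::.softmax_rows(as.matrix(fm$x))
  expect_equal(unname(sm[1, ]), c(1 / 3, 2 / 3))
  expect_equal(nm$norm_stats$col_min, c(x = 1 / 3, y = 1 / 2))
  expect_error(normalize_features(nm), "already normalized")
})

test_that("all-zero rows softmax to uniform and constant columns map to 0", {
  m <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  sm <- pathcolor:::.softmax_rows(m)
  expect_equal(unname(sm[1, ]), rep(1 / 3, 3))
  expect_equal(sum(sm[2, ]), 1)
  cst <- matrix(c(0.2, 0.5, 0.3, 0.7, 0.1, 0.3), 2, 3, byrow = TRUE)
  out <- pathcolor:::.minmax_cols(cst, apply(cst, 2, min), apply(cst, 2, max))
  expect_equal(unname(out[, 3]), c(0, 0))   # constant column maps to 0
  expect_equal(unname(out[, 1]), c(0, 1))
})

test_that("toy normalized compound matrix is the hand-computed permutation pattern", {
  # after dedup each compound row keeps a single distinct color column, so
  # each column attains its softmax max at exactly one row: min-max turns the
  # matrix into a 0/1 permutation matrix
  x <- unname(as.matrix(toy_dataset()$cm$x))
  expect_equal(sort(unique(as.numeric(round(x, 12)))), c(0, 1))
  expect_equal(unname(rowSums(x)), rep(1, 4))
  expect_equal(unname(colSums(x)), rep(1, 4))
})

test_that("cross-join is block-diagonal with union-semantics labels", {
  d <- toy_dataset()
  pd <- cross_join(d$cm, d$pm)
  # KB1: 2 compound rows x 2 pathway rows; KB2: 2 x 1 -> 6 pairs
  expect_equal(nrow(pd$pairs), 6L)
  expect_equal(sum(pd$blocks$n_compound_rows * pd$blocks$n_pathway_rows), 6L)
  expect_equal(sum(pd$pairs$label), 4L)
  # every pair has a shared-KB witness
  expect_true(all(nzchar(pd$pairs$kbs)))
  # labels: merged methanol row positive for p1 and p2; methane for p2;
  # ethanol for p3; ammonia row all negative
  lab <- matrix(NA_integer_, nrow(d$cm$x), nrow(d$pm$x),
                dimnames = list(rownames(d$cm$x), rownames(d$pm$x)))
  for (r in seq_len(nrow(pd$pairs))) {
    lab[pd$pairs$ci[r], pd$pairs$pi[r]] <- pd$pairs$label[r]
  }
  expect_equal(lab["KB1:c1", "KB1:p1"], 1L)
  expect_equal(lab["KB1:c1", "KB1:p2"], 1L)
  expect_equal(lab["KB1:c3", "KB1:p1"], 0L)
  expect_equal(lab["KB1:c3", "KB1:p2"], 1L)
  expect_equal(lab["KB2:c4", "KB2:p3"], 1L)
  expect_equal(lab["KB2:c5", "KB2:p3"], 0L)
  # cross-KB cells were never emitted
  expect_true(all(is.na(lab["KB1:c1", "KB2:p3"])))
  expect_error(pair_label(pd, which(rownames(d$cm$x) == "KB1:c1"),
                          which(rownames(d$pm$x) == "KB2:p3")),
               "outside all knowledgebase blocks")
})

test_that("pipeline determinism: same inputs give bit-identical datasets", {
  d1 <- toy_dataset(); d2 <- toy_dataset()
  expect_identical(as.matrix(d1$cm$x), as.matrix(d2$cm$x))
  pd1 <- cross_join(d1$cm, d1$pm); pd2 <- cross_join(d2$cm, d2$pm)
  expect_identical(pd1$pairs, pd2$pairs)
})

test_that("a merged row spanning KBs is paired once per pathway row with both witnesses", {
  recs <- c(toy_records(),
            list(list(compound_id = "c6", source_kb = "KB2",
                      graph = mol_methane(), pathway_ids = character())))
  cm <- normalize_features(dedup(build_compound_matrix(
    recs, coloring_config(max_rounds = 1), std_config("none"))))
  pm <- normalize_features(dedup(aggregate_pathway_features(toy_pathways(),
    build_compound_matrix(recs, coloring_config(max_rounds = 1), std_config("none")))))
  pd <- cross_join(cm, pm)
  # methane row now represents KB1:c3 and KB2:c6 -> paired with all 3 pathway rows
  methane_row <- which(vapply(cm$row_meta, function(m) "c3" %in% m$id, logical(1)))
  got <- pd$pairs[pd$pairs$ci == methane_row, ]
  expect_equal(nrow(got), 3L)
  expect_false(anyDuplicated(paste(got$ci, got$pi)) > 0)
})

test_that("oversampling duplicates positives by the stated rounding rule", {
  d <- toy_dataset()
  pd <- cross_join(d$cm, d$pm)
  with_labels <- function(lab) {
    fake <- pd
    fake$pairs <- data.frame(ci = 1L, pi = 1L, kbs = "KB1", label = lab)
    fake
  }
  fake <- with_labels(rep(c(1L, 0L), c(10, 95)))
  os <- oversample_positives(fake, seq_len(105))
  expect_equal(sum(fake$pairs$label[os] == 1L), 100L)   # k = round(95/10) = 10
  expect_equal(sum(fake$pairs$label[os] == 0L), 95L)
  os2 <- oversample_positives(with_labels(rep(c(1L, 0L), c(3, 4))), seq_len(7))
  expect_equal(length(os2), 7L)                          # k = round(4/3) = 1
  expect_equal(sort(oversample_positives(with_labels(rep(c(1L, 0L), c(5, 5))),
                                         seq_len(10))), 1:10)
  expect_error(oversample_positives(with_labels(rep(0L, 10)), seq_len(10)),
               "no positive")
})
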