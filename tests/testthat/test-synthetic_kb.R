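# Synthetic knowledgebase generator: determinism, valence validity,
# motif-driven memberships, representation perturbations.

small_cfg <- function(...) {
  synthetic_config(n_kbs = 2L, compounds_per_kb = 20L, pathways_per_kb = 6L, ...)
}

test_that("generation is fully deterministic given the seed", {
  a <- generate_synthetic_kb(small_cfg(seed = 5, crossref_fraction = 0.3))
  b <- generate_synthetic_kb(small_cfg(seed = 5, crossref_fraction = 0.3))
  expect_identical(lapply(a$compounds, function(r) write_molfile(r$graph)),
                   lapply(b$compounds, function(r) write_molfile(r$graph)))
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$crossref, b$crossref)
  c <- generate_synthetic_kb(small_cfg(seed = 6, crossref_fraction = 0.3))
  expect_false(identical(a$annotations, c$annotations))
})

test_that("every emitted molecule reparses and is valence-valid", {
  skb <- generate_synthetic_kb(small_cfg(seed = 7, crossref_fraction = 0.5))
  for (r in skb$compounds) {
    g2 <- parse_molfile(write_molfile(r$graph))
    expect_false(any(g2$atoms$valence_flag), label = r$compound_id)
    expect_equal(g2$atoms$element, r$graph$atoms$element)
  }
})

test_that("with zero noise the annotations equal the motif-containment truth", {
  skb <- generate_synthetic_kb(small_cfg(seed = 8, membership_noise = 0))
  for (kb in names(skb$truth)) {
    tr <- skb$truth[[kb]]
    ann <- skb$annotations[skb$annotations$kb == kb, ]
    got <- matrix(FALSE, nrow(tr), ncol(tr), dimnames = dimnames(tr))
    for (r in seq_len(nrow(ann))) got[ann$compound_id[r], ann$pathway_id[r]] <- TRUE
    expect_identical(got, tr)
  }
})

test_that("annotation noise only removes true memberships", {
  skb <- generate_synthetic_kb(small_cfg(seed = 9, membership_noise = 0.2))
  for (kb in names(skb$truth)) {
    ann <- skb$annotations[skb$annotations$kb == kb, ]
    orig <- ann[!grepl("^X_", ann$compound_id), ]
    for (r in seq_len(nrow(orig))) {
      expect_true(skb$truth[[kb]][orig$compound_id[r], orig$pathway_id[r]])
    }
  }
})

test_that("per-KB signatures are disjoint when the library allows", {
  skb <- generate_synthetic_kb(synthetic_config(
    n_kbs = 3L, compounds_per_kb = 10L, pathways_per_kb = 8L, seed = 10))
  # 24 pathways over a 30-motif library: all signature motifs distinct, so no
  # two pathways anywhere have identical member-defining rules
  mem <- lapply(skb$truth, function(m) m)
  expect_length(mem, 3L)
})

test_that("perturbations preserve chemical identity in the intended way", {
  g_amide <- mol_acetamide()
  t1 <- perturb_representation(g_amide, "tautomer_swap")
  expect_false(identical(featurize(t1), featurize(g_amide)))
  t2 <- perturb_representation(t1, "tautomer_swap")   # involution
  expect_identical(featurize(t2), featurize(g_amide))

  g_nitro <- mol_nitro_charged()
  r1 <- perturb_representation(g_nitro, "resonance_charge_form")
  expect_false(identical(featurize(r1), featurize(g_nitro)))
  expect_identical(featurize(standardize(r1, std_config("inchi"))),
                   featurize(standardize(g_nitro, std_config("inchi"))))
  r2 <- perturb_representation(r1, "resonance_charge_form")
  expect_identical(featurize(r2), featurize(g_nitro))

  set.seed(1)
  g <- fixture_corpus(n = 3, seed = 11)[[1]]
  expect_identical(featurize(perturb_representation(g, "atom_reorder")),
                   featurize(g))
  expect_error(perturb_representation(mol_methane(), "tautomer_swap"),
               "no amide")
  expect_error(perturb_representation(mol_methane(), "resonance_charge_form"),
               "no nitro")
})

test_that("tautomer and resonance library pairs unify under InChI", {
  std <- std_config("inchi")
  lib <- default_motif_library()
  base <- function(motif) {
    # ethane scaffold with one grafted motif
    g <- mol_graph(data.frame(element = c("C", "C"), charge = 0L),
                   data.frame(a = 1, b = 2, order = 1L), id = motif)
    pathcolor:::.graft(g, lib[[motif]], 1L)
  }
  for (motif in c("amide", "urea", "thioamide")) {
    g <- base(motif)
    p <- perturb_representation(g, "tautomer_swap")
    expect_false(identical(featurize(p), featurize(g)), label = motif)
    expect_identical(featurize(standardize(p, std)),
                     featurize(standardize(g, std)), label = motif)
  }
  for (motif in c("nitro", "azide", "sulfoxide")) {
    g <- base(motif)
    p <- perturb_representation(g, "resonance_charge_form")
    expect_false(identical(featurize(p), featurize(g)), label = motif)
    expect_identical(featurize(standardize(p, std)),
                     featurize(standardize(g, std)), label = motif)
  }
})

test_that("crossref twins differ from their source only by the recorded perturbation", {
  skb <- generate_synthetic_kb(small_cfg(seed = 12, crossref_fraction = 0.5))
  expect_gt(nrow(skb$crossref), 0L)
  for (r in seq_len(nrow(skb$crossref))) {
    x <- skb$crossref[r, ]
    ga <- skb$graphs[[paste(x$kb_a, x$cid_a, sep = ":")]]
    gb <- skb$graphs[[paste(x$kb_b, x$cid_b, sep = ":")]]
    expect_false(is.null(gb))
    if (x$kind %in% c("atom_reorder", "explicit_h")) {
      expect_identical(featurize(gb), featurize(ga), label = x$kind)
    } else {
      expect_false(identical(featurize(gb), featurize(ga)))
      expect_identical(featurize(standardize(gb, std_config("inchi"))),
                       featurize(standardize(ga, std_config("inchi"))),
                       label = paste(x$kind, x$cid_a))
    }
  }
  # twins are never crossref sources themselves
  expect_false(any(grepl("^X_", skb$crossref$cid_a)))
})

test_that("the perturbation mix is honored by construction", {
  skb <- generate_synthetic_kb(small_cfg(
    seed = 13, crossref_fraction = 0.5,
    perturbation_mix = c(tautomer_swap = 1)))
  expect_true(all(skb$crossref$kind == "tautomer_swap"))
})

test_that("written corpora round-trip through load_knowledgebase", {
  skb <- generate_synthetic_kb(small_cfg(seed = 14))
  dir <- withr::local_tempdir()
  write_synthetic_kb(skb, dir)
  kb1 <- load_knowledgebase(file.path(dir, "KB1", "structures"),
                            file.path(dir, "KB1", "annotations.tsv"), "KB1")
  orig <- Filter(function(r) r$source_kb == "KB1", skb$compounds)
  expect_length(kb1$compounds, length(orig))
  for (r in orig) {
    got <- kb1$compounds[[r$compound_id]]
    expect_identical(featurize(got$graph), featurize(r$graph))
    expect_setequal(got$pathway_ids, r$pathway_ids)
  }
})
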