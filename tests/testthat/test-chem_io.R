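# Molfile V2000 parsing/writing and knowledgebase loading.

test_that("minimal methane molfile parses to one carbon with four implicit H", {
  txt <- paste(c("methane", "", "",
                 "  1  0  0  0  0  0  0  0  0  0999 V2000",
                 "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                 "M  END"), collapse = "\n")
  g <- parse_molfile(txt)
  expect_s3_class(g, "mol_graph")
  expect_equal(nrow(g$atoms), 1L)
  expect_equal(g$atoms$element, "C")
  expect_equal(g$atoms$h_count, 4L)
  expect_equal(nrow(g$bonds), 0L)
})

test_that("write_molfile emits the V2000 counts line and M CHG properties", {
  txt <- write_molfile(mol_methane())
  expect_match(strsplit(txt, "\n")[[1]][4], "^  1  0")
  expect_match(txt, "V2000")

  charged <- mol_graph(data.frame(element = c("C", "O"), charge = c(0L, -1L)),
                       data.frame(a = 1, b = 2, order = 1L), id = "methoxide")
  ctxt <- write_molfile(charged)
  expect_match(ctxt, "M  CHG  1   2  -1", fixed = TRUE)
  expect_equal(parse_molfile(ctxt)$atoms$charge, c(0L, -1L))
})

test_that("round-trip write/parse preserves atoms, bonds, charges and stereo", {
  graphs <- c(list(mol_acetamide(), mol_nitro_charged(), mol_stereocenter(1L),
                   mol_butene(3L)),
              fixture_corpus(n = 15, seed = 3))
  for (g in graphs) {
    g2 <- parse_molfile(write_molfile(g), id = g$id)
    expect_equal(g2$atoms$element, g$atoms$element)
    expect_equal(g2$atoms$charge, g$atoms$charge)
    expect_equal(g2$atoms$h_count, g$atoms$h_count)
    expect_equal(g2$atoms$stereo, g$atoms$stereo)
    expect_equal(g2$bonds[c("a", "b", "order", "stereo")],
                 g$bonds[c("a", "b", "order", "stereo")])
  }
})

test_that("malformed molfiles are rejected with line information", {
  bad_bond <- paste(c("x", "", "",
                      "  2  1  0  0  0  0  0  0  0  0999 V2000",
                      "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                      "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                      "  1  3  1  0  0  0  0",
                      "M  END"), collapse = "\n")
  expect_error(parse_molfile(bad_bond), "outside 1\\.\\.2.*line 7")
  bad_zero <- sub("  1  3  1", "  0  1  1", bad_bond)
  expect_error(parse_molfile(bad_zero), "line 7")
  expect_error(parse_molfile(sub("C  ", "Xx ", bad_bond)), "unknown element")
  expect_error(parse_molfile(sub("V2000", "V3000", bad_bond)), "V3000")
  expect_error(parse_molfile("just one line"), "counts line")
})

test_that("graphs beyond the V2000 size limit are refused", {
  big <- mol_graph(data.frame(element = rep("C", 1000), charge = 0L),
                   data.frame(a = 1:999, b = 2:1000, order = 1L), id = "big")
  expect_error(write_molfile(big), "999")
})

test_that("mol_graph enforces bond and element invariants", {
  expect_error(mol_graph(data.frame(element = "C", charge = 0L),
                         data.frame(a = 1, b = 2, order = 1L)), "outside")
  expect_error(mol_graph(data.frame(element = "C", charge = 0L),
                         data.frame(a = 1, b = 1, order = 1L)), "identical endpoints")
  expect_error(mol_graph(data.frame(element = c("C", "C"), charge = 0L),
                         data.frame(a = c(1, 2), b = c(2, 1), order = 1L)),
               "duplicate")
  expect_error(mol_graph(data.frame(element = "Zz", charge = 0L)), "unknown element")
})

test_that("valence-overflowing atoms are flagged, not rejected", {
  g <- mol_graph(data.frame(element = c("C", rep("F", 5)), charge = 0L),
                 data.frame(a = rep(1, 5), b = 2:6, order = 1L), id = "CF5")
  expect_true(g$atoms$valence_flag[1])
  expect_equal(g$atoms$h_count[1], 0L)
})

test_that("read_sdf splits records on $$$$", {
  sdf <- paste(c(sub("^methane", "m1", write_molfile(mol_methane())), "$$$$",
                 sub("^ammonia", "m2", write_molfile(mol_ammonia())), "$$$$", ""),
               collapse = "\n")
  recs <- read_sdf(sdf)
  expect_length(recs, 2L)
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("m1", "m2"))
})

write_toy_kb <- function(dir, ann_rows) {
  dir.create(file.path(dir, "structures"), recursive = TRUE, showWarnings = FALSE)
  mols <- list(c1 = mol_methanol(), c2 = mol_ethanol(), c3 = mol_methane())
  for (id in names(mols)) {
    writeLines(write_molfile(mols[[id]]), file.path(dir, "structures", paste0(id, ".mol")))
  }
  writeLines(ann_rows, file.path(dir, "annotations.tsv"))
  dir
}

test_that("load_knowledgebase inverts the annotation table", {
  dir <- write_toy_kb(withr::local_tempdir(),
                      c("c1\tp1", "c2\tp1", "c2\tp2"))
  kb <- load_knowledgebase(file.path(dir, "structures"),
                           file.path(dir, "annotations.tsv"), "KBX")
  expect_length(kb$compounds, 3L)
  expect_length(kb$pathways, 2L)
  expect_equal(kb$pathways$p1$member_compound_ids, c("c1", "c2"))
  expect_equal(kb$pathways$p2$member_compound_ids, "c2")
  # compound without annotations is retained with empty pathway set
  expect_equal(kb$compounds$c3$pathway_ids, character(0))
  expect_equal(kb$compounds$c2$source_kb, "KBX")
})

test_that("load_knowledgebase is invariant to annotation row order", {
  d1 <- write_toy_kb(withr::local_tempdir(), c("c1\tp1", "c2\tp1", "c2\tp2"))
  d2 <- write_toy_kb(withr::local_tempdir(), c("c2\tp2", "c2\tp1", "c1\tp1"))
  kb1 <- load_knowledgebase(file.path(d1, "structures"), file.path(d1, "annotations.tsv"), "K")
  kb2 <- load_knowledgebase(file.path(d2, "structures"), file.path(d2, "annotations.tsv"), "K")
  expect_equal(kb1$compounds[order(names(kb1$compounds))],
               kb2$compounds[order(names(kb2$compounds))])
  expect_equal(kb1$pathways, kb2$pathways)
})

test_that("load_knowledgebase errors name offending annotation ids", {
  dir <- write_toy_kb(withr::local_tempdir(), c("c1\tp1", "c9\tp1"))
  expect_error(load_knowledgebase(file.path(dir, "structures"),
                                  file.path(dir, "annotations.tsv"), "K"),
               "c9")
  empty <- withr::local_tempdir()
  dir.create(file.path(empty, "structures"))
  writeLines("c1\tp1", file.path(empty, "ann.tsv"))
  expect_error(load_knowledgebase(file.path(empty, "structures"),
                                  file.path(empty, "ann.tsv"), "K"),
               "empty knowledgebase")
})
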