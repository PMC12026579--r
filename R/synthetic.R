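# Synthetic multi-knowledgebase generator: valence-valid molecules built by
# grafting functional-group motifs onto alkyl/ring scaffolds, motif-driven
# pathway memberships with controllable annotation noise, and cross-reference
# pairs whose two members differ only by a recorded representation
# perturbation (atom order, explicit hydrogens, nitro charge form, or
# amide/imidic-acid tautomer).

.frag <- function(elements, bonds = NULL, charges = NULL, attach = 1L) {
  n <- length(elements)
  list(elements = elements,
       charges = if (is.null(charges)) integer(n) else as.integer(charges),
       bonds = if (is.null(bonds)) data.frame(a = integer(), b = integer(), order = integer())
               else as.data.frame(bonds),
       attach = attach)
}

#' Default functional-group motif library
#'
#' Thirty curated functional-group motifs (halogens, oxygen/nitrogen/sulfur
#' substituents, carbonyl chemistry, rings, charge-bearing groups). Each
#' contributes atom colors distinctive against alkyl/heteroatom scaffold
#' chemistry at neighborhood depth 1, so motif-driven pathway membership is
#' genuinely predictable from color counts. The amide, urea and
#' thioamide motifs carry a mobile hydrogen (tautomer-swappable); the
#' nitro, azide and sulfoxide motifs have an alternate charge-separated
#' drawing (resonance-swappable); all six alternate forms were validated
#' once against the InChI standard as mapping to the same identifier.
#'
#' @return Named list of motif fragments.
#' @export
default_motif_library <- function() {
  b <- function(a, bb, o) data.frame(a = a, b = bb, order = o)
  list(
    hydroxyl = .frag("O"),
    amine    = .frag("N"),
    thiol    = .frag("S"),
    fluoro   = .frag("F"),
    chloro   = .frag("Cl"),
    bromo    = .frag("Br"),
    iodo     = .frag("I"),
    carboxyl = .frag(c("C", "O", "O"), b(c(1, 1), c(2, 3), c(2, 1))),
    amide    = .frag(c("C", "O", "N"), b(c(1, 1), c(2, 3), c(2, 1))),
    nitro    = .frag(c("N", "O", "O"), b(c(1, 1), c(2, 3), c(2, 1)),
                     charges = c(1L, 0L, -1L)),
    formyl   = .frag(c("C", "O"), b(1, 2, 2)),
    nitrile  = .frag(c("C", "N"), b(1, 2, 3)),
    isothiocyanate = .frag(c("N", "C", "S"), b(c(1, 2), c(2, 3), c(2, 2))),
    phenyl   = .frag(rep("C", 6),
                     b(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 1),
                       c(2, 1, 2, 1, 2, 1))),
    sulfo    = .frag(c("S", "O", "O", "O"),
                     b(c(1, 1, 1), c(2, 3, 4), c(2, 2, 1))),
    phosphate = .frag(c("P", "O", "O", "O"),
                      b(c(1, 1, 1), c(2, 3, 4), c(2, 1, 1))),
    methylketone = .frag(c("C", "O", "C"), b(c(1, 1), c(2, 3), c(2, 1))),
    ester    = .frag(c("C", "O", "O", "C"),
                     b(c(1, 1, 3), c(2, 3, 4), c(2, 1, 1))),
    methylsulfonyl = .frag(c("S", "O", "O", "C"),
                           b(c(1, 1, 1), c(2, 3, 4), c(2, 2, 1))),
    dimethylamino = .frag(c("N", "C", "C"), b(c(1, 1), c(2, 3), c(1, 1))),
    oxime    = .frag(c("C", "N", "O"), b(c(1, 2), c(2, 3), c(2, 1))),
    urea     = .frag(c("N", "C", "O", "N"),
                     b(c(1, 2, 2), c(2, 3, 4), c(1, 2, 1))),
    thioamide = .frag(c("C", "S", "N"), b(c(1, 1), c(2, 3), c(2, 1))),
    pyridyl  = .frag(c("N", rep("C", 5)),
                     b(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 1),
                       c(2, 1, 2, 1, 2, 1)), attach = 3L),
    guanidino = .frag(c("N", "C", "N", "N"),
                      b(c(1, 2, 2), c(2, 3, 4), c(1, 2, 1))),
    vinyl    = .frag(c("C", "C"), b(1, 2, 2)),
    isopropyl = .frag(c("C", "C", "C"), b(c(1, 1), c(2, 3), c(1, 1))),
    trifluoromethyl = .frag(c("C", "F", "F", "F"),
                            b(c(1, 1, 1), c(2, 3, 4), c(1, 1, 1))),
    azide    = .frag(c("N", "N", "N"), b(c(1, 2), c(2, 3), c(2, 2)),
                     charges = c(0L, 1L, -1L)),
    sulfoxide = .frag(c("S", "O", "C"), b(c(1, 1), c(2, 3), c(2, 1)))
  )
}

#' Synthetic knowledgebase configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' evaluation: three knowledgebases of 150 compounds and 30 motif-defined
#' pathways each, 5% membership noise.
#'
#' @param n_kbs Number of knowledgebases.
#' @param compounds_per_kb Compounds generated per knowledgebase (before any
#'   cross-reference twins are added).
#' @param pathways_per_kb Pathways per knowledgebase.
#' @param motif_library Named list of motif fragments.
#' @param membership_noise Probability that a true membership is missing
#'   from the annotations (annotation incompleteness).
#' @param crossref_fraction Fraction of each knowledgebase's compounds that
#'   get a cross-reference twin in another knowledgebase.
#' @param perturbation_mix Named weights over `atom_reorder`, `explicit_h`,
#'   `resonance_charge_form`, `tautomer_swap`.
#' @param motifs_per_compound Range of distinct motifs grafted per compound.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_kbs = 3L, compounds_per_kb = 150L,
                             pathways_per_kb = 30L,
                             motif_library = default_motif_library(),
                             membership_noise = 0.05,
                             crossref_fraction = 0,
                             perturbation_mix = c(atom_reorder = 0.25,
                                                  explicit_h = 0.25,
                                                  resonance_charge_form = 0.25,
                                                  tautomer_swap = 0.25),
                             motifs_per_compound = c(3L, 5L),
                             seed = 1L) {
  stopifnot(length(motif_library) > 0L, membership_noise >= 0,
            membership_noise < 0.5, crossref_fraction >= 0,
            crossref_fraction <= 1)
  kinds <- c("atom_reorder", "explicit_h", "resonance_charge_form", "tautomer_swap")
  if (!all(names(perturbation_mix) %in% kinds) || sum(perturbation_mix) <= 0) {
    stop("perturbation_mix must be non-negative weights over the four perturbation kinds")
  }
  mix <- stats::setNames(numeric(4), kinds)
  mix[names(perturbation_mix)] <- perturbation_mix
  structure(list(n_kbs = as.integer(n_kbs),
                 compounds_per_kb = as.integer(compounds_per_kb),
                 pathways_per_kb = as.integer(pathways_per_kb),
                 motif_library = motif_library,
                 membership_noise = membership_noise,
                 crossref_fraction = crossref_fraction,
                 perturbation_mix = mix / sum(mix),
                 motifs_per_compound = as.integer(motifs_per_compound),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# graft a fragment onto graph g at atom `site` (single bond to the fragment's
# attachment atom); returns the grown graph
.graft <- function(g, frag, site) {
  off <- nrow(g$atoms)
  atoms <- data.frame(element = c(g$atoms$element, frag$elements),
                      charge = c(g$atoms$charge, frag$charges),
                      stringsAsFactors = FALSE)
  fb <- frag$bonds
  bonds <- rbind(
    g$bonds[, c("a", "b", "order")],
    if (nrow(fb) > 0L) data.frame(a = fb$a + off, b = fb$b + off, order = fb$order)
    else NULL,
    data.frame(a = site, b = frag$attach + off, order = 1L))
  mol_graph(atoms, bonds, id = g$id)
}

.free_valence <- function(g) {
  sums <- .bond_order_sums(g)
  vapply(seq_len(nrow(g$atoms)), function(i) {
    vals <- .charge_adjusted_valences(g$atoms$element[i], g$atoms$charge[i])
    if (is.null(vals)) 0L else max(0L, as.integer(max(vals) - sums[i]))
  }, integer(1))
}

# one random molecule: a small metabolite-like scaffold (short chain with
# optional heteroatom, unsaturation and methyl branch, or a 5/6-ring with an
# optional ring heteroatom) plus grafted motifs; returns list(graph, motifs)
.random_molecule <- function(config, id) {
  lib <- config$motif_library
  if (stats::runif(1) < 0.2) {
    n_c <- sample(5:6, 1L)
    el <- rep("C", n_c)
    if (stats::runif(1) < 0.4) el[1] <- sample(c("O", "N", "S"), 1L)
    bonds <- data.frame(a = seq_len(n_c), b = c(2:n_c, 1L), order = 1L)
  } else {
    n_c <- sample(1:6, 1L)
    el <- rep("C", n_c)
    if (n_c >= 3 && stats::runif(1) < 0.35) {
      el[sample(2:(n_c - 1L), 1L)] <- sample(c("O", "N", "S"), 1L)
    }
    bonds <- if (n_c > 1L) data.frame(a = seq_len(n_c - 1L), b = 2:n_c, order = 1L)
             else data.frame(a = integer(), b = integer(), order = integer())
    if (n_c >= 2 && stats::runif(1) < 0.3) {
      k <- sample(seq_len(n_c - 1L), 1L)
      if (el[k] == "C" && el[k + 1L] == "C") bonds$order[k] <- 2L
    }
    if (n_c >= 2 && stats::runif(1) < 0.3) {
      el <- c(el, "C")
      bonds <- rbind(bonds, data.frame(a = sample(n_c, 1L), b = length(el), order = 1L))
    }
  }
  g <- mol_graph(data.frame(element = el, charge = 0L, stringsAsFactors = FALSE),
                 bonds, id = id)
  n_scaffold <- nrow(g$atoms)
  k <- sample(seq(config$motifs_per_compound[1], config$motifs_per_compound[2]), 1L)
  k <- min(k, length(lib))
  wanted <- sort(sample(names(lib), k))
  grafted <- character()
  for (m in wanted) {
    for (try in 1:20) {
      fv <- .free_valence(g)[seq_len(n_scaffold)]
      # substituents go on backbone carbons, as in typical metabolites
      open <- which(fv >= 1L & g$atoms$element[seq_len(n_scaffold)] == "C")
      if (length(open) == 0L) break
      site <- open[sample.int(length(open), 1L)]
      g2 <- tryCatch(.graft(g, lib[[m]], site), error = function(e) NULL)
      if (!is.null(g2)) { g <- g2; grafted <- c(grafted, m); break }
    }
  }
  # only successfully grafted motifs define the compound's chemistry
  list(graph = g, motifs = grafted)
}

# ---- representation perturbations -----------------------------------------

# Resonance-swappable sites: nitro (pentavalent vs charge-separated), azide
# (cumulated vs charge-localized), sulfoxide (S=O vs S+-O-). All alternate
# drawings map to one InChI.
.find_resonance_site <- function(g) {
  adj <- .adjacency(g)
  for (i in seq_len(nrow(g$atoms))) {
    el <- g$atoms$element[i]
    nb <- adj[[i]]
    if (el == "N") {
      o_sel <- g$atoms$element[nb$nbr] == "O"
      o_idx <- nb$nbr[o_sel]; o_ord <- nb$order[o_sel]
      if (length(o_idx) == 2L) {
        chg <- g$atoms$charge[o_idx]
        if (g$atoms$charge[i] == 1L && setequal(o_ord, c(1L, 2L)) &&
            min(chg) == -1L) {
          return(list(kind = "nitro", form = "charge_separated", n = i,
                      o_single = o_idx[o_ord == 1L], o_double = o_idx[o_ord == 2L]))
        }
        if (g$atoms$charge[i] == 0L && all(o_ord == 2L) && all(chg == 0L)) {
          return(list(kind = "nitro", form = "pentavalent", n = i, o_pair = o_idx))
        }
      }
      n_sel <- g$atoms$element[nb$nbr] == "N"
      if (g$atoms$charge[i] == 1L && sum(n_sel) == 2L) {
        n_idx <- nb$nbr[n_sel]; n_ord <- nb$order[n_sel]
        deg <- vapply(n_idx, function(j) length(adj[[j]]$nbr), integer(1))
        if (all(n_ord == 2L) && any(deg == 1L)) {
          term <- n_idx[deg == 1L][1]
          return(list(kind = "azide", form = "cumulated", center = i,
                      inner = n_idx[n_idx != term][1], terminal = term))
        }
        if (setequal(n_ord, c(1L, 3L))) {
          return(list(kind = "azide", form = "localized", center = i,
                      inner = n_idx[n_ord == 1L], terminal = n_idx[n_ord == 3L]))
        }
      }
    }
    if (el == "S") {
      o_sel <- g$atoms$element[nb$nbr] == "O"
      if (sum(o_sel) == 1L) {
        o <- nb$nbr[o_sel]; oo <- nb$order[o_sel]
        if (g$atoms$charge[i] == 0L && oo == 2L && g$atoms$charge[o] == 0L) {
          return(list(kind = "sulfoxide", form = "double", s = i, o = o))
        }
        if (g$atoms$charge[i] == 1L && oo == 1L && g$atoms$charge[o] == -1L) {
          return(list(kind = "sulfoxide", form = "charged", s = i, o = o))
        }
      }
    }
  }
  NULL
}

.apply_resonance_swap <- function(g, site) {
  if (site$kind == "nitro") {
    if (site$form == "charge_separated") {
      g$atoms$charge[site$n] <- 0L
      g$atoms$charge[site$o_single] <- 0L
      g <- .set_bond_order(g, site$n, site$o_single, 2L)
    } else {
      o2 <- max(site$o_pair)
      g$atoms$charge[site$n] <- 1L
      g$atoms$charge[o2] <- -1L
      g <- .set_bond_order(g, site$n, o2, 1L)
    }
  } else if (site$kind == "azide") {
    if (site$form == "cumulated") {
      g$atoms$charge[site$inner] <- -1L
      g$atoms$charge[site$terminal] <- 0L
      g <- .set_bond_order(g, site$center, site$inner, 1L)
      g <- .set_bond_order(g, site$center, site$terminal, 3L)
    } else {
      g$atoms$charge[site$inner] <- 0L
      g$atoms$charge[site$terminal] <- -1L
      g <- .set_bond_order(g, site$center, site$inner, 2L)
      g <- .set_bond_order(g, site$center, site$terminal, 2L)
    }
  } else {
    if (site$form == "double") {
      g$atoms$charge[site$s] <- 1L
      g$atoms$charge[site$o] <- -1L
      g <- .set_bond_order(g, site$s, site$o, 1L)
    } else {
      g$atoms$charge[site$s] <- 0L
      g$atoms$charge[site$o] <- 0L
      g <- .set_bond_order(g, site$s, site$o, 2L)
    }
  }
  g
}

# Mobile-hydrogen (tautomer) sites: C(=X)-N(H) <-> C(-XH)=N for X in {O, S}
# (amide, urea, thioamide and their imidic forms).
.find_amide_site <- function(g) {
  adj <- .adjacency(g)
  for (i in seq_len(nrow(g$atoms))) {
    if (g$atoms$element[i] != "C") next
    nb <- adj[[i]]
    is_x <- g$atoms$element[nb$nbr] %in% c("O", "S")
    x_d <- nb$nbr[is_x & nb$order == 2L]
    x_d <- x_d[g$atoms$charge[x_d] == 0L]
    n_s <- nb$nbr[g$atoms$element[nb$nbr] == "N" & nb$order == 1L]
    n_s <- n_s[g$atoms$h_count[n_s] >= 1L & g$atoms$charge[n_s] == 0L]
    if (length(x_d) == 1L && length(n_s) >= 1L) {
      return(list(c = i, x = x_d, n = n_s[1], form = "amide"))
    }
    n_d <- nb$nbr[g$atoms$element[nb$nbr] == "N" & nb$order == 2L]
    x_s <- nb$nbr[is_x & nb$order == 1L]
    x_s <- x_s[g$atoms$h_count[x_s] >= 1L & g$atoms$charge[x_s] == 0L]
    if (length(n_d) == 1L && length(x_s) >= 1L) {
      return(list(c = i, x = x_s[1], n = n_d, form = "imidic"))
    }
  }
  NULL
}

.set_bond_order <- function(g, a, b, order) {
  hit <- which((g$bonds$a == a & g$bonds$b == b) | (g$bonds$a == b & g$bonds$b == a))
  stopifnot(length(hit) == 1L)
  g$bonds$order[hit] <- order
  g
}

.rebuild <- function(g) {
  # re-derive implicit hydrogens from the valence table after an edit
  mol_graph(data.frame(element = g$atoms$element, charge = g$atoms$charge,
                       stereo = g$atoms$stereo, isotope = g$atoms$isotope,
                       stringsAsFactors = FALSE),
            g$bonds, id = g$id)
}

#' Perturb the representation of a molecule
#'
#' Produces a chemically equivalent (or tautomeric) alternative
#' representation of the same compound: `atom_reorder` permutes atom
#' indices; `explicit_h` materializes implicit hydrogens as atoms;
#' `resonance_charge_form` toggles a nitro, azide or sulfoxide group
#' between its charge-separated and charge-free drawings; `tautomer_swap`
#' moves the mobile hydrogen of an amide, urea or thioamide group and
#' shifts the adjacent double bond. The result is valence-valid.
#'
#' @param g A `mol_graph`.
#' @param kind One of `"atom_reorder"`, `"explicit_h"`,
#'   `"resonance_charge_form"`, `"tautomer_swap"`.
#' @return The perturbed `mol_graph`.
#' @export
perturb_representation <- function(g, kind = c("atom_reorder", "explicit_h",
                                               "resonance_charge_form",
                                               "tautomer_swap")) {
  kind <- match.arg(kind)
  switch(kind,
    atom_reorder = permute_atoms(g, sample.int(nrow(g$atoms))),
    explicit_h = {
      atoms <- data.frame(element = g$atoms$element, charge = g$atoms$charge,
                          stereo = g$atoms$stereo, isotope = g$atoms$isotope,
                          stringsAsFactors = FALSE)
      bonds <- g$bonds[, c("a", "b", "order", "stereo")]
      n <- nrow(atoms)
      for (i in seq_len(nrow(g$atoms))) {
        h <- g$atoms$h_count[i]
        if (h > 0L) {
          for (j in seq_len(h)) {
            n <- n + 1L
            atoms <- rbind(atoms, data.frame(element = "H", charge = 0L,
                                             stereo = 0L, isotope = 0L,
                                             stringsAsFactors = FALSE))
            bonds <- rbind(bonds, data.frame(a = i, b = n, order = 1L, stereo = 0L))
          }
        }
      }
      mol_graph(atoms, bonds, id = g$id)
    },
    resonance_charge_form = {
      site <- .find_resonance_site(g)
      if (is.null(site)) stop("no nitro/azide/sulfoxide site applicable for resonance_charge_form")
      .rebuild(.apply_resonance_swap(g, site))
    },
    tautomer_swap = {
      site <- .find_amide_site(g)
      if (is.null(site)) stop("no amide/urea/thioamide site applicable for tautomer_swap")
      if (site$form == "amide") {
        g <- .set_bond_order(g, site$c, site$x, 1L)
        g <- .set_bond_order(g, site$c, site$n, 2L)
      } else {
        g <- .set_bond_order(g, site$c, site$x, 2L)
        g <- .set_bond_order(g, site$c, site$n, 1L)
      }
      .rebuild(g)
    })
}

.perturbation_applicable <- function(g, kind) {
  switch(kind,
    atom_reorder = TRUE,
    explicit_h = TRUE,
    resonance_charge_form = !is.null(.find_resonance_site(g)),
    tautomer_swap = !is.null(.find_amide_site(g)))
}

# ---- generation ------------------------------------------------------------

# Assign each knowledgebase pathways_per_kb single-motif signatures, sampled
# without replacement within the KB and preferring motifs not yet used by
# any other KB: per-KB definitions are therefore fully disjoint whenever
# n_kbs * pathways_per_kb <= library size, and otherwise distinct KBs reuse
# signatures the way real knowledgebases define overlapping pathways.
.assign_signatures <- function(motif_names, n_kbs, per_kb) {
  if (per_kb > length(motif_names)) {
    stop("pathways_per_kb exceeds the motif library size; supply more motifs")
  }
  used <- character()
  out <- vector("list", n_kbs)
  for (ki in seq_len(n_kbs)) {
    fresh <- setdiff(motif_names, used)
    take <- if (length(fresh) >= per_kb) {
      fresh[sample.int(length(fresh), per_kb)]
    } else {
      rest <- setdiff(motif_names, fresh)
      c(fresh[sample.int(length(fresh))],
        rest[sample.int(length(rest), per_kb - length(fresh))])
    }
    used <- c(used, take)
    out[[ki]] <- as.list(take)
  }
  out
}

#' Generate a synthetic multi-knowledgebase corpus
#'
#' Molecules are metabolite-like scaffolds with grafted functional-group
#' motifs. Each pathway is assigned one signature motif and its true members
#' are the compounds carrying that motif, so membership is genuinely
#' predictable from color counts; signatures are sampled without
#' replacement within each knowledgebase, preferring globally unused motifs
#' (per-KB pathway definitions are fully disjoint whenever
#' `n_kbs * pathways_per_kb` does not exceed the motif library size).
#' Annotation incompleteness is emulated by dropping each true membership
#' with probability `membership_noise`.
#' Cross-reference twins are created for a `crossref_fraction` of each
#' knowledgebase's compounds: the perturbation kind is sampled from
#' `perturbation_mix` first and an applicable source compound is then drawn,
#' the twin is added to the next knowledgebase (cyclically) with that
#' knowledgebase's motif-derived noisy annotations. Fully deterministic
#' given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_kb`: `compounds` and `pathways` (flat record lists
#'   across KBs), `annotations` (kb, compound_id, pathway_id), `crossref`
#'   (kb_a, cid_a, kb_b, cid_b, kind), `truth` (per-KB noise-free membership
#'   matrices), `graphs` (registry keyed `"kb:compound_id"`), `motifs`
#'   (per compound), and `config`.
#' @export
generate_synthetic_kb <- function(config = synthetic_config()) {
  .with_seed(config$seed, .generate_synthetic_kb(config))
}

.generate_synthetic_kb <- function(config) {
  kb_names <- sprintf("KB%d", seq_len(config$n_kbs))
  lib_names <- names(config$motif_library)
  sig_by_kb <- .assign_signatures(lib_names, config$n_kbs, config$pathways_per_kb)

  compounds <- list(); motifs_of <- list(); graphs <- list()
  annotations <- data.frame(kb = character(), compound_id = character(),
                            pathway_id = character(), stringsAsFactors = FALSE)
  pathways <- list(); truth <- list()
  kb_sigs <- list(); kb_cids <- list()

  for (ki in seq_along(kb_names)) {
    kb <- kb_names[ki]
    cids <- sprintf("%s_C%03d", kb, seq_len(config$compounds_per_kb))
    kb_cids[[kb]] <- cids
    for (ci in seq_along(cids)) {
      m <- .random_molecule(config, id = cids[ci])
      key <- paste(kb, cids[ci], sep = ":")
      graphs[[key]] <- m$graph
      motifs_of[[key]] <- m$motifs
    }
    pids <- sprintf("%s_P%02d", kb, seq_len(config$pathways_per_kb))
    kb_sigs[[kb]] <- sig_by_kb[[ki]]

    mem_true <- matrix(FALSE, length(cids), length(pids), dimnames = list(cids, pids))
    for (p in seq_along(pids)) {
      sig <- kb_sigs[[kb]][[p]]
      mem_true[, p] <- vapply(cids, function(cid) {
        all(sig %in% motifs_of[[paste(kb, cid, sep = ":")]])
      }, logical(1))
    }
    truth[[kb]] <- mem_true
    # annotation incompleteness: each true membership is lost with prob eps
    drop <- matrix(stats::runif(length(mem_true)) < config$membership_noise,
                   nrow = nrow(mem_true))
    mem <- mem_true & !drop
    w <- which(mem, arr.ind = TRUE)
    if (nrow(w) > 0L) {
      annotations <- rbind(annotations, data.frame(
        kb = kb, compound_id = cids[w[, 1]], pathway_id = pids[w[, 2]],
        stringsAsFactors = FALSE))
    }
  }

  # cross-reference twins
  crossref <- data.frame(kb_a = character(), cid_a = character(),
                         kb_b = character(), cid_b = character(),
                         kind = character(), stringsAsFactors = FALSE)
  kinds <- names(config$perturbation_mix)
  if (config$crossref_fraction > 0) {
    original_cids <- kb_cids  # twins never become crossref sources themselves
    for (ki in seq_along(kb_names)) {
      kb <- kb_names[ki]
      target <- kb_names[ki %% length(kb_names) + 1L]
      n_x <- round(config$crossref_fraction * config$compounds_per_kb)
      available <- original_cids[[kb]]
      for (x in seq_len(n_x)) {
        twin <- NULL
        for (try in 1:50) {
          kind <- sample(kinds, 1L, prob = config$perturbation_mix)
          appl <- available[vapply(available, function(cid) {
            .perturbation_applicable(graphs[[paste(kb, cid, sep = ":")]], kind)
          }, logical(1))]
          if (length(appl) == 0L) next
          cid <- appl[sample.int(length(appl), 1L)]
          twin <- list(cid = cid, kind = kind)
          break
        }
        if (is.null(twin)) break
        available <- setdiff(available, twin$cid)
        src_key <- paste(kb, twin$cid, sep = ":")
        twin_id <- sprintf("X_%s", twin$cid)
        pg <- perturb_representation(graphs[[src_key]], twin$kind)
        pg$id <- twin_id
        tkey <- paste(target, twin_id, sep = ":")
        graphs[[tkey]] <- pg
        motifs_of[[tkey]] <- motifs_of[[src_key]]
        # annotate the twin in its own knowledgebase from its motifs
        tpids <- colnames(truth[[target]])
        tmem <- vapply(seq_along(tpids), function(p) {
          all(kb_sigs[[target]][[p]] %in% motifs_of[[tkey]])
        }, logical(1))
        tmem <- tmem & !(stats::runif(length(tmem)) < config$membership_noise)
        if (any(tmem)) {
          annotations <- rbind(annotations, data.frame(
            kb = target, compound_id = twin_id, pathway_id = tpids[tmem],
            stringsAsFactors = FALSE))
        }
        kb_cids[[target]] <- c(kb_cids[[target]], twin_id)
        crossref <- rbind(crossref, data.frame(
          kb_a = kb, cid_a = twin$cid, kb_b = target, cid_b = twin_id,
          kind = twin$kind, stringsAsFactors = FALSE))
      }
    }
  }

  # assemble records
  comp_records <- list()
  for (kb in kb_names) {
    for (cid in kb_cids[[kb]]) {
      key <- paste(kb, cid, sep = ":")
      pids <- annotations$pathway_id[annotations$kb == kb &
                                     annotations$compound_id == cid]
      comp_records[[key]] <- list(compound_id = cid, source_kb = kb,
                                  graph = graphs[[key]],
                                  pathway_ids = sort(unique(pids)))
    }
  }
  path_records <- list()
  for (kb in kb_names) {
    for (pid in sprintf("%s_P%02d", kb, seq_len(config$pathways_per_kb))) {
      members <- annotations$compound_id[annotations$kb == kb &
                                         annotations$pathway_id == pid]
      path_records[[paste(kb, pid, sep = ":")]] <-
        list(pathway_id = pid, source_kb = kb,
             member_compound_ids = sort(unique(members)))
    }
  }

  structure(list(compounds = comp_records, pathways = path_records,
                 annotations = annotations, crossref = crossref,
                 truth = truth, graphs = graphs, motifs = motifs_of,
                 config = config),
            class = "synthetic_kb")
}

#' @export
print.synthetic_kb <- function(x, ...) {
  cat(sprintf("<synthetic_kb: %d KBs, %d compounds, %d pathways, %d annotations, %d crossrefs>\n",
              x$config$n_kbs, length(x$compounds), length(x$pathways),
              nrow(x$annotations), nrow(x$crossref)))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits per-KB molfile directories and annotation TSVs, a cross-reference
#' TSV and a ground-truth JSON, in the layout [load_knowledgebase()] reads.
#'
#' @param skb A `synthetic_kb`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_kb <- function(skb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kbs <- unique(vapply(skb$compounds, function(r) r$source_kb, character(1)))
  for (kb in kbs) {
    sdir <- file.path(dir, kb, "structures")
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (r in skb$compounds) {
      if (r$source_kb != kb) next
      writeLines(write_molfile(r$graph), file.path(sdir, paste0(r$compound_id, ".mol")))
    }
    ann <- skb$annotations[skb$annotations$kb == kb, c("compound_id", "pathway_id")]
    utils::write.table(ann, file.path(dir, kb, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(skb$crossref, file.path(dir, "crossref.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(lapply(skb$truth, function(m) {
    list(compounds = rownames(m), pathways = colnames(m),
         membership = unname(apply(m, 1L, as.integer, simplify = FALSE)))
  }), file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
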