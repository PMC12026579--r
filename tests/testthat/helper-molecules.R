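# Molecule fixtures built in code.

mol_methane <- function() mol_graph(data.frame(element = "C", charge = 0L), id = "methane")

mol_ethanol <- function() {
  mol_graph(data.frame(element = c("C", "C", "O"), charge = 0L),
            data.frame(a = c(1, 2), b = c(2, 3), order = 1L), id = "ethanol")
}

mol_methanol <- function() {
  mol_graph(data.frame(element = c("C", "O"), charge = 0L),
            data.frame(a = 1, b = 2, order = 1L), id = "methanol")
}

mol_ammonia <- function() mol_graph(data.frame(element = "N", charge = 0L), id = "ammonia")

mol_benzene <- function() {
  mol_graph(data.frame(element = rep("C", 6), charge = 0L),
            data.frame(a = 1:6, b = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)),
            id = "benzene")
}

# amide / imidic acid tautomer pair (acetamide backbone)
mol_acetamide <- function() {
  mol_graph(data.frame(element = c("C", "C", "O", "N"), charge = 0L),
            data.frame(a = c(1, 2, 2), b = c(2, 3, 4), order = c(1, 2, 1)),
            id = "acetamide")
}
mol_imidic <- function() {
  mol_graph(data.frame(element = c("C", "C", "O", "N"), charge = 0L),
            data.frame(a = c(1, 2, 2), b = c(2, 3, 4), order = c(1, 1, 2)),
            id = "acetimidic_acid")
}

# nitromethane resonance/charge forms
mol_nitro_penta <- function() {
  mol_graph(data.frame(element = c("C", "N", "O", "O"), charge = 0L),
            data.frame(a = c(1, 2, 2), b = c(2, 3, 4), order = c(1, 2, 2)),
            id = "nitromethane_pentavalent")
}
mol_nitro_charged <- function() {
  mol_graph(data.frame(element = c("C", "N", "O", "O"),
                       charge = c(0L, 1L, 0L, -1L)),
            data.frame(a = c(1, 2, 2), b = c(2, 3, 4), order = c(1, 2, 1)),
            id = "nitromethane_charge_separated")
}

# R/S-style pair: a tetrahedral stereocenter with odd vs even parity flags
mol_stereocenter <- function(parity) {
  mol_graph(data.frame(element = c("C", "F", "Cl", "Br"), charge = 0L,
                       stereo = c(parity, 0L, 0L, 0L)),
            data.frame(a = c(1, 1, 1), b = c(2, 3, 4), order = 1L),
            id = sprintf("stereocenter_p%d", parity))
}

# E/Z-style pair: 2-butene with and without a stereo flag on the double bond
mol_butene <- function(bond_flag) {
  mol_graph(data.frame(element = rep("C", 4), charge = 0L),
            data.frame(a = 1:3, b = 2:4, order = c(1, 2, 1),
                       stereo = c(0L, bond_flag, 0L)),
            id = sprintf("butene_b%d", bond_flag))
}

# a small deterministic corpus of valence-valid molecules for property tests
fixture_corpus <- function(n = 40, seed = 42) {
  skb <- generate_synthetic_kb(synthetic_config(
    n_kbs = 1L, compounds_per_kb = n, pathways_per_kb = 5L,
    membership_noise = 0, seed = seed))
  lapply(skb$compounds, `[[`, "graph")
}

random_permutation_of <- function(g) {
  permute_atoms(g, sample.int(nrow(g$atoms)))
}
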