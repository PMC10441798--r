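test_that("amino-acid fractions come from residue counting", {
  prot <- Biostrings::AAStringSet(c(p1 = paste(rep("MAA", 50),
                                               collapse = "")))
  aa <- amino_acid_coefficients(prot, protein_mass_fraction = 0.5)
  expect_equal(aa$fraction[aa$amino_acid == "M"], 1 / 3)
  expect_equal(aa$fraction[aa$amino_acid == "A"], 2 / 3)
  expect_equal(sum(aa$fraction), 1)
  # normalization identity: coefficients weigh back to the mass input
  expect_equal(sum(aa$coefficient * aa$residue_mw) / 1000, 0.5)
})

test_that("an equal-frequency proteome gives 20 equal coefficients", {
  prot <- gen_sequences(4, "protein", length = 20000,
                        frequencies = stats::setNames(
                          rep(1 / 20, 20),
                          c("A", "R", "N", "D", "C", "E", "Q", "G",
                            "H", "I", "L", "K", "M", "F", "P", "S",
                            "T", "W", "Y", "V")))
  # construct an exactly uniform proteome to isolate the symmetry
  uniform <- Biostrings::AAStringSet(c(u = paste(
    rep(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V"), 100),
    collapse = "")))
  aa <- amino_acid_coefficients(uniform, 0.55)
  expect_lt(max(aa$fraction) - min(aa$fraction), 1e-12)
  expect_gt(min(aa$coefficient), 0)
  # non-standard residues are rejected with a count
  bad <- Biostrings::AAStringSet(c(b = "MAXB"))
  expect_error(amino_acid_coefficients(bad, 0.5), "non-standard")
  expect_error(amino_acid_coefficients(Biostrings::AAStringSet(), 0.5),
               "empty")
  expect_silent(amino_acid_coefficients(prot, 0.55))
})

test_that("synthetic proteome fractions are recovered within 1%", {
  freqs <- stats::setNames(rep(1 / 20, 20),
                           c("A", "R", "N", "D", "C", "E", "Q", "G",
                             "H", "I", "L", "K", "M", "F", "P", "S",
                             "T", "W", "Y", "V"))
  prot <- gen_sequences(17, "protein", length = 1e5,
                        frequencies = freqs)
  aa <- amino_acid_coefficients(prot, 0.55)
  expect_lt(max(abs(aa$fraction - 0.05)), 0.01 * 0.05 + 0.005)
  expect_true(all(abs(aa$fraction - 0.05) < 0.005))
})

test_that("nucleotide fractions reflect strand symmetry and GC content", {
  g <- Biostrings::DNAStringSet(c(g = paste(rep("ATGC", 500),
                                            collapse = "")))
  nt <- nucleotide_coefficients(g, dna_fraction = 0.03,
                                rna_fraction = 0.2)
  expect_equal(nt$dna$fraction, rep(0.25, 4))
  expect_equal(sum(nt$dna$coefficient * nt$dna$residue_mw) / 1000, 0.03)
  expect_equal(sum(nt$rna$coefficient * nt$rna$residue_mw) / 1000, 0.2)

  gc6 <- gen_sequences(5, "dna", length = 1e5, gc_content = 0.6)
  nt6 <- nucleotide_coefficients(gc6, 0.03, 0.2)
  gc_frac <- sum(nt6$dna$fraction[nt6$dna$base %in% c("G", "C")])
  expect_lt(abs(gc_frac - 0.6), 0.01)
  # double-strand counting forces A=T and G=C exactly
  expect_equal(nt6$dna$fraction[nt6$dna$base == "A"],
               nt6$dna$fraction[nt6$dna$base == "T"])

  # zero DNA fraction zeroes the dNTP coefficients
  nt0 <- nucleotide_coefficients(g, dna_fraction = 0,
                                 rna_fraction = 0.2)
  expect_true(all(nt0$dna$coefficient == 0))

  amb <- Biostrings::DNAStringSet(c(a = "ATGCN"))
  expect_error(nucleotide_coefficients(amb, 0.03, 0.2), "ambiguity")
  expect_silent(nucleotide_coefficients(amb, 0.03, 0.2,
                                        ambiguity = "drop"))
})

full_composition <- function() {
  prot <- gen_sequences(3, "protein", length = 20000)
  gen <- gen_sequences(3, "dna", length = 20000, gc_content = 0.65)
  aa <- amino_acid_coefficients(prot, 0.55)
  nt <- nucleotide_coefficients(gen, 0.031, 0.205)
  default_bof_composition(aa, nt)
}

test_that("the assembled biomass reaction is mass-consistent", {
  comp <- normalize_bof_composition(full_composition())
  bof <- assemble_bof(comp, gam = 40)
  expect_equal(bof$kind, "biomass")
  expect_length(attr(bof, "clusters"), 9)
  tab <- do.call(rbind, comp)
  mass <- sum(abs(tab$coefficient) * tab$mw) / 1000
  expect_equal(mass, 1, tolerance = 1e-9)
  expect_equal(attr(bof, "n_constituents"),
               length(unique(tab$metabolite)))
  # maintenance ATP terms present and signed as hydrolysis; atp is
  # consumed beyond the GAM share because ATP is also an RNA precursor
  expect_equal(bof$stoichiometry[["adp_c"]], 40)
  expect_lt(bof$stoichiometry[["atp_c"]], -40)
  expect_gt(bof$stoichiometry[["biomass_c"]], 0)

  # gam = 0 removes the hydrolysis terms
  bof0 <- assemble_bof(comp, gam = 0)
  expect_false("adp_c" %in% names(bof0$stoichiometry))

  # an unnormalized composition fails the 1 g/gDW check
  expect_error(assemble_bof(full_composition(), gam = 40),
               "g/gDW")
  # an incomplete cluster set is rejected
  expect_error(assemble_bof(comp[-1], gam = 40), "nine clusters")
})

test_that("the maintenance reaction pins baseline ATP hydrolysis", {
  atpm <- maintenance_reaction(ngam = 3)
  expect_equal(atpm$lower_bound, 3)
  expect_equal(atpm$stoichiometry[["atp_c"]], -1)
  expect_equal(atpm$stoichiometry[["adp_c"]], 1)
  expect_error(maintenance_reaction(-1))
})

test_that("uniform rescaling of cluster fractions is invisible after normalization", {
  comp <- full_composition()
  doubled <- lapply(comp, function(df) {
    df$coefficient <- df$coefficient * 2
    df
  })
  a <- assemble_bof(normalize_bof_composition(comp), gam = 40)
  b <- assemble_bof(normalize_bof_composition(doubled), gam = 40)
  expect_equal(a$stoichiometry, b$stoichiometry, tolerance = 1e-12)
})

test_that("a toy model grows on the assembled biomass objective", {
  # two-precursor toy: both must be supplied for the BOF to fire
  comp <- list(
    amino_acids = data.frame(metabolite = "aa_c", coefficient = 4,
                             mw = 110),
    carbohydrates = data.frame(metabolite = "carb_c", coefficient = 3,
                               mw = 162),
    cell_wall = data.frame(), pigments = data.frame(),
    cofactors = data.frame(), RNA = data.frame(), DNA = data.frame(),
    minerals = data.frame(), miscellaneous = data.frame())
  bof <- assemble_bof(normalize_bof_composition(comp), gam = 0)
  m <- metabolic_model(
    "bof_toy", c(c = "cytoplasm", e = "extracellular"),
    metabolites = list(
      metabolite("aa_e", compartment = "e"),
      metabolite("carb_e", compartment = "e"),
      metabolite("aa_c", compartment = "c"),
      metabolite("carb_c", compartment = "c"),
      metabolite("biomass_c", compartment = "c")),
    reactions = list(
      reaction("EX_aa", c(aa_e = -1), lower_bound = -10,
               kind = "exchange"),
      reaction("EX_carb", c(carb_e = -1), lower_bound = -10,
               kind = "exchange"),
      reaction("T_aa", c(aa_e = -1, aa_c = 1)),
      reaction("T_carb", c(carb_e = -1, carb_c = 1)),
      bof,
      reaction("DM_bm", c(biomass_c = -1), kind = "demand")),
    objective = "BIOMASS")
  sol <- fba(m, medium = c(EX_aa = 10, EX_carb = 10))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
  expect_true(is.finite(sol$objective))
  # starving one precursor stalls growth
  sol0 <- fba(m, medium = c(EX_aa = 10))
  expect_equal(sol0$objective, 0)
})
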