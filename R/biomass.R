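#' Biomass objective construction
#'
#' The biomass objective function (BOF) is a pseudo-reaction consuming
#' precursor metabolites in the proportions needed to build one gram of
#' dry cell weight, grouped into nine constituent clusters: amino
#' acids, cell wall, pigments, cofactors, RNA, DNA, carbohydrates,
#' minerals, and miscellaneous. Amino-acid and nucleotide coefficients
#' are derived from proteome/genome composition; the remaining clusters
#' come from configuration tables (template-model conventions and
#' literature mineral requirements).
#'
#' @name biomass_builder
NULL

#' The nine biomass constituent clusters
#' @export
BIOMASS_CLUSTERS <- c("amino_acids", "cell_wall", "pigments", "cofactors",
                      "RNA", "DNA", "carbohydrates", "minerals",
                      "miscellaneous")

# average residue masses, g/mol: monomer minus one water of
# polymerization (peptide bond / phosphodiester bond already formed)
AA_RESIDUE_MW <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

DNA_RESIDUE_MW <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
RNA_RESIDUE_MW <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)

#' Amino-acid biomass coefficients from a proteome
#'
#' Residues are counted across all protein sequences; the mole fraction
#' of each amino acid, scaled by the protein mass fraction of dry
#' weight and normalised by the frequency-weighted mean residue mass
#' (monomer minus water, so polymerization water is accounted for),
#' gives the mmol of each amino acid consumed per gram dry weight.
#'
#' @param proteome an [Biostrings::AAStringSet], or path to a protein
#'   FASTA file.
#' @param protein_mass_fraction grams of protein per gram dry weight,
#'   in (0, 1].
#' @return data.frame with `amino_acid` (one-letter code), `fraction`
#'   (mole fraction), `coefficient` (mmol/gDW) and `residue_mw`
#'   (g/mol). The identity
#'   `sum(coefficient * residue_mw) / 1000 == protein_mass_fraction`
#'   holds exactly.
#' @export
amino_acid_coefficients <- function(proteome, protein_mass_fraction) {
  stopifnot(protein_mass_fraction > 0, protein_mass_fraction <= 1)
  if (is.character(proteome)) {
    proteome <- Biostrings::readAAStringSet(proteome)
  }
  if (length(proteome) == 0 || sum(Biostrings::width(proteome)) == 0) {
    stop("empty proteome", call. = FALSE)
  }
  counts <- colSums(Biostrings::letterFrequency(
    proteome, letters = names(AA_RESIDUE_MW)))
  total <- sum(Biostrings::width(proteome))
  nonstd <- total - sum(counts)
  if (nonstd > 0) {
    stop("proteome contains ", nonstd,
         " non-standard residue letters; only the 20 canonical amino ",
         "acids are supported", call. = FALSE)
  }
  frac <- counts / total
  mean_mw <- sum(frac * AA_RESIDUE_MW)        # g/mol per average residue
  coef <- 1000 * protein_mass_fraction * frac / mean_mw
  data.frame(amino_acid = names(AA_RESIDUE_MW),
             fraction = as.numeric(frac),
             coefficient = as.numeric(coef),
             residue_mw = as.numeric(AA_RESIDUE_MW),
             stringsAsFactors = FALSE)
}

#' dNTP and NTP biomass coefficients from a genome
#'
#' DNA base fractions are counted over both strands (the genome plus
#' its reverse complement, so A pairs T and G pairs C exactly); RNA
#' base fractions use the sense strand only, with T read as U — a
#' documented approximation of the average transcript pool. Both sets
#' are mass-normalised like the amino-acid coefficients, using residue
#' (monophosphate minus water) masses.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a nucleotide
#'   FASTA file.
#' @param dna_fraction,rna_fraction grams of DNA and RNA per gram dry
#'   weight (either may be 0).
#' @param ambiguity `"reject"` (default: error on non-ACGT letters) or
#'   `"drop"` (ignore them).
#' @return list with data.frames `dna` and `rna`, columns `base`,
#'   `fraction`, `coefficient` (mmol/gDW), `residue_mw`.
#' @export
nucleotide_coefficients <- function(genome, dna_fraction, rna_fraction,
                                    ambiguity = c("reject", "drop")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(dna_fraction >= 0, rna_fraction >= 0)
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  counts <- colSums(Biostrings::letterFrequency(genome,
                                                letters = c("A", "C", "G", "T")))
  total <- sum(Biostrings::width(genome))
  if (sum(counts) < total && ambiguity == "reject") {
    stop("genome contains ", total - sum(counts),
         " ambiguity letters; set ambiguity = 'drop' to ignore them",
         call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty genome", call. = FALSE)
  # double-stranded counts: every A pairs a T, every G pairs a C
  ds <- c(A = counts[["A"]] + counts[["T"]],
          C = counts[["C"]] + counts[["G"]],
          G = counts[["G"]] + counts[["C"]],
          T = counts[["T"]] + counts[["A"]])
  dna_frac <- ds / sum(ds)
  rna_counts <- c(A = counts[["A"]], C = counts[["C"]],
                  G = counts[["G"]], U = counts[["T"]])
  rna_frac <- rna_counts / sum(rna_counts)
  normalise <- function(frac, mw, mass_fraction) {
    coef <- if (mass_fraction > 0) {
      1000 * mass_fraction * frac / sum(frac * mw)
    } else {
      rep(0, length(frac))
    }
    data.frame(base = names(mw), fraction = as.numeric(frac),
               coefficient = as.numeric(coef),
               residue_mw = as.numeric(mw), stringsAsFactors = FALSE)
  }
  list(dna = normalise(dna_frac, DNA_RESIDUE_MW, dna_fraction),
       rna = normalise(rna_frac, RNA_RESIDUE_MW, rna_fraction))
}

#' Non-growth-associated maintenance (NGAM) reaction
#'
#' ATP hydrolysis forced at a baseline rate regardless of growth,
#' expressed as an ATPM reaction whose lower bound pins the flux.
#'
#' @param ngam maintenance flux, mmol ATP/gDW/h (default 3, a typical
#'   Gram-negative value; an assumption to revisit per organism).
#' @param atp,h2o,adp,pi,h currency metabolite ids.
#' @return a [reaction()] with `lower_bound = ngam`.
#' @export
maintenance_reaction <- function(ngam = 3, atp = "atp_c",
                                 h2o = "h2o_c", adp = "adp_c",
                                 pi = "pi_c", h = "h_c") {
  stopifnot(ngam >= 0)
  reaction("ATPM",
           stats::setNames(c(-1, -1, 1, 1, 1),
                           c(atp, h2o, adp, pi, h)),
           lower_bound = ngam, upper_bound = GLOBAL_FLUX_BOUND,
           name = "ATP maintenance requirement", kind = "internal")
}

#' Rescale a biomass composition to one gram per gram dry weight
#'
#' Multiplies every constituent coefficient by a common factor so the
#' total consumed mass is exactly `total` g/gDW. Because the factor is
#' common, relative proportions — and therefore the coefficients after
#' normalisation — are invariant to any prior uniform scaling of the
#' cluster fractions.
#'
#' @param compositions as in [assemble_bof()].
#' @param total target mass, g/gDW (default 1).
#' @return the rescaled compositions list.
#' @export
normalize_bof_composition <- function(compositions, total = 1) {
  mass <- 0
  for (df in compositions) {
    if (!is.null(df) && nrow(df) > 0) {
      mass <- mass + sum(abs(df$coefficient) * df$mw) / 1000
    }
  }
  if (mass <= 0) stop("composition has zero mass", call. = FALSE)
  lapply(compositions, function(df) {
    if (is.null(df) || nrow(df) == 0) return(df)
    df$coefficient <- df$coefficient * total / mass
    df
  })
}

#' Assemble the biomass reaction
#'
#' Combines per-cluster constituent tables into a single biomass
#' pseudo-reaction consuming every constituent plus growth-associated
#' maintenance ATP (hydrolysed to ADP, phosphate and a proton) and
#' producing one unit of the biomass pseudo-metabolite. The total
#' consumed mass must be one gram per gram dry weight within 1e-3.
#'
#' @param compositions named list over the nine clusters (every member
#'   of [BIOMASS_CLUSTERS] must be present); each element a data.frame
#'   with columns `metabolite`, `coefficient` (mmol/gDW, positive =
#'   consumed) and `mw` (g/mol). Empty data.frames are allowed for
#'   clusters a configuration leaves void.
#' @param gam growth-associated maintenance, mmol ATP hydrolysed per
#'   gram dry weight (default 40; 0 omits the ATP terms).
#' @param biomass_met id of the biomass pseudo-metabolite (default
#'   `"biomass_c"`).
#' @param atp,h2o,adp,pi,h currency metabolite ids for the maintenance
#'   term.
#' @param mass_tol tolerance on the 1 g/gDW mass check.
#' @return a [reaction()] of kind `"biomass"` with attribute
#'   `"n_constituents"` (number of distinct consumed metabolites,
#'   excluding maintenance currency).
#' @export
assemble_bof <- function(compositions, gam = 40,
                         biomass_met = "biomass_c",
                         atp = "atp_c", h2o = "h2o_c", adp = "adp_c",
                         pi = "pi_c", h = "h_c", mass_tol = 1e-3) {
  missing_cl <- setdiff(BIOMASS_CLUSTERS, names(compositions))
  if (length(missing_cl) > 0) {
    stop("compositions must cover all nine clusters; missing: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  tab <- do.call(rbind, lapply(BIOMASS_CLUSTERS, function(cl) {
    df <- compositions[[cl]]
    if (is.null(df) || nrow(df) == 0) return(NULL)
    stopifnot(all(c("metabolite", "coefficient", "mw") %in% names(df)))
    cbind(df, cluster = cl)
  }))
  if (is.null(tab) || nrow(tab) == 0) {
    stop("no biomass constituents supplied", call. = FALSE)
  }
  mass <- sum(abs(tab$coefficient) * tab$mw) / 1000
  if (abs(mass - 1) > mass_tol) {
    stop(sprintf(
      "biomass composition sums to %.6f g/gDW (must be 1 within %g)",
      mass, mass_tol), call. = FALSE)
  }
  st <- tapply(-abs(tab$coefficient), tab$metabolite, sum)
  st <- stats::setNames(as.numeric(st), names(st))
  if (gam > 0) {
    gam_terms <- stats::setNames(c(-gam, -gam, gam, gam, gam),
                                 c(atp, h2o, adp, pi, h))
    for (m in names(gam_terms)) {
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) + gam_terms[[m]]
    }
  }
  st[biomass_met] <- 1
  rxn <- reaction(id = "BIOMASS", stoichiometry = st,
                  lower_bound = 0, upper_bound = GLOBAL_FLUX_BOUND,
                  name = "Biomass objective function", kind = "biomass")
  attr(rxn, "n_constituents") <- length(unique(tab$metabolite))
  attr(rxn, "clusters") <- sort(unique(tab$cluster))
  rxn
}
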