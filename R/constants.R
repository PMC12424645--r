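# Residue-level constants shared across the package: amino-acid masses,
# modification deltas, pKa tables, and the canonical Abeta / APP region
# sequences.

# The 20 proteinogenic amino acids, one-letter code, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Monoisotopic residue masses (Da), i.e. the mass each residue contributes
# to a peptide chain (water added once per peptide).
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

# Average residue masses (Da).
AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MONO <- 18.010565
WATER_AVG  <- 18.01528
PROTON_MONO <- 1.007276
PROTON_AVG  <- 1.00794

# Mass deltas for supported modifications (Da). Stereo- and isomerization
# of Asp are mass-neutral by definition.
MOD_DELTA <- list(
  phospho          = c(mono = 79.966331, avg = 79.9799),
  `pyroglutamate-E` = c(mono = -18.010565, avg = -18.0153),
  `pyroglutamate-Q` = c(mono = -17.026549, avg = -17.0305),
  amide            = c(mono = -0.984016, avg = -0.9847),
  `d-stereo`       = c(mono = 0, avg = 0),
  `iso-aspartate`  = c(mono = 0, avg = 0))

MOD_TAGS <- c("none", "phospho", "pyroglutamate", "d-stereo", "iso-aspartate")

# Abeta region displayed on the arrays: APP770 residues 649-722, i.e.
# Abeta coordinates -23..51 (23 N-terminal APP residues, Abeta1-42, 9
# C-terminal APP residues). Position 0 does not exist in Abeta numbering.
ABETA_UPSTREAM   <- "GLTTRPGSGLTNIKTEEISEVKM"                    # -23..-1
ABETA_1_42       <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA" #  1..42
ABETA_DOWNSTREAM <- "TVIVITLVM"                                  # 43..51
ABETA_REGION     <- paste0(ABETA_UPSTREAM, ABETA_1_42, ABETA_DOWNSTREAM)

APP770_OFFSET_NEG <- 672L # app = abeta + 672 for abeta < 0
APP770_OFFSET_POS <- 671L # app = abeta + 671 for abeta > 0
APP770_FIRST <- 649L
APP770_LAST  <- 722L
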