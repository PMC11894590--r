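# Residue scales and dipeptide weights used by the property engine.
# All vectors/matrices are indexed by the 20 canonical one-letter codes.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy
SCALE_KD <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Boman protein-binding potential (kcal/mol; hydrophilic residues positive,
# from side-chain water/cyclohexane transfer free energies; Pro has no analog and scores 0)
SCALE_BOMAN <- c(A = -1.81, C = -1.28, D = 8.72, E = 6.81, F = -2.98, G = -0.94, H = 4.66, I = -4.92, K = 5.55, L = -4.92, M = -2.35, N = 6.64, P = 0.00, Q = 5.54, R = 14.92, S = 3.40, T = 2.57, V = -4.04, W = -2.33, Y = 0.14)

# average residue masses (Da), monomer mass minus one water
MASS_AVG <- c(A = 71.0779, C = 103.1429, D = 115.0874, E = 129.1140, F = 147.1738, G = 57.0513, H = 137.1393, I = 113.1576, K = 128.1723, L = 113.1576, M = 131.1960, N = 114.1026, P = 97.1152, Q = 128.1292, R = 156.1857, S = 87.0773, T = 101.1039, V = 99.1310, W = 186.2099, Y = 163.1732)
MASS_WATER <- 18.0153
MASS_PROTON <- 1.008

# Guruprasad dipeptide instability weights (DIWV); rows = first residue
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))
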