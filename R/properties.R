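#' Property-engine configuration
#'
#' @param pH pH at which the `charge` column is evaluated (default 7.0;
#'   presets of interest are 7.4 and the brain extracellular window
#'   6.47-7.19).
#' @param pka_set `"bjellqvist"` (default) or `"emboss"`; the ionisable
#'   side-chain and terminal pKa values used for charge and pI.
#' @param mass `"average"` (default, linear-TOF convention) or
#'   `"monoisotopic"`.
#' @param boman_high Boman-index threshold above which a peptide is called
#'   interaction-prone (2.48).
#' @param aliphatic_stable Aliphatic-index threshold above which a peptide
#'   is called thermostable (70).
#' @param instability_stable Instability-index threshold below which a
#'   peptide is called stable (40).
#' @return A `property_config` list.
#' @export
property_config <- function(pH = 7.0, pka_set = c("bjellqvist", "emboss"),
                            mass = c("average", "monoisotopic"),
                            boman_high = 2.48, aliphatic_stable = 70,
                            instability_stable = 40) {
  pka_set <- match.arg(pka_set)
  mass <- match.arg(mass)
  stopifnot(pH > 0, pH < 14, boman_high > 0, aliphatic_stable > 0,
            instability_stable > 0)
  structure(list(pH = pH, pka_set = pka_set, mass = mass,
                 boman_high = boman_high,
                 aliphatic_stable = aliphatic_stable,
                 instability_stable = instability_stable),
            class = "property_config")
}

PKA_SETS <- list(
  # Bjellqvist-style values as used by common pI calculators
  bjellqvist = list(
    nterm = 7.50, cterm = 3.55,
    positive = c(K = 10.00, R = 12.00, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  ),
  emboss = list(
    nterm = 8.60, cterm = 3.60,
    positive = c(K = 10.80, R = 12.50, H = 6.50),
    negative = c(D = 3.90, E = 4.10, C = 8.50, Y = 10.10)
  )
)

MASS_MONO <- c(A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259,
               F = 147.06841, G = 57.02146, H = 137.05891, I = 113.08406,
               K = 128.09496, L = 113.08406, M = 131.04049, N = 114.04293,
               P = 97.05276, Q = 128.05858, R = 156.10111, S = 87.03203,
               T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)

# residue-composition count matrix, one row per sequence
aa_counts <- function(sequences) {
  n <- length(sequences)
  out <- matrix(0L, nrow = n, ncol = 20L,
                dimnames = list(NULL, AA_ALPHABET))
  lens <- nchar(sequences)
  codes <- strsplit(sequences, "", fixed = TRUE)
  row <- rep.int(seq_len(n), lens)
  col <- match(unlist(codes, use.names = FALSE), AA_ALPHABET)
  if (anyNA(col)) {
    i <- row[which(is.na(col))[1L]]
    stop("non-canonical residue in sequence ", i)
  }
  tab <- table(factor(row, levels = seq_len(n)),
               factor(col, levels = 1:20))
  out[] <- as.integer(tab)
  out
}

check_sequences <- function(sequences) {
  stopifnot(is.character(sequences))
  if (length(sequences) == 0L) return(invisible(sequences))
  if (any(!nzchar(sequences))) stop("empty peptide sequence")
  toupper(sequences)
}

#' Average (or monoisotopic) peptide molecular weight
#'
#' Sum of residue masses plus one water. The companion [mz_value()] reports
#' the singly protonated ion, `mw + 1.008`, the positive-mode linear-TOF
#' convention.
#'
#' @param sequences Character vector of peptide sequences.
#' @param config A [property_config()].
#' @return Numeric vector of masses in Da.
#' @export
molecular_weight <- function(sequences, config = property_config()) {
  sequences <- check_sequences(sequences)
  scale <- if (config$mass == "average") MASS_AVG else MASS_MONO
  cts <- aa_counts(sequences)
  as.numeric(cts %*% scale[colnames(cts)]) + MASS_WATER
}

#' @rdname molecular_weight
#' @export
mz_value <- function(sequences, config = property_config()) {
  molecular_weight(sequences, config) + MASS_PROTON
}

#' Boman index (protein-binding potential)
#'
#' Length-normalised sum of per-residue solubility/binding-potential values
#' (side-chain water/cyclohexane transfer free energies, kcal/mol, with
#' hydrophilic residues positive). Values above 2.48 indicate a high
#' propensity for molecular interactions.
#'
#' @param sequences Character vector of peptide sequences.
#' @return Numeric vector (kcal/mol per residue).
#' @export
boman_index <- function(sequences) {
  sequences <- check_sequences(sequences)
  cts <- aa_counts(sequences)
  as.numeric(cts %*% SCALE_BOMAN[colnames(cts)]) / nchar(sequences)
}

#' Aliphatic index
#'
#' `AI = (100 / L) * (nA + 2.9 nV + 3.9 (nI + nL))` (Ikai's relative-volume
#' formula). Values above 70 indicate thermostability.
#'
#' @param sequences Character vector of peptide sequences.
#' @return Numeric vector (dimensionless).
#' @export
aliphatic_index <- function(sequences) {
  sequences <- check_sequences(sequences)
  cts <- aa_counts(sequences)
  as.numeric(100 * (cts[, "A"] + 2.9 * cts[, "V"] +
                    3.9 * (cts[, "I"] + cts[, "L"]))) / nchar(sequences)
}

#' Instability index
#'
#' `II = (10 / L) * sum` of the Guruprasad dipeptide weights (DIWV) over the
#' `L - 1` overlapping dipeptides; 0 for single residues. Values below 40
#' indicate in vitro stability.
#'
#' @param sequences Character vector of peptide sequences.
#' @return Numeric vector (dimensionless).
#' @export
instability_index <- function(sequences) {
  sequences <- check_sequences(sequences)
  vapply(sequences, function(s) {
    n <- nchar(s)
    if (n < 2L) return(0)
    codes <- strsplit(s, "", fixed = TRUE)[[1L]]
    i <- match(codes[-n], AA_ALPHABET)
    j <- match(codes[-1L], AA_ALPHABET)
    10 * sum(DIWV[cbind(i, j)]) / n
  }, 0, USE.NAMES = FALSE)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; higher values are more
#' hydrophobic. Bounded by the scale extrema, -4.5 (Arg) and 4.5 (Ile).
#'
#' @param sequences Character vector of peptide sequences.
#' @return Numeric vector (dimensionless).
#' @export
gravy <- function(sequences) {
  sequences <- check_sequences(sequences)
  cts <- aa_counts(sequences)
  as.numeric(cts %*% SCALE_KD[colnames(cts)]) / nchar(sequences)
}

# Henderson-Hasselbalch net charge from composition counts of the ionisable
# residues; `counts` has columns D, E, C, Y, H, K, R.
charge_from_counts <- function(counts, pH, pka) {
  pos <- 1 / (1 + 10^(pH - pka$nterm)) +
    as.numeric(counts[, "K"]) / (1 + 10^(pH - pka$positive[["K"]])) +
    as.numeric(counts[, "R"]) / (1 + 10^(pH - pka$positive[["R"]])) +
    as.numeric(counts[, "H"]) / (1 + 10^(pH - pka$positive[["H"]]))
  neg <- 1 / (1 + 10^(pka$cterm - pH)) +
    as.numeric(counts[, "D"]) / (1 + 10^(pka$negative[["D"]] - pH)) +
    as.numeric(counts[, "E"]) / (1 + 10^(pka$negative[["E"]] - pH)) +
    as.numeric(counts[, "C"]) / (1 + 10^(pka$negative[["C"]] - pH)) +
    as.numeric(counts[, "Y"]) / (1 + 10^(pka$negative[["Y"]] - pH))
  unname(pos - neg)
}

# vectorised bisection for the isoelectric point on (0, 14); net charge is
# strictly decreasing in pH, so the root is unique
pi_from_counts <- function(counts, pka, tol = 1e-3) {
  if (nrow(counts) == 0L) return(numeric(0))
  lo <- rep(0, nrow(counts))
  hi <- rep(14, nrow(counts))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    q <- charge_from_counts(counts, mid, pka)
    up <- q > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Net charge and isoelectric point
#'
#' Henderson-Hasselbalch sum over the ionisable side chains (D, E, C, Y, H,
#' K, R) and the free termini. `isoelectric_point()` solves
#' `net_charge(pI) = 0` by bisection on (0, 14) to a tolerance of 0.001 pH
#' units; the charge is strictly decreasing in pH, so the root is unique.
#'
#' @param sequences Character vector of peptide sequences.
#' @param pH Evaluation pH for `net_charge`.
#' @param config A [property_config()] (selects the pKa set).
#' @return Numeric vector (elementary charges, or pH units for the pI).
#' @export
net_charge <- function(sequences, pH = 7.0, config = property_config()) {
  sequences <- check_sequences(sequences)
  charge_from_counts(aa_counts(sequences), pH, PKA_SETS[[config$pka_set]])
}

#' @rdname net_charge
#' @export
isoelectric_point <- function(sequences, config = property_config()) {
  sequences <- check_sequences(sequences)
  pi_from_counts(aa_counts(sequences), PKA_SETS[[config$pka_set]])
}

#' Full property vectors for arbitrary peptides
#'
#' @param sequences Character vector of peptide sequences.
#' @param config A [property_config()].
#' @return data.frame with columns `sequence`, `length`, `mw`, `mz`,
#'   `boman`, `aliphatic`, `instability`, `gravy`, `charge`, `pI`.
#' @export
peptide_properties <- function(sequences, config = property_config()) {
  sequences <- check_sequences(sequences)
  cts <- aa_counts(sequences)
  pka <- PKA_SETS[[config$pka_set]]
  lens <- nchar(sequences)
  mass_scale <- if (config$mass == "average") MASS_AVG else MASS_MONO
  mw <- as.numeric(cts %*% mass_scale[colnames(cts)]) + MASS_WATER
  data.frame(
    sequence = sequences,
    length = lens,
    mw = mw,
    mz = mw + MASS_PROTON,
    boman = as.numeric(cts %*% SCALE_BOMAN[colnames(cts)]) / lens,
    aliphatic = as.numeric(100 * (cts[, "A"] + 2.9 * cts[, "V"] +
                                  3.9 * (cts[, "I"] + cts[, "L"]))) / lens,
    instability = instability_index(sequences),
    gravy = as.numeric(cts %*% SCALE_KD[colnames(cts)]) / lens,
    charge = charge_from_counts(cts, config$pH, pka),
    pI = pi_from_counts(cts, pka),
    stringsAsFactors = FALSE
  )
}

#' Annotate every distinct atlas sequence with its property vector
#'
#' Properties are functions of the sequence alone, so coordinate duplicates
#' share values and the table has one row per distinct per-isoform sequence
#' (the pools that pool-level summaries operate on). Composition sums are
#' taken from per-isoform cumulative scale sums over the parent sequence,
#' so the cost is linear in the number of fragments regardless of their
#' lengths.
#'
#' @param atlas A [build_atlas()] result.
#' @param config A [property_config()].
#' @return A data.table with columns `isoform`, `sequence`, `start`, `end`,
#'   `copies`, `length`, `mw`, `mz`, `boman`, `aliphatic`, `instability`,
#'   `gravy`, `charge`, `pI`.
#' @export
annotate_atlas <- function(atlas, config = property_config()) {
  stopifnot(inherits(atlas, "degradome_atlas"))
  pka <- PKA_SETS[[config$pka_set]]
  mass_scale <- if (config$mass == "average") MASS_AVG else MASS_MONO
  ion_res <- c("D", "E", "C", "Y", "H", "K", "R")
  out <- vector("list", length(atlas$records))
  for (k in seq_along(atlas$records)) {
    rec <- atlas$records[[k]]
    idx <- atlas$index[atlas$index$isoform == rec$id, ]
    codes <- match(strsplit(rec$sequence, "", fixed = TRUE)[[1L]],
                   AA_ALPHABET)
    s <- idx$start
    e <- idx$end
    lens <- e - s + 1L
    span <- function(cums) cums[e + 1L] - cums[s]
    cum_of <- function(v) c(0, cumsum(v))
    mass_sum <- span(cum_of(mass_scale[codes]))
    boman_sum <- span(cum_of(SCALE_BOMAN[codes]))
    kd_sum <- span(cum_of(SCALE_KD[codes]))
    n <- rec$length
    ali_sum <- span(cum_of(100 * ((AA_ALPHABET[codes] == "A") +
                                    2.9 * (AA_ALPHABET[codes] == "V") +
                                    3.9 * (AA_ALPHABET[codes] %in% c("I", "L")))))
    # dipeptide weights: fragment (s, e) covers dipeptides s..e-1
    dw <- DIWV[cbind(codes[-n], codes[-1L])]
    cdw <- c(0, cumsum(dw))
    dip_sum <- cdw[e] - cdw[s]
    counts <- matrix(0, nrow = nrow(idx), ncol = length(ion_res),
                     dimnames = list(NULL, ion_res))
    for (r in ion_res) {
      counts[, r] <- span(cum_of(as.numeric(AA_ALPHABET[codes] == r)))
    }
    mw <- mass_sum + MASS_WATER
    out[[k]] <- data.table::data.table(
      isoform = idx$isoform, sequence = idx$sequence,
      start = s, end = e, copies = idx$copies, length = lens,
      mw = mw, mz = mw + MASS_PROTON,
      boman = boman_sum / lens,
      aliphatic = ali_sum / lens,
      instability = 10 * dip_sum / lens,
      gravy = kd_sum / lens,
      charge = charge_from_counts(counts, config$pH, pka),
      pI = pi_from_counts(counts, pka)
    )
  }
  data.table::rbindlist(out)
}
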