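## coupling_stats module, thermodynamic part: nearest-neighbor duplex
## energetics of the lock unit and the transport-efficiency titration.

## Unified nearest-neighbor free energy parameters, dG37 in kcal/mol at
## 1 M NaCl (SantaLucia 1998 unified set). Keys are the top-strand
## dinucleotide read 5'->3'; the complementary stack has the same value.
NN_DG37 <- c(
  AA = -1.00, TT = -1.00,
  AT = -0.88,
  TA = -0.58,
  CA = -1.45, TG = -1.45,
  GT = -1.44, AC = -1.44,
  CT = -1.28, AG = -1.28,
  GA = -1.30, TC = -1.30,
  CG = -2.17,
  GC = -2.24,
  GG = -1.84, CC = -1.84)

NN_INIT_GC <- 0.98   # initiation with a terminal G.C pair
NN_INIT_AT <- 1.03   # initiation with a terminal A.T pair
NN_SYMMETRY <- 0.43  # self-complementary duplex correction

reverseComplement <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

#' Nearest-neighbor hybridization free energy of a lock duplex
#'
#' Standard free energy of duplex formation at 37 C from the unified
#' nearest-neighbor parameter set (1 M NaCl, no salt correction): the sum
#' of stacked-pair contributions along the duplex, plus one initiation
#' term per terminal base pair, plus a symmetry correction for
#' self-complementary sequences. The hybridization energy of a lock unit
#' grows with its number of hybridizing base pairs; this function maps a
#' lock sequence to that energy.
#'
#' @param sequence top strand, 5' to 3', characters ACGT, length >= 2.
#'   The bottom strand is its perfect complement.
#' @return dG37 of duplex formation in kcal/mol (negative = stable). The
#'   parameter set and salt condition are recorded in attributes
#'   \code{parameterSet} and \code{salt}.
#' @examples
#' nnHybridizationEnergy("ACGT")
#' @export
nnHybridizationEnergy <- function(sequence) {
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  if (length(chars) < 2) stop("sequence must have length >= 2")
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("sequence must contain only A, C, G, T")
  steps <- paste0(chars[-length(chars)], chars[-1])
  dg <- sum(NN_DG37[steps])
  ends <- chars[c(1, length(chars))]
  dg <- dg + sum(ifelse(ends %in% c("G", "C"), NN_INIT_GC, NN_INIT_AT))
  if (identical(s, reverseComplement(s))) dg <- dg + NN_SYMMETRY
  structure(unname(dg), parameterSet = "unified NN dG37",
            salt = "1 M NaCl")
}

#' Transport efficiency versus lock hybridization energy
#'
#' Fits a two-parameter logistic to the fraction of structures whose
#' downstream position transforms within the observation window, as a
#' function of the lock duplex hybridization energy (magnitude,
#' kcal/mol), and returns the energy at 50 percent transport efficiency
#' with its fit standard error.
#'
#' @param dG hybridization energies (kcal/mol, magnitudes).
#' @param fraction transformed fractions in [0, 1] (one per energy).
#' @param n optional per-point structure counts; if given, a binomial
#'   GLM on counts is fitted, otherwise nonlinear least squares on the
#'   fractions.
#' @return list with \code{midpoint} (kcal/mol), \code{se},
#'   \code{slope}, \code{fit}.
#' @export
transportEfficiencyFit <- function(dG, fraction, n = NULL) {
  stopifnot(length(dG) == length(fraction), length(dG) >= 3)
  if (all(fraction >= 0.5) || all(fraction <= 0.5))
    stop("no 50% crossing within the measured energy range; ",
         "refusing to extrapolate")
  if (!is.null(n)) {
    succ <- round(fraction * n)
    fit <- glm(cbind(succ, n - succ) ~ dG, family = binomial())
    co <- coef(fit)
    mid <- -co[1] / co[2]
    V <- vcov(fit)
    grad <- c(-1 / co[2], co[1] / co[2]^2)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    slope <- co[2]
  } else {
    ## proportions without counts: quasi-binomial logistic regression
    fit <- suppressWarnings(glm(fraction ~ dG, family = quasibinomial()))
    co <- coef(fit)
    mid <- -co[1] / co[2]
    V <- vcov(fit)
    grad <- c(-1 / co[2], co[1] / co[2]^2)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    slope <- co[2]
  }
  list(midpoint = unname(mid), se = unname(se), slope = unname(slope),
       fit = fit)
}
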