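#' Isotope constants
#'
#' Natural-abundance baselines and labelled-substrate enrichments used to
#' turn measured atom fractions into atom percent excess (APE) and
#' substrate-derived biomass fractions (X_net). Defaults: natural 13C
#' 0.0111 (VPDB convention), natural 15N 0.003676 (atmospheric N2), and a
#' labelled virus substrate at 40 atom% 13C / 80 atom% 15N. Substrate
#' enrichments vary batch to batch and should be set per experiment.
#'
#' @param f13C_nat,f15N_nat natural-abundance atom fractions
#' @param f13C_source,f15N_source substrate atom fractions
#' @return object of class `isotope_constants`
#' @export
isotope_constants <- function(f13C_nat = 0.0111, f15N_nat = 0.003676,
                              f13C_source = 0.40, f15N_source = 0.80) {
  k <- list(f13C_nat = f13C_nat, f15N_nat = f15N_nat,
            f13C_source = f13C_source, f15N_source = f15N_source)
  for (nm in names(k)) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a single number in [0, 1]")
  }
  if (k$f13C_nat <= 0 || k$f13C_source <= k$f13C_nat)
    stop("require 0 < f13C_nat < f13C_source <= 1")
  if (k$f15N_nat <= 0 || k$f15N_source <= k$f15N_nat)
    stop("require 0 < f15N_nat < f15N_source <= 1")
  structure(k, class = "isotope_constants")
}

#' Convert a C2-dimer secondary-ion ratio to a 13C atom fraction
#'
#' Under independent binomial assembly of two-carbon secondary ions from a
#' pool with 13C atom fraction f, P(13C12C)/P(12C12C) = 2f/(1-f), i.e. the
#' measured 13C12C-/12C2- ratio is twice the atomic 13C/12C ratio. Inverting,
#' f = R / (R + 2).
#'
#' @param r_dimer measured 13C12C- / 12C2- count ratio (>= 0)
#' @return 13C atom fraction in [0, 1)
#' @export
carbon_ion_ratio_to_atom_fraction <- function(r_dimer) {
  if (any(!is.finite(r_dimer)) || any(r_dimer < 0))
    stop("r_dimer must be non-negative and finite")
  r_dimer / (r_dimer + 2)
}

#' @rdname carbon_ion_ratio_to_atom_fraction
#' @param f 13C atom fraction in [0, 1)
#' @export
atom_fraction_to_carbon_ion_ratio <- function(f) {
  if (any(f < 0) || any(f >= 1)) stop("f must lie in [0, 1)")
  2 * f / (1 - f)
}

#' Convert a CN secondary-ion ratio to a 15N atom fraction
#'
#' The 12C15N- / 12C14N- count ratio equals the atomic 15N/14N ratio, so
#' f = R / (1 + R).
#'
#' @param r_cn measured 12C15N- / 12C14N- count ratio (>= 0)
#' @return 15N atom fraction in [0, 1)
#' @export
nitrogen_ion_ratio_to_atom_fraction <- function(r_cn) {
  if (any(!is.finite(r_cn)) || any(r_cn < 0))
    stop("r_cn must be non-negative and finite")
  r_cn / (1 + r_cn)
}

#' @rdname nitrogen_ion_ratio_to_atom_fraction
#' @param f 15N atom fraction in [0, 1)
#' @export
atom_fraction_to_nitrogen_ion_ratio <- function(f) {
  if (any(f < 0) || any(f >= 1)) stop("f must lie in [0, 1)")
  f / (1 - f)
}

#' Binomial C2 isotopologue probabilities
#'
#' Probabilities of the three two-carbon isotopologues when carbon atoms pair
#' independently at 13C atom fraction `f`.
#'
#' @param f 13C atom fraction
#' @return named vector `c(P12C2, P13C12C, P13C2)`
#' @export
c2_isotopologue_probs <- function(f) {
  if (any(f < 0) || any(f > 1)) stop("f must lie in [0, 1]")
  cbind(P12C2 = (1 - f)^2, P13C12C = 2 * f * (1 - f), P13C2 = f^2)
}

#' Dimer ratio factor
#'
#' The constant relating the C2-dimer ion ratio P(13C12C)/P(12C12C) to the
#' atomic ratio f/(1-f), computed from the binomial isotopologue
#' probabilities. Equals 2 identically for any f in (0, 1).
#'
#' @param f 13C atom fraction(s) in (0, 1)
#' @return numeric factor(s)
#' @export
dimer_ratio_factor <- function(f) {
  if (any(f <= 0) || any(f >= 1)) stop("f must lie strictly in (0, 1)")
  p <- c2_isotopologue_probs(f)
  (p[, "P13C12C"] / p[, "P12C2"]) / (f / (1 - f))
}

#' Atom percent excess
#'
#' Measured rare-isotope atom percent above its natural abundance:
#' `100 * (f_meas - f_nat)`. Negative values (measurement noise below natural
#' abundance) are preserved unless `floor_zero = TRUE`.
#'
#' @param f_meas measured atom fraction(s), in [0, 1]
#' @param f_nat natural-abundance atom fraction, in [0, 1]
#' @param floor_zero floor the result at 0 (reporting convenience)
#' @return atom percent excess (%)
#' @export
atom_percent_excess <- function(f_meas, f_nat, floor_zero = FALSE) {
  if (any(f_meas < 0) || any(f_meas > 1)) stop("f_meas must lie in [0, 1]")
  if (any(f_nat < 0) || any(f_nat > 1)) stop("f_nat must lie in [0, 1]")
  out <- 100 * (f_meas - f_nat)
  if (isTRUE(floor_zero)) out <- pmax(out, 0)
  out
}

#' Substrate-derived biomass fraction (X_net)
#'
#' Two-end-member linear mixing between natural-abundance biomass and the
#' labelled substrate: `100 * (f_meas - f_nat) / (f_source - f_nat)` percent
#' of the cell's element derived from the substrate.
#'
#' @param f_meas measured atom fraction(s)
#' @param f_nat natural-abundance atom fraction
#' @param f_source substrate atom fraction (must exceed `f_nat`)
#' @return X_net in percent (can be slightly negative for unlabelled
#'   material under measurement noise)
#' @export
x_net <- function(f_meas, f_nat, f_source) {
  if (any(f_meas < 0) || any(f_meas > 1)) stop("f_meas must lie in [0, 1]")
  if (f_source <= f_nat)
    stop("degenerate mixing line: f_source (", f_source,
         ") must exceed f_nat (", f_nat, ")")
  100 * (f_meas - f_nat) / (f_source - f_nat)
}

#' Implied cell divisions from X_net
#'
#' Under exponential growth in which every newly synthesised atom comes from
#' the labelled substrate, a cell that has divided d times carries
#' `X_net = 100 * (1 - 2^-d)` percent substrate-derived biomass (50% after
#' one division, 75% after two). `divisions_from_xnet` inverts this:
#' `d = -log2(1 - X_net/100)`.
#'
#' @param xnet X_net in percent, `0 <= xnet < 100`
#' @return implied number of divisions (possibly fractional)
#' @export
divisions_from_xnet <- function(xnet) {
  if (any(xnet < 0)) stop("xnet must be >= 0")
  if (any(xnet >= 100))
    stop("xnet >= 100% implies infinitely many divisions")
  -log2(1 - xnet / 100)
}

#' @rdname divisions_from_xnet
#' @param d number of divisions (>= 0)
#' @export
xnet_from_divisions <- function(d) {
  if (any(d < 0)) stop("d must be >= 0")
  100 * (1 - 2^(-d))
}

#' Full isotope measurement record
#'
#' Derives APE, X_net for carbon and nitrogen, and implied divisions from a
#' pair of measured atom fractions.
#'
#' @param f13C,f15N measured atom fractions
#' @param constants an [isotope_constants()] block
#' @return list of class `isotope_measurement` with fields `f13C`, `f15N`,
#'   `ape13C`, `ape15N`, `c_net`, `n_net`, `divisions_C`, `divisions_N` and
#'   the `constants` used
#' @export
isotope_measurement <- function(f13C, f15N, constants = isotope_constants()) {
  if (!inherits(constants, "isotope_constants"))
    constants <- do.call(isotope_constants, as.list(constants))
  cn <- x_net(f13C, constants$f13C_nat, constants$f13C_source)
  nn <- x_net(f15N, constants$f15N_nat, constants$f15N_source)
  div_of <- function(x) if (is.finite(x) && x >= 0 && x < 100)
    divisions_from_xnet(x) else NA_real_
  structure(list(
    f13C = f13C, f15N = f15N,
    ape13C = atom_percent_excess(f13C, constants$f13C_nat),
    ape15N = atom_percent_excess(f15N, constants$f15N_nat),
    c_net = cn, n_net = nn,
    divisions_C = div_of(cn), divisions_N = div_of(nn),
    constants = constants
  ), class = "isotope_measurement")
}

#' @export
print.isotope_measurement <- function(x, ...) {
  cat(sprintf("Isotope measurement: f13C = %.4f (APE %.2f%%, C_net %.1f%%), f15N = %.4f (APE %.2f%%, N_net %.1f%%)\n",
              x$f13C, x$ape13C, x$c_net, x$f15N, x$ape15N, x$n_net))
  invisible(x)
}
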