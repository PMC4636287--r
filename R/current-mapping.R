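#' Channel count and surface density from the saturating-Gbetagamma current
#'
#' At saturating coexpressed Gbetagamma the channel operates at its maximal
#' open probability, so `I_bg = i_single * Po,max * N / f_sc` can be inverted
#' to count functional channels: `N = I_bg * f_sc / (i_single * Po,max)`.
#'
#' @param i_bg Whole-cell current at saturating Gbetagamma (uA, 24 mM K+,
#'   -80 mV); scalar or vector.
#' @param po_max Maximal open probability.
#' @param consts A [recording_consts()] object.
#' @return A tibble with columns `i_bg`, `n_channels` and `channel_density`
#'   (channels/um^2).
#' @examples
#' channels_from_ibg(c(3.49, 12.34, 27.6))
#' @export
channels_from_ibg <- function(i_bg, po_max = 0.105,
                              consts = recording_consts()) {
  if (anyNA(i_bg) || any(i_bg < 0)) abort("`i_bg` must be non-negative (uA).")
  if (po_max <= 0) abort("`po_max` must be > 0.")
  n <- i_bg * 1e6 * consts$f_sc / (consts$i_single * po_max)
  tibble::tibble(
    i_bg = i_bg,
    n_channels = n,
    channel_density = n / consts$membrane_area
  )
}

#' Convert surface density to submembrane concentration (and back)
#'
#' Surface densities (molecules/um^2) are mapped to molar concentrations in
#' the submembrane interaction shell of width W via `C = N / (W * S * A)`.
#' With the default 10 nm width this gives ~166 nM per molecule/um^2; the
#' factor is derived from the geometry on every call so that width sweeps
#' remain consistent.
#'
#' @param density Surface density (molecules/um^2).
#' @param concentration Concentration (nM).
#' @param geom A [geometry_consts()] object.
#' @return `density_to_concentration`: nM; `concentration_to_density`:
#'   molecules/um^2. Exact mutual inverses.
#' @examples
#' density_to_concentration(1)        # ~166 nM
#' concentration_to_density(166.06)   # ~1 molecule/um^2
#' @export
density_to_concentration <- function(density, geom = geometry_consts()) {
  if (anyNA(density) || any(density < 0)) {
    abort("`density` must be non-negative (molecules/um^2).")
  }
  # molecules/um^2 -> molecules/m^2 (1e12); slab volume per m^2 of membrane
  # is width[m] * 1e3 L; result in mol/L, reported as nM.
  density * 1e12 / (geom$avogadro * geom$width * 1e-9 * 1e3) * 1e9
}

#' @rdname density_to_concentration
#' @export
concentration_to_density <- function(concentration, geom = geometry_consts()) {
  if (anyNA(concentration) || any(concentration < 0)) {
    abort("`concentration` must be non-negative (nM).")
  }
  concentration / density_to_concentration(1, geom)
}

#' Normalize currents across cell types and recording conditions
#'
#' Converts a current measurement to the common reference scale:
#' current density (pA/pF) at 24 mM external K+ and -80 mV. Oocyte whole-cell
#' currents (uA) are divided by the cell capacitance; HEK293 currents
#' recorded in 90 mM K+ are divided by the empirical solution factor; and
#' currents recorded at a different holding potential are rescaled by the
#' linear driving-force ratio `(V_ref - E_K)/(V - E_K)` (an approximation
#' that ignores inward rectification over this small voltage range). The 1 mM
#' difference between the 24 and 25 mM K+ solutions is ignored.
#'
#' @param value Current; uA for `units = "uA"`, otherwise pA/pF.
#' @param cell_type `"oocyte"`, `"hek"` or `"neuron"`.
#' @param units `"uA"` or `"pA_pF"`.
#' @param k_out External K+ (mM); 24/25 (reference), 90 (HEK high-K) or 144
#'   (patch solution) are recognized.
#' @param holding Holding potential (mV).
#' @param consts A [recording_consts()] object.
#' @return Current density (pA/pF) at 24 mM K+, -80 mV.
#' @examples
#' normalize_current(0.6, "oocyte", units = "uA")            # 3 pA/pF
#' normalize_current(10, "neuron", holding = -70)            # 10 * 43/33
#' @export
normalize_current <- function(value,
                              cell_type = c("oocyte", "hek", "neuron"),
                              units = if (cell_type == "oocyte") "uA"
                                      else "pA_pF",
                              k_out = if (cell_type == "hek") 90 else 24,
                              holding = -80,
                              consts = recording_consts()) {
  cell_type <- match.arg(cell_type)
  units <- match.arg(units, c("uA", "pA_pF"))
  if (anyNA(value)) abort("`value` must not contain missing values.")
  out <- value
  if (units == "uA") {
    if (cell_type != "oocyte") {
      abort("Whole-cell uA measurements are only supported for oocytes.")
    }
    out <- out * 1e6 / (consts$capacitance * 1e3)  # uA -> pA, nF -> pF
  }
  if (k_out %in% c(24, 25)) {
    # reference solution (24 mM) or neuronal 25 mM, treated as equal
  } else if (k_out == 90) {
    out <- out / consts$f_hek_k
  } else if (k_out == 144) {
    out <- out / consts$f_sc
  } else {
    abort(sprintf("No conversion factor known for k_out = %g mM.", k_out))
  }
  if (holding != -80) {
    if (holding >= consts$e_k) {
      abort("Holding potential must be negative to E_K for the correction.")
    }
    out <- out * (-80 - consts$e_k) / (holding - consts$e_k)
  }
  out
}

#' Surface density of a fluorophore using a tagged channel as molecular ruler
#'
#' Calibrates fluorescence intensity to absolute surface density using a
#' YFP-tagged channel whose density is known from its saturating-Gbetagamma
#' current: the reference label density is `ref_density *
#' labels_per_ref_unit` (2 labels per channel for a tagged subunit in a 2:2
#' heterotetramer), and the target density scales linearly with the
#' background-subtracted intensity ratio.
#'
#' @param intensity_target,intensity_ref Background-subtracted fluorescence
#'   intensities of the target protein and the reference channel, acquired
#'   with identical settings.
#' @param ref_density Reference channel density (channels/um^2), e.g. from
#'   [channels_from_ibg()].
#' @param labels_per_ref_unit Fluorophores per reference channel (default 2).
#' @return Target label density (molecules/um^2).
#' @examples
#' molecular_ruler_density(1, 1, 11.4)    # 22.8 YFP/um^2
#' molecular_ruler_density(0.5, 1, 11.4)  # 11.4
#' @export
molecular_ruler_density <- function(intensity_target, intensity_ref,
                                    ref_density, labels_per_ref_unit = 2) {
  if (any(intensity_ref <= 0)) abort("`intensity_ref` must be > 0.")
  if (any(ref_density < 0) || any(intensity_target < 0)) {
    abort("Densities and intensities must be non-negative.")
  }
  ref_density * labels_per_ref_unit * intensity_target / intensity_ref
}

#' Bracket the number of bound Gbetagamma for a fractional open probability
#'
#' Maps a measured P_o/P_o,max (e.g. I_total/I_bg) onto the discrete ladder
#' of fractional open probabilities: returns the pair of consecutive
#' occupancy numbers whose fractional open probabilities bracket the value,
#' or `(n, n)` for an exact match.
#'
#' @param value P_o/P_o,max in \[0, 1\].
#' @param fp Fractional open probabilities for 1..4 bound Gbetagamma.
#' @param tol Tolerance for an exact match.
#' @return Integer vector `c(n_low, n_high)`.
#' @examples
#' equivalent_bound_gbg(0.26)  # c(3, 3)
#' equivalent_bound_gbg(0.5)   # c(3, 4)
#' @export
equivalent_bound_gbg <- function(value, fp = c(0.01, 0.06, 0.26, 1),
                                 tol = 1e-9) {
  if (length(value) != 1L || is.na(value) || value < 0 || value > 1) {
    abort("`value` must be a single number in [0, 1].")
  }
  ladder <- c(0, fp)  # occupancies 0..4
  hit <- which(abs(ladder - value) <= tol)
  if (length(hit)) {
    n <- hit[[1L]] - 1L
    return(c(n_low = n, n_high = n))
  }
  n_high <- which(ladder > value)[[1L]] - 1L
  c(n_low = n_high - 1L, n_high = n_high)
}
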