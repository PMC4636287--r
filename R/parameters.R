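#' Gating parameters of the GIRK1/2 channel
#'
#' Bundles the parameters of the steady-state gating model: the gating
#' variant, the fractional open probabilities of the four Gbetagamma-occupied
#' channel states, the maximal open probability, the Gbetagamma-dependent
#' fraction of open probability, and the binding affinities of the
#' channel-Gbetagamma and Galpha(GDP)-Gbetagamma interactions.
#'
#' The defaults are the experimentally grounded standard values: fractional
#' open probabilities of roughly 1%, 6%, 26% and 100% of `po_max` for one to
#' four bound Gbetagamma; `po_max = 0.105` measured at saturating Gbetagamma;
#' a channel-Gbetagamma dissociation constant of 50 nM from direct biochemical
#' measurements; and a heterotrimer dissociation constant of 1.86 nM
#' (association and dissociation rates 0.7e6 /M/s and 0.0013 /s). The
#' heterotrimer equilibrium depends only on the ratio `koff/kon`, so the rates
#' are retained purely for a consistency check against `kd_trimer`.
#'
#' @param variant Gating variant. `"graded"`: every Gbetagamma-occupied state
#'   contributes its fractional open probability. `"concerted"`: only the
#'   fully occupied channel opens. `"graded_intrinsic"`: graded model plus a
#'   Gbetagamma-independent intrinsic activity; `phi` is the fraction of
#'   `po_max` that remains Gbetagamma-dependent.
#' @param fp Numeric length-4 vector of fractional open probabilities for
#'   channels with 1..4 bound Gbetagamma. Must be non-decreasing with last
#'   element 1.
#' @param po_max Maximal open probability (0 < po_max <= 1).
#' @param phi Gbetagamma-dependent fraction of `po_max` (0 < phi <= 1). Only
#'   used by the `"graded_intrinsic"` variant; an intrinsic open probability
#'   of x% of `po_max` corresponds to `phi = 1 - x/100`.
#' @param kd_channel Dissociation constant of the GIRK-Gbetagamma interaction
#'   (nM), identical and occupancy-independent for all four sites.
#' @param kd_trimer Dissociation constant of the Galpha(GDP)-Gbetagamma
#'   heterotrimer (nM).
#' @param kon_trimer,koff_trimer Association (/M/s) and dissociation (/s)
#'   rates of the heterotrimer; checked for consistency with `kd_trimer`
#'   (|koff/kon - kd_trimer| must be < 5% of kd_trimer).
#'
#' @return An object of class `girk_gating` (a validated list).
#' @examples
#' gating_params()
#' gating_params(variant = "concerted")
#' @export
gating_params <- function(variant = c("graded", "concerted", "graded_intrinsic"),
                          fp = c(0.01, 0.06, 0.26, 1),
                          po_max = 0.105,
                          phi = 1,
                          kd_channel = 50,
                          kd_trimer = 1.86,
                          kon_trimer = 0.7e6,
                          koff_trimer = 0.0013) {
  variant <- match.arg(variant)
  if (length(fp) != 4L || !is.numeric(fp) || anyNA(fp)) {
    abort("`fp` must be a numeric vector of 4 fractional open probabilities.")
  }
  if (any(diff(fp) < 0) || abs(fp[4] - 1) > 1e-12) {
    abort("`fp` must be non-decreasing with fp[4] = 1.")
  }
  if (!is.numeric(po_max) || po_max <= 0 || po_max > 1) {
    abort("`po_max` must lie in (0, 1].")
  }
  if (!is.numeric(phi) || phi <= 0 || phi > 1) {
    abort("`phi` must lie in (0, 1].")
  }
  if (kd_channel <= 0) abort("`kd_channel` must be > 0 (nM).")
  if (kd_trimer <= 0) abort("`kd_trimer` must be > 0 (nM).")
  if (!is.null(kon_trimer) && !is.null(koff_trimer)) {
    kd_rates <- koff_trimer / kon_trimer * 1e9  # M -> nM
    if (abs(kd_rates - kd_trimer) / kd_trimer >= 0.05) {
      abort(sprintf(
        "koff/kon (%.4g nM) is inconsistent with kd_trimer (%.4g nM).",
        kd_rates, kd_trimer
      ))
    }
  }
  structure(
    list(
      variant = variant, fp = as.numeric(fp), po_max = po_max, phi = phi,
      kd_channel = kd_channel, kd_trimer = kd_trimer,
      kon_trimer = kon_trimer, koff_trimer = koff_trimer
    ),
    class = "girk_gating"
  )
}

#' @export
print.girk_gating <- function(x, ...) {
  cat("<girk_gating> variant:", x$variant, "\n")
  cat("  fp:", paste(format(x$fp), collapse = ", "),
      " po_max:", format(x$po_max), "\n")
  if (x$variant == "graded_intrinsic") {
    cat("  phi (Gbg-dependent fraction):", format(x$phi), "\n")
  }
  cat("  kd_channel:", format(x$kd_channel), "nM;  kd_trimer:",
      format(x$kd_trimer), "nM\n")
  invisible(x)
}

#' G-protein pool available to the channel
#'
#' One-compartment totals (submembrane concentrations, nM) of channel,
#' Gbetagamma and Galpha available for interaction. Surface densities in
#' molecules/um^2 are converted to nM with [density_to_concentration()].
#'
#' @param c_total Total channel concentration (nM).
#' @param gbg_total Total available Gbetagamma (nM).
#' @param ga_total Total available Galpha (nM).
#' @return An object of class `girk_pool`.
#' @examples
#' gprotein_pool(c_total = 455, gbg_total = 1700, ga_total = 620)
#' @export
gprotein_pool <- function(c_total, gbg_total, ga_total = 0) {
  vals <- c(c_total = c_total, gbg_total = gbg_total, ga_total = ga_total)
  if (anyNA(vals) || any(vals < 0)) {
    abort("Pool concentrations must be non-negative and non-missing (nM).")
  }
  structure(as.list(vals), class = "girk_pool")
}

#' @export
print.girk_pool <- function(x, ...) {
  cat(sprintf(
    "<girk_pool> channel %.4g nM, Gbg %.4g nM, Ga %.4g nM\n",
    x$c_total, x$gbg_total, x$ga_total
  ))
  invisible(x)
}

#' Recording and cell constants
#'
#' Constants relating single-channel properties and whole-cell currents:
#' the single-channel current at 144 mM external K+, the solution conversion
#' factor between the 144 mM (patch) and 24 mM (whole-cell) K+ solutions, the
#' oocyte surface area and capacitance, the HEK293 90->24 mM K+ current
#' factor, and the K+ reversal potential used for holding-potential
#' corrections.
#'
#' @param i_single Single-channel current (pA) at 144 mM K+, -80 mV.
#' @param f_sc Current ratio between the 144 mM and 24 mM K+ solutions.
#' @param membrane_area Cell surface area (um^2); the oocyte default follows
#'   from 200 nF capacitance at 1 uF/cm^2.
#' @param capacitance Cell capacitance (nF), used to convert oocyte currents
#'   to current densities (pA/pF).
#' @param f_hek_k Current ratio between 90 mM (HEK) and 24 mM K+ solutions.
#' @param e_k K+ reversal potential (mV) in the ~25 mM K+ solution, used for
#'   linear driving-force corrections between holding potentials.
#' @return An object of class `girk_recording`.
#' @examples
#' recording_consts()
#' @export
recording_consts <- function(i_single = 2.8,
                             f_sc = 4.63,
                             membrane_area = 2e7,
                             capacitance = 200,
                             f_hek_k = 3.27,
                             e_k = -37) {
  vals <- c(i_single, f_sc, membrane_area, capacitance, f_hek_k)
  if (anyNA(vals) || any(vals <= 0)) {
    abort("Recording constants must be strictly positive.")
  }
  structure(
    list(
      i_single = i_single, f_sc = f_sc, membrane_area = membrane_area,
      capacitance = capacitance, f_hek_k = f_hek_k, e_k = e_k
    ),
    class = "girk_recording"
  )
}

#' @export
print.girk_recording <- function(x, ...) {
  cat(sprintf(
    "<girk_recording> i_single %.3g pA, f_sc %.3g, area %.3g um^2, C %.3g nF\n",
    x$i_single, x$f_sc, x$membrane_area, x$capacitance
  ))
  invisible(x)
}

#' Submembrane geometry constants
#'
#' The width of the submembrane interaction space within which surface
#' densities are converted to molar concentrations, plus Avogadro's number.
#' With the default 10 nm width, 1 molecule/um^2 corresponds to ~166 nM.
#'
#' @param width Width of the submembrane interaction space (nm).
#' @param avogadro Avogadro's number (/mol).
#' @return An object of class `girk_geometry`.
#' @examples
#' density_to_concentration(1, geometry_consts())
#' @export
geometry_consts <- function(width = 10, avogadro = 6.02214076e23) {
  if (!is.numeric(width) || width <= 0) abort("`width` must be > 0 (nm).")
  structure(list(width = width, avogadro = avogadro), class = "girk_geometry")
}

#' @export
print.girk_geometry <- function(x, ...) {
  cat(sprintf(
    "<girk_geometry> width %.3g nm (1 molecule/um^2 = %.4g nM)\n",
    x$width, density_to_concentration(1, x)
  ))
  invisible(x)
}
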