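#' Physical parameters, rates and boundary conditions
#'
#' Collects every physical constant, forcing rate and boundary value of the
#' coupled xylem-phloem model, with defaults set to the core
#' parameterisation. Internal units are fixed: MPa, m, s, mmol for water,
#' mol for sucrose; `R * T * C` with `R` in MPa m^3 mol^-1 K^-1 then yields
#' MPa directly.
#'
#' @param T Leaf temperature (K), default 293.
#' @param R Gas constant (MPa m^3 mol^-1 K^-1), default 8.31e-6.
#' @param D_su Sucrose diffusivity (m^2 s^-1), default 5.22e-10.
#' @param v_mu Molal volume of water (m^3 mmol^-1), default 18.00e-9.
#' @param K_c Phloem/xylem cross-conduit conductance (mmol s^-1 MPa^-1),
#'   default 0.50 (altered value 0.0005 virtually isolates the networks).
#' @param E Transpiration rate (mmol s^-1 m^-2), uniform per node, default
#'   -2.00 (negative = efflux); alternatives -1.00 and 0.00.
#' @param Lambda Mean sucrose loading rate (mol s^-1 m^-2), default 2.78e-7.
#' @param loading `"uniform"` or `"gradient"` (linear, +50% of the mean at the
#'   leaf base to -50% at the tip, same leaf-area-weighted mean).
#' @param petiole_p_xyl Xylem pressure at the petiole (MPa), default 0.00.
#' @param petiole_p_ph Phloem pressure at the petiole (MPa), default 0.20.
#' @param sigma_lateral Reflection coefficient along phloem conduits
#'   (default 0: solutes move freely between phloem nodes).
#' @param sigma_cross Reflection coefficient of the cross conduit (default 1:
#'   ideal semipermeable membrane between xylem and phloem).
#' @param phloem_factor Ratio of phloem to xylem conductance, default 3/100.
#' @param sucrose_scheme `"literal"` (convective sucrose flux always carries
#'   the centre-node concentration) or `"upwind"` (donor-cell: carries the
#'   concentration of the node the water flows from, which conserves sucrose
#'   pairwise).
#' @param conductivity Per-order xylem conductivities (m mmol s^-1 MPa^-1);
#'   see [default_conductivities()].
#' @param diameter Per-order vein diameters (m).
#' @return A list of class `model_params`.
#' @examples
#' p5 <- model_params(conductivity = order2_multiplier(5))
#' @export
model_params <- function(T = 293, R = 8.31e-6, D_su = 5.22e-10, v_mu = 18.00e-9,
                         K_c = 0.50, E = -2.00, Lambda = 2.78e-7,
                         loading = c("uniform", "gradient"),
                         petiole_p_xyl = 0.00, petiole_p_ph = 0.20,
                         sigma_lateral = 0, sigma_cross = 1,
                         phloem_factor = 3 / 100,
                         sucrose_scheme = c("literal", "upwind"),
                         conductivity = default_conductivities()$conductivity,
                         diameter = default_conductivities()$diameter) {
  loading <- match.arg(loading)
  sucrose_scheme <- match.arg(sucrose_scheme)
  stopifnot(T > 0, K_c >= 0, D_su >= 0, v_mu > 0, phloem_factor > 0,
            length(conductivity) == 5, length(diameter) == 5,
            all(conductivity > 0), all(diameter > 0))
  structure(
    list(
      T = T, R = R, D_su = D_su, v_mu = v_mu, K_c = K_c, E = E,
      Lambda = Lambda, loading = loading,
      petiole_p_xyl = petiole_p_xyl, petiole_p_ph = petiole_p_ph,
      sigma_lateral = sigma_lateral, sigma_cross = sigma_cross,
      phloem_factor = phloem_factor, sucrose_scheme = sucrose_scheme,
      conductivity = conductivity, diameter = diameter
    ),
    class = "model_params"
  )
}

#' Conductivity table with a scaled second-order vein conductivity
#'
#' Convenience for the conductance-variant experiments: returns the default
#' conductivity table with the order-2 entry multiplied by `factor`
#' (5 and 1/5 are the canonical variants).
#'
#' @param factor Multiplier applied to the order-2 conductivity.
#' @return Numeric vector of per-order conductivities.
#' @export
order2_multiplier <- function(factor) {
  k <- default_conductivities()$conductivity
  k[2] <- k[2] * factor
  k
}

#' Per-node sucrose loading rates
#'
#' Uniform loading assigns the mean rate everywhere; the gradient option
#' varies linearly from 1.5x the mean at the leaf base (z = 0) to 0.5x at the
#' tip (z = L). Because the leaf outline is symmetric about mid-blade, the
#' leaf-area-weighted mean is preserved.
#'
#' @param params A [model_params()] object.
#' @param nodes Node tibble with `z` (m).
#' @param L Leaf length (m).
#' @return Numeric vector of loading rates (mol s^-1 m^-2) per node.
#' @export
loading_rates <- function(params, nodes, L) {
  if (params$loading == "uniform") {
    rep(params$Lambda, nrow(nodes))
  } else {
    params$Lambda * (1.5 - nodes$z / L)
  }
}
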