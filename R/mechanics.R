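# Capsid-wall mechanics: the packaged genome pressurises the capsid, which
# behaves as a thin-walled spherical pressure vessel. Pressure units are
# abstract — outputs carry whatever unit the input pressure carries.

#' Hoop stress in a thin spherical capsid wall
#'
#' Tangential (hoop) tensile stress in a thin shell of radius `rc` and wall
#' thickness `t` under internal pressure `pc`:
#' \eqn{\sigma = p_c r_c / t}. The thin-wall assumption \eqn{t \ll r_c} is
#' checked: a warning is emitted when `t > rc / 5`.
#'
#' @param pc Internal pressure (>= 0, any consistent unit).
#' @param rc Inner radius in nm.
#' @param t Wall thickness in nm, `0 < t < rc`.
#' @return Wall stress in the units of `pc`.
#' @examples
#' hoop_stress(10, 50, 5)  # 100
#' @export
hoop_stress <- function(pc, rc, t) {
  if (any(pc < 0)) stop("pressure must be non-negative", call. = FALSE)
  if (any(t <= 0)) stop("thickness must be positive", call. = FALSE)
  if (any(t >= rc))
    stop("thickness >= radius: not a thin-walled shell", call. = FALSE)
  if (any(t > rc / 5))
    warning("t > rc/5: thin-wall approximation is questionable",
            call. = FALSE)
  pc * rc / t
}

#' Scaling exponent of packing density with capsid radius
#'
#' Given the allometric law \eqn{V_c \propto L_g^m}, i.e.
#' \eqn{r_c \propto L_g^{m/3}}, the packing density
#' \eqn{\rho = L_g / r_c^3} scales as \eqn{r_c^{3/m - 3}}. For phages
#' (m = 1) the exponent is 0 — packing density, and hence capsid pressure,
#' varies little with phage size. For NCLDVs (m = 2) it is -3/2: density
#' and pressure fall with size, which is how large NCLDV capsids stay below
#' their ultimate wall strength.
#'
#' @param m Allometric exponent (> 0).
#' @return The exponent \eqn{3/m - 3} of \eqn{\rho} versus \eqn{r_c}.
#' @examples
#' density_scaling_exponent(1)  # 0
#' density_scaling_exponent(2)  # -1.5
#' @export
density_scaling_exponent <- function(m) {
  if (any(m <= 0)) stop("exponent m must be positive", call. = FALSE)
  3 / m - 3
}

#' Structural integrity margin of a capsid wall
#'
#' A capsid stays intact while its wall stress is below the ultimate
#' tensile strength: the margin is
#' \eqn{\sigma_u - p_c r_c / t}; positive means intact under this
#' criterion, zero is the bursting boundary. \eqn{\sigma_u} is an input —
#' typically a literature curve, possibly decreasing with radius — never
#' computed here.
#'
#' @inheritParams hoop_stress
#' @param sigma_u Ultimate tensile strength of the wall (> 0, same unit as
#'   `pc`).
#' @return `sigma_u - hoop_stress(pc, rc, t)`.
#' @export
integrity_margin <- function(pc, rc, t, sigma_u) {
  if (any(sigma_u <= 0))
    stop("ultimate tensile strength must be positive", call. = FALSE)
  sigma_u - hoop_stress(pc, rc, t)
}
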