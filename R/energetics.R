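# ATP-denominated virion energy budget: genome replication and capsid
# translation costs. Costs are dimensionless counts of ATP hydrolysis
# events per virion. The genome-packaging motor (~0.5 ATP/bp) is excluded —
# it is two orders of magnitude below the replication cost — so the total
# budget here is translation + replication only.

#' ATP cost constants per host type
#'
#' Per-monomer biosynthesis costs, in ATP hydrolysis events:
#' \describe{
#'   \item{ed}{direct cost of one DNA nucleotide from precursor metabolites
#'     (11 ATP);}
#'   \item{ep}{chain elongation per base (2 ATP);}
#'   \item{eod}{opportunity cost per nucleotide — 34 ATP in a bacterial
#'     host, 42 ATP in a eukaryote;}
#'   \item{ea}{direct cost of one amino acid (2 ATP);}
#'   \item{eea}{peptide-bond formation (4 ATP);}
#'   \item{eoa}{opportunity cost per amino acid — 25 ATP bacterial,
#'     30 ATP eukaryote;}
#'   \item{vd}{volume of one base pair, ~1 nm^3;}
#'   \item{va}{volume of one amino acid, ~0.1 nm^3.}
#' }
#' Opportunity costs are the ATP equivalents the host forgoes by diverting
#' the monomer from its own metabolism.
#'
#' @param host `"bacterial"` or `"eukaryote"`.
#' @return An object of class `energy_constants` (a named list).
#' @examples
#' energy_constants("bacterial")$eod
#' @export
energy_constants <- function(host = c("bacterial", "eukaryote")) {
  host <- match.arg(host)
  k <- list(ed = 11, ep = 2, eod = if (host == "bacterial") 34 else 42,
            ea = 2, eea = 4, eoa = if (host == "bacterial") 25 else 30,
            vd = 1, va = 0.1, host = host)
  class(k) <- "energy_constants"
  k
}

#' @export
print.energy_constants <- function(x, ...) {
  cat(sprintf("ATP cost constants (%s host):\n", x$host))
  cat(sprintf("  DNA:   ed = %g, ep = %g, eod = %g  (per nt; x2 strands)\n",
              x$ed, x$ep, x$eod))
  cat(sprintf("  AA:    ea = %g, eea = %g, eoa = %g  (per amino acid)\n",
              x$ea, x$eea, x$eoa))
  cat(sprintf("  vols:  vd = %g nm^3/bp, va = %g nm^3/aa\n", x$vd, x$va))
  invisible(x)
}

.check_constants <- function(k) {
  if (!inherits(k, "energy_constants"))
    stop("`constants` must come from energy_constants()", call. = FALSE)
  k
}

#' Genome replication cost from genome length
#'
#' \eqn{E_{rep} = 2 L_g (e_d + e_p + e_{od})} ATP per virion; the factor 2
#' reflects the two strands of the dsDNA genome. Per base pair this is
#' 94 ATP for a bacterial host and 110 ATP for a eukaryote.
#'
#' @param genome_length_bp Genome length in bp (> 0).
#' @param constants An [energy_constants()] object.
#' @return ATP hydrolysis events per virion.
#' @examples
#' replication_cost_length(1, energy_constants("bacterial"))  # 94
#' @export
replication_cost_length <- function(genome_length_bp,
                                    constants = energy_constants("bacterial")) {
  k <- .check_constants(constants)
  if (any(genome_length_bp <= 0))
    stop("genome length must be positive", call. = FALSE)
  2 * genome_length_bp * (k$ed + k$ep + k$eod)
}

#' Genome replication cost from capsid inner radius
#'
#' Capacity-based variant: the packaged genome length is approximated by
#' the inner capsid volume divided by the base-pair volume \eqn{v_d}, giving
#' \eqn{E_{rep} = \frac{4\pi r_c^3}{3 v_d}(e_d + e_p + e_{od})}, a pure
#' \eqn{r_c^3} law.
#'
#' @param rc Inner capsid radius in nm (> 0).
#' @param constants An [energy_constants()] object.
#' @return ATP hydrolysis events per virion.
#' @export
replication_cost_radius <- function(rc,
                                    constants = energy_constants("bacterial")) {
  k <- .check_constants(constants)
  if (any(rc <= 0)) stop("radius must be positive", call. = FALSE)
  4 * pi * rc^3 / (3 * k$vd) * (k$ed + k$ep + k$eod)
}

#' NCLDV replication cost from capsid inner radius
#'
#' For NCLDVs the genome does not fill the capsid, so capacity-based
#' costing overstates \eqn{E_{rep}}; instead the group's fitted allometry is
#' inverted ([genome_length_from_radius()], \eqn{L_g \propto r_c^{3/m}})
#' and the length-based cost applied. With m = 2 the cost scales as
#' \eqn{r_c^{3/2}}.
#'
#' @param rc Inner capsid radius in nm (> 0).
#' @param fit An inner-volume `allofit` for the NCLDV group (defaults to the
#'   literature coefficients m = 2.00, A = 1.38).
#' @param constants An [energy_constants()] object; eukaryote host by
#'   default.
#' @return ATP hydrolysis events per virion.
#' @export
replication_cost_ncldv <- function(rc, fit = reference_fit("ncldv"),
                                   constants = energy_constants("eukaryote")) {
  lg <- genome_length_from_radius(rc, fit)
  unit_factor <- switch(fit$genome_unit, kb = 1000, bp = 1,
                        stop("unknown genome unit in fit: ", fit$genome_unit,
                             call. = FALSE))
  replication_cost_length(lg * unit_factor, constants)
}

#' Capsid protein translation cost
#'
#' The number of amino acids in the capsid shell is approximated by the
#' shell volume \eqn{4\pi r_c^2 t} divided by the amino-acid volume
#' \eqn{v_a}, giving
#' \eqn{E_{tl} = \frac{4\pi r_c^2 t}{v_a}(e_a + e_{ea} + e_{oa})}, a pure
#' \eqn{r_c^2} law.
#'
#' @param rc Inner capsid radius in nm (> 0).
#' @param thickness Capsid wall thickness t in nm (> 0); 3 nm for phages,
#'   10 nm for NCLDVs.
#' @param constants An [energy_constants()] object.
#' @return ATP hydrolysis events per virion.
#' @export
translation_cost <- function(rc, thickness,
                             constants = energy_constants("bacterial")) {
  k <- .check_constants(constants)
  if (any(rc <= 0)) stop("radius must be positive", call. = FALSE)
  if (any(thickness <= 0)) stop("thickness must be positive", call. = FALSE)
  4 * pi * rc^2 * thickness / k$va * (k$ea + k$eea + k$eoa)
}

#' Radius at which replication cost overtakes translation cost
#'
#' Closed-form crossover of the capacity-based replication law
#' (\eqn{\propto r_c^3}) and the translation law (\eqn{\propto r_c^2}):
#' \eqn{r_c^* = \frac{3 t v_d (e_a + e_{ea} + e_{oa})}
#' {v_a (e_d + e_p + e_{od})}}. With bacterial constants and t = 3 nm this
#' is ~59.4 nm; below it translation dominates the phage budget, above it
#' replication does.
#'
#' @param constants An [energy_constants()] object.
#' @param thickness Wall thickness in nm.
#' @return Crossover inner radius in nm.
#' @export
crossover_radius <- function(constants = energy_constants("bacterial"),
                             thickness = 3) {
  k <- .check_constants(constants)
  3 * thickness * k$vd * (k$ea + k$eea + k$eoa) /
    (k$va * (k$ed + k$ep + k$eod))
}

#' Energy budget table over a radius grid
#'
#' Tabulates translation and replication costs against inner radius for one
#' virus group, ready for log-log plotting. Phages use bacterial host
#' constants and t = 3 nm, with replication costed from actual genome
#' lengths when supplied and from capsid capacity
#' ([replication_cost_radius()]) otherwise. NCLDVs use eukaryote constants,
#' t = 10 nm, and the fitted \eqn{L_g(r_c)} relation
#' ([replication_cost_ncldv()]); a fit is required for this group.
#'
#' @param radii Inner radii in nm (> 0).
#' @param group `"phage"` or `"ncldv"`.
#' @param fit Inner-volume `allofit` used for the NCLDV replication cost.
#' @param genome_length_bp Optional per-radius actual genome lengths (bp)
#'   for the phage replication cost.
#' @param thickness Wall thickness override in nm (defaults to the group's).
#' @return A tibble with columns `rc_nm`, `translation_atp`,
#'   `replication_atp`, `group`.
#' @export
energy_table <- function(radii, group = c("phage", "ncldv"), fit = NULL,
                         genome_length_bp = NULL, thickness = NULL) {
  group <- match.arg(group)
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  if (group == "phage") {
    k <- energy_constants("bacterial")
    t <- if (is.null(thickness)) 3 else thickness
    erep <- if (is.null(genome_length_bp)) {
      replication_cost_radius(radii, k)
    } else {
      if (length(genome_length_bp) != length(radii))
        stop("genome_length_bp must match radii in length", call. = FALSE)
      replication_cost_length(genome_length_bp, k)
    }
  } else {
    if (is.null(fit))
      stop("an inner-volume fit is required for the NCLDV energy table",
           call. = FALSE)
    k <- energy_constants("eukaryote")
    t <- if (is.null(thickness)) 10 else thickness
    erep <- replication_cost_ncldv(radii, fit, k)
  }
  tibble::tibble(rc_nm = radii,
                 translation_atp = translation_cost(radii, t, k),
                 replication_atp = erep,
                 group = group)
}
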