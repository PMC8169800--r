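# Controlled vocabularies for trait tables and the literature constants the
# models plug in. Everything user-auditable is surfaced through
# allometry_defaults().

.host_groups <- c("bacteria", "archaea", "protozoa_algae", "fungi",
                  "plant", "invertebrate", "vertebrate")

.genome_types <- c("dsDNA", "ssDNA", "dsRNA", "ssRNA_pos", "ssRNA_neg",
                   "RT_dsDNA", "RT_ssRNA")

.capsid_shapes <- c("icosahedral_spherical", "ovoid", "rod_filamentous",
                    "brick")

.group_tags <- c("phage", "jumbo_phage", "NCLDV", "other")

# Capsid wall thickness (nm): 3 nm for tailed phage heads, 10 nm for NCLDVs
# with a single internal lipid bilayer. Multilayer capsids (e.g. the 70 nm
# Mimivirus wall) are handled per record via thickness_nm overrides.
.thickness_nm <- c(phage = 3, jumbo_phage = 3, NCLDV = 10)

# DNA cylinder model: radius 1 nm, axial rise 0.34 nm per bp, so
# Vg = pi * 1^2 * 0.34 * Lg.
.bp_rise_nm <- 0.34

#' Default constants used across the pipeline
#'
#' Returns every numeric convention the package bakes in, in one auditable
#' list: capsid wall thicknesses per virus group, the DNA cylinder model
#' behind genome volume, molecular volumes, ATP cost constants per host, the
#' unit convention used by the allometric fits, and the generator defaults.
#'
#' @return A named list of constants.
#' @examples
#' allometry_defaults()$thickness_nm
#' @export
allometry_defaults <- function() {
  list(
    host_groups       = .host_groups,
    genome_types      = .genome_types,
    capsid_shapes     = .capsid_shapes,
    group_tags        = .group_tags,
    thickness_nm      = .thickness_nm,
    bp_rise_nm        = .bp_rise_nm,
    dna_radius_nm     = 1,
    fit_units         = c(genome = "kb", volume = "nm3"),
    energy_bacterial  = unclass(energy_constants("bacterial")),
    energy_eukaryote  = unclass(energy_constants("eukaryote")),
    synthetic_phage   = list(m = 0.95, A = 3.49, sigma = 0.3,
                             lg_range_kb = c(10, 500)),
    synthetic_ncldv   = list(m = 2.00, A = 1.38, sigma = 0.3,
                             lg_range_kb = c(100, 2500))
  )
}

#' Published allometric coefficients for a virus group
#'
#' Literature values of the inner-volume scaling \eqn{V_c = a L_g^m}
#' (genome length in kb, volume in nm^3) for icosahedral dsDNA phages
#' (m = 0.95, A = 3.49) and NCLDVs (m = 2.00, A = 1.38). These are the
#' group-level coefficients the energy and synthetic modules use when no
#' freshly fitted model is supplied.
#'
#' @param group `"phage"` or `"ncldv"`.
#' @return An object of class `allofit` carrying `m`, `A`, `a = 10^A` and
#'   the unit convention; statistical fields (`r_squared`, `p_value`, ...)
#'   are `NA` because the object is not a fresh fit.
#' @examples
#' reference_fit("ncldv")$m
#' @export
reference_fit <- function(group = c("phage", "ncldv")) {
  group <- match.arg(group)
  par <- switch(group,
                phage = list(m = 0.95, A = 3.49),
                ncldv = list(m = 2.00, A = 1.38))
  structure(
    list(m = par$m, A = par$A, a = 10^par$A,
         r_squared = NA_real_, p_value = NA_real_, n = NA_integer_,
         se_m = NA_real_, ci_m = c(NA_real_, NA_real_),
         genome_unit = "kb", volume_kind = "inner",
         source = "literature"),
    class = "allofit")
}
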