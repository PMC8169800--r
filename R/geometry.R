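# Capsid geometry: shape-specific volumes, wall thickness, DNA volume and
# packing fraction. Icosahedral capsids are treated as spheres of the
# reported radius throughout (no triangulation-number geometry).

#' Outer capsid volume from reported dimensions
#'
#' Shape-specific volume formulas, all dimensions in nm:
#' \describe{
#'   \item{icosahedral_spherical}{\eqn{V = \frac{4}{3}\pi R_c^3} with `dim1`
#'     the outer radius \eqn{R_c}.}
#'   \item{ovoid}{\eqn{V = \frac{4}{3}\pi a^2 c} with `dim1` the equatorial
#'     radius \eqn{a} and `dim2` the centre-to-pole distance \eqn{c}.}
#'   \item{rod_filamentous}{\eqn{V = \pi R_c^2 l} with `dim1` the radius and
#'     `dim2` the length.}
#'   \item{brick}{\eqn{V = h d l}, the three edge lengths.}
#' }
#'
#' @param shape Character vector of capsid shapes (recycled against dims).
#' @param dim1,dim2,dim3 Shape-dependent dimensions in nm.
#' @return Volume(s) in nm^3.
#' @examples
#' capsid_volume("icosahedral_spherical", 30)
#' capsid_volume("brick", 2, 2, 2)
#' @export
capsid_volume <- function(shape, dim1, dim2 = NA_real_, dim3 = NA_real_) {
  n <- max(length(shape), length(dim1), length(dim2), length(dim3))
  shape <- rep_len(shape, n); dim1 <- rep_len(dim1, n)
  dim2 <- rep_len(dim2, n);   dim3 <- rep_len(dim3, n)
  bad <- !shape %in% .capsid_shapes
  if (any(bad))
    stop("unknown capsid shape: ", paste(unique(shape[bad]), collapse = ", "),
         call. = FALSE)
  need <- c(icosahedral_spherical = 1L, ovoid = 2L, rod_filamentous = 2L,
            brick = 3L)[shape]
  dims <- cbind(dim1, dim2, dim3)
  for (i in seq_len(n)) {
    d <- dims[i, seq_len(need[i])]
    if (anyNA(d))
      stop("shape '", shape[i], "' requires ", need[i],
           " dimension(s); got fewer", call. = FALSE)
    if (any(d <= 0))
      stop("non-positive capsid dimension", call. = FALSE)
  }
  out <- numeric(n)
  sph <- shape == "icosahedral_spherical"
  out[sph] <- 4 / 3 * pi * dim1[sph]^3
  ov <- shape == "ovoid"
  out[ov] <- 4 / 3 * pi * dim1[ov]^2 * dim2[ov]
  rod <- shape == "rod_filamentous"
  out[rod] <- pi * dim1[rod]^2 * dim2[rod]
  br <- shape == "brick"
  out[br] <- dim1[br] * dim2[br] * dim3[br]
  out
}

#' Capsid wall thickness for a virus group
#'
#' A per-record override (multi-layered capsids such as the 70 nm Mimivirus
#' wall) takes precedence; otherwise 3 nm for phages and jumbo phages, and
#' 10 nm for NCLDVs, whose capsid includes a single internal lipid bilayer.
#'
#' @param group_tag Character vector of group tags (`"phage"`,
#'   `"jumbo_phage"`, `"NCLDV"`), or `NA` when an override is supplied.
#' @param override Optional per-record thickness in nm (`NA` = no override).
#' @return Thickness in nm.
#' @examples
#' wall_thickness(c("phage", "NCLDV"))
#' wall_thickness("NCLDV", override = 70)
#' @export
wall_thickness <- function(group_tag, override = NA_real_) {
  n <- max(length(group_tag), length(override))
  group_tag <- rep_len(group_tag, n)
  override <- rep_len(as.numeric(override), n)
  out <- unname(.thickness_nm[group_tag])
  out[!is.na(override)] <- override[!is.na(override)]
  if (anyNA(out))
    stop("wall thickness undefined: record has neither a known group tag ",
         "(phage, jumbo_phage, NCLDV) nor a thickness override", call. = FALSE)
  if (any(out <= 0)) stop("wall thickness must be positive", call. = FALSE)
  out
}

#' Inner capsid radius
#'
#' The radius of the genome-accessible cavity: outer radius minus wall
#' thickness.
#'
#' @param outer_radius Outer radius \eqn{R_c} in nm.
#' @param thickness Wall thickness \eqn{t} in nm, `0 < t < outer_radius`.
#' @return Inner radius \eqn{r_c = R_c - t} in nm.
#' @export
inner_radius <- function(outer_radius, thickness) {
  if (any(thickness <= 0)) stop("thickness must be positive", call. = FALSE)
  if (any(thickness >= outer_radius))
    stop("thickness >= outer radius: degenerate capsid", call. = FALSE)
  outer_radius - thickness
}

#' Volume of a packaged dsDNA genome
#'
#' Models B-form DNA as a cylinder of radius 1 nm with an axial rise of
#' 0.34 nm per base pair, so \eqn{V_g = 0.34\,\pi\,L_g} — approximately
#' 1 nm^3 per bp.
#'
#' @param genome_length_bp Genome length in bp (> 0).
#' @return Genome volume in nm^3.
#' @examples
#' genome_volume(48500)
#' @export
genome_volume <- function(genome_length_bp) {
  if (any(!is.finite(genome_length_bp)) || any(genome_length_bp <= 0))
    stop("genome length must be positive", call. = FALSE)
  .bp_rise_nm * pi * genome_length_bp
}

# Rows for which a packing fraction is computable: dsDNA icosahedral with a
# resolvable wall thickness (known group tag or per-record override).
.packable_idx <- function(records) {
  which(records$genome_type == "dsDNA" &
          records$shape == "icosahedral_spherical" &
          (records$group_tag %in% names(.thickness_nm) |
             !is.na(records$thickness_nm)))
}

# Core packing computation on resolved numeric inputs.
.packing_core <- function(outer_radius, genome_length_bp, thickness) {
  r_in <- inner_radius(outer_radius, thickness)
  v_out <- 4 / 3 * pi * outer_radius^3
  v_in <- 4 / 3 * pi * r_in^3
  v_g <- genome_volume(genome_length_bp)
  frac <- v_g / v_in
  tibble::tibble(
    outer_volume_nm3 = v_out, inner_radius_nm = r_in,
    inner_volume_nm3 = v_in, genome_volume_nm3 = v_g,
    packing_fraction = frac, overpacked = frac > 1)
}

#' DNA packing fraction of dsDNA icosahedral capsids
#'
#' Ratio of genome volume to inner capsid volume, \eqn{V_g / V_c^{inner}},
#' defined only for dsDNA icosahedral/spherical virions: the inner radius is
#' the reported outer radius minus the wall thickness, the inner volume is
#' the sphere of that radius, and the genome volume follows the DNA cylinder
#' model of [genome_volume()]. A fraction above 1 flags the record as
#' over-packed.
#'
#' @param records A trait tibble whose rows are all dsDNA
#'   icosahedral/spherical; wall thickness is resolved per record via
#'   [wall_thickness()]. Rows of any other genome type or shape raise an
#'   error — packing density is not defined for them here.
#' @return A tibble with one row per record: `outer_volume_nm3`,
#'   `inner_radius_nm`, `inner_volume_nm3`, `genome_volume_nm3`,
#'   `packing_fraction`, `overpacked`.
#' @export
packing_fraction <- function(records) {
  if (nrow(records) == 0)
    return(.packing_core(numeric(0), numeric(0), numeric(0))[0, ])
  if (any(records$genome_type != "dsDNA") ||
      any(records$shape != "icosahedral_spherical"))
    stop("packing fraction is defined only for dsDNA icosahedral/spherical ",
         "records", call. = FALSE)
  t <- wall_thickness(records$group_tag, records$thickness_nm)
  .packing_core(records$dim1_nm, records$genome_length_bp, t)
}

#' Append derived geometry columns to a trait table
#'
#' Computes the outer capsid volume for every record and, for the dsDNA
#' icosahedral/spherical records with a resolvable wall thickness, the
#' inner radius/volume, genome volume, packing fraction and over-packed
#' flag; other records carry `NA` in the packing columns.
#'
#' @param records A trait tibble.
#' @return `records` with columns `outer_volume_nm3`, `inner_radius_nm`,
#'   `inner_volume_nm3`, `genome_volume_nm3`, `packing_fraction`,
#'   `overpacked` appended.
#' @export
add_derived_columns <- function(records) {
  n <- nrow(records)
  records$outer_volume_nm3 <- if (n) capsid_volume(
    records$shape, records$dim1_nm, records$dim2_nm, records$dim3_nm
  ) else numeric(0)
  pack_cols <- c("inner_radius_nm", "inner_volume_nm3", "genome_volume_nm3",
                 "packing_fraction")
  for (cn in pack_cols) records[[cn]] <- rep(NA_real_, n)
  records$overpacked <- rep(NA, n)
  idx <- .packable_idx(records)
  if (length(idx) > 0) {
    p <- packing_fraction(records[idx, , drop = FALSE])
    for (cn in c(pack_cols, "overpacked")) records[[cn]][idx] <- p[[cn]]
  }
  records
}
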