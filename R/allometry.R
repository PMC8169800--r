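# Allometric power-law fitting: Vc = a * Lg^m becomes the linear model
# log10(Vc) = A + m * log10(Lg), fit by ordinary least squares. All logs are
# base 10. The default unit convention is genome length in kb and volume in
# nm^3; every fit records the convention it was made under.

#' Fit the allometric power law on log-log axes
#'
#' Ordinary least squares of \eqn{\log_{10} V_c} on \eqn{\log_{10} L_g},
#' i.e. the power law \eqn{V_c = a L_g^m} linearised as
#' \eqn{Y = m X + A} with \eqn{A = \log_{10} a}. The slope p-value is the
#' two-sided t-test of slope = 0 on n - 2 degrees of freedom. Plain OLS: no
#' weighting, no robust loss, no errors-in-variables.
#'
#' @param genome_length Predictor values (> 0), in `genome_unit`.
#' @param capsid_volume Response values (> 0), nm^3.
#' @param genome_unit Unit label recorded in the fit (`"kb"` or `"bp"`);
#'   the intercept `A` is specific to this choice.
#' @param volume_kind Optional label (`"outer"` or `"inner"`) recording which
#'   capsid volume the fit used.
#' @return An object of class `allofit`: list with elements `m` (slope),
#'   `A` (intercept), `a = 10^A`, `r_squared`, `p_value`, `n`, `se_m`,
#'   `ci_m` (95\% interval for the slope), `genome_unit`, `volume_kind`.
#' @examples
#' lg <- c(10, 50, 100, 480)
#' fit <- loglog_fit(lg, 10^3.49 * lg^0.95)
#' fit$m
#' @export
loglog_fit <- function(genome_length, capsid_volume,
                       genome_unit = "kb", volume_kind = NULL) {
  if (length(genome_length) != length(capsid_volume))
    stop("genome_length and capsid_volume lengths differ", call. = FALSE)
  keep <- is.finite(genome_length) & is.finite(capsid_volume)
  genome_length <- genome_length[keep]
  capsid_volume <- capsid_volume[keep]
  if (length(genome_length) < 3)
    stop("at least 3 points are required to fit the power law",
         call. = FALSE)
  if (any(genome_length <= 0) || any(capsid_volume <= 0))
    stop("log-log fit requires strictly positive values", call. = FALSE)
  x <- log10(genome_length)
  y <- log10(capsid_volume)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  m <- unname(coef(fit)[2])
  A <- unname(coef(fit)[1])
  se_m <- sm$coefficients[2, "Std. Error"]
  p <- sm$coefficients[2, "Pr(>|t|)"]
  ci <- unname(confint(fit, "x", level = 0.95)[1, ])
  structure(
    list(m = m, A = A, a = 10^A, r_squared = sm$r.squared,
         p_value = p, n = length(x), se_m = se_m, ci_m = ci,
         genome_unit = genome_unit,
         volume_kind = if (is.null(volume_kind)) NA_character_ else volume_kind,
         source = "ols"),
    class = "allofit")
}

#' @export
print.allofit <- function(x, ...) {
  kind <- if (is.na(x$volume_kind)) "" else paste0(" (", x$volume_kind, " volume)")
  cat("Allometric power-law fit Vc = a * Lg^m", kind, "\n", sep = "")
  cat(sprintf("  m  = %.4f  (se %.4f, 95%% CI [%.4f, %.4f])\n",
              x$m, x$se_m, x$ci_m[1], x$ci_m[2]))
  cat(sprintf("  A  = %.4f  (a = 10^A = %.4g; Lg in %s, Vc in nm^3)\n",
              x$A, x$a, x$genome_unit))
  if (!is.na(x$r_squared))
    cat(sprintf("  R^2 = %.3f, p = %.3g, n = %d\n",
                x$r_squared, x$p_value, x$n))
  invisible(x)
}

# Volume column used by the group-fit interface. Inner volume is defined
# only for icosahedral records with a resolvable wall thickness.
.fit_volumes <- function(records, volume) {
  if (volume == "outer") {
    v <- capsid_volume(records$shape, records$dim1_nm, records$dim2_nm,
                       records$dim3_nm)
    return(list(volume = v, usable = rep(TRUE, nrow(records))))
  }
  usable <- records$shape == "icosahedral_spherical" &
    (records$group_tag %in% names(.thickness_nm) |
       !is.na(records$thickness_nm))
  v <- rep(NA_real_, nrow(records))
  if (any(usable)) {
    t <- wall_thickness(records$group_tag[usable],
                        records$thickness_nm[usable])
    r_in <- inner_radius(records$dim1_nm[usable], t)
    v[usable] <- 4 / 3 * pi * r_in^3
  }
  list(volume = v, usable = usable)
}

#' Group-wise allometric fits
#'
#' Splits a curated trait table by a grouping column and fits the power law
#' within each group. Groups with fewer than `min_n` usable records are
#' reported as skipped (in `attr(, "skipped")`), never silently dropped.
#'
#' @param records A curated trait tibble.
#' @param group_by Grouping column: one of `"host_group"`, `"genome_type"`,
#'   `"group_tag"`, `"enveloped"`, `"shape"`.
#' @param volume `"outer"` (reported dimensions, any shape) or `"inner"`
#'   (wall-thickness-corrected sphere; icosahedral records only).
#' @param genome_unit `"kb"` (default) or `"bp"` for the fit's x axis.
#' @param min_n Minimum usable records per group (default 3).
#' @return Named list of `allofit` objects, one per fitted group;
#'   `attr(, "skipped")` is a tibble naming groups below the threshold.
#' @export
fit_by_group <- function(records,
                         group_by = c("group_tag", "host_group",
                                      "genome_type", "enveloped", "shape"),
                         volume = c("inner", "outer"),
                         genome_unit = "kb", min_n = 3) {
  group_by <- match.arg(group_by)
  volume <- match.arg(volume)
  if (!group_by %in% names(records))
    stop("unknown grouping column: ", group_by, call. = FALSE)
  vols <- .fit_volumes(records, volume)
  lg <- records$genome_length_bp
  if (genome_unit == "kb") lg <- lg / 1000
  g <- as.character(records[[group_by]])
  g[is.na(g)] <- "<untagged>"
  fits <- list()
  skipped <- list()
  for (grp in unique(g)) {
    sel <- g == grp & vols$usable & is.finite(vols$volume)
    if (sum(sel) < min_n) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(group = grp, n_usable = sum(sel),
                       reason = sprintf("fewer than %d usable records", min_n))
      next
    }
    fits[[grp]] <- loglog_fit(lg[sel], vols$volume[sel],
                              genome_unit = genome_unit,
                              volume_kind = volume)
  }
  attr(fits, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(group = character(), n_usable = integer(),
                   reason = character())
  fits
}

#' Predict capsid volume from genome length
#'
#' Evaluates the fitted power law \eqn{V_c = a L_g^m =
#' 10^{A + m \log_{10} L_g}}.
#'
#' @param fit An `allofit` object.
#' @param genome_length Genome length(s) in the fit's genome unit (> 0).
#' @return Predicted capsid volume(s) in nm^3.
#' @export
predict_volume <- function(fit, genome_length) {
  stopifnot(inherits(fit, "allofit"))
  if (any(genome_length <= 0))
    stop("genome length must be positive", call. = FALSE)
  10^(fit$A + fit$m * log10(genome_length))
}

#' Genome length implied by a capsid radius
#'
#' Inverts the fitted power law through the sphere volume
#' \eqn{V_c = \frac{4}{3}\pi r_c^3 = a L_g^m}, giving
#' \eqn{L_g = \left(\frac{4\pi}{3a}\right)^{1/m} r_c^{3/m}}. For NCLDVs
#' (m = 2) this is the \eqn{L_g \sim r_c^{3/2}} relation underlying their
#' replication-cost scaling.
#'
#' @param rc Inner capsid radius (nm), > 0.
#' @param fit An `allofit` object with `a > 0`, `m > 0` (typically an
#'   inner-volume fit).
#' @return Genome length in the fit's genome unit.
#' @examples
#' genome_length_from_radius(100, reference_fit("ncldv"))  # ~418 kb
#' @export
genome_length_from_radius <- function(rc, fit) {
  stopifnot(inherits(fit, "allofit"))
  if (!is.finite(fit$a) || fit$a <= 0 || !is.finite(fit$m) || fit$m <= 0)
    stop("fit must have positive coefficient a and exponent m", call. = FALSE)
  if (any(rc <= 0)) stop("radius must be positive", call. = FALSE)
  ((4 * pi / 3) / fit$a)^(1 / fit$m) * rc^(3 / fit$m)
}

#' Tabulate a list of group fits
#'
#' @param fits Result of [fit_by_group()].
#' @return A tibble with one row per fitted group.
#' @export
fits_to_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble::tibble(group = nm, n = f$n, m = f$m, A = f$A, a = f$a,
                   se_m = f$se_m, ci_m_low = f$ci_m[1], ci_m_high = f$ci_m[2],
                   r_squared = f$r_squared, p_value = f$p_value,
                   genome_unit = f$genome_unit, volume_kind = f$volume_kind)
  })
  dplyr::bind_rows(rows)
}

#' Log-log scatter of capsid volume against genome length
#'
#' A diagnostic plot in the style of the classic allometry panels: points on
#' log10-log10 axes with the fitted regression line(s).
#'
#' @param records A trait tibble.
#' @param fits Optional list of `allofit` objects (named by group) whose
#'   lines are drawn.
#' @param volume `"outer"` or `"inner"` (must match the fits).
#' @param group_by Column used to colour points.
#' @param genome_unit `"kb"` or `"bp"` x axis.
#' @return A ggplot object.
#' @export
plot_loglog <- function(records, fits = NULL, volume = c("inner", "outer"),
                        group_by = "group_tag", genome_unit = "kb") {
  volume <- match.arg(volume)
  vols <- .fit_volumes(records, volume)
  lg <- records$genome_length_bp
  if (genome_unit == "kb") lg <- lg / 1000
  df <- tibble::tibble(lg = lg, vc = vols$volume,
                       group = as.character(records[[group_by]]))
  df <- df[vols$usable & is.finite(df$vc), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lg, y = .data$vc,
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("genome length (%s)", genome_unit),
                  y = expression("capsid volume" ~ (nm^3)),
                  colour = group_by)
  if (!is.null(fits)) {
    for (nm in names(fits)) {
      f <- fits[[nm]]
      rng <- range(df$lg[df$group == nm], na.rm = TRUE)
      line <- tibble::tibble(
        lg = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 50))
      line$vc <- predict_volume(f, line$lg)
      line$group <- nm
      p <- p + ggplot2::geom_line(data = line)
    }
  }
  p
}
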