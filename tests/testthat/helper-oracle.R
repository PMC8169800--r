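# Closed-form simple-OLS oracle from sums of squares, independent of lm():
# slope/intercept from the normal equations, textbook R^2 and the two-sided
# slope t-test on n - 2 df.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  m <- sxy / sxx
  A <- mean(y) - m * mean(x)
  resid <- y - (A + m * x)
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  se_m <- sqrt(sse / (n - 2) / sxx)
  tstat <- m / se_m
  list(m = m, A = A, r_squared = 1 - sse / sst,
       se_m = se_m, p_value = 2 * pt(-abs(tstat), df = n - 2))
}

# One canonical dsDNA icosahedral record, fields overridable.
make_record <- function(name = "v1", outer_radius = 30, lg = 48500,
                        group_tag = "phage", host_group = "bacteria",
                        genome_type = "dsDNA",
                        shape = "icosahedral_spherical",
                        thickness = NA_real_) {
  tibble::tibble(name = name, host_group = host_group,
                 genome_type = genome_type, genome_length_bp = lg,
                 shape = shape, dim1_nm = outer_radius,
                 dim2_nm = NA_real_, dim3_nm = NA_real_, enveloped = FALSE,
                 thickness_nm = thickness, n_genes = NA_integer_,
                 group_tag = group_tag)
}

# Outer radius that gives a dsDNA icosahedral record the requested packing
# fraction, given genome length and wall thickness.
radius_for_fraction <- function(lg, fraction, thickness = 3) {
  r_in <- (3 * 0.34 * pi * lg / (4 * pi * fraction))^(1 / 3)
  r_in + thickness
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
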