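# Seeded synthetic virus populations with the statistical structure the
# allometric analysis assumes: log-uniform genome lengths, log-normal
# capsid volumes around the group's power law, and optional injected
# pathologies (duplicates, range-valued dimensions, over-packed rows) to
# exercise the curation rules.

#' Configuration for a synthetic virus population
#'
#' Defaults are the group-level study conditions: phages m = 0.95,
#' A = 3.49, genome lengths 10-500 kb (up to the ~500 kb G-phage extreme);
#' NCLDVs m = 2.00, A = 1.38, genome lengths 100-2500 kb (up to the 2.5 Mb
#' Pandoravirus extreme). Noise is Gaussian on log10 inner volume with
#' sd 0.3, which reproduces the observed scatter (R^2 ~ 0.7) at the phage
#' geometry. `"mixed"` concatenates a phage and an NCLDV population of
#' n/2 records each at their group defaults.
#'
#' @param group `"phage"`, `"ncldv"` or `"mixed"`.
#' @param n Number of records (>= 0).
#' @param m,A Power-law exponent and log10 intercept (genome in kb, volume
#'   in nm^3); group defaults when `NULL`. Not settable for `"mixed"`.
#' @param sigma Gaussian noise sd on log10 volume (>= 0).
#' @param lg_range_kb Genome-length range in kb, `c(min, max)`, positive
#'   and ordered; group default when `NULL`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(group = c("phage", "ncldv", "mixed"), n = 100,
                             m = NULL, A = NULL, sigma = 0.3,
                             lg_range_kb = NULL, seed = 1L) {
  group <- match.arg(group)
  def <- switch(group,
                phage = allometry_defaults()$synthetic_phage,
                ncldv = allometry_defaults()$synthetic_ncldv,
                mixed = NULL)
  if (group == "mixed" && (!is.null(m) || !is.null(A) || !is.null(lg_range_kb)))
    stop("custom m/A/lg_range_kb apply to single-group configs only",
         call. = FALSE)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!is.null(lg_range_kb)) {
    if (length(lg_range_kb) != 2 || any(lg_range_kb <= 0) ||
        lg_range_kb[1] > lg_range_kb[2])
      stop("lg_range_kb must be positive and ordered c(min, max)",
           call. = FALSE)
  }
  structure(
    list(group = group, n = as.integer(n),
         m = if (is.null(m)) def$m else m,
         A = if (is.null(A)) def$A else A,
         sigma = sigma,
         lg_range_kb = if (is.null(lg_range_kb)) def$lg_range_kb else lg_range_kb,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

.sim_one_group <- function(group, n, m, A, sigma, lg_range_kb, name_prefix) {
  tag <- if (group == "phage") "phage" else "NCLDV"
  host <- if (group == "phage") "bacteria" else "protozoa_algae"
  t <- unname(.thickness_nm[tag])
  lg_kb <- 10^runif(n, log10(lg_range_kb[1]), log10(lg_range_kb[2]))
  log10_v_true <- A + m * log10(lg_kb)
  log10_v <- log10_v_true + rnorm(n, 0, sigma)
  r_in <- (3 * 10^log10_v / (4 * pi))^(1 / 3)
  bad <- !is.finite(r_in) | r_in <= 0
  if (any(bad))
    stop("generation failed for record ", which(bad)[1],
         ": non-physical inner radius after back-solve", call. = FALSE)
  name <- sprintf("%s_%04d", name_prefix, seq_len(n))
  records <- tibble::tibble(
    name = name, host_group = host, genome_type = "dsDNA",
    genome_length_bp = round(lg_kb * 1000),
    shape = "icosahedral_spherical",
    dim1_nm = r_in + t, dim2_nm = NA_real_, dim3_nm = NA_real_,
    enveloped = FALSE, thickness_nm = NA_real_, n_genes = NA_integer_,
    group_tag = tag)
  truth <- tibble::tibble(
    name = name, lg_kb = lg_kb, log10_v_true = log10_v_true,
    log10_v = log10_v, inner_radius_nm = r_in, thickness_nm = t)
  list(records = records, truth = truth)
}

#' Generate a synthetic virus population
#'
#' Genome lengths are drawn log-uniformly over the configured range;
#' log10 inner capsid volume is `A + m * log10(Lg_kb)` plus Gaussian noise;
#' records are back-solved to outer radii through the group's wall
#' thickness (3 nm phage, 10 nm NCLDV). Identical configs (including seed)
#' give identical output.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_population`: `records` (canonical
#'   trait tibble), `truth` (per-record noiseless volumes, for recovery
#'   scoring) and `config`.
#' @examples
#' sim <- simulate_viruses(synthetic_config("phage", n = 20, seed = 42))
#' loglog_fit(sim$truth$lg_kb, 10^sim$truth$log10_v)
#' @export
simulate_viruses <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  if (config$n == 0) {
    empty <- .sim_one_group("phage", 0, 0.95, 3.49, 0, c(10, 500), "syn")
    return(structure(list(records = empty$records, truth = empty$truth,
                          config = config), class = "synthetic_population"))
  }
  if (config$group == "mixed") {
    n_ph <- config$n %/% 2
    n_nc <- config$n - n_ph
    dp <- allometry_defaults()$synthetic_phage
    dn <- allometry_defaults()$synthetic_ncldv
    ph <- .sim_one_group("phage", n_ph, dp$m, dp$A, config$sigma,
                         dp$lg_range_kb, "syn_phage")
    nc <- .sim_one_group("ncldv", n_nc, dn$m, dn$A, config$sigma,
                         dn$lg_range_kb, "syn_ncldv")
    out <- list(records = dplyr::bind_rows(ph$records, nc$records),
                truth = dplyr::bind_rows(ph$truth, nc$truth),
                config = config)
  } else {
    g <- .sim_one_group(config$group, config$n, config$m, config$A,
                        config$sigma, config$lg_range_kb,
                        paste0("syn_", config$group))
    out <- list(records = g$records, truth = g$truth, config = config)
  }
  structure(out, class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("Synthetic virus population: %d %s record(s), seed %d\n",
              nrow(x$records), x$config$group, x$config$seed))
  cat(sprintf("  m = %.3f, A = %.3f, sigma = %.3f, Lg %g-%g kb\n",
              x$config$m %||% NA, x$config$A %||% NA, x$config$sigma,
              x$config$lg_range_kb[1] %||% NA, x$config$lg_range_kb[2] %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject curation pathologies into a trait table
#'
#' Adds, in this order: exact duplicate rows (same capsid and genome size,
#' renamed), range-valued `dim1_nm` entries whose midpoint equals the
#' original value, and over-packed rewrites (the outer radius of a dsDNA
#' icosahedral record is shrunk until its packing fraction exceeds 1). The
#' three target sets are disjoint, so curation removes/resolves exactly the
#' injected numbers. Dimension columns are returned as character so the
#' result round-trips through [write_trait_table()] /
#' [read_trait_table()].
#'
#' @param records A canonical trait tibble (e.g. from
#'   [simulate_viruses()]).
#' @param duplicates,ranges,overpacked Counts of each pathology to inject.
#' @param range_frac Half-width of injected ranges, as a fraction of the
#'   original value.
#' @return The contaminated tibble (character dimension columns);
#'   `attr(, "injected")` records the counts.
#' @export
inject_contamination <- function(records, duplicates = 0, ranges = 0,
                                 overpacked = 0, range_frac = 0.1) {
  n <- nrow(records)
  if (duplicates > n)
    stop("cannot duplicate more records than exist", call. = FALSE)
  packable <- .packable_idx(records)
  if (overpacked > length(packable))
    stop("not enough dsDNA icosahedral records to over-pack", call. = FALSE)
  if (ranges + overpacked > n)
    stop("contamination spec exceeds record count", call. = FALSE)

  out <- records
  # over-packed targets first (need packable rows), then ranges on others
  over_idx <- utils::head(packable, overpacked)
  range_idx <- utils::head(setdiff(seq_len(n), over_idx), ranges)
  if (overpacked > 0) {
    t <- wall_thickness(out$group_tag[over_idx], out$thickness_nm[over_idx])
    r_needed <- (3 * genome_volume(out$genome_length_bp[over_idx]) /
                   (4 * pi))^(1 / 3)
    out$dim1_nm[over_idx] <- 0.8 * r_needed + t
  }
  dim1 <- as.character(out$dim1_nm)
  if (ranges > 0) {
    v <- out$dim1_nm[range_idx]
    dim1[range_idx] <- sprintf("%.6g-%.6g",
                               v * (1 - range_frac), v * (1 + range_frac))
  }
  out$dim1_nm <- dim1
  out$dim2_nm <- as.character(out$dim2_nm)
  out$dim3_nm <- as.character(out$dim3_nm)
  if (duplicates > 0) {
    dup <- out[seq_len(duplicates), , drop = FALSE]
    dup$name <- paste0(dup$name, "_dup")
    out <- dplyr::bind_rows(out, dup)
  }
  attr(out, "injected") <- list(duplicates = duplicates, ranges = ranges,
                                overpacked = overpacked)
  out
}
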