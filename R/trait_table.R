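# Trait-table ingest and curation.
#
# Canonical schema (header names; order immaterial):
#   name, host_group, genome_type, genome_length_bp, shape,
#   dim1_nm, dim2_nm, dim3_nm, enveloped, thickness_nm, n_genes, group_tag
# dim columns may hold "low-high" ranges; genome_length_bp may hold
# ";"-separated segment lists; a genome_length_kb column is accepted and
# converted to bp at ingest. All stored lengths are nm, genomes bp.

.mandatory_cols <- c("name", "host_group", "genome_type", "shape",
                     "dim1_nm", "enveloped")
.optional_cols <- c("dim2_nm", "dim3_nm", "thickness_nm", "n_genes",
                    "group_tag")

#' Midpoint of a reported size range
#'
#' Capsid dimensions reported as a range are resolved to the average of the
#' highest and lowest value.
#'
#' @param low,high Range endpoints in nm, `0 < low <= high`. Vectorized.
#' @return `(low + high) / 2`.
#' @examples
#' midpoint_of_range(40, 60)  # 50
#' @export
midpoint_of_range <- function(low, high) {
  if (any(!is.finite(low)) || any(!is.finite(high)) || any(low <= 0))
    stop("range endpoints must be positive finite numbers", call. = FALSE)
  if (any(low > high))
    stop("range low endpoint exceeds high endpoint", call. = FALSE)
  (low + high) / 2
}

#' Total length of a segmented genome
#'
#' For segmented genomes the total size of all segments is used.
#'
#' @param segment_lengths Non-empty numeric vector of positive segment
#'   lengths (bp).
#' @return The sum of the segment lengths.
#' @examples
#' sum_segments(c(3000, 4000, 5000))  # 12000
#' @export
sum_segments <- function(segment_lengths) {
  if (length(segment_lengths) == 0)
    stop("empty segment list", call. = FALSE)
  if (any(!is.finite(segment_lengths)) || any(segment_lengths <= 0))
    stop("segment lengths must be positive", call. = FALSE)
  sum(segment_lengths)
}

# Parse one cell that may be a plain number or a "low-high" range.
# Returns NA (not an error) for unparseable input; callers report the row.
.parse_dim_cell <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "" || toupper(x) == "NA") return(NA_real_)
  # en-dash tolerated; a leading minus sign is not expected in sizes
  x <- gsub("–", "-", x)
  if (grepl("-", x, fixed = TRUE)) {
    parts <- suppressWarnings(as.numeric(strsplit(x, "-", fixed = TRUE)[[1]]))
    if (length(parts) != 2 || anyNA(parts)) return(NA_real_)
    return(midpoint_of_range(parts[1], parts[2]))
  }
  suppressWarnings(as.numeric(x))
}

# Parse a genome-length cell: plain number or ";"-separated segments.
.parse_genome_cell <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "") return(NA_real_)
  parts <- suppressWarnings(as.numeric(trimws(strsplit(x, ";", fixed = TRUE)[[1]])))
  if (length(parts) == 0 || anyNA(parts) || any(parts <= 0)) return(NA_real_)
  sum_segments(parts)
}

.parse_logical_cell <- function(x) {
  x <- toupper(trimws(x))
  if (x %in% c("TRUE", "T", "1", "YES")) return(TRUE)
  if (x %in% c("FALSE", "F", "0", "NO")) return(FALSE)
  NA
}

#' Read and validate a virus trait table
#'
#' Reads a CSV/TSV trait table, resolves `low-high` dimension ranges to their
#' midpoints, sums `;`-separated genome segments, converts `genome_length_kb`
#' to bp when that column is used, and validates every row against the
#' controlled vocabularies. Rows failing validation are rejected with
#' row-level diagnostics (kept in `attr(, "rejects")` and reported via a
#' warning); a missing mandatory column is a format error.
#'
#' @param path Path to the table.
#' @param dialect `"auto"` (by file extension), `"csv"` or `"tsv"`.
#' @return A tibble with numeric dimension/genome columns, one row per
#'   accepted record. Rejected rows are described in `attr(, "rejects")`.
#' @seealso [write_trait_table()], [deduplicate()], [filter_overpacked()]
#' @export
read_trait_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "tsv" else "csv"
  raw <- if (dialect == "tsv") {
    read.delim(path, colClasses = "character", check.names = FALSE,
               na.strings = c("NA", ""))
  } else {
    read.csv(path, colClasses = "character", check.names = FALSE,
             na.strings = c("NA", ""))
  }
  genome_col <- intersect(c("genome_length_bp", "genome_length_kb"), names(raw))
  if (length(genome_col) == 0)
    stop("missing mandatory column: genome_length_bp", call. = FALSE)
  missing <- setdiff(.mandatory_cols, names(raw))
  if (length(missing) > 0)
    stop("missing mandatory column: ", paste(missing, collapse = ", "),
         call. = FALSE)
  genome_col <- genome_col[1]
  kb <- genome_col == "genome_length_kb"

  n <- nrow(raw)
  rejects <- list()
  reject <- function(row, reason) {
    rejects[[length(rejects) + 1]] <<- tibble::tibble(row = row, reason = reason)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- raw[i, , drop = FALSE]
    if (is.na(r$name) || !nzchar(trimws(r$name))) { reject(i, "missing name"); next }
    lg <- .parse_genome_cell(r[[genome_col]])
    if (is.na(lg)) { reject(i, "missing or non-numeric genome length"); next }
    if (kb) lg <- lg * 1000
    host <- trimws(r$host_group)
    if (!host %in% .host_groups) { reject(i, paste0("unknown host_group '", host, "'")); next }
    gtype <- trimws(r$genome_type)
    if (!gtype %in% .genome_types) { reject(i, paste0("unknown genome_type '", gtype, "'")); next }
    shape <- trimws(r$shape)
    if (!shape %in% .capsid_shapes) { reject(i, paste0("unknown shape '", shape, "'")); next }
    dims <- unname(vapply(c("dim1_nm", "dim2_nm", "dim3_nm"), function(cn) {
      if (!cn %in% names(r)) NA_real_ else .parse_dim_cell(r[[cn]])
    }, numeric(1)))
    if (is.na(dims[1]) && !is.na(r$dim1_nm)) { reject(i, paste0("non-numeric dimension in row ", i)); next }
    if (is.na(dims[1])) { reject(i, "missing dim1_nm"); next }
    need <- switch(shape, icosahedral_spherical = 1L, ovoid = 2L,
                   rod_filamentous = 2L, brick = 3L)
    if (sum(!is.na(dims)) < need) { reject(i, paste0("shape '", shape, "' needs ", need, " dimensions")); next }
    if (any(dims[seq_len(need)] <= 0, na.rm = TRUE)) { reject(i, "non-positive dimension"); next }
    env <- .parse_logical_cell(r$enveloped)
    if (is.na(env)) { reject(i, "enveloped flag not interpretable as logical"); next }
    thick <- if ("thickness_nm" %in% names(r)) .parse_dim_cell(r$thickness_nm) else NA_real_
    if (!is.na(thick) && thick >= dims[1]) { reject(i, "thickness_nm not below smallest radius"); next }
    tag <- if ("group_tag" %in% names(r) && !is.na(r$group_tag)) trimws(r$group_tag) else NA_character_
    if (!is.na(tag) && !tag %in% .group_tags) { reject(i, paste0("unknown group_tag '", tag, "'")); next }
    ngenes <- if ("n_genes" %in% names(r)) suppressWarnings(as.integer(r$n_genes)) else NA_integer_
    out[[i]] <- tibble::tibble(
      name = trimws(r$name), host_group = host, genome_type = gtype,
      genome_length_bp = lg, shape = shape,
      dim1_nm = dims[1], dim2_nm = dims[2], dim3_nm = dims[3],
      enveloped = env, thickness_nm = thick, n_genes = ngenes,
      group_tag = tag)
  }
  records <- dplyr::bind_rows(out)
  rejects <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble::tibble(row = integer(), reason = character())
  if (nrow(rejects) > 0)
    warning(nrow(rejects), " row(s) rejected; see attr(x, 'rejects')",
            call. = FALSE)
  attr(records, "rejects") <- rejects
  records
}

#' Write a trait table in the canonical CSV schema
#'
#' @param records A trait tibble (numeric or raw character dimensions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

.append_exclusions <- function(records, excl) {
  prev <- attr(records, "exclusions")
  if (is.null(prev))
    prev <- tibble::tibble(name = character(), rule = character(),
                           detail = character())
  attr(records, "exclusions") <- dplyr::bind_rows(prev, excl)
  records
}

#' Exclusion report of a curated table
#'
#' Every record dropped by [deduplicate()] or [filter_overpacked()] is listed
#' with the rule that removed it.
#'
#' @param records A curated trait tibble.
#' @return A tibble with columns `name`, `rule`, `detail`.
#' @export
exclusions <- function(records) {
  excl <- attr(records, "exclusions")
  if (is.null(excl))
    excl <- tibble::tibble(name = character(), rule = character(),
                           detail = character())
  excl
}

#' Remove statistically redundant records
#'
#' Viruses with the same capsid and genome sizes are represented only once:
#' among records with identical post-curation dimensions (shape plus all dim
#' columns) and genome length, only the first in input order is retained.
#' First-in-order retention is this package's tie-break; duplicates that
#' differ in name are flagged as such in the exclusion report.
#'
#' @param records A trait tibble.
#' @return The deduplicated tibble; removals appended to [exclusions()].
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(.append_exclusions(records, NULL))
  key <- paste(records$shape, records$dim1_nm, records$dim2_nm,
               records$dim3_nm, records$genome_length_bp, sep = "|")
  dup <- duplicated(key)
  removed <- records[dup, , drop = FALSE]
  excl <- if (nrow(removed)) {
    first_name <- records$name[match(key[dup], key)]
    tibble::tibble(
      name = removed$name, rule = "duplicate",
      detail = paste0("same capsid and genome size as '", first_name,
                      "' (first occurrence retained)"))
  } else NULL
  out <- records[!dup, , drop = FALSE]
  attr(out, "exclusions") <- attr(records, "exclusions")
  .append_exclusions(out, excl)
}

#' Remove over-packed records
#'
#' dsDNA icosahedral records whose DNA packing fraction exceeds 1 are
#' physically impossible (the double helix cannot be compressed below its
#' crystallographic volume) and are attributed to capsid-measurement error;
#' they are removed. The cutoff is strict: a fraction of exactly 1 is
#' retained. Records outside the dsDNA icosahedral subgroup pass through
#' untouched.
#'
#' @param records A trait tibble.
#' @param packing Optional packing tibble from [packing_fraction()] computed
#'   on the dsDNA icosahedral subset of `records`; computed internally when
#'   omitted (records with no resolvable wall thickness are left untouched).
#' @return The filtered tibble; removals (with their fractions) appended to
#'   [exclusions()].
#' @export
filter_overpacked <- function(records, packing = NULL) {
  if (nrow(records) == 0) return(.append_exclusions(records, NULL))
  idx <- .packable_idx(records)
  if (is.null(packing) && length(idx) > 0)
    packing <- packing_fraction(records[idx, , drop = FALSE])
  drop <- logical(nrow(records))
  detail <- character(nrow(records))
  if (length(idx) > 0) {
    over <- packing$packing_fraction > 1
    drop[idx] <- over
    detail[idx] <- sprintf("packing fraction %.3f > 1", packing$packing_fraction)
  }
  removed <- records[drop, , drop = FALSE]
  excl <- if (nrow(removed)) {
    tibble::tibble(name = removed$name, rule = "overpacked",
                   detail = detail[drop])
  } else NULL
  out <- records[!drop, , drop = FALSE]
  attr(out, "exclusions") <- attr(records, "exclusions")
  .append_exclusions(out, excl)
}

#' Curate a trait table
#'
#' Applies the two curation rules in order: deduplication of records with
#' identical capsid and genome sizes, then removal of over-packed dsDNA
#' icosahedral records (packing fraction > 1).
#'
#' @param records A trait tibble from [read_trait_table()] or
#'   [simulate_viruses()].
#' @return The curated tibble with an [exclusions()] report attached.
#' @export
curate <- function(records) {
  filter_overpacked(deduplicate(records))
}

#' Write the exclusions report
#'
#' @param records A curated trait tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_exclusions <- function(records, path) {
  utils::write.table(as.data.frame(exclusions(records)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
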