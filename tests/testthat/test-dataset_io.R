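header <- paste("name,host_group,genome_type,genome_length_bp,shape",
                "dim1_nm,dim2_nm,dim3_nm,enveloped,thickness_nm,n_genes,group_tag",
                sep = ",")

test_that("a well-formed table reads back one record per row", {
  path <- write_temp_csv(c(
    header,
    "lambda,bacteria,dsDNA,48500,icosahedral_spherical,30,,,FALSE,,70,phage",
    "tmv,plant,ssRNA_pos,6400,rod_filamentous,9,300,,FALSE,,,",
    "vaccinia,vertebrate,dsDNA,195000,brick,360,270,250,TRUE,,,other"))
  rec <- read_trait_table(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$genome_length_bp, c(48500, 6400, 195000))
  expect_equal(rec$dim2_nm[2], 300)
  expect_true(rec$enveloped[3])
  expect_equal(nrow(attr(rec, "rejects")), 0)
})

test_that("segmented genomes are summed and size ranges resolved to midpoints", {
  path <- write_temp_csv(c(
    header,
    "phi6,bacteria,dsRNA,6374;4063;2948,icosahedral_spherical,40-60,,,TRUE,,,",
    "cpv,invertebrate,dsRNA,25000,icosahedral_spherical,155-165,,,FALSE,,,"))
  rec <- read_trait_table(path)
  expect_equal(rec$genome_length_bp[1], 6374 + 4063 + 2948)
  expect_equal(rec$dim1_nm, c(50, 160))
})

test_that("a genome_length_kb column is converted to bp at ingest", {
  path <- write_temp_csv(c(
    gsub("genome_length_bp", "genome_length_kb", header),
    "g_phage,bacteria,dsDNA,498,icosahedral_spherical,90,,,FALSE,,,jumbo_phage",
    "segmented,plant,ssRNA_neg,4.5;3.2,icosahedral_spherical,25,,,TRUE,,,"))
  rec <- read_trait_table(path)
  expect_equal(rec$genome_length_bp, c(498000, 7700))
})

test_that("a missing mandatory column is a format error naming the column", {
  path <- write_temp_csv(c(
    "name,host_group,genome_type,genome_length_bp,dim1_nm,enveloped",
    "x,bacteria,dsDNA,1000,30,FALSE"))
  expect_error(read_trait_table(path), "shape")
})

test_that("bad rows are rejected with row-level diagnostics, good rows kept", {
  path <- write_temp_csv(c(
    header,
    "ok,bacteria,dsDNA,48500,icosahedral_spherical,30,,,FALSE,,,phage",
    "bad_dim,bacteria,dsDNA,48500,icosahedral_spherical,thirty,,,FALSE,,,phage",
    "bad_host,martian,dsDNA,48500,icosahedral_spherical,30,,,FALSE,,,phage",
    "missing_len,bacteria,dsDNA,,icosahedral_spherical,30,,,FALSE,,,phage"))
  expect_warning(rec <- read_trait_table(path), "rejected")
  expect_equal(rec$name, "ok")
  rej <- attr(rec, "rejects")
  expect_equal(rej$row, c(2, 3, 4))
  expect_match(rej$reason[1], "dimension")
})

test_that("midpoint_of_range averages endpoints and rejects inverted ranges", {
  expect_equal(midpoint_of_range(40, 60), 50)
  expect_equal(midpoint_of_range(50, 50), 50)
  expect_equal(midpoint_of_range(155, 165), 160)
  expect_error(midpoint_of_range(60, 40), "exceeds")
  expect_error(midpoint_of_range(0, 10), "positive")
})

test_that("sum_segments totals positive segment lists", {
  expect_equal(sum_segments(c(3000, 4000, 5000)), 12000)
  expect_equal(sum_segments(48500), 48500)
  expect_equal(sum_segments(c(2300, 2300, 2200)), 6800)
  expect_error(sum_segments(numeric(0)), "empty")
  expect_error(sum_segments(c(100, -5)), "positive")
})

test_that("deduplicate keeps the first of identical capsid+genome records", {
  recs <- dplyr::bind_rows(
    make_record("a", outer_radius = 30, lg = 48500),
    make_record("b", outer_radius = 30, lg = 48500),
    make_record("c", outer_radius = 30, lg = 40000))
  out <- deduplicate(recs)
  expect_equal(out$name, c("a", "c"))
  excl <- exclusions(out)
  expect_equal(excl$name, "b")
  expect_equal(excl$rule, "duplicate")
  expect_match(excl$detail, "'a'")
  # differing genome length alone is not a duplicate
  expect_equal(nrow(out) + nrow(excl), nrow(recs))
})

test_that("deduplicate is idempotent and handles the empty table", {
  recs <- dplyr::bind_rows(make_record("a"), make_record("a2"),
                           make_record("b", lg = 9999))
  once <- deduplicate(recs)
  twice <- deduplicate(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))
  expect_equal(nrow(deduplicate(recs[0, ])), 0)
})

test_that("filter_overpacked removes only fractions strictly above 1", {
  recs <- dplyr::bind_rows(
    make_record("over", outer_radius = radius_for_fraction(48500, 1.2)),
    make_record("lambda", outer_radius = 30),      # fraction ~0.63
    make_record("rna", genome_type = "ssRNA_pos")) # passes through untouched
  out <- filter_overpacked(recs)
  expect_setequal(out$name, c("lambda", "rna"))
  excl <- exclusions(out)
  expect_equal(excl$name, "over")
  expect_equal(excl$rule, "overpacked")
  expect_match(excl$detail, "1\\.2")
  expect_equal(nrow(out) + nrow(excl), nrow(recs))
})

test_that("curation never removes a record with fraction <= 1", {
  for (frac in c(0.09, 0.47, 0.9999)) {
    rec <- make_record("x", outer_radius = radius_for_fraction(30000, frac),
                       lg = 30000)
    expect_equal(nrow(filter_overpacked(rec)), 1)
  }
})

test_that("the over-packed cutoff is strict: exactly 1 is retained", {
  rec <- make_record("boundary")
  pk <- packing_fraction(rec)
  pk$packing_fraction <- 1.0  # exact boundary, rule tested independently
  expect_equal(nrow(filter_overpacked(rec, packing = pk)), 1)
  pk$packing_fraction <- 1 + 1e-9
  expect_equal(nrow(filter_overpacked(rec, packing = pk)), 0)
})

test_that("write -> read round-trips numeric fields", {
  recs <- dplyr::bind_rows(
    make_record("a", outer_radius = 31.25, lg = 48502),
    make_record("o", shape = "ovoid", host_group = "archaea") |>
      dplyr::mutate(dim2_nm = 110.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(recs, path)
  back <- read_trait_table(path)
  expect_equal(back$dim1_nm, recs$dim1_nm)
  expect_equal(back$dim2_nm, recs$dim2_nm)
  expect_equal(back$genome_length_bp, recs$genome_length_bp)
  expect_equal(back$group_tag, recs$group_tag)
})
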