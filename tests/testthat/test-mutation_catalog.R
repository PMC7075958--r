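test_that("variant tokens parse across notations", {
  v <- parse_variant("L203P")
  expect_equal(v$position, 203L)
  expect_equal(v$ref_aa, "L")
  expect_equal(v$alt_aa, "P")
  expect_equal(v$variant_class, "missense")

  expect_equal(parse_variant("p.Leu203Pro")$variant_class, "missense")
  expect_equal(parse_variant("p.(Leu203Pro)")$position, 203L)
  expect_equal(parse_variant("p.Leu203Leu")$variant_class, "silent")
  expect_equal(parse_variant("L203L")$variant_class, "silent")

  d <- parse_variant("K552del")
  expect_equal(d$position, 552L)
  expect_equal(d$variant_class, "single_aa_deletion")
  expect_equal(parse_variant("p.Lys552del")$variant_class,
               "single_aa_deletion")

  expect_equal(parse_variant("R213*")$variant_class, "nonsense")
  expect_equal(parse_variant("p.Arg213Ter")$variant_class, "nonsense")

  expect_error(parse_variant("not-a-variant"), "unrecognized")
  expect_error(parse_variant("p.Xyz203Pro"), "unrecognized")
  expect_error(parse_variant(""), "empty")
})

test_that("parsing validates the reference residue against a sequence", {
  ps <- protein_sequence("MKVLRS")
  expect_equal(parse_variant("V3A", ps)$position, 3L)
  expect_error(parse_variant("A3V", ps), "sequence has V at position 3")
  expect_error(parse_variant("K9A", ps), "beyond sequence length")
})

test_that("parse and format are inverse on canonical tokens", {
  for (tok in c("L203P", "K552del", "R213*", "G45G")) {
    expect_identical(format_variant(parse_variant(tok)), tok)
  }
})

test_that("catalogs collapse duplicate substitutions and tally classes", {
  df <- data.frame(
    variant = c("A10V", "A10V", "A10G", "R20*", rep("L30P", 1)),
    class = c("missense", "missense", "missense", "nonsense", "missense"),
    severity = "severe_ee", stringsAsFactors = FALSE)
  cat1 <- variant_catalog(df)
  expect_equal(nrow(cat1$records), 4L)  # exact duplicate collapsed

  cc <- classify_counts(cat1)
  expect_equal(cc$by_class[["missense"]], 3L)
  expect_equal(cc$by_class[["nonsense"]], 1L)
  expect_equal(cc$total, 4L)

  empty <- variant_catalog(df[0, ])
  expect_true(all(classify_counts(empty)$by_class == 0L))

  expect_error(variant_catalog(data.frame(variant = "A1B", class = "weird",
                                          severity = "uncertain")),
               "unknown variant class")
})

test_that("hotspot-test input selection applies class, region and severity filters", {
  df <- data.frame(
    variant = c("A10V", "R20*", "A10G"),
    class = c("missense", "nonsense", "missense"),
    severity = "severe_ee", stringsAsFactors = FALSE)
  cat1 <- variant_catalog(df)
  S <- select_mhf_input(cat1, analysis_region(1, 100))
  expect_equal(S$size, 2L)
  expect_equal(S$positions, c(10L, 10L))

  # idempotent and order-independent
  S2 <- select_mhf_input(cat1, analysis_region(1, 100))
  expect_identical(S, S2)
  catr <- variant_catalog(df[c(3, 1, 2), ])
  Sr <- select_mhf_input(catr, analysis_region(1, 100))
  expect_equal(sort(Sr$positions), sort(S$positions))

  expect_warning(select_mhf_input(cat1, analysis_region(1, 100),
                                  severity_filter = "nonpathogenic"),
                 "empty")

  # region filter: position 10 outside 20..100
  S3 <- suppressWarnings(select_mhf_input(cat1, analysis_region(20, 100)))
  expect_equal(S3$size, 0L)
})

test_that("start-codon substitutions are excluded from the input set", {
  ps <- protein_sequence("MKVLRS")
  df <- data.frame(variant = c("M1V", "K2A"), class = "missense",
                   severity = "severe_ee", stringsAsFactors = FALSE)
  S <- select_mhf_input(variant_catalog(df, ps), analysis_region(1, 6))
  expect_equal(S$positions, 2L)
})

test_that("the worked-example catalog reproduces the published composition", {
  fx <- kv72()
  cc <- classify_counts(fx$catalog)
  expect_equal(cc$total, 194L)
  expect_equal(cc$by_class[["missense"]], 126L)
  expect_equal(cc$by_class[["frameshift"]], 25L)
  expect_equal(cc$by_class[["splice_site"]], 17L)
  expect_equal(cc$by_class[["nonsense"]], 10L)
  expect_equal(cc$by_class[["gene_deletion"]], 10L)
  expect_equal(cc$by_class[["non_initiation"]], 2L)
  expect_equal(cc$by_class[["single_aa_deletion"]], 4L)

  S <- select_mhf_input(fx$catalog, fx$region_full)
  expect_equal(S$size, 130L)

  # |S| is invariant under relabeling alt residues (class/position fixed)
  rec <- fx$catalog$records
  mis <- rec$variant_class == "missense" & !is.na(rec$position)
  rec$raw_label[mis] <- paste0(rec$ref_aa[mis], rec$position[mis], "X")
  expect_equal(sum(mis & rec$position > 1), 126L)
})

test_that("catalog files round-trip through the TSV reader", {
  fx <- kv72()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_catalog(fx$catalog, f)
  back <- read_variant_catalog(f, fx$sequence)
  expect_equal(nrow(back$records), nrow(fx$catalog$records))
  expect_identical(back$records$raw_label, fx$catalog$records$raw_label)
  expect_identical(back$records$severity, fx$catalog$records$severity)

  shipped <- read_variant_catalog(extdata("kv72_catalog_synthetic.tsv"))
  expect_equal(nrow(shipped$records), 194L)
})
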