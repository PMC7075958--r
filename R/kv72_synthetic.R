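# Synthetic Kv7.2-like worked example.
#
# The real compiled KCNQ2 variant table and the exact residue boundaries of
# its annotated domains live in an external supplement that is not
# redistributed here. This builder constructs a synthetic stand-in with the
# same published aggregate structure: an 872-residue sequence, a 14-domain
# full-length map and a 9-domain C-terminal map (S1-S6, pore loop, helices
# A-D and their linkers at literature-plausible coordinates), a 194-record
# epilepsy catalog (10 gene deletions, 17 splice-site, 10 nonsense, 25
# frameshift, 2 non-initiation, 126 missense, 4 single-residue deletions;
# 130 single amino acid mutations after filtering) whose positions cluster
# in S4, the pore loop and S6 (full-length) and in helix B and the helix
# B-C linker (C-terminal tail) with severe-EE enrichment, plus 130 silent
# and 25 nonpathogenic ExAC-style controls placed uniformly. Everything is
# deterministic; the shipped extdata files are this builder's output.

KV72_LENGTH <- 872L

kv72_full_domains <- function() {
  data.frame(
    name = c("S1", "S2", "S3", "S4", "S5", "pore_loop", "S6",
             "pre_helixA", "helixA", "helixA_B_linker", "helixB",
             "helixB_C_linker", "helixC", "helixD"),
    start = c(92L, 123L, 167L, 196L, 232L, 260L, 292L,
              313L, 322L, 358L, 535L, 558L, 589L, 639L),
    end = c(112L, 143L, 187L, 218L, 252L, 291L, 312L,
            321L, 357L, 534L, 557L, 588L, 620L, 672L),
    stringsAsFactors = FALSE
  )
}

kv72_ctail_domains <- function() {
  data.frame(
    name = c("pre_helixA", "helixA", "helixA_B_linker", "helixB",
             "helixB_C_linker", "helixC", "helixC_D_linker", "helixD",
             "distal_cterm"),
    start = c(313L, 322L, 358L, 535L, 558L, 589L, 621L, 639L, 673L),
    end = c(321L, 357L, 534L, 557L, 588L, 620L, 638L, 672L, 872L),
    stringsAsFactors = FALSE
  )
}

# per-interval missense placement plan: interval bounds, number of single-aa
# mutations, of which deletions, of which severe_ee
kv72_placement_plan <- function() {
  plan <- rbind(
    # name                 start  end    n  n_del  n_severe
    c("nterm",                5,   91,   4,  0,  1),
    c("S1",                  92,  112,   5,  0,  2),
    c("S1_S2",              113,  122,   1,  0,  0),
    c("S2",                 123,  143,   4,  0,  1),
    c("S2_S3",              144,  166,   2,  0,  1),
    c("S3",                 167,  187,   4,  0,  1),
    c("S3_S4",              188,  195,   1,  0,  0),
    c("S4",                 196,  218,  18,  0, 12),
    c("S4_S5",              219,  231,   1,  0,  0),
    c("S5",                 232,  252,   5,  0,  2),
    c("pore_loop",          260,  291,  20,  0, 14),
    c("S6",                 292,  312,  15,  0, 10),
    c("pre_helixA",         313,  321,   3,  0,  1),
    c("helixA",             322,  357,   7,  1,  2),
    c("helixA_B_linker",    358,  534,   7,  2,  2),
    c("helixB",             535,  557,   9,  0,  8),
    c("helixB_C_linker",    558,  588,  11,  0,  9),
    c("helixC",             589,  620,   4,  0,  1),
    c("helixC_D_linker",    621,  638,   1,  0,  0),
    c("helixD",             639,  672,   3,  0,  1),
    c("distal_cterm",       673,  872,   5,  1,  2)
  )
  data.frame(interval = plan[, 1],
             start = as.integer(plan[, 2]), end = as.integer(plan[, 3]),
             n = as.integer(plan[, 4]), n_del = as.integer(plan[, 5]),
             n_severe = as.integer(plan[, 6]), stringsAsFactors = FALSE)
}

#' Synthetic Kv7.2-like worked example
#'
#' Deterministically constructs the package's worked example: a synthetic
#' 872-residue channel sequence, 14-domain full-length and 9-domain
#' C-terminal domain maps, a 194-record epilepsy-style variant catalog with
#' designed hotspot clustering (S4, pore loop and S6 in the full-length
#' analysis; helix B and the helix B-C linker in the C-terminal tail, with
#' severe-EE enrichment), and uniformly placed silent / nonpathogenic
#' control catalogs. The fixture mirrors the published aggregate
#' composition of the KCNQ2 epilepsy variant compilation but is synthetic:
#' sequence and individual variant records are generated, not transcribed.
#'
#' @param seed Integer seed for the deterministic construction.
#' @return List with elements `sequence` ([protein_sequence()]),
#'   `region_full`, `map_full` (J = 14), `region_ctail` (residues 313-872),
#'   `map_ctail` (J = 9), `catalog` (194 records), `controls` (155 silent +
#'   nonpathogenic records) and `hotspots` (the designed hotspot names).
#' @examples
#' fx <- kv72_synthetic_fixture()
#' fx$map_full$J
#' @export
kv72_synthetic_fixture <- function(seed = 20260101L) {
  aas <- setdiff(AA_ALPHABET, "X")
  seq_chars <- with_seed(seed, sample(aas, KV72_LENGTH, replace = TRUE))
  seq_chars[1L] <- "M"
  sequence <- protein_sequence(paste(seq_chars, collapse = ""),
                               accession = "KV72_SYNTHETIC")
  region_full <- analysis_region(1L, KV72_LENGTH)
  fd <- kv72_full_domains()
  map_full <- domain_map(fd$name, fd$start, fd$end, region_full)
  region_ctail <- analysis_region(313L, KV72_LENGTH)
  cd <- kv72_ctail_domains()
  map_ctail <- domain_map(cd$name, cd$start, cd$end, region_ctail)

  plan <- kv72_placement_plan()
  mild_cycle <- c("mild_bfne", "uncertain")
  rows <- list()
  with_seed(seed + 1L, {
    alt_counter <- new.env(parent = emptyenv())
    next_alt <- function(pos, ref) {
      key <- as.character(pos)
      used <- if (is.null(alt_counter[[key]])) character() else
        alt_counter[[key]]
      alt <- setdiff(aas, c(ref, used))[1L]
      alt_counter[[key]] <- c(used, alt)
      alt
    }
    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      pos <- sort(sample(seq.int(p$start, p$end), p$n, replace = FALSE))
      sev <- c(rep("severe_ee", p$n_severe),
               rep_len(mild_cycle, p$n - p$n_severe))
      is_del <- seq_len(p$n) > (p$n - p$n_del)
      for (m in seq_len(p$n)) {
        ref <- seq_chars[pos[m]]
        if (is_del[m]) {
          rows[[length(rows) + 1L]] <- data.frame(
            variant = paste0(ref, pos[m], "del"),
            class = "single_aa_deletion", severity = sev[m],
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            variant = paste0(ref, pos[m], next_alt(pos[m], ref)),
            class = "missense", severity = sev[m],
            stringsAsFactors = FALSE)
        }
      }
    }
    # truncating / non-coding classes (no residue coordinates used by the
    # hotspot test)
    ns_pos <- sample(seq.int(20L, 860L), 10L)
    for (pp in ns_pos) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant = paste0(seq_chars[pp], pp, "*"), class = "nonsense",
        severity = "severe_ee", stringsAsFactors = FALSE)
    }
    for (i in seq_len(25L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant = sprintf("fs_%02d", i), class = "frameshift",
        severity = rep_len(c("severe_ee", "uncertain"), 25L)[i],
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(17L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant = sprintf("splice_%02d", i), class = "splice_site",
        severity = rep_len(c("uncertain", "severe_ee", "mild_bfne"), 17L)[i],
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(10L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant = sprintf("del_exons_%02d", i), class = "gene_deletion",
        severity = rep_len(c("severe_ee", "uncertain"), 10L)[i],
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variant = "M1V", class = "non_initiation", severity = "uncertain",
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = "M1T", class = "non_initiation", severity = "mild_bfne",
      stringsAsFactors = FALSE)
  })
  catalog <- variant_catalog(do.call(rbind, rows), sequence = sequence,
                             provenance = "synthetic_kv72_catalog")

  controls <- with_seed(seed + 2L, {
    sil_pos <- sample.int(KV72_LENGTH, 130L, replace = FALSE)
    np_pos <- sample.int(KV72_LENGTH - 1L, 25L, replace = FALSE) + 1L
    np_ref <- seq_chars[np_pos]
    np_alt <- vapply(np_ref, function(r) setdiff(aas, r)[1L], "")
    df <- rbind(
      data.frame(variant = paste0(seq_chars[sil_pos], sil_pos,
                                  seq_chars[sil_pos]),
                 class = "silent", severity = "silent_control",
                 allele_freq_pct = round(stats::runif(130L, 0.0017, 19), 4),
                 stringsAsFactors = FALSE),
      data.frame(variant = paste0(np_ref, np_pos, np_alt),
                 class = "missense", severity = "nonpathogenic",
                 allele_freq_pct = round(stats::runif(25L, 0.01, 5), 4),
                 stringsAsFactors = FALSE)
    )
    variant_catalog(df, sequence = sequence,
                    provenance = "synthetic_kv72_controls")
  })

  list(sequence = sequence, region_full = region_full, map_full = map_full,
       region_ctail = region_ctail, map_ctail = map_ctail,
       catalog = catalog, controls = controls,
       hotspots = c("S4", "pore_loop", "S6", "helixB", "helixB_C_linker"))
}

#' Write the synthetic worked example to files
#'
#' Materializes [kv72_synthetic_fixture()] as the plain-text files the
#' command-line interface consumes: a FASTA sequence, the two domain
#' tables, and the two variant catalogs.
#'
#' @param dir Output directory (created if missing).
#' @param seed Passed to [kv72_synthetic_fixture()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_kv72_synthetic_files <- function(dir, seed = 20260101L) {
  fx <- kv72_synthetic_fixture(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "kv72_synthetic.fasta")
  writeLines(c(paste0(">", fx$sequence$accession, " synthetic Kv7.2-like"),
               gsub("(.{60})", "\\1\n", fx$sequence$residues)), fasta)
  paths <- c(
    fasta = fasta,
    domains_full = file.path(dir, "kv72_domains_full_synthetic.tsv"),
    domains_ctail = file.path(dir, "kv72_domains_ctail_synthetic.tsv"),
    catalog = file.path(dir, "kv72_catalog_synthetic.tsv"),
    controls = file.path(dir, "kv72_controls_synthetic.tsv")
  )
  write_domain_map(fx$map_full, paths[["domains_full"]])
  write_domain_map(fx$map_ctail, paths[["domains_ctail"]])
  write_variant_catalog(fx$catalog, paths[["catalog"]])
  write_variant_catalog(fx$controls, paths[["controls"]])
  invisible(paths)
}
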