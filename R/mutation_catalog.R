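VARIANT_CLASSES <- c("missense", "single_aa_deletion", "nonsense",
                     "frameshift", "splice_site", "gene_deletion",
                     "non_initiation", "silent")

SEVERITY_LEVELS <- c("mild_bfne", "uncertain", "severe_ee", "nonpathogenic",
                     "silent_control")

# classes whose records carry a residue position / ref / alt
POSITIONAL_CLASSES <- c("missense", "single_aa_deletion", "nonsense", "silent")

AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
              Ter = "*")

residue_at <- function(sequence, position) {
  substr(sequence$residues, position, position)
}

#' Parse a protein variant token
#'
#' Recognizes the notations used for single amino acid variants:
#' one-letter shorthand (`L203P`, `R213*`, `K552del`, `L203L`) and
#' three-letter HGVS-p (`p.Leu203Pro`, `p.(Leu203Pro)`, `p.Lys552del`,
#' `p.Arg213Ter`). The variant class is inferred from the grammar:
#' substitution with ref != alt is `missense`, ref == alt is `silent`,
#' alt `*`/`Ter` is `nonsense`, a `del` suffix is `single_aa_deletion`.
#' When a reference sequence is supplied the stated reference residue is
#' validated against it.
#'
#' @param token Variant label, e.g. `"L203P"` or `"p.Leu203Pro"`.
#' @param sequence Optional [protein_sequence()] for reference validation.
#' @return A `variant_record`: list with `raw_label`, `position`, `ref_aa`,
#'   `alt_aa`, `variant_class`, `severity` (initially `NA`),
#'   `allele_frequency_pct` (initially `NA`).
#' @examples
#' parse_variant("L203P")
#' parse_variant("p.Lys552del")
#' @export
parse_variant <- function(token, sequence = NULL) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- trimws(token)
  if (!nzchar(tok)) stop("empty variant token", call. = FALSE)

  body <- sub("^p\\.", "", tok)
  body <- sub("^\\((.*)\\)$", "\\1", body)

  pos <- NA_integer_; ref <- NA_character_; alt <- NA_character_
  m1 <- regexec("^([A-Z])([0-9]+)([A-Z*])$", body)[[1L]]
  m1d <- regexec("^([A-Z])([0-9]+)del$", body)[[1L]]
  m3 <- regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", body)[[1L]]
  m3d <- regexec("^([A-Z][a-z]{2})([0-9]+)del$", body)[[1L]]

  grab <- function(m) {
    parts <- substring(body, m[-1L], m[-1L] + attr(m, "match.length")[-1L] - 1L)
    parts
  }
  if (m1[1L] != -1L) {
    p <- grab(m1); ref <- p[1L]; pos <- as.integer(p[2L]); alt <- p[3L]
  } else if (m1d[1L] != -1L) {
    p <- grab(m1d); ref <- p[1L]; pos <- as.integer(p[2L]); alt <- "del"
  } else if (m3[1L] != -1L) {
    p <- grab(m3)
    if (!all(p[c(1L, 3L)] %in% names(AA3_TO_1))) {
      stop("unrecognized amino-acid code in variant token: ", token,
           call. = FALSE)
    }
    ref <- AA3_TO_1[[p[1L]]]; pos <- as.integer(p[2L])
    alt <- AA3_TO_1[[p[3L]]]
  } else if (m3d[1L] != -1L) {
    p <- grab(m3d)
    if (!p[1L] %in% names(AA3_TO_1)) {
      stop("unrecognized amino-acid code in variant token: ", token,
           call. = FALSE)
    }
    ref <- AA3_TO_1[[p[1L]]]; pos <- as.integer(p[2L]); alt <- "del"
  } else {
    stop("unrecognized variant syntax: ", token, call. = FALSE)
  }

  if (ref == "*") stop("reference residue cannot be a stop: ", token,
                       call. = FALSE)
  cls <- if (alt == "del") "single_aa_deletion"
         else if (alt == "*") "nonsense"
         else if (alt == ref) "silent"
         else "missense"

  if (!is.null(sequence)) {
    if (pos > sequence$length) {
      stop("variant position ", pos, " beyond sequence length ",
           sequence$length, call. = FALSE)
    }
    expected <- residue_at(sequence, pos)
    if (expected != ref) {
      stop("reference mismatch for ", token, ": sequence has ", expected,
           " at position ", pos, call. = FALSE)
    }
  }

  structure(list(raw_label = tok, position = pos, ref_aa = ref, alt_aa = alt,
                 variant_class = cls, severity = NA_character_,
                 allele_frequency_pct = NA_real_),
            class = "variant_record")
}

#' Format a variant record as a canonical one-letter token
#'
#' Inverse of [parse_variant()] for positional variants.
#'
#' @param record A `variant_record`.
#' @return Canonical token, e.g. `"L203P"` or `"K552del"`.
#' @export
format_variant <- function(record) {
  stopifnot(inherits(record, "variant_record"))
  if (!record$variant_class %in% POSITIONAL_CLASSES &&
      record$variant_class != "single_aa_deletion") {
    return(record$raw_label)
  }
  paste0(record$ref_aa, record$position,
         if (record$alt_aa == "del") "del" else record$alt_aa)
}

#' Build a variant catalog from a data frame
#'
#' The catalog is the compiled table of variants entering analysis. Rows
#' whose class is positional (`missense`, `single_aa_deletion`, `nonsense`,
#' `silent`) have their `variant` token parsed; other classes
#' (`frameshift`, `splice_site`, `gene_deletion`, `non_initiation`) are kept
#' as labels without coordinates. Duplicate identical substitutions (same
#' position, ref, alt) are collapsed to one record; distinct substitutions
#' at the same codon remain separate records.
#'
#' @param df data.frame with columns `variant`, `class`, `severity`, and
#'   optionally `allele_freq_pct` and `source`.
#' @param sequence Optional [protein_sequence()] for reference validation.
#' @param provenance Free-text source tag.
#' @return An object of class `variant_catalog`: list with `records`
#'   (data.frame with columns `raw_label`, `position`, `ref_aa`, `alt_aa`,
#'   `variant_class`, `severity`, `allele_frequency_pct`) and `provenance`.
#' @export
variant_catalog <- function(df, sequence = NULL, provenance = "") {
  stopifnot(is.data.frame(df))
  need <- c("variant", "class", "severity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cls <- as.character(df$class)
  badc <- setdiff(unique(cls), VARIANT_CLASSES)
  if (length(badc) > 0L || anyNA(cls)) {
    stop("unknown variant class: ", paste(badc, collapse = ", "),
         call. = FALSE)
  }
  sev <- as.character(df$severity)
  bads <- setdiff(unique(sev), SEVERITY_LEVELS)
  if (length(bads) > 0L) {
    stop("unknown severity label: ", paste(bads, collapse = ", "),
         call. = FALSE)
  }
  afq <- if ("allele_freq_pct" %in% names(df)) {
    suppressWarnings(as.numeric(df$allele_freq_pct))
  } else rep(NA_real_, nrow(df))

  n <- nrow(df)
  pos <- rep(NA_integer_, n)
  ref <- rep(NA_character_, n)
  alt <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (cls[i] %in% c(POSITIONAL_CLASSES, "single_aa_deletion")) {
      rec <- parse_variant(as.character(df$variant[i]), sequence)
      if (rec$variant_class != cls[i]) {
        stop("variant '", df$variant[i], "' parses as class ",
             rec$variant_class, " but the table says ", cls[i],
             call. = FALSE)
      }
      pos[i] <- rec$position; ref[i] <- rec$ref_aa; alt[i] <- rec$alt_aa
    }
  }
  records <- data.frame(raw_label = as.character(df$variant), position = pos,
                        ref_aa = ref, alt_aa = alt, variant_class = cls,
                        severity = sev, allele_frequency_pct = afq,
                        stringsAsFactors = FALSE)
  # collapse duplicate identical substitutions
  key <- ifelse(is.na(pos), paste0("label:", records$raw_label),
                paste(pos, ref, alt, sep = ":"))
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, provenance = provenance),
            class = "variant_catalog")
}

#' Read a variant catalog from a tab-separated table
#'
#' Expected format: header
#' `variant<TAB>class<TAB>severity<TAB>allele_freq_pct<TAB>source`,
#' `#`-prefixed comment lines ignored.
#'
#' @param path Path to the table.
#' @param sequence Optional [protein_sequence()] for reference validation.
#' @return A [variant_catalog()].
#' @export
read_variant_catalog <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop("catalog file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  variant_catalog(df, sequence = sequence, provenance = path)
}

#' Write a variant catalog to a tab-separated table
#'
#' @param catalog A [variant_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "variant_catalog"))
  out <- data.frame(variant = catalog$records$raw_label,
                    class = catalog$records$variant_class,
                    severity = catalog$records$severity,
                    allele_freq_pct = catalog$records$allele_frequency_pct,
                    source = catalog$provenance,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("Variant catalog: ", nrow(x$records), " records",
      if (nzchar(x$provenance)) paste0(" [", x$provenance, "]"), "\n",
      sep = "")
  print(table(x$records$variant_class))
  invisible(x)
}

#' Tally a catalog by variant class and by severity
#'
#' Exhaustive, mutually exclusive counts; each margin sums to the record
#' count.
#'
#' @param catalog A [variant_catalog()].
#' @return List with `by_class` and `by_severity` (named integer vectors
#'   over the full enumerations) and `total`.
#' @export
classify_counts <- function(catalog) {
  stopifnot(inherits(catalog, "variant_catalog"))
  cls <- catalog$records$variant_class
  if (anyNA(cls)) stop("record with unset variant class", call. = FALSE)
  by_class <- table(factor(cls, levels = VARIANT_CLASSES))
  by_sev <- table(factor(catalog$records$severity, levels = SEVERITY_LEVELS))
  list(by_class = stats::setNames(as.integer(by_class), names(by_class)),
       by_severity = stats::setNames(as.integer(by_sev), names(by_sev)),
       total = nrow(catalog$records))
}

#' Select the hotspot-test input set
#'
#' Filters a catalog to the multiset S of residue positions the resampling
#' test operates on: keeps the positional single-residue classes
#' (`missense`, `single_aa_deletion`, and `silent` for control runs;
#' truncating classes are excluded because they delete one or more
#' domains), drops start-codon records (position 1 missense and
#' `non_initiation`), keeps positions inside the analysis region, and
#' applies the severity filter. |S| counts unique substitutions, so a codon
#' with several distinct alt residues contributes several positions.
#'
#' @param catalog A [variant_catalog()].
#' @param region An [analysis_region()].
#' @param severity_filter Either `"all-pathogenic"` (mild_bfne, uncertain
#'   and severe_ee) or a character vector of severity labels.
#' @return An object of class `mutation_set`: list with `positions`
#'   (integer multiset), `size` (|S|) and `severity` (label per position).
#' @export
select_mhf_input <- function(catalog, region,
                             severity_filter = "all-pathogenic") {
  stopifnot(inherits(catalog, "variant_catalog"),
            inherits(region, "analysis_region"))
  sev_keep <- if (identical(severity_filter, "all-pathogenic")) {
    c("mild_bfne", "uncertain", "severe_ee")
  } else {
    bad <- setdiff(severity_filter, SEVERITY_LEVELS)
    if (length(bad) > 0L) stop("unknown severity label: ",
                               paste(bad, collapse = ", "), call. = FALSE)
    severity_filter
  }
  r <- catalog$records
  keep <- r$variant_class %in% c("missense", "single_aa_deletion", "silent") &
    r$severity %in% sev_keep &
    !is.na(r$position) &
    r$position >= region$start & r$position <= region$end &
    !(r$variant_class == "missense" & r$position == 1L)
  positions <- r$position[keep]
  if (length(positions) == 0L) {
    warning("hotspot-test input set is empty for this filter/region",
            call. = FALSE)
  }
  structure(list(positions = as.integer(positions),
                 size = length(positions),
                 severity = r$severity[keep]),
            class = "mutation_set")
}

#' Construct a mutation set directly from positions
#'
#' @param positions Integer multiset of 1-based residue indices.
#' @param severity Optional severity label per position.
#' @return A `mutation_set`.
#' @export
mutation_set <- function(positions, severity = NULL) {
  positions <- as.integer(positions)
  if (anyNA(positions)) stop("non-integral positions", call. = FALSE)
  if (!is.null(severity) && length(severity) != length(positions)) {
    stop("severity length must match positions", call. = FALSE)
  }
  structure(list(positions = positions, size = length(positions),
                 severity = severity),
            class = "mutation_set")
}

#' @export
print.mutation_set <- function(x, ...) {
  cat("Mutation set: |S| =", x$size, "\n")
  invisible(x)
}
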