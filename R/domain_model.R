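#' @keywords internal
"_PACKAGE"

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Construct a protein sequence object
#'
#' A minimal container for a single protein chain: an accession label and a
#' one-letter residue string. All residue coordinates elsewhere in the
#' package are 1-based indices into this sequence.
#'
#' @param residues One-letter amino-acid string (20-letter alphabet plus
#'   optional `X` for unknown residues).
#' @param accession Text identifier for the sequence.
#' @return An object of class `protein_sequence` with elements `accession`,
#'   `residues` and `length`.
#' @examples
#' ps <- protein_sequence("MKVLRS", "toy")
#' ps$length
#' @export
protein_sequence <- function(residues, accession = "unnamed") {
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid amino-acid letter(s) in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(accession = accession, residues = residues, length = nchar(residues)),
    class = "protein_sequence"
  )
}

#' Read a protein sequence from a FASTA file
#'
#' Reads the first record of a FASTA file into a [protein_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return A `protein_sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no sequence records in ", path, call. = FALSE)
  acc <- sub("\\s.*$", "", names(aas)[1L])
  protein_sequence(as.character(aas[[1L]]), accession = acc)
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("Protein sequence <", x$accession, ">: ", x$length, " residues\n",
      sep = "")
  invisible(x)
}

#' Define the analysis region
#'
#' The residue interval over which the null model distributes mutations:
#' either the full protein or a sub-range such as an intracellular tail.
#' Uniform resampling in the hotspot test draws positions from this interval,
#' so its length is the denominator of every per-domain expectation.
#'
#' @param start,end 1-based inclusive residue bounds.
#' @param sequence Optional `protein_sequence`; when supplied, `end` may be
#'   omitted (defaults to the sequence length) and bounds are checked against
#'   the sequence.
#' @return An object of class `analysis_region` with `start`, `end`, `length`.
#' @examples
#' analysis_region(1, 100)
#' @export
analysis_region <- function(start = 1L, end = NULL, sequence = NULL) {
  if (is.null(end)) {
    if (is.null(sequence)) stop("either `end` or `sequence` must be given",
                                call. = FALSE)
    end <- sequence$length
  }
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid region bounds: require 1 <= start <= end", call. = FALSE)
  }
  if (!is.null(sequence) && end > sequence$length) {
    stop("region end ", end, " exceeds sequence length ", sequence$length,
         call. = FALSE)
  }
  structure(list(start = start, end = end, length = end - start + 1L),
            class = "analysis_region")
}

#' @export
print.analysis_region <- function(x, ...) {
  cat("Analysis region ", x$start, "-", x$end, " (L = ", x$length, ")\n",
      sep = "")
  invisible(x)
}

#' Build a domain map from name/start/end vectors
#'
#' A domain map is the hypothesis set of the hotspot test: an ordered list of
#' non-overlapping residue intervals inside one analysis region, one test per
#' domain. Residues not covered by any domain remain part of the sampling
#' space but carry no hypothesis.
#'
#' @param name Character vector of domain names (unique).
#' @param start,end Integer vectors of 1-based inclusive bounds.
#' @param region An [analysis_region()] containing every domain.
#' @return An object of class `domain_map`: a list with `region`, `domains`
#'   (data.frame with columns `name`, `start`, `end`, `length`) and `J`.
#' @examples
#' r <- analysis_region(1, 10)
#' domain_map(c("A", "B"), c(1, 6), c(5, 10), r)
#' @export
domain_map <- function(name, start, end, region) {
  stopifnot(inherits(region, "analysis_region"))
  name <- as.character(name)
  start <- as.integer(start); end <- as.integer(end)
  n <- length(name)
  if (n < 1L) stop("a domain map needs at least one domain", call. = FALSE)
  if (length(start) != n || length(end) != n) {
    stop("name/start/end lengths differ", call. = FALSE)
  }
  if (anyNA(start) || anyNA(end)) stop("non-integral domain coordinates",
                                       call. = FALSE)
  if (anyDuplicated(name)) {
    stop("duplicate domain name: ", name[duplicated(name)][1L], call. = FALSE)
  }
  bad <- which(start > end)
  if (length(bad) > 0L) {
    stop("domain '", name[bad[1L]], "' has start > end", call. = FALSE)
  }
  outside <- which(start < region$start | end > region$end)
  if (length(outside) > 0L) {
    stop("domain '", name[outside[1L]], "' (", start[outside[1L]], "-",
         end[outside[1L]], ") lies outside region ", region$start, "-",
         region$end, call. = FALSE)
  }
  ord <- order(start)
  os <- start[ord]; oe <- end[ord]; on <- name[ord]
  if (n > 1L) {
    clash <- which(os[-1L] <= oe[-n])
    if (length(clash) > 0L) {
      i <- clash[1L]
      stop("domains overlap: '", on[i], "' and '", on[i + 1L], "'",
           call. = FALSE)
    }
  }
  domains <- data.frame(name = name, start = start, end = end,
                        length = end - start + 1L,
                        stringsAsFactors = FALSE)
  structure(list(region = region, domains = domains, J = n),
            class = "domain_map")
}

#' Load a domain map from a tab-separated table
#'
#' Expected format: header `name<TAB>start<TAB>end`, one domain per row,
#' `#`-prefixed comment lines ignored. Row order is preserved.
#'
#' @param path Path to the table.
#' @param region An [analysis_region()].
#' @return A [domain_map()].
#' @export
load_domain_map <- function(path, region) {
  if (!file.exists(path)) stop("domain table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  raw <- lines[keep]
  lineno <- which(keep)
  if (length(raw) < 2L) stop("domain table has no data rows: ", path,
                             call. = FALSE)
  header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("name", "start", "end")
  if (!all(need %in% header)) {
    stop("domain table must have columns name/start/end, got: ",
         paste(header, collapse = ", "), call. = FALSE)
  }
  rows <- strsplit(raw[-1L], "\t", fixed = TRUE)
  parse_row <- function(i) {
    f <- rows[[i]]
    if (length(f) < length(header)) {
      stop("malformed domain row at line ", lineno[i + 1L], " of ", path,
           call. = FALSE)
    }
    rec <- stats::setNames(as.list(f[seq_along(header)]), header)
    st <- suppressWarnings(as.numeric(rec$start))
    en <- suppressWarnings(as.numeric(rec$end))
    if (is.na(st) || is.na(en) || st != round(st) || en != round(en)) {
      stop("non-integral coordinates at line ", lineno[i + 1L], " of ", path,
           call. = FALSE)
    }
    list(name = rec$name, start = as.integer(st), end = as.integer(en))
  }
  parsed <- lapply(seq_along(rows), parse_row)
  domain_map(vapply(parsed, `[[`, "", "name"),
             vapply(parsed, `[[`, 0L, "start"),
             vapply(parsed, `[[`, 0L, "end"),
             region)
}

#' Write a domain map to a tab-separated table
#'
#' Inverse of [load_domain_map()]; round-trips valid maps exactly.
#'
#' @param map A [domain_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_map <- function(map, path) {
  stopifnot(inherits(map, "domain_map"))
  utils::write.table(map$domains[, c("name", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.domain_map <- function(x, ...) {
  cat("Domain map: J =", x$J, "domains on region", x$region$start, "-",
      x$region$end, "\n")
  print(x$domains, row.names = FALSE)
  invisible(x)
}

# Integer lookup vector over the region: entry i gives the domain index
# (1..J) of residue region$start + i - 1, or 0 outside all domains.
domain_index_lookup <- function(map) {
  idx <- integer(map$region$length)
  for (j in seq_len(map$J)) {
    a <- map$domains$start[j] - map$region$start + 1L
    b <- map$domains$end[j] - map$region$start + 1L
    idx[a:b] <- j
  }
  idx
}

#' Find the domain containing a residue position
#'
#' @param position 1-based residue index (vectorized).
#' @param map A [domain_map()].
#' @return Character vector of domain names, `NA` for residues inside the
#'   region but outside every domain.
#' @examples
#' r <- analysis_region(1, 10)
#' m <- domain_map(c("A", "B"), c(1, 6), c(5, 10), r)
#' domain_of(c(3, 6), m)
#' @export
domain_of <- function(position, map) {
  stopifnot(inherits(map, "domain_map"))
  position <- as.integer(position)
  if (anyNA(position)) stop("non-integral position", call. = FALSE)
  out <- position < map$region$start | position > map$region$end
  if (any(out)) {
    stop("position ", position[out][1L], " outside region ",
         map$region$start, "-", map$region$end, call. = FALSE)
  }
  idx <- domain_index_lookup(map)[position - map$region$start + 1L]
  ifelse(idx == 0L, NA_character_, map$domains$name[pmax(idx, 1L)])
}
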