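#' Build the hotspot-by-severity 2x2 contingency table
#'
#' Stratifies the single amino acid pathogenic variants of a catalog into a
#' 2x2 table: rows = variant position inside one of the named hotspot
#' domains vs elsewhere in the region; columns = `severe_ee` vs the other
#' pathogenic severities. The stratification (the hotspot set and the
#' severity split) is exposed as explicit parameters rather than fixed to
#' one canonical form.
#'
#' @param catalog A [variant_catalog()] (or a `mutation_set` carrying
#'   severity labels).
#' @param map A [domain_map()].
#' @param hotspot_domains Character vector of domain names in `map`.
#' @param severe_levels Severity labels forming the first column (default
#'   `"severe_ee"`).
#' @param severity_filter Catalog filter applied first (default
#'   all-pathogenic).
#' @return An object of class `contingency_2x2`: 2x2 integer matrix with
#'   dimnames `hotspot` (in/out) and `severity` (severe/other).
#' @export
build_contingency <- function(catalog, map, hotspot_domains,
                              severe_levels = "severe_ee",
                              severity_filter = "all-pathogenic") {
  stopifnot(inherits(map, "domain_map"))
  unknown <- setdiff(hotspot_domains, map$domains$name)
  if (length(unknown) > 0L) {
    stop("unknown hotspot domain name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  S <- if (inherits(catalog, "mutation_set")) catalog
       else select_mhf_input(catalog, map$region, severity_filter)
  if (is.null(S$severity)) stop("mutation set carries no severity labels",
                                call. = FALSE)
  dom <- domain_of(S$positions, map)
  in_hot <- !is.na(dom) & dom %in% hotspot_domains
  severe <- S$severity %in% severe_levels
  tab <- matrix(c(sum(in_hot & severe), sum(in_hot & !severe),
                  sum(!in_hot & severe), sum(!in_hot & !severe)),
                nrow = 2, byrow = TRUE,
                dimnames = list(hotspot = c("in", "out"),
                                severity = c("severe", "other")))
  structure(tab, class = c("contingency_2x2", "matrix", "array"))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact test of independence computed from the hypergeometric distribution
#' of the top-left cell at fixed margins. The two-sided p-value follows the
#' minimum-likelihood convention: it sums the probabilities of all tables
#' consistent with the margins whose point probability does not exceed that
#' of the observed table (with the customary 1e-7 relative tolerance for
#' ties). One-sided "greater" sums the right tail of the top-left cell.
#'
#' @param table 2x2 matrix of non-negative counts (or `contingency_2x2`).
#' @param sidedness `"two-sided"` (default) or `"one-sided-greater"`.
#' @return The exact p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table, sidedness = c("two-sided",
                                                  "one-sided-greater")) {
  sidedness <- match.arg(sidedness)
  tab <- unclass(table)
  if (!is.matrix(tab) || !all(dim(tab) == c(2L, 2L))) {
    stop("need a 2x2 table", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  if (N < 1) stop("undefined test: all-zero table", call. = FALSE)
  m <- a + c        # first-column total
  r1 <- a + b       # first-row total
  lo <- max(0L, r1 - (N - m))
  hi <- min(r1, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, N - m, r1)
  p_obs <- stats::dhyper(a, m, N - m, r1)
  if (sidedness == "one-sided-greater") {
    p <- sum(dens[support >= a])
  } else {
    p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  }
  min(1, p)
}
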