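# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bootstrap configuration
#'
#' @param K Number of resampling iterations (default 10000).
#' @param seed Integer master seed; a run is fully reproducible from
#'   `(seed, K, n, region)`.
#' @param alpha Significance level applied to the Bonferroni-corrected
#'   p-values when flagging hotspots (default 0.05).
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(K = 10000L, seed = 1L, alpha = 0.05) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(K = K, seed = as.integer(seed), alpha = alpha),
            class = "bootstrap_config")
}

#' Observed per-domain mutation counts
#'
#' Tallies the mutation multiset over the domains of a map. Repeated
#' positions (distinct substitutions at one codon) count with multiplicity;
#' positions outside every domain contribute to no tally, so the column sum
#' is at most |S|.
#'
#' @param S A `mutation_set` (see [mutation_set()], [select_mhf_input()]).
#' @param map A [domain_map()].
#' @return Named integer vector D of length J.
#' @examples
#' r <- analysis_region(1, 10)
#' m <- domain_map(c("A", "B"), c(1, 6), c(5, 10), r)
#' observed_counts(mutation_set(c(3, 3, 7)), m)
#' @export
observed_counts <- function(S, map) {
  stopifnot(inherits(S, "mutation_set"), inherits(map, "domain_map"))
  pos <- S$positions
  if (length(pos) > 0L &&
      (min(pos) < map$region$start || max(pos) > map$region$end)) {
    stop("mutation position outside analysis region", call. = FALSE)
  }
  idx <- domain_index_lookup(map)
  d <- if (length(pos) == 0L) integer(map$J) else {
    tabulate(idx[pos - map$region$start + 1L], nbins = map$J)
  }
  stats::setNames(as.integer(d), map$domains$name)
}

#' Resample null per-domain counts
#'
#' Draws `K` bootstrapped mutation sets of size `n`, each position sampled
#' independently and uniformly with replacement from the `L_X` residues of
#' the analysis region (the stated null: mutations equally likely at every
#' residue), and tallies each set over the domain map. Sampling without
#' replacement is available for sensitivity analysis only.
#'
#' @param region An [analysis_region()].
#' @param map A [domain_map()] on that region.
#' @param n Size of each bootstrapped set (|S|).
#' @param config A [bootstrap_config()].
#' @param replace Sample with replacement (default `TRUE`, the bootstrap).
#' @return An object of class `null_count_matrix`: list with `counts`
#'   (K x J integer matrix), `n`, `region`, `config`.
#' @export
bootstrap_null <- function(region, map, n, config = bootstrap_config(),
                           replace = TRUE) {
  stopifnot(inherits(region, "analysis_region"), inherits(map, "domain_map"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("empty mutation set: n must be >= 1",
                               call. = FALSE)
  if (!replace && n > region$length) {
    stop("cannot sample ", n, " positions without replacement from ",
         region$length, " residues", call. = FALSE)
  }
  K <- config$K
  J <- map$J
  idx <- domain_index_lookup(map)
  counts <- with_seed(config$seed, {
    if (replace) {
      draws <- sample.int(region$length, n * K, replace = TRUE)
      dom <- idx[draws]
      k_of <- rep.int(seq_len(K), rep.int(n, K))
      keep <- dom > 0L
      tab <- tabulate((k_of[keep] - 1L) * J + dom[keep], nbins = K * J)
      matrix(as.integer(tab), nrow = K, ncol = J, byrow = TRUE)
    } else {
      t(vapply(seq_len(K), function(k) {
        dom <- idx[sample.int(region$length, n, replace = FALSE)]
        tabulate(dom[dom > 0L], nbins = J)
      }, integer(J)))
    }
  })
  colnames(counts) <- map$domains$name
  structure(list(counts = counts, n = n, region = region, config = config),
            class = "null_count_matrix")
}

#' Empirical add-one p-value for one domain
#'
#' Right-tailed resampling p-value
#' \eqn{\hat P = (1 + \#\{k : \tilde D(k) \ge D\}) / (K + 1)}. The add-one
#' (permutation) form guarantees \eqn{\hat P \in [1/(K+1), 1]} and makes the
#' p-value super-uniform under the null, so it can never report an exact
#' zero.
#'
#' @param D_j Observed count for the domain.
#' @param null_column Integer vector of K resampled counts for the domain.
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(D_j, null_column) {
  stopifnot(is.numeric(D_j), length(D_j) == 1L, is.numeric(null_column),
            length(null_column) >= 1L)
  K <- length(null_column)
  (1 + sum(null_column >= D_j)) / (K + 1)
}

#' Bonferroni adjustment over J domains
#'
#' \eqn{p_{adj} = \min(1, J \cdot p)}, elementwise.
#'
#' @param p_raw Vector of raw p-values in (0, 1].
#' @param J Number of domains tested (defaults to `length(p_raw)`).
#' @return Adjusted p-values.
#' @export
adjust_bonferroni <- function(p_raw, J = length(p_raw)) {
  if (any(p_raw <= 0 | p_raw > 1)) stop("p-values must lie in (0, 1]",
                                        call. = FALSE)
  pmin(1, J * p_raw)
}

#' Exact binomial tail probability (analytic oracle)
#'
#' Under the uniform null each of the `n` mutations lands in a domain of
#' length `L_j` with probability `L_j / L_X` independently, so the null
#' count is Binomial(n, L_j/L_X). Returns the right tail
#' \eqn{P(\mathrm{Bin}(n, L_j/L_X) \ge D_j)} by direct summation of the
#' probability mass function. Serves as the analytic reference the
#' resampling p-value must converge to.
#'
#' @param D_j Observed count, 0..n.
#' @param n Mutation set size.
#' @param L_j Domain length.
#' @param L_X Region length.
#' @return Tail probability.
#' @export
exact_binomial_pvalue <- function(D_j, n, L_j, L_X) {
  if (D_j < 0 || D_j > n) stop("require 0 <= D_j <= n", call. = FALSE)
  if (L_j <= 0 || L_j > L_X) stop("require 0 < L_j <= L_X", call. = FALSE)
  p <- L_j / L_X
  sum(stats::dbinom(seq.int(D_j, n), n, p))
}

significance_stars <- function(p) {
  ifelse(p < 0.005, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Run the full mutation hotspot test
#'
#' Orchestrates the pipeline: filter the catalog to the input multiset S
#' ([select_mhf_input()]), tally observed per-domain counts, resample the
#' uniform null ([bootstrap_null()]), compute add-one empirical p-values,
#' Bonferroni-adjust over the J domains of the map, and flag domains at
#' `config$alpha`.
#'
#' @param catalog A [variant_catalog()], or a ready-made `mutation_set`
#'   (then `severity_filter` is ignored).
#' @param map A [domain_map()].
#' @param region An [analysis_region()]; defaults to the map's region.
#' @param severity_filter Passed to [select_mhf_input()].
#' @param config A [bootstrap_config()].
#' @param replace Passed to [bootstrap_null()].
#' @return An object of class `hotspot_result`: a data.frame with one row
#'   per domain (columns `domain`, `start`, `end`, `L_j`, `D_j`, `E_hat`,
#'   `E_analytic`, `p_raw`, `p_bonferroni`, `stars`, `significant`) and
#'   attributes `n` (|S|), `K`, `seed`, `alpha`, `severity_filter`,
#'   `region`.
#' @examples
#' r <- analysis_region(1, 100)
#' m <- domain_map(c("A", "B"), c(1, 21), c(20, 40), r)
#' S <- mutation_set(rep(c(5, 15), c(6, 6)))
#' run_mhf(S, m, config = bootstrap_config(K = 1000, seed = 7))
#' @export
run_mhf <- function(catalog, map, region = map$region,
                    severity_filter = "all-pathogenic",
                    config = bootstrap_config(), replace = TRUE) {
  stopifnot(inherits(map, "domain_map"))
  S <- if (inherits(catalog, "mutation_set")) catalog
       else select_mhf_input(catalog, region, severity_filter)
  if (S$size == 0L) {
    stop("refusing to run the hotspot test on an empty mutation set (|S| = 0)",
         call. = FALSE)
  }
  D <- observed_counts(S, map)
  null <- bootstrap_null(region, map, S$size, config, replace = replace)
  p_raw <- vapply(seq_len(map$J),
                  function(j) empirical_pvalue(D[j], null$counts[, j]),
                  numeric(1))
  p_adj <- adjust_bonferroni(p_raw, map$J)
  res <- data.frame(
    domain = map$domains$name,
    start = map$domains$start,
    end = map$domains$end,
    L_j = map$domains$length,
    D_j = as.integer(D),
    E_hat = colMeans(null$counts),
    E_analytic = S$size * map$domains$length / region$length,
    p_raw = p_raw,
    p_bonferroni = p_adj,
    stars = significance_stars(p_adj),
    significant = p_adj <= config$alpha,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("hotspot_result", "data.frame"),
            n = S$size, K = config$K, seed = config$seed,
            alpha = config$alpha,
            severity_filter = paste(severity_filter, collapse = ","),
            region = c(start = region$start, end = region$end))
}

#' @export
print.hotspot_result <- function(x, digits = 4, ...) {
  reg <- attr(x, "region")
  cat("Mutation hotspot test: |S| =", attr(x, "n"), " K =", attr(x, "K"),
      " region", reg["start"], "-", reg["end"], "\n")
  df <- as.data.frame(x)
  df$E_hat <- round(df$E_hat, digits)
  df$E_analytic <- round(df$E_analytic, digits)
  df$p_raw <- signif(df$p_raw, digits)
  df$p_bonferroni <- signif(df$p_bonferroni, digits)
  print(df[, setdiff(names(df), "significant")], row.names = FALSE)
  hs <- df$domain[x$significant]
  cat(if (length(hs) > 0L) paste0("Hotspots at alpha = ", attr(x, "alpha"),
                                  ": ", paste(hs, collapse = ", "), "\n")
      else paste0("No hotspot at alpha = ", attr(x, "alpha"), "\n"))
  invisible(x)
}
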