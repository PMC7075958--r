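#' Simulation design for the calibration harness
#'
#' Describes one generating mechanism for synthetic mutation catalogs: a
#' mixture in which each mutation falls, with probability `pi`, uniformly
#' inside one of the designated hotspot domains (chosen with probability
#' proportional to domain length, so `pi` is the total extra hotspot mass)
#' and otherwise uniformly over the whole region. `pi = 0` is the uniform
#' null. Severity labels are drawn independently: `severe_ee` with
#' probability `rho` for hotspot-placed mutations and `baseline_severe`
#' otherwise.
#'
#' @param region An [analysis_region()].
#' @param map A [domain_map()] on that region.
#' @param n Mutations per simulated set.
#' @param hotspot_domains Character vector of domain names (may be empty
#'   when `pi = 0`).
#' @param pi Hotspot placement probability in \[0, 1\].
#' @param rho P(severe_ee | hotspot placement).
#' @param baseline_severe P(severe_ee | background placement).
#' @param replicates Number of replicate sets for [run_calibration()].
#' @param seed Master seed.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(region, map, n = 130L,
                              hotspot_domains = character(), pi = 0,
                              rho = 0.5, baseline_severe = 0.5,
                              replicates = 100L, seed = 1L) {
  stopifnot(inherits(region, "analysis_region"), inherits(map, "domain_map"))
  if (pi < 0 || pi > 1 || rho < 0 || rho > 1) {
    stop("pi and rho must lie in [0, 1]", call. = FALSE)
  }
  if (n < 1L || replicates < 1L) stop("n and replicates must be >= 1",
                                      call. = FALSE)
  if (pi > 0 && length(hotspot_domains) == 0L) {
    stop("pi > 0 requires a non-empty hotspot set", call. = FALSE)
  }
  unknown <- setdiff(hotspot_domains, map$domains$name)
  if (length(unknown) > 0L) {
    stop("unknown hotspot domain name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(region = region, map = map, n = as.integer(n),
                 hotspot_domains = hotspot_domains, pi = pi, rho = rho,
                 baseline_severe = baseline_severe,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a uniform-null mutation set
#'
#' `n` positions drawn i.i.d. uniformly over the residues of the region —
#' the null the hotspot test resamples under.
#'
#' @param region An [analysis_region()].
#' @param n Number of positions.
#' @param seed Integer seed.
#' @return A [mutation_set()].
#' @export
simulate_null_set <- function(region, n, seed = 1L) {
  stopifnot(inherits(region, "analysis_region"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  pos <- with_seed(seed, {
    region$start + sample.int(region$length, n, replace = TRUE) - 1L
  })
  mutation_set(pos)
}

# draw positions under the mixture design; internal core shared by
# simulate_clustered_catalog
draw_mixture_positions <- function(design) {
  reg <- design$region
  n <- design$n
  if (design$pi > 0) {
    hd <- design$map$domains[design$map$domains$name %in%
                               design$hotspot_domains, , drop = FALSE]
    in_hot <- stats::runif(n) < design$pi
    k <- sum(in_hot)
    pos <- integer(n)
    if (k > 0L) {
      which_dom <- sample.int(nrow(hd), k, replace = TRUE, prob = hd$length)
      offs <- floor(stats::runif(k) * hd$length[which_dom])
      pos[in_hot] <- hd$start[which_dom] + as.integer(offs)
    }
    pos[!in_hot] <- reg$start +
      sample.int(reg$length, n - k, replace = TRUE) - 1L
    list(pos = pos, in_hot = in_hot)
  } else {
    list(pos = reg$start + sample.int(reg$length, n, replace = TRUE) - 1L,
         in_hot = rep(FALSE, n))
  }
}

#' Simulate a clustered variant catalog
#'
#' Generates `n` missense records under the mixture of
#' [simulation_design()], with parseable one-letter tokens (random
#' reference and alternate residues, alternate != reference) and severity
#' labels `severe_ee` / `mild_bfne` drawn with the design's hotspot and
#' baseline severity rates.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed (defaults to the design seed).
#' @return A [variant_catalog()].
#' @export
simulate_clustered_catalog <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  aas <- setdiff(AA_ALPHABET, "X")
  with_seed(seed, {
    drawn <- draw_mixture_positions(design)
    n <- design$n
    ref <- sample(aas, n, replace = TRUE)
    # repeated draws at one residue share the reference and take distinct
    # alternates, so every record is a distinct substitution
    ref <- ref[match(drawn$pos, drawn$pos)]
    occ <- stats::ave(seq_len(n), drawn$pos, FUN = seq_along)
    others <- vapply(ref, function(r) list(setdiff(aas, r)), vector("list", 1))
    alt <- vapply(seq_len(n), function(i) {
      o <- others[[i]]
      o[(occ[i] - 1L) %% length(o) + 1L]
    }, "")
    p_sev <- ifelse(drawn$in_hot, design$rho, design$baseline_severe)
    sev <- ifelse(stats::runif(n) < p_sev, "severe_ee", "mild_bfne")
    df <- data.frame(variant = paste0(ref, drawn$pos, alt),
                     class = "missense", severity = sev,
                     stringsAsFactors = FALSE)
    variant_catalog(df, provenance = "simulated")
  })
}

#' Type-I error and power calibration of the hotspot test
#'
#' Runs the full resampling pipeline on `design$replicates` independently
#' simulated catalogs and reports, per domain, the fraction of replicates
#' whose raw and Bonferroni-corrected p-values fall at or below each
#' significance level. Under the null design (`pi = 0`) the raw rejection
#' rate estimates the per-domain type-I error (the add-one p-value makes it
#' conservative); under a clustered design the corrected rate for the
#' hotspot domain estimates power.
#'
#' @param design A [simulation_design()].
#' @param config A [bootstrap_config()]; its seed is combined with the
#'   design seed so each replicate uses an independent substream.
#' @param alphas Significance levels at which rejection rates are reported.
#' @return data.frame with columns `domain`, `alpha`, `reject_raw`,
#'   `reject_adj` plus attribute `replicates`.
#' @export
run_calibration <- function(design, config = bootstrap_config(),
                            alphas = c(0.01, 0.05, 0.1)) {
  stopifnot(inherits(design, "simulation_design"))
  R <- design$replicates
  J <- design$map$J
  p_raw <- matrix(NA_real_, R, J)
  for (r in seq_len(R)) {
    cat_r <- simulate_clustered_catalog(design,
                                        seed = design$seed + 7919L * r)
    S <- select_mhf_input(cat_r, design$region,
                          severity_filter = c("mild_bfne", "severe_ee"))
    cfg_r <- bootstrap_config(K = config$K,
                              seed = config$seed + 104729L + r,
                              alpha = config$alpha)
    res <- run_mhf(S, design$map, design$region, config = cfg_r)
    p_raw[r, ] <- res$p_raw
  }
  p_adj <- matrix(pmin(1, p_raw * J), nrow = R)
  out <- do.call(rbind, lapply(alphas, function(a) {
    data.frame(domain = design$map$domains$name, alpha = a,
               reject_raw = colMeans(p_raw <= a),
               reject_adj = colMeans(p_adj <= a),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "replicates") <- R
  out
}
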