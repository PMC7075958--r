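# Shared builders for the test suite. The Kv7.2-like worked example is
# deterministic but not free to build, so it is constructed once per run.

kv72_cache <- new.env(parent = emptyenv())

kv72 <- function() {
  if (is.null(kv72_cache$fx)) kv72_cache$fx <- kv72_synthetic_fixture()
  kv72_cache$fx
}

extdata <- function(...) {
  system.file("extdata", ..., package = "mhf", mustWork = TRUE)
}

# two-domain toy map on residues 1..10 (tiling partition)
toy_map <- function() {
  domain_map(c("A", "B"), c(1, 6), c(5, 10), analysis_region(1, 10))
}

# two short domains inside a 100-residue region (for plotting tests)
toy_long_map <- function() {
  domain_map(c("D1", "D2"), c(5, 25), c(15, 40), analysis_region(1, 100))
}

# single 20-residue domain inside a 100-residue region
onefifth_map <- function() {
  domain_map("A", 1, 20, analysis_region(1, 100))
}

# brute-force Fisher oracle: enumerate every table consistent with the
# margins via log-binomial coefficients (no dhyper), minimum-likelihood
# two-sided convention with the customary 1e-7 tie tolerance
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  r1 <- a + b; m <- a + c
  lo <- max(0, r1 - (N - m)); hi <- min(r1, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(N - m, r1 - x) - lchoose(N, r1)
  }
  dens <- exp(vapply(lo:hi, logp, numeric(1)))
  p_obs <- exp(logp(a))
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}
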