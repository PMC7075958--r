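#' Build a run manifest
#'
#' Provenance record sufficient to reproduce a hotspot run bit-for-bit:
#' input file digests, seed, iteration count, |S|, region and package
#' version.
#'
#' @param inputs Named character vector of input file paths (digested with
#'   MD5).
#' @param result A `hotspot_result` (optional; contributes n, K, seed,
#'   region, filter).
#' @param command Free-text command line.
#' @return A named list of class `run_manifest`.
#' @export
run_manifest <- function(inputs = character(), result = NULL, command = "") {
  digests <- if (length(inputs) > 0L) {
    md5 <- tools::md5sum(inputs)
    stats::setNames(unname(md5), names(inputs))
  } else character()
  man <- list(command = command,
              inputs = as.list(digests),
              package_version = as.character(utils::packageVersion("mhf")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(result)) {
    man$n <- attr(result, "n")
    man$K <- attr(result, "K")
    man$seed <- attr(result, "seed")
    man$alpha <- attr(result, "alpha")
    man$severity_filter <- attr(result, "severity_filter")
    man$region <- as.list(attr(result, "region"))
  }
  structure(man, class = "run_manifest")
}

#' Write hotspot results and provenance to files
#'
#' Writes `<prefix>.results.tsv` (columns domain, start, end, L_j, D_j,
#' E_hat, E_analytic, p_raw, p_bonferroni, stars, in stable order) and
#' `<prefix>.run.json` (the manifest). Round-trips through
#' [read_results()].
#'
#' @param results A `hotspot_result`.
#' @param manifest A [run_manifest()] (default: built from `results`).
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_results <- function(results, prefix, manifest = NULL) {
  stopifnot(inherits(results, "hotspot_result"))
  if (is.null(manifest)) manifest <- run_manifest(result = results)
  cols <- c("domain", "start", "end", "L_j", "D_j", "E_hat", "E_analytic",
            "p_raw", "p_bonferroni", "stars")
  tsv <- paste0(prefix, ".results.tsv")
  json <- paste0(prefix, ".run.json")
  df <- as.data.frame(results)[, cols]
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(manifest), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Read back a written hotspot results table
#'
#' @param prefix The prefix passed to [write_results()].
#' @return List with `results` (data.frame) and `manifest` (list).
#' @export
read_results <- function(prefix) {
  tsv <- paste0(prefix, ".results.tsv")
  json <- paste0(prefix, ".run.json")
  if (!file.exists(tsv)) stop("no results at prefix ", prefix, call. = FALSE)
  df <- utils::read.table(tsv, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  df$stars[is.na(df$stars)] <- ""
  man <- if (file.exists(json)) jsonlite::read_json(json) else NULL
  list(results = df, manifest = man)
}

SEVERITY_COLORS <- c(mild_bfne = "#3B6FB6", uncertain = "#8E44AD",
                     severe_ee = "#C0392B", nonpathogenic = "#7F8C8D",
                     silent_control = "#AAB7B8")

#' Lollipop plot of mutation positions over the primary structure
#'
#' Draws one stem per mutated residue (height = number of distinct
#' mutations at that residue, color = most severe class observed there)
#' above a track of domain bands. Unparseable or position-free records are
#' skipped with a warning.
#'
#' @param catalog A [variant_catalog()].
#' @param map A [domain_map()].
#' @param file Optional output path (`.png` or `.pdf`); when `NULL`, draws
#'   on the active device.
#' @param main Plot title.
#' @param width,height Device size in inches when `file` is given.
#' @return Invisibly, the per-position data.frame plotted.
#' @export
plot_lollipop <- function(catalog, map, file = NULL, main = "Mutation map",
                          width = 10, height = 4) {
  stopifnot(inherits(catalog, "variant_catalog"), inherits(map, "domain_map"))
  r <- catalog$records
  skip <- is.na(r$position)
  if (any(skip)) {
    warning(sum(skip), " record(s) without residue coordinates skipped",
            call. = FALSE)
  }
  r <- r[!skip & r$position >= map$region$start &
           r$position <= map$region$end, , drop = FALSE]
  sev_rank <- c(silent_control = 1, nonpathogenic = 2, mild_bfne = 3,
                uncertain = 4, severe_ee = 5)
  agg <- if (nrow(r) > 0L) {
    sp <- split(r$severity, r$position)
    data.frame(position = as.integer(names(sp)),
               count = lengths(sp),
               severity = vapply(sp, function(s)
                 names(sev_rank)[max(sev_rank[s])], ""),
               stringsAsFactors = FALSE)
  } else {
    data.frame(position = integer(), count = integer(),
               severity = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = width,
                                               height = height)
    else grDevices::png(file, width = width, height = height, units = "in",
                        res = 150)
    on.exit(grDevices::dev.off())
  }
  ymax <- max(3, agg$count)
  graphics::plot(NA, xlim = c(map$region$start, map$region$end),
                 ylim = c(-ymax / 4, ymax * 1.05),
                 xlab = "Residue", ylab = "Mutations", main = main,
                 yaxt = "n", bty = "n")
  graphics::axis(2, at = seq_len(ymax))
  # domain bands beneath the stems
  y0 <- -ymax / 5; y1 <- -ymax / 12
  for (j in seq_len(map$J)) {
    graphics::rect(map$domains$start[j], y0, map$domains$end[j], y1,
                   col = "grey85", border = "grey40")
    graphics::text((map$domains$start[j] + map$domains$end[j]) / 2,
                   (y0 + y1) / 2, map$domains$name[j], cex = 0.45)
  }
  graphics::abline(h = 0, col = "grey70")
  if (nrow(agg) > 0L) {
    cols <- SEVERITY_COLORS[agg$severity]
    graphics::segments(agg$position, 0, agg$position, agg$count,
                       col = cols)
    graphics::points(agg$position, agg$count, pch = 19, col = cols,
                     cex = 0.7)
  }
  invisible(agg)
}
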