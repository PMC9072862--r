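#' Export genotypes as TSV, VCF or PLINK-style map
#'
#' `write_geno_tsv()` writes a lines x markers table in 0/2 allele-dosage
#' coding (homozygous material, so dosages are 0 or 2). `write_vcf()` writes
#' a minimal VCF 4.2 with one pseudo-contig per chromosome; the physical
#' position of a marker is `round(cM x 1e5)` so genetic order is preserved.
#' `write_plink_map()` writes the four-column PLINK `.map` layout
#' (chrom, id, cM, bp).
#'
#' @param x A `founder_panel` or `dh_population`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @name genotype-export
NULL

geno_dosage <- function(x) {
  if (inherits(x, "founder_panel")) {
    list(geno = x$haplotypes * 2L, map = x$map)
  } else if (inherits(x, "dh_population")) {
    list(geno = x$genotypes + 1L, map = x$map)
  } else {
    stop("`x` must be a founder_panel or dh_population", call. = FALSE)
  }
}

#' @rdname genotype-export
#' @export
write_geno_tsv <- function(x, path) {
  d <- geno_dosage(x)
  tbl <- tibble::as_tibble(d$geno, rownames = "line_id")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname genotype-export
#' @export
read_geno_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  geno <- as.matrix(tbl[, -1])
  rownames(geno) <- tbl[[1]]
  geno
}

#' @rdname genotype-export
#' @export
write_vcf <- function(x, path) {
  d <- geno_dosage(x)
  map <- d$map
  gt <- t(d$geno) # markers x lines, dosage 0/2
  gt_str <- matrix(c("0/0", "1/1")[(gt > 0) + 1L], nrow(gt), ncol(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gpsim",
    sprintf("##contig=<ID=chr%s,length=%d>",
            names(chrom_lengths(map)),
            as.integer(round(chrom_lengths(map) * 100 * 1e5)) + 1L),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d$geno)), collapse = "\t")
  )
  body <- paste(
    sprintf("chr%d", map$chrom),
    as.integer(round(map$pos * 100 * 1e5)) + 1L, # cM x 1e5, 1-based
    map$marker_id, "A", "T", ".", "PASS", ".", "GT",
    apply(gt_str, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname genotype-export
#' @param map A `genetic_map` (for `write_plink_map()`).
#' @export
write_plink_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  tbl <- tibble::tibble(
    chrom = map$chrom, marker_id = map$marker_id,
    cM = map$pos * 100,
    bp = as.integer(round(map$pos * 100 * 1e5)) + 1L
  )
  readr::write_tsv(tbl, path, col_names = FALSE)
  invisible(path)
}

#' Export tabular results
#'
#' `write_qc_report()` writes the per-marker table of a QC report;
#' `write_phenotypes()` the per-line phenotype set (with the g/u/v/w
#' components); `write_effects_tsv()` the per-marker effects;
#' `write_calibration_json()` the calibration record of calibrated effects;
#' `write_rrblup()` a fitted model as an effects TSV plus a JSON with the
#' intercept, shrinkage and variance estimates.
#'
#' @param x The object to write (see above).
#' @param path Output file path (for `write_rrblup()`: the TSV path; the JSON
#'   is written next to it with extension `.json`).
#' @return The path(s), invisibly.
#' @name result-export
NULL

#' @rdname result-export
#' @export
write_qc_report <- function(x, path) {
  stopifnot(inherits(x, "marker_qc_report"))
  readr::write_tsv(x$markers, path)
  invisible(path)
}

#' @rdname result-export
#' @export
write_phenotypes <- function(x, path) {
  stopifnot(is.data.frame(x))
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname result-export
#' @export
write_effects_tsv <- function(x, path) {
  stopifnot(inherits(x, "marker_effects"))
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname result-export
#' @export
write_calibration_json <- function(x, path) {
  stopifnot(inherits(x, "marker_effects"))
  cal <- attr(x, "calibration")
  if (is.null(cal)) stop("effects are not calibrated", call. = FALSE)
  jsonlite::write_json(c(cal, list(intercept = attr(x, "intercept"))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname result-export
#' @export
write_rrblup <- function(x, path) {
  stopifnot(inherits(x, "rrblup"))
  readr::write_tsv(tidy(x), path)
  json_path <- sub("\\.[^.]+$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(mu = x$mu, lambda = x$lambda, sigma_a2 = x$sigma_a2,
         sigma_e2 = x$sigma_e2, mode = x$mode, converged = x$converged),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, json_path))
}
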