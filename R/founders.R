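#' Simulate a panel of homozygous founder lines in two pools
#'
#' Generates the parental material for the mating designs: `n_elite` elite
#' lines and `n_donor` donor lines, all fully homozygous inbreds, genotyped at
#' the markers of `map`. Because the founders are fully homozygous a single
#' haplotype per founder (alleles coded 0/1) defines its genotype;
#' heterozygosity only exists transiently in the simulated F1s.
#'
#' A fraction `pool_divergence` of the markers is fixed for opposite alleles
#' in the two pools (elite carry allele 0, donors allele 1); these markers
#' segregate 1:1 in every elite x donor cross and are monomorphic within each
#' pool. At the remaining markers alleles are drawn independently per founder
#' (Bernoulli 1/2), redrawing any marker whose panel-wide minor allele
#' frequency falls below `min_maf` or that happens to separate the pools, so
#' that pool differentiation is exactly the requested fraction of markers.
#'
#' @param map A `genetic_map`.
#' @param n_elite,n_donor Founders per pool (defaults 5 + 5).
#' @param pool_divergence Fraction of markers fixed between pools, in [0, 1].
#'   The count of differentiated markers is `round(pool_divergence * n_markers)`.
#' @param min_maf Minimum panel minor-allele frequency for the
#'   non-differentiated markers, in [0, 0.5].
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A `founder_panel`: list with elements `map`, `haplotypes` (founder
#'   x marker 0/1 matrix), `pool` (factor `elite`/`donor` per founder) and
#'   `pool_diff` (logical per marker: fixed between pools by construction).
#'
#' @examples
#' map <- build_map(n_markers = 70)
#' panel <- simulate_founders(map, seed = 1)
#' table(panel$pool)
#' @export
simulate_founders <- function(map, n_elite = 5, n_donor = 5,
                              pool_divergence = 0.3, min_maf = 0.1,
                              seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (n_elite + n_donor < 2) stop("need at least two founders", call. = FALSE)
  if (pool_divergence < 0 || pool_divergence > 1) {
    stop("`pool_divergence` must be in [0, 1]", call. = FALSE)
  }
  if (min_maf < 0 || min_maf > 0.5) stop("`min_maf` must be in [0, 0.5]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_f <- n_elite + n_donor
  m <- nrow(map)
  pool <- factor(rep(c("elite", "donor"), c(n_elite, n_donor)),
                 levels = c("elite", "donor"))
  ids <- c(sprintf("E%02d", seq_len(n_elite)), sprintf("D%02d", seq_len(n_donor)))

  n_diff <- round(pool_divergence * m)
  diff_idx <- if (n_diff > 0) sort(sample.int(m, n_diff)) else integer(0)
  pool_diff <- seq_len(m) %in% diff_idx

  hap <- matrix(0L, n_f, m, dimnames = list(ids, map$marker_id))
  hap[pool == "donor", diff_idx] <- 1L

  free_idx <- setdiff(seq_len(m), diff_idx)
  # a polymorphic non-separating configuration only exists when some pool has
  # at least two founders; with single-founder pools every polymorphic marker
  # is pool-fixed, so only the MAF constraint applies there
  check_sep <- n_elite > 0 && n_donor > 0 && (n_elite >= 2 || n_donor >= 2)
  for (j in free_idx) {
    for (try in seq_len(10000)) {
      a <- stats::rbinom(n_f, 1L, 0.5)
      maf <- min(mean(a), 1 - mean(a))
      separates <- check_sep &&
        length(unique(a[pool == "elite"])) == 1 &&
        length(unique(a[pool == "donor"])) == 1 &&
        a[match("elite", pool)] != a[match("donor", pool)]
      if (maf >= min_maf && !separates) break
      if (try == 10000) {
        stop("could not draw a marker satisfying `min_maf`; relax the constraint",
             call. = FALSE)
      }
    }
    hap[, j] <- a
  }

  structure(
    list(map = map, haplotypes = hap, pool = stats::setNames(pool, ids),
         pool_diff = pool_diff),
    class = "founder_panel"
  )
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("<founder_panel> %d founders (%d elite, %d donor), %d markers, %d pool-differentiated\n",
              nrow(x$haplotypes), sum(x$pool == "elite"), sum(x$pool == "donor"),
              ncol(x$haplotypes), sum(x$pool_diff)))
  invisible(x)
}

#' Founder genotypes as a tibble
#'
#' @param x A `founder_panel`.
#' @param ... Unused.
#' @return A tibble with one row per founder x marker combination:
#'   `founder_id`, `pool`, `marker_id`, `allele`.
#' @export
tidy.founder_panel <- function(x, ...) {
  tibble::tibble(
    founder_id = rep(rownames(x$haplotypes), ncol(x$haplotypes)),
    pool = rep(as.character(x$pool), ncol(x$haplotypes)),
    marker_id = rep(colnames(x$haplotypes), each = nrow(x$haplotypes)),
    allele = as.integer(x$haplotypes)
  )
}

#' Gene diversity (expected heterozygosity) per marker
#'
#' Computes `1 - sum(allele frequency^2)` per marker over non-missing calls,
#' the standard gene-diversity statistic for inbred panels. For a biallelic
#' marker this is `2 p (1 - p)` with `p` the allele frequency.
#'
#' @param genotypes Lines x markers matrix of homozygous biallelic genotypes.
#'   Any two-valued coding works (0/1, 0/2, -1/1); `NA` marks missing calls.
#' @return Numeric vector of per-marker gene diversity in [0, 0.5].
#' @export
gene_diversity <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  apply(genotypes, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    1 - sum((table(g) / length(g))^2)
  })
}

#' Filter a genotype matrix by marker and line quality rules
#'
#' Applies the standard SNP-panel quality control for homozygous material:
#' markers with strictly more than `max_missing_marker` missing calls or gene
#' diversity strictly smaller than `min_diversity` are removed first; then
#' lines with strictly more than `max_missing_line` missing calls over the
#' retained markers are removed. The marker rules are applied before the line
#' rule; both stages are reported.
#'
#' @param genotypes Lines x markers matrix (rows named by line, columns by
#'   marker) of homozygous biallelic genotypes with `NA` for missing.
#' @param max_missing_marker Maximum tolerated per-marker missing fraction
#'   (exclusive threshold; default 0.10).
#' @param min_diversity Minimum tolerated per-marker gene diversity
#'   (exclusive threshold; default 0.10).
#' @param max_missing_line Maximum tolerated per-line missing fraction on the
#'   retained markers (exclusive threshold; default 0.15).
#'
#' @return A list with `genotypes` (the filtered matrix) and `report`, a
#'   `marker_qc_report`: counts in/kept for markers and lines plus per-marker
#'   missingness and diversity (tibble `markers`) and per-line missingness
#'   (tibble `lines`).
#' @seealso [gene_diversity()]
#' @export
filter_markers <- function(genotypes, max_missing_marker = 0.10,
                           min_diversity = 0.10, max_missing_line = 0.15) {
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes))) colnames(genotypes) <- sprintf("m%d", seq_len(ncol(genotypes)))
  if (is.null(rownames(genotypes))) rownames(genotypes) <- sprintf("l%d", seq_len(nrow(genotypes)))

  miss_m <- colMeans(is.na(genotypes))
  div <- gene_diversity(genotypes)
  keep_m <- miss_m <= max_missing_marker & !is.na(div) & div >= min_diversity
  if (!any(keep_m)) stop("empty panel: all markers removed by QC", call. = FALSE)

  kept <- genotypes[, keep_m, drop = FALSE]
  miss_l <- rowMeans(is.na(kept))
  keep_l <- miss_l <= max_missing_line
  if (!any(keep_l)) stop("empty panel: all lines removed by QC", call. = FALSE)
  out <- kept[keep_l, , drop = FALSE]

  report <- structure(
    list(
      n_markers_in = ncol(genotypes), n_markers_kept = ncol(out),
      n_lines_in = nrow(genotypes), n_lines_kept = nrow(out),
      markers = tibble::tibble(
        marker_id = colnames(genotypes),
        missing_fraction = unname(miss_m),
        gene_diversity = unname(div),
        kept = unname(keep_m)
      ),
      lines = tibble::tibble(
        line_id = rownames(genotypes),
        missing_fraction_post_marker_qc = unname(rowMeans(is.na(kept))),
        kept = unname(keep_l)
      )
    ),
    class = "marker_qc_report"
  )
  list(genotypes = out, report = report)
}

#' @export
print.marker_qc_report <- function(x, ...) {
  cat(sprintf("<marker_qc_report> markers %d -> %d, lines %d -> %d\n",
              x$n_markers_in, x$n_markers_kept, x$n_lines_in, x$n_lines_kept))
  invisible(x)
}

#' @rdname filter_markers
#' @param x A `marker_qc_report`.
#' @param ... Unused.
#' @export
glance.marker_qc_report <- function(x, ...) {
  tibble::tibble(
    n_markers_in = x$n_markers_in, n_markers_kept = x$n_markers_kept,
    n_lines_in = x$n_lines_in, n_lines_kept = x$n_lines_kept
  )
}

#' Modified Rogers' distance between homozygous lines
#'
#' Pairwise modified Rogers' distance
#' `MRD(i, j) = sqrt(sum over markers and alleles of (f_ai - f_aj)^2 / (2 m))`
#' where `f_ai` is the frequency of allele `a` in line `i` (0 or 1 for fully
#' homozygous material) and `m` the marker count. For homozygous biallelic
#' lines this reduces to the square root of the fraction of markers at which
#' the two lines differ, so the distance lies in [0, 1] and is a metric.
#'
#' @param x A `founder_panel`, a `dh_population`, or a lines x markers matrix
#'   of homozygous biallelic genotypes (no missing values; run
#'   [filter_markers()] first).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
modified_rogers_distance <- function(x) {
  geno <- if (inherits(x, "founder_panel")) x$haplotypes
    else if (inherits(x, "dh_population")) x$genotypes
    else as.matrix(x)
  if (anyNA(geno)) stop("missing genotypes present; filter first", call. = FALSE)
  vals <- sort(unique(as.vector(geno)))
  if (length(vals) > 2) stop("genotypes must be biallelic and homozygous", call. = FALSE)
  b <- matrix(as.numeric(geno == vals[length(vals)]), nrow(geno), ncol(geno))
  m <- ncol(geno)
  # fraction of differing markers via inner products of 0/1 indicators
  cross <- tcrossprod(b) # count both-allele1
  ones <- rowSums(b)
  diff_count <- outer(ones, ones, "+") - 2 * cross
  d <- sqrt(pmax(diff_count, 0) / m)
  dimnames(d) <- list(rownames(geno), rownames(geno))
  diag(d) <- 0
  d
}
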