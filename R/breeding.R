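#' Lay out a factorial or diallel cross plan
#'
#' A factorial plan crosses every elite founder with every donor founder
#' (5 x 5 gives 25 crosses); a diallel plan makes all unordered pairwise
#' crosses among the elite founders only, excluding selfs and reciprocals
#' (5 elite gives 10 crosses).
#'
#' @param panel A `founder_panel`.
#' @param scheme `"factorial"` or `"diallel"`.
#' @param n_lines_per_cross DH family size per cross (10 lines for the
#'   250-line factorial, 6 for the 150-line factorial, 25 for the diallel).
#'
#' @return A `cross_plan` tibble with columns `cross_id`, `parent_a`,
#'   `parent_b`, carrying `scheme` and `n_lines_per_cross` as attributes.
#' @examples
#' panel <- simulate_founders(build_map(n_markers = 70), seed = 1)
#' cross_plan(panel, "factorial", 10)
#' @export
cross_plan <- function(panel, scheme = c("factorial", "diallel"),
                       n_lines_per_cross = 10) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(panel, "founder_panel"))
  if (n_lines_per_cross < 1) stop("`n_lines_per_cross` must be >= 1", call. = FALSE)
  elite <- names(panel$pool)[panel$pool == "elite"]
  donor <- names(panel$pool)[panel$pool == "donor"]
  crosses <- switch(scheme,
    factorial = {
      if (length(elite) == 0 || length(donor) == 0) {
        stop("factorial plan needs founders in both pools", call. = FALSE)
      }
      expand.grid(parent_a = elite, parent_b = donor,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 1:2]
    },
    diallel = {
      if (length(elite) < 2) stop("diallel plan needs >= 2 elite founders", call. = FALSE)
      pairs <- utils::combn(elite, 2)
      data.frame(parent_a = pairs[1, ], parent_b = pairs[2, ],
                 stringsAsFactors = FALSE)
    }
  )
  out <- tibble::as_tibble(crosses)
  out <- dplyr::mutate(out, cross_id = sprintf("C%02d", dplyr::row_number()),
                       .before = 1)
  structure(out, scheme = scheme,
            n_lines_per_cross = as.integer(n_lines_per_cross),
            class = c("cross_plan", class(out)))
}

#' @export
print.cross_plan <- function(x, ...) {
  cat(sprintf("<cross_plan> %s: %d crosses x %d DH lines = %d lines\n",
              attr(x, "scheme"), nrow(x), attr(x, "n_lines_per_cross"),
              nrow(x) * attr(x, "n_lines_per_cross")))
  NextMethod()
}

# Recombination fractions between adjacent markers of one chromosome under
# the Haldane map function r = (1 - exp(-2 d)) / 2 (Poisson crossovers, no
# interference). The crossover process is Poisson count-location along the
# chromosome; restricted to the marker loci it is exactly an inhomogeneous
# two-state Markov chain with these switch probabilities, which is how
# gametes are drawn (vectorised over many gametes at once).
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d))

# n gamete origin indicators (0 = first haplotype, 1 = second) at the marker
# loci of one chromosome with positions `pos` (sorted, Morgan).
# Returns n x length(pos) 0/1 matrix.
sample_origins <- function(n, pos) {
  m <- length(pos)
  orig <- matrix(0L, n, m)
  cur <- stats::rbinom(n, 1L, 0.5) # starting parent: fair coin
  orig[, 1] <- cur
  if (m > 1) {
    r <- haldane_r(diff(pos))
    for (j in 2:m) {
      cur <- (cur + stats::rbinom(n, 1L, r[j - 1])) %% 2L
      orig[, j] <- cur
    }
  }
  orig
}

#' Simulate one gamete from a pair of parental haplotypes
#'
#' Draws a single recombinant gamete from an individual carrying haplotypes
#' `hap_a` and `hap_b`. Crossovers follow the Haldane model: on each
#' chromosome the crossover count is Poisson with mean equal to the map
#' length in Morgan, crossover locations are uniform, and there is no
#' interference; the gamete alternates parental origin at crossovers, with
#' the starting parent chosen by a fair coin.
#'
#' @param hap_a,hap_b Allele vectors (one entry per marker of `map`).
#' @param map A `genetic_map`.
#' @return Allele vector of the gamete (same length and type as the inputs).
#' @examples
#' map <- build_map(n_chrom = 1, chrom_length_morgan = 1, n_markers = 10)
#' simulate_gamete(rep(0, 10), rep(1, 10), map)
#' @export
simulate_gamete <- function(hap_a, hap_b, map) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(hap_a) != nrow(map) || length(hap_b) != nrow(map)) {
    stop("haplotype length must equal the marker count of the map", call. = FALSE)
  }
  gam <- hap_a
  for (idx in chrom_index(map)) {
    o <- sample_origins(1, map$pos[idx])[1, ]
    gam[idx][o == 1L] <- hap_b[idx][o == 1L]
  }
  gam
}

# Batch of n DH genotypes from one cross of two homozygous parents.
# The F1 carries one haplotype from each parent; ONE gamete per DH line is
# drawn from the F1 and doubled, so each line is fully homozygous.
# Returns an n x n_markers matrix in -1/+1 coding (allele 0 -> -1).
dh_batch <- function(hap_a, hap_b, map, n) {
  m <- nrow(map)
  out <- matrix(rep(as.integer(hap_a), each = n), n, m)
  hb <- as.integer(hap_b)
  for (idx in chrom_index(map)) {
    seg <- idx[hap_a[idx] != hb[idx]] # only segregating loci can differ
    if (length(seg) == 0) next
    o <- sample_origins(n, map$pos[seg])
    rep_b <- o == 1L
    out[, seg][rep_b] <- matrix(rep(hb[seg], each = n), n)[rep_b]
  }
  out * 2L - 1L
}

#' Derive one DH line from a cross of two homozygous parents
#'
#' Forms the F1 (one haplotype from each parent), draws a single gamete by
#' [simulate_gamete()] and doubles it, so the resulting line is fully
#' homozygous — one meiosis fixes the genotype.
#'
#' @param hap_a,hap_b Parental haplotypes (0/1 alleles; the parents are fully
#'   homozygous so one haplotype defines each).
#' @param map A `genetic_map`.
#' @return Genotype vector in -1/+1 coding (homozygous allele 0 / allele 1).
#' @export
make_dh_line <- function(hap_a, hap_b, map) {
  if (!all(hap_a %in% c(0, 1)) || !all(hap_b %in% c(0, 1))) {
    stop("parents must be fully homozygous with alleles coded 0/1", call. = FALSE)
  }
  drop(dh_batch(hap_a, hap_b, map, 1))
}

#' Simulate a DH population from a founder panel and cross plan
#'
#' Generates `n_lines_per_cross` DH lines from every cross in the plan,
#' cross by cross in plan order (so results are stable under a fixed seed).
#' Each DH line is one doubled gamete of the cross F1.
#'
#' @param panel A `founder_panel`.
#' @param plan A `cross_plan`; all plan parents must exist in the panel.
#' @param seed Optional integer seed.
#'
#' @return A `dh_population`: list with `map`, `genotypes` (lines x markers,
#'   -1/+1 coding) and `lines`, a tibble (`line_id`, `cross_id`, `parent_a`,
#'   `parent_b`) recording each line's cross of origin.
#' @examples
#' panel <- simulate_founders(build_map(n_markers = 70), seed = 1)
#' pop <- simulate_population(panel, cross_plan(panel, "factorial", 10), seed = 2)
#' dim(pop$genotypes)
#' @export
simulate_population <- function(panel, plan, seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"), inherits(plan, "cross_plan"))
  missing_parents <- setdiff(unique(c(plan$parent_a, plan$parent_b)),
                             rownames(panel$haplotypes))
  if (length(missing_parents) > 0) {
    stop("unknown parent id(s): ", paste(missing_parents, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_l <- attr(plan, "n_lines_per_cross")
  map <- panel$map

  # gamete origins are drawn chromosome-wise for the whole population at once
  # (the switch process does not depend on the cross), then translated into
  # alleles cross by cross
  n_c <- nrow(plan)
  n_tot <- n_c * n_l
  m <- nrow(map)
  geno <- matrix(0L, n_tot, m)
  rows_of <- split(seq_len(n_tot), rep(seq_len(n_c), each = n_l))
  ha <- panel$haplotypes[plan$parent_a, , drop = FALSE]
  hb <- panel$haplotypes[plan$parent_b, , drop = FALSE]
  for (idx in chrom_index(map)) {
    orig <- sample_origins(n_tot, map$pos[idx])
    m_c <- length(idx)
    for (k in seq_len(n_c)) {
      gk <- matrix(rep(as.integer(ha[k, idx]), each = n_l), n_l, m_c)
      pick <- orig[rows_of[[k]], , drop = FALSE] == 1L
      gk[pick] <- matrix(rep(as.integer(hb[k, idx]), each = n_l), n_l, m_c)[pick]
      geno[rows_of[[k]], idx] <- gk
    }
  }
  geno <- geno * 2L - 1L
  lines <- tibble::tibble(
    line_id = sprintf("L%04d", seq_len(nrow(geno))),
    cross_id = rep(plan$cross_id, each = n_l),
    parent_a = rep(plan$parent_a, each = n_l),
    parent_b = rep(plan$parent_b, each = n_l)
  )
  rownames(geno) <- lines$line_id
  colnames(geno) <- map$marker_id
  structure(list(map = map, genotypes = geno, lines = lines),
            class = "dh_population")
}

#' @export
print.dh_population <- function(x, ...) {
  cat(sprintf("<dh_population> %d DH lines (%d crosses) x %d markers\n",
              nrow(x$genotypes), dplyr::n_distinct(x$lines$cross_id),
              ncol(x$genotypes)))
  invisible(x)
}

#' DH population genotypes as a tibble
#'
#' @param x A `dh_population`.
#' @param ... Unused.
#' @return One row per line: `line_id`, `cross_id`, `parent_a`, `parent_b`.
#'   Genotypes stay in the matrix; this tidies the line metadata.
#' @export
tidy.dh_population <- function(x, ...) x$lines
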