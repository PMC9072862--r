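#' Build a synthetic genetic map
#'
#' Constructs a multi-chromosome genetic map in Morgan units. The map is the
#' coordinate system for all downstream recombination simulation: marker
#' positions determine the recombination fractions between adjacent loci under
#' the Haldane model.
#'
#' Markers are distributed across chromosomes as evenly as possible (the first
#' `n_markers %% n_chrom` chromosomes receive one extra marker). With
#' `spacing = "uniform"` the markers on each chromosome sit on a regular grid
#' from 0 to the chromosome length; with `spacing = "random"` positions are
#' drawn uniformly and sorted.
#'
#' @param n_chrom Number of chromosomes (default 7, barley-like).
#' @param chrom_length_morgan Chromosome length in Morgan. Either a single
#'   value recycled to all chromosomes or a vector of length `n_chrom`.
#' @param n_markers Total number of markers across the genome; at least two
#'   per chromosome so every chromosome supports recombination.
#' @param spacing `"uniform"` (regular grid) or `"random"` (uniform draws).
#' @param seed Optional integer seed; only consulted for random spacing.
#'
#' @return A `genetic_map`: a tibble with columns `marker_id`, `chrom`, `pos`
#'   (Morgan), sorted by (chrom, pos), carrying the chromosome lengths in
#'   attribute `chrom_len`.
#'
#' @examples
#' map <- build_map(n_chrom = 7, chrom_length_morgan = 1.5, n_markers = 700)
#' chrom_lengths(map)
#' @export
build_map <- function(n_chrom = 7, chrom_length_morgan = 1.5, n_markers = 700,
                      spacing = c("uniform", "random"), seed = NULL) {
  spacing <- match.arg(spacing)
  if (length(n_chrom) != 1 || is.na(n_chrom) || n_chrom < 1) {
    stop("`n_chrom` must be a single integer >= 1", call. = FALSE)
  }
  n_chrom <- as.integer(n_chrom)
  if (any(!is.finite(chrom_length_morgan)) || any(chrom_length_morgan <= 0)) {
    stop("`chrom_length_morgan` must be positive", call. = FALSE)
  }
  if (!length(chrom_length_morgan) %in% c(1L, n_chrom)) {
    stop("`chrom_length_morgan` must have length 1 or `n_chrom`", call. = FALSE)
  }
  len <- rep_len(as.numeric(chrom_length_morgan), n_chrom)
  if (length(n_markers) != 1 || is.na(n_markers) || n_markers < 2 * n_chrom) {
    stop("`n_markers` must be at least 2 per chromosome", call. = FALSE)
  }
  n_markers <- as.integer(n_markers)

  # even split: first (n_markers %% n_chrom) chromosomes get one extra marker
  per_chrom <- rep(n_markers %/% n_chrom, n_chrom) +
    rep(c(1L, 0L), c(n_markers %% n_chrom, n_chrom - n_markers %% n_chrom))

  if (spacing == "random" && !is.null(seed)) set.seed(as.integer(seed))
  pos <- lapply(seq_len(n_chrom), function(k) {
    m <- per_chrom[k]
    if (spacing == "uniform") seq(0, len[k], length.out = m) else sort(stats::runif(m, 0, len[k]))
  })

  map <- tibble::tibble(
    chrom = rep(seq_len(n_chrom), per_chrom),
    pos = unlist(pos)
  )
  map <- dplyr::mutate(map,
    marker_id = sprintf("M%d_%03d", .data$chrom, stats::ave(.data$pos, .data$chrom, FUN = seq_along)),
    .before = 1
  )
  new_genetic_map(map, len)
}

new_genetic_map <- function(markers, chrom_len) {
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(markers)))
  names(chrom_len) <- as.character(seq_along(chrom_len))
  out <- tibble::as_tibble(markers[, c("marker_id", "chrom", "pos")])
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  validate_genetic_map(out, chrom_len)
  structure(out, chrom_len = chrom_len,
            class = c("genetic_map", class(out)))
}

validate_genetic_map <- function(markers, chrom_len) {
  if (anyDuplicated(markers$marker_id)) stop("duplicate marker ids", call. = FALSE)
  cnt <- table(markers$chrom)
  if (any(cnt < 2)) stop("every chromosome needs >= 2 markers", call. = FALSE)
  bad <- markers$pos < 0 | markers$pos > chrom_len[as.character(markers$chrom)] + 1e-12
  if (any(bad)) stop("marker positions outside chromosome bounds", call. = FALSE)
  invisible(markers)
}

#' Chromosome lengths of a genetic map
#'
#' @param map A `genetic_map` from [build_map()].
#' @return Named numeric vector of chromosome lengths in Morgan.
#' @export
chrom_lengths <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  attr(map, "chrom_len")
}

n_markers <- function(map) nrow(map)

#' @export
print.genetic_map <- function(x, ...) {
  len <- attr(x, "chrom_len")
  cat(sprintf("<genetic_map> %d markers on %d chromosomes (%.3g M total)\n",
              nrow(x), length(len), sum(len)))
  NextMethod()
}

# per-chromosome marker row indices, in map order
chrom_index <- function(map) split(seq_len(nrow(map)), map$chrom)
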