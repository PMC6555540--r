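#' Genome map for linkage simulation and mapping
#'
#' A genome map holds the ordered chromosome sizes used to place deletion
#' barcodes along the genome, plus a uniform genetic-map rate converting
#' physical distance (kb) into genetic distance (cM).
#'
#' @param chromosomes character vector of unique chromosome names.
#' @param lengths integer-ish vector of chromosome lengths in bp, same
#'   length as `chromosomes`, all positive.
#' @param cm_per_kb genetic-map rate in centiMorgans per kilobase, applied
#'   uniformly along every chromosome. Default 0.35, a typical
#'   \emph{S. cerevisiae} genome-wide average.
#'
#' @return An object of class `genome_map`: a data frame with columns
#'   `chrom` and `length`, and attribute `cm_per_kb`.
#' @examples
#' gm <- genome_map(c("chrI", "chrII"), c(230218, 813184))
#' genetic_distance(gm, 10000, 150000)
#' @seealso [yeast_genome_map()], [haldane_recomb()]
#' @export
genome_map <- function(chromosomes, lengths, cm_per_kb = 0.35) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths) || length(chromosomes) == 0L)
    stop("'chromosomes' and 'lengths' must be non-empty and of equal length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive")
  if (!is.numeric(cm_per_kb) || length(cm_per_kb) != 1L || cm_per_kb <= 0)
    stop("'cm_per_kb' must be a single positive number")
  gm <- data.frame(chrom = chromosomes, length = lengths,
                   stringsAsFactors = FALSE)
  attr(gm, "cm_per_kb") <- cm_per_kb
  class(gm) <- c("genome_map", "data.frame")
  gm
}

#' The sixteen S. cerevisiae nuclear chromosomes
#'
#' Standard sacCer3 chromosome lengths, used as the default genome for
#' synthetic screens.
#'
#' @inheritParams genome_map
#' @return A [genome_map()] with 16 chromosomes (~12.07 Mb).
#' @export
yeast_genome_map <- function(cm_per_kb = 0.35) {
  genome_map(
    chromosomes = paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII",
                                  "VIII", "IX", "X", "XI", "XII", "XIII",
                                  "XIV", "XV", "XVI")),
    lengths = c(230218, 813184, 316620, 1531933, 576874, 270161, 1090940,
                562643, 439888, 745751, 666816, 1078177, 924431, 784333,
                1091291, 948066),
    cm_per_kb = cm_per_kb
  )
}

#' Haldane map function
#'
#' Converts genetic distance to a recombination fraction assuming no
#' crossover interference: r = (1 - exp(-2 d)) / 2 with d in Morgans.
#' r(0) = 0 and r approaches 1/2 for unlinked loci.
#'
#' @param distance_cM genetic distance(s) in centiMorgans, >= 0.
#' @return Recombination fraction(s) in [0, 0.5).
#' @examples
#' haldane_recomb(c(0, 10, 50))
#' @export
haldane_recomb <- function(distance_cM) {
  if (!is.numeric(distance_cM) || any(!is.finite(distance_cM)) ||
      any(distance_cM < 0))
    stop("'distance_cM' must be finite and non-negative")
  0.5 * (1 - exp(-2 * distance_cM / 100))
}

#' Genetic distance between two physical positions
#'
#' @param genome a [genome_map()].
#' @param pos1,pos2 positions in bp (1-based) on the same chromosome.
#' @return Distance in centiMorgans, `abs(pos1 - pos2) / 1000 * cm_per_kb`.
#' @export
genetic_distance <- function(genome, pos1, pos2) {
  stopifnot(inherits(genome, "genome_map"))
  abs(pos1 - pos2) / 1000 * attr(genome, "cm_per_kb")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("Genome map: %d chromosomes, %.2f Mb, %.2f cM/kb\n",
              nrow(x), sum(x$length) / 1e6, attr(x, "cm_per_kb")))
  invisible(x)
}
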