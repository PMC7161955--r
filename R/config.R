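#' Configuration for a synthetic MAC/germline genome pair
#'
#' Describes the genome that the synthetic-data module emulates: a somatic
#' (MAC) genome into which short, single-copy, TA-bounded IESs are inserted to
#' form the germline (MAC+IES) genome. Defaults are a scaled-down
#' *Paramecium tetraurelia*-like genome: an AT-rich backbone, ~500 IESs with a
#' dominant 26--30 bp first length peak and ~10 bp periodic secondary peaks,
#' and a fraction of IESs clustered into IES-dense regions. IESs inside dense
#' regions draw their lengths from a separate, mildly short-biased peak-weight
#' vector, so that density and short length are correlated the way IES-dense
#' regions are observed to be.
#'
#' @param n_replicons number of replicons (chromosome-scale scaffolds).
#' @param replicon_length length of each MAC replicon in bp.
#' @param n_ies total number of IESs across the genome.
#' @param min_ies_length minimum IES length in bp (>= 26; the shortest
#'   observed IESs define the 26--30 bp first size peak).
#' @param length_peak_weights probability vector over consecutive length-peak
#'   bins for IESs outside dense regions; bin 1 is `[min_ies_length,
#'   min_ies_length + 4]` and later bins advance by `peak_period` bp.
#' @param dense_length_peak_weights same, for IESs placed inside dense
#'   regions.
#' @param peak_period spacing of the length-peak bins beyond the first, bp.
#' @param cluster_fraction probability that an IES is placed inside a dense
#'   region.
#' @param dense_region_count number of designated IES-dense regions.
#' @param dense_region_span span of each dense region in bp.
#' @param gc_content GC fraction of the random genome backbone.
#' @param read_length sequencing read length in nt (used for spacing
#'   constraints and downstream read simulation).
#' @param mean_insert paired-end insert (fragment) length in bp.
#' @param rho fraction of sequenced DNA originating from the new developing
#'   MAC; the remaining `1 - rho` is old-MAC material that always carries the
#'   excised (IES-) form. This is the dilution that makes retention scores
#'   "apparent".
#' @param rng_seed integer seed; identical config + seed gives byte-identical
#'   genomes and reads.
#' @return an object of class `ies_sim_config` (a validated list).
#' @export
simulation_config <- function(n_replicons = 2,
                              replicon_length = 250000,
                              n_ies = 500,
                              min_ies_length = 26,
                              length_peak_weights = c(0.25, 0.30, 0.25, 0.20),
                              dense_length_peak_weights = c(0.50, 0.25, 0.15, 0.10),
                              peak_period = 10,
                              cluster_fraction = 0.25,
                              dense_region_count = 8,
                              dense_region_span = 3000,
                              gc_content = 0.28,
                              read_length = 100,
                              mean_insert = 300,
                              rho = 0.5,
                              rng_seed = 1) {
  for (nm in c("n_replicons", "replicon_length", "n_ies", "dense_region_count",
               "dense_region_span", "read_length", "mean_insert", "rng_seed")) {
    if (!.is_count(get(nm)))
      stop(sprintf("'%s' must be a single non-negative integer", nm),
           call. = FALSE)
  }
  if (min_ies_length < 26)
    stop("'min_ies_length' must be >= 26", call. = FALSE)
  .check_weights(length_peak_weights)
  .check_weights(dense_length_peak_weights)
  .check_prob(cluster_fraction, "cluster_fraction")
  .check_prob(gc_content, "gc_content")
  .check_prob(rho, "rho")
  if (mean_insert < read_length)
    stop("'mean_insert' must be >= 'read_length'", call. = FALSE)
  structure(list(
    n_replicons = as.integer(n_replicons),
    replicon_length = as.integer(replicon_length),
    n_ies = as.integer(n_ies),
    min_ies_length = as.integer(min_ies_length),
    length_peak_weights = length_peak_weights,
    dense_length_peak_weights = dense_length_peak_weights,
    peak_period = as.integer(peak_period),
    cluster_fraction = cluster_fraction,
    dense_region_count = as.integer(dense_region_count),
    dense_region_span = as.integer(dense_region_span),
    gc_content = gc_content,
    read_length = as.integer(read_length),
    mean_insert = as.integer(mean_insert),
    rho = rho,
    rng_seed = as.integer(rng_seed)
  ), class = "ies_sim_config")
}

.check_weights <- function(w) {
  if (!is.numeric(w) || length(w) < 1L || anyNA(w) || any(w < 0))
    stop("peak weights must be a non-negative numeric vector", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("peak weights must sum to 1 (within 1e-9)", call. = FALSE)
  invisible(w)
}

#' @export
print.ies_sim_config <- function(x, ...) {
  cat(sprintf(
    "ies_sim_config: %d replicon(s) x %d bp, %d IESs (cluster fraction %.2f,
 %d dense regions x %d bp), reads 2x%d nt, insert %d bp, rho = %.2f, seed %d\n",
    x$n_replicons, x$replicon_length, x$n_ies, x$cluster_fraction,
    x$dense_region_count, x$dense_region_span, x$read_length, x$mean_insert,
    x$rho, x$rng_seed))
  invisible(x)
}
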