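#' Sample IES lengths from a mixture over periodic size-peak bins
#'
#' IES lengths fall into discrete size peaks: the first peak spans
#' `min_length` to `min_length + 4` bp (26--30 bp by default) and subsequent
#' peaks advance by `peak_period` bp. Lengths are drawn by choosing a peak
#' bin with probability `peak_weights` and then uniformly within the bin.
#'
#' @param n number of lengths to draw.
#' @param peak_weights probability vector over consecutive bins (sums to 1).
#' @param rng_seed optional integer seed for a self-contained reproducible
#'   draw; if `NULL`, the current RNG stream is used.
#' @param min_length first-peak lower bound, bp.
#' @param peak_period bin spacing beyond the first peak, bp.
#' @return integer vector of `n` lengths.
#' @export
sample_ies_lengths <- function(n, peak_weights, rng_seed = NULL,
                               min_length = 26, peak_period = 10) {
  if (!.is_count(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  .check_weights(peak_weights)
  draw <- function() {
    if (n == 0L) return(integer(0))
    bin <- sample.int(length(peak_weights), n, replace = TRUE,
                      prob = peak_weights)
    lo <- min_length + (bin - 1L) * peak_period
    as.integer(lo + sample.int(5L, n, replace = TRUE) - 1L)
  }
  if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
}

.random_dna <- function(n, gc) {
  if (n == 0L) return("")
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  paste(base, collapse = "")
}

#' Generate a matched MAC / germline genome pair with annotated IESs
#'
#' Builds a random MAC genome, places `n_ies` insertion points on it (a
#' `cluster_fraction` share inside designated dense regions, the rest spaced
#' at least two read lengths apart), and inserts a TA-initial IES sequence at
#' each point to produce the germline genome. The MAC carries its own `TA` at
#' every insertion point, so precise excision of an IES (removing the IES
#' sequence, which itself starts with `TA`) leaves exactly one TA behind:
#' `germline = MAC[0:p] + IES + MAC[p:]` with `MAC[p:p+2] == "TA"`.
#'
#' @param config an [simulation_config()] object.
#' @return a list of class `ies_genome_pair` with elements `mac` and
#'   `germline` ([Biostrings::DNAStringSet]), `annotations` (data.frame with
#'   columns `ies_id`, `replicon`, `mac_position` (0-based insertion offset),
#'   `germline_start` (0-based), `length`, `sequence`, `in_dense_region`),
#'   `dense_regions` and the `config`.
#' @export
generate_genome_pair <- function(config) {
  stopifnot(inherits(config, "ies_sim_config"))
  withr::with_seed(config$rng_seed, .generate_genome_pair_impl(config))
}

.generate_genome_pair_impl <- function(cfg) {
  n_rep <- cfg$n_replicons
  L <- cfg$replicon_length
  rep_names <- sprintf("scaffold_%d", seq_len(n_rep))

  # split IES and dense-region counts across replicons
  n_per_rep <- diff(round(seq(0, cfg$n_ies, length.out = n_rep + 1)))
  dense_per_rep <- diff(round(seq(0, cfg$dense_region_count,
                                  length.out = n_rep + 1)))

  margin <- 2L * cfg$read_length + cfg$mean_insert
  min_gap_sparse <- 2L * cfg$read_length
  min_gap_dense <- 50L

  mac <- character(n_rep)
  germ <- character(n_rep)
  ann_list <- vector("list", n_rep)
  dense_list <- vector("list", n_rep)

  for (ri in seq_len(n_rep)) {
    n_ies_rep <- n_per_rep[ri]
    n_dense <- dense_per_rep[ri]
    span <- cfg$dense_region_span

    if (L < 2L * margin + n_dense * (span + min_gap_sparse) +
          n_ies_rep * min_gap_dense)
      stop("infeasible packing: replicon_length too small for the requested ",
           "IES count, spacing and dense regions", call. = FALSE)

    # place non-overlapping dense regions
    regions <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(regions) < n_dense) {
      s <- sample.int(L - 2L * margin - span, 1L) + margin
      ok <- nrow(regions) == 0L ||
        all(s > regions[, 2] + min_gap_sparse | s + span <
              regions[, 1] - min_gap_sparse)
      if (ok) regions <- rbind(regions, c(s, s + span))
      tries <- tries + 1L
      if (tries > 1000L * max(1L, n_dense))
        stop("infeasible packing: could not place dense regions",
             call. = FALSE)
    }
    if (n_dense > 0L) regions <- regions[order(regions[, 1]), , drop = FALSE]

    n_clustered <- if (n_dense > 0L)
      round(cfg$cluster_fraction * n_ies_rep) else 0L
    n_sparse <- n_ies_rep - n_clustered

    in_dense_region <- function(p) {
      n_dense > 0L && any(p >= regions[, 1] & p <= regions[, 2])
    }
    near_dense_region <- function(p) {
      n_dense > 0L && any(p >= regions[, 1] - min_gap_sparse &
                            p <= regions[, 2] + min_gap_sparse)
    }

    pos <- integer(0)
    dense_flag <- logical(0)
    place <- function(candidate, gap_ok) {
      if (length(pos) == 0L || gap_ok(candidate)) {
        pos <<- c(pos, candidate)
        dense_flag <<- c(dense_flag, in_dense_region(candidate))
        TRUE
      } else FALSE
    }

    tries <- 0L
    max_tries <- 500L * max(1L, n_ies_rep)
    while (sum(dense_flag) < n_clustered) {
      reg <- regions[sample.int(n_dense, 1L), ]
      cand <- sample.int(reg[2] - reg[1] + 1L, 1L) + reg[1] - 1L
      place(cand, function(p) all(abs(pos - p) >= min_gap_dense))
      tries <- tries + 1L
      if (tries > max_tries)
        stop("infeasible packing: could not place clustered IESs",
             call. = FALSE)
    }
    tries <- 0L
    while (length(pos) < n_ies_rep) {
      cand <- sample.int(L - 2L * margin, 1L) + margin
      if (!near_dense_region(cand))
        place(cand, function(p) all(abs(pos - p) >= min_gap_sparse))
      tries <- tries + 1L
      if (tries > max_tries)
        stop("infeasible packing: could not place isolated IESs",
             call. = FALSE)
    }

    ord <- order(pos)
    pos <- pos[ord]
    dense_flag <- dense_flag[ord]

    # lengths: dense-region IESs use the (short-biased) dense weights
    len <- integer(n_ies_rep)
    if (any(dense_flag))
      len[dense_flag] <- sample_ies_lengths(
        sum(dense_flag), cfg$dense_length_peak_weights,
        min_length = cfg$min_ies_length, peak_period = cfg$peak_period)
    if (any(!dense_flag))
      len[!dense_flag] <- sample_ies_lengths(
        sum(!dense_flag), cfg$length_peak_weights,
        min_length = cfg$min_ies_length, peak_period = cfg$peak_period)

    mac_seq <- .random_dna(L, cfg$gc_content)
    # the MAC carries a TA at every insertion point
    for (p in pos) substr(mac_seq, p + 1L, p + 2L) <- "TA"

    ies_seq <- vapply(len, function(l)
      paste0("TA", .random_dna(l - 2L, cfg$gc_content)), character(1))

    # germline: interleave MAC segments with IES sequences
    cuts <- c(0L, pos, L)
    segs <- substring(mac_seq, head(cuts, -1L) + 1L, cuts[-1L])
    germ_seq <- paste0(paste0(segs[-length(segs)], ies_seq, collapse = ""),
                       segs[length(segs)])

    g_start <- pos + c(0L, cumsum(len)[-n_ies_rep])
    ann_list[[ri]] <- data.frame(
      ies_id = sprintf("IES_%s_%07d", rep_names[ri], pos + 1L),
      replicon = rep_names[ri],
      mac_position = as.integer(pos),
      germline_start = as.integer(g_start),
      length = as.integer(len),
      sequence = ies_seq,
      in_dense_region = dense_flag,
      stringsAsFactors = FALSE)
    dense_list[[ri]] <- if (n_dense > 0L)
      data.frame(replicon = rep_names[ri], start = as.integer(regions[, 1]),
                 end = as.integer(regions[, 2]))
    else
      data.frame(replicon = character(0), start = integer(0),
                 end = integer(0))
    mac[ri] <- mac_seq
    germ[ri] <- germ_seq
  }

  out <- list(
    mac = Biostrings::DNAStringSet(setNames(mac, rep_names)),
    germline = Biostrings::DNAStringSet(setNames(germ, rep_names)),
    annotations = do.call(rbind, ann_list),
    dense_regions = do.call(rbind, dense_list),
    config = cfg)
  class(out) <- "ies_genome_pair"
  out
}

#' @export
print.ies_genome_pair <- function(x, ...) {
  cat(sprintf("ies_genome_pair: %d replicon(s), MAC %d bp, germline %d bp, %d IESs\n",
              length(x$mac), sum(Biostrings::width(x$mac)),
              sum(Biostrings::width(x$germline)), nrow(x$annotations)))
  invisible(x)
}

#' Excise all annotated IESs from a germline genome
#'
#' Removes every annotated IES sequence from the germline; by construction
#' this must reproduce the MAC genome exactly (the round-trip invariant of
#' the genome generator).
#'
#' @param germline [Biostrings::DNAStringSet] germline (MAC+IES) genome.
#' @param annotations IES annotation data.frame (see
#'   [generate_genome_pair()]).
#' @return [Biostrings::DNAStringSet] with the IESs removed.
#' @export
excise_ies <- function(germline, annotations) {
  out <- setNames(character(length(germline)), names(germline))
  for (rn in names(germline)) {
    g <- as.character(germline[[rn]])
    a <- annotations[annotations$replicon == rn, , drop = FALSE]
    if (nrow(a) == 0L) { out[rn] <- g; next }
    a <- a[order(a$germline_start), , drop = FALSE]
    keep_start <- c(0L, a$germline_start + a$length)
    keep_end <- c(a$germline_start, nchar(g))
    out[rn] <- paste(substring(g, keep_start + 1L, keep_end), collapse = "")
  }
  Biostrings::DNAStringSet(out)
}

.validate_annotations <- function(mac, germline, annotations,
                                  min_ies_length = 26L) {
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (substr(a$sequence, 1L, 2L) != "TA")
      stop(sprintf("IES '%s': germline sequence does not start with TA",
                   a$ies_id), call. = FALSE)
    if (nchar(a$sequence) != a$length || a$length < min_ies_length)
      stop(sprintf("IES '%s': length field inconsistent with sequence",
                   a$ies_id), call. = FALSE)
    m <- as.character(mac[[a$replicon]])
    if (substr(m, a$mac_position + 1L, a$mac_position + 2L) != "TA")
      stop(sprintf("IES '%s': MAC lacks TA at insertion point %d",
                   a$ies_id, a$mac_position), call. = FALSE)
    g <- as.character(germline[[a$replicon]])
    if (substr(g, a$germline_start + 1L, a$germline_start + a$length) !=
          a$sequence)
      stop(sprintf("IES '%s': germline sequence mismatch at %d",
                   a$ies_id, a$germline_start), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign per-IES retention probabilities for an experimental condition
#'
#' The retention probability `r` of an IES is the probability that a copy of
#' its locus in the new developing MAC still carries the IES (excision
#' failed). Conditions are modelled as: `all_retained` (complete knockdown of
#' the excision machinery, every `r = 1`), `none_retained` (control, every
#' `r = 0`), `uniform` (a common `r` for all IESs), or `feature_logistic`,
#' where `r_i = plogis(b0 + b_len * [length_i <= 30] + b_dens * density_i)`
#' captures retention that favors short IESs in IES-dense regions.
#'
#' @param annotations IES annotation data.frame.
#' @param densities named vector of neighbor densities (see
#'   [neighbor_density()]); required for `feature_logistic`.
#' @param model one of `"uniform"`, `"all_retained"`, `"none_retained"`,
#'   `"feature_logistic"`.
#' @param r common retention probability for `model = "uniform"`.
#' @param b0,b_len,b_dens logistic coefficients for `feature_logistic`.
#' @param rng_seed kept for interface symmetry; the implemented models are
#'   deterministic functions of the annotations.
#' @return named numeric vector of retention probabilities (names `ies_id`).
#' @export
assign_retention <- function(annotations, densities = NULL,
                             model = c("uniform", "all_retained",
                                       "none_retained", "feature_logistic"),
                             r = 0.5, b0 = 0, b_len = 0, b_dens = 0,
                             rng_seed = NULL) {
  model <- match.arg(model)
  ids <- annotations$ies_id
  ret <- switch(model,
    all_retained = rep(1, length(ids)),
    none_retained = rep(0, length(ids)),
    uniform = {
      .check_prob(r, "r")
      rep(r, length(ids))
    },
    feature_logistic = {
      if (is.null(densities) || !all(ids %in% names(densities)))
        stop("feature_logistic requires 'densities' covering every ies_id",
             call. = FALSE)
      d <- densities[ids]
      stats::plogis(b0 + b_len * (annotations$length <= 30) + b_dens * d)
    })
  setNames(as.numeric(ret), ids)
}

#' Bundle a retention map and an old/new MAC mixture fraction
#'
#' @param retention named numeric vector in `[0, 1]` (names `ies_id`).
#' @param rho fraction of junction-covering DNA from the new developing MAC;
#'   `1 - rho` is old-MAC material, which is always IES-.
#' @return a list of class `ies_truth`.
#' @export
simulation_truth <- function(retention, rho) {
  if (is.null(names(retention)) || anyNA(retention) ||
      any(retention < 0 | retention > 1))
    stop("'retention' must be a named vector with values in [0, 1]",
         call. = FALSE)
  .check_prob(rho, "rho")
  structure(list(retention = retention, rho = rho), class = "ies_truth")
}
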