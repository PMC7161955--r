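#' Neighbor density of IES insertion points
#'
#' For each IES, the number of other IESs whose MAC insertion point lies
#' strictly within `window` bp on either side of the focal insertion point on
#' the same replicon. Density is symmetric: *i* counts *j* exactly when *j*
#' counts *i*.
#'
#' @param annotations IES annotation data.frame (needs `ies_id`, `replicon`,
#'   `mac_position`). Duplicate insertion points on a replicon are an error
#'   (IESs are single-copy).
#' @param window distance cutoff in bp (strict `<`), default 1000.
#' @return named integer vector of densities (names `ies_id`).
#' @export
neighbor_density <- function(annotations, window = 1000) {
  out <- integer(nrow(annotations))
  names(out) <- annotations$ies_id
  for (rn in unique(annotations$replicon)) {
    sel <- which(annotations$replicon == rn)
    p <- annotations$mac_position[sel]
    if (anyDuplicated(p))
      stop(sprintf("duplicate IES insertion point on '%s': IESs are single-copy",
                   rn), call. = FALSE)
    sp <- sort(p)
    # others with |delta| < window: indices in (p - window, p + window)
    hi <- findInterval(p + window - 1L, sp)
    lo <- findInterval(p - window, sp)
    out[sel] <- hi - lo - 1L  # exclude self
  }
  out
}

#' Density-class enrichment of a retained IES set
#'
#' Classifies IESs into neighbor-density classes (`0, 1, ..., max_class - 1`
#' and a top class `>= max_class`) and compares the class composition of a
#' retained set against the IES universe: the enrichment index of a class is
#' `EI = log2(f_retained / f_universe)`, undefined (`NA`) when either
#' fraction is zero.
#'
#' @param retained_ids character vector of retained IES ids (subset of the
#'   universe).
#' @param annotations the IES universe annotation data.frame.
#' @param profile named density vector from [neighbor_density()].
#' @param max_class densities `>= max_class` are pooled into the top class.
#' @return data.frame with one row per density class: `class`, `n_retained`,
#'   `n_universe`, `f_retained`, `f_universe`, `enrichment_index`.
#' @export
enrichment_index <- function(retained_ids, annotations, profile,
                             max_class = 8) {
  ids <- annotations$ies_id
  if (!all(retained_ids %in% ids))
    stop("retained ids absent from the universe: ",
         paste(head(setdiff(retained_ids, ids), 5), collapse = ", "),
         call. = FALSE)
  d <- profile[ids]
  cls_levels <- c(as.character(seq.int(0L, max_class - 1L)),
                  paste0(">=", max_class))
  cls <- ifelse(d >= max_class, paste0(">=", max_class), as.character(d))
  cls <- factor(cls, levels = cls_levels)
  n_univ <- as.integer(table(cls))
  n_ret <- as.integer(table(cls[ids %in% retained_ids]))
  f_univ <- n_univ / sum(n_univ)
  f_ret <- if (length(retained_ids)) n_ret / sum(n_ret) else rep(NA_real_,
                                                                 length(n_ret))
  ei <- ifelse(f_ret > 0 & f_univ > 0, log2(f_ret / f_univ), NA_real_)
  data.frame(class = cls_levels, n_retained = n_ret, n_universe = n_univ,
             f_retained = f_ret, f_universe = f_univ, enrichment_index = ei,
             stringsAsFactors = FALSE)
}

#' Length-peak fraction and cumulative length distribution
#'
#' @param lengths IES lengths in bp.
#' @param first_peak closed interval of the first size peak, bp.
#' @param max_length optional upper cutoff: only IESs shorter than
#'   `max_length` enter the statistics.
#' @return list with `peak_fraction` (share of lengths inside `first_peak`;
#'   `NA` with `empty = TRUE` for an empty set), `cumulative` (an [ecdf()]),
#'   and `n`.
#' @export
length_stats <- function(lengths, first_peak = c(26, 30),
                         max_length = NULL) {
  if (!is.null(max_length)) lengths <- lengths[lengths < max_length]
  if (length(lengths) == 0L)
    return(list(peak_fraction = NA_real_, cumulative = NULL, n = 0L,
                empty = TRUE))
  list(peak_fraction = mean(lengths >= first_peak[1] &
                              lengths <= first_peak[2]),
       cumulative = stats::ecdf(lengths),
       n = length(lengths), empty = FALSE)
}

#' Random IES sample matched to a reference set
#'
#' Draws, without replacement from the universe, a random sample with the
#' same stratum composition as a reference set: strata are exact length in bp
#' (`match_on = "length"`) or the exact neighbor-density count
#' (`match_on = "density"`). Per stratum the sample takes as many members as
#' the reference holds; when the universe holds fewer, all available members
#' are taken, so the sample can be slightly smaller than the reference.
#'
#' @param annotations the IES universe annotation data.frame.
#' @param reference_ids ids of the reference set (non-empty, subset of the
#'   universe).
#' @param match_on `"length"` or `"density"`.
#' @param profile named density vector (required for `match_on = "density"`).
#' @param rng_seed integer seed; same seed reproduces the sample exactly.
#' @return a list of class `ies_matched_sample`: `ids`, `match_on`,
#'   `requested` and `obtained` per-stratum counts, `rng_seed`.
#' @export
matched_random_sample <- function(annotations, reference_ids,
                                  match_on = c("length", "density"),
                                  profile = NULL, rng_seed = 1) {
  match_on <- match.arg(match_on)
  if (length(reference_ids) == 0L)
    stop("empty reference set", call. = FALSE)
  ids <- annotations$ies_id
  if (!all(reference_ids %in% ids))
    stop("reference ids absent from the universe", call. = FALSE)
  strata <- if (match_on == "length") {
    setNames(annotations$length, ids)
  } else {
    if (is.null(profile))
      stop("'profile' is required for match_on = \"density\"", call. = FALSE)
    profile[ids]
  }
  ref_tab <- table(strata[reference_ids])
  sampled <- withr::with_seed(rng_seed, {
    unlist(lapply(names(ref_tab), function(s) {
      pool <- ids[strata[ids] == as.numeric(s)]
      take <- min(ref_tab[[s]], length(pool))
      pool[sample.int(length(pool), take)]
    }), use.names = FALSE)
  })
  obtained <- table(strata[sampled])
  structure(list(ids = sampled, match_on = match_on,
                 requested = ref_tab, obtained = obtained,
                 rng_seed = rng_seed),
            class = "ies_matched_sample")
}

#' @export
print.ies_matched_sample <- function(x, ...) {
  cat(sprintf(
    "ies_matched_sample: %d IESs matched on %s over %d strata (requested %d)\n",
    length(x$ids), x$match_on, length(x$requested), sum(x$requested)))
  invisible(x)
}

#' Overlap of two IES sets
#'
#' @param set_a,set_b character vectors of IES ids (de-duplicated).
#' @return list with `n_a`, `n_b`, `n_intersect`, and the overlap fractions
#'   `frac_a = |A n B| / |A|`, `frac_b = |A n B| / |B|` (`NA` for an empty
#'   set).
#' @export
set_overlap <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  n_int <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_intersect = n_int,
       frac_a = if (length(a)) n_int / length(a) else NA_real_,
       frac_b = if (length(b)) n_int / length(b) else NA_real_)
}

#' Spearman correlation of replicate retention scores
#'
#' Rank correlation (average ranks for ties) of per-IES scores between two
#' replicates, computed on the IESs with a defined score in both.
#'
#' @param scores_a,scores_b named numeric vectors (names `ies_id`), e.g. the
#'   `irs` column of [count_and_score()] named by `ies_id`.
#' @return list with `rho` (`NA` with `flagged = TRUE` when fewer than 3
#'   shared defined scores) and `n`, the number of IESs used.
#' @export
replicate_correlation <- function(scores_a, scores_b) {
  shared <- intersect(names(scores_a), names(scores_b))
  ok <- shared[is.finite(scores_a[shared]) & is.finite(scores_b[shared])]
  if (length(ok) < 3L)
    return(list(rho = NA_real_, n = length(ok), flagged = TRUE))
  list(rho = stats::cor(scores_a[ok], scores_b[ok], method = "spearman"),
       n = length(ok), flagged = FALSE)
}
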