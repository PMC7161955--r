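#' Expected apparent retention score under old-MAC dilution
#'
#' With a fraction `rho` of junction-covering DNA from the new developing MAC
#' and a per-locus retention probability `r`, the expected fraction of IES+
#' molecules is `rho * r / (rho * r + rho * (1 - r) + (1 - rho)) = rho * r`:
#' old-MAC material (always IES-) dilutes the score, which is why observed
#' scores are "apparent" (IRS_app). This closed form holds in the
#' symmetric-catchment limit, where an IES+ and an IES- molecule are equally
#' likely to yield a classifiable read pair. With the package's junction
#' probes the IES+ catchment is somewhat larger (two boundary windows against
#' one junction window); `catchment_ratio` generalizes the expectation to
#' `k * rho * r / (k * rho * r + 1 - rho * r)` with
#' `k = c_plus / c_minus` from [vote_catchment()].
#'
#' The inverse estimator is [estimate_retention()]; in the symmetric limit it
#' reduces to `r_hat = min(1, irs / rho)`.
#'
#' @param r retention probability in `[0, 1]` (vectorized).
#' @param rho new-MAC fraction in `[0, 1]`.
#' @param catchment_ratio IES+/IES- vote catchment ratio `k` (default 1, the
#'   symmetric limit).
#' @return expected apparent IRS.
#' @export
expected_apparent_irs <- function(r, rho, catchment_ratio = 1) {
  if (anyNA(r) || any(r < 0 | r > 1))
    stop("'r' must be in [0, 1]", call. = FALSE)
  .check_prob(rho, "rho")
  if (any(catchment_ratio <= 0))
    stop("'catchment_ratio' must be positive", call. = FALSE)
  x <- rho * r
  catchment_ratio * x / (catchment_ratio * x + 1 - x)
}

#' Vote catchments of the junction probes for one IES
#'
#' Enumerates every fragment start position around an interior IES locus and
#' counts how many yield an IES+ vote from a retained template (`c_plus`:
#' either mate covers a boundary with `min_overlap` bases on each side,
#' counted once per fragment) and how many yield an IES- vote from an excised
#' template (`c_minus`: either mate covers the junction TA with `min_overlap`
#' bases on each side). For short IESs the two boundary windows merge inside
#' a single read, so `c_plus < 2 * c_minus` but `c_plus > c_minus`: the
#' ratio `c_plus / c_minus` quantifies how much raw counts over-represent the
#' IES+ form.
#'
#' @param ies_length IES length in bp (vectorized).
#' @param read_length read length in nt.
#' @param mean_insert fragment length in bp.
#' @param min_overlap minimum overlap on each side of a junction/boundary.
#' @return data.frame with `ies_length`, `c_plus`, `c_minus`, `ratio`.
#' @export
vote_catchment <- function(ies_length, read_length, mean_insert,
                           min_overlap = 10) {
  one <- function(L) {
    m <- min_overlap
    rl <- read_length
    F <- mean_insert
    # template coordinates with the IES (retained form) at [0, L);
    # excised form: junction TA at [0, 2)
    covers <- function(s, w_from, w_to) {
      (w_from >= s & w_to <= s + rl) |            # mate 1
        (w_from >= s + F - rl & w_to <= s + F)    # mate 2
    }
    s <- seq.int(-F - rl, L + F + rl)
    plus <- covers(s, -m, m) | covers(s, L - m, L + m)
    minus <- covers(s, -m, m + 2)
    c(c_plus = sum(plus), c_minus = sum(minus))
  }
  cc <- vapply(ies_length, one, c(c_plus = 0L, c_minus = 0L))
  data.frame(ies_length = ies_length,
             c_plus = cc["c_plus", ], c_minus = cc["c_minus", ],
             ratio = cc["c_plus", ] / cc["c_minus", ])
}

#' Estimate true retention from apparent scores
#'
#' Inverts [expected_apparent_irs()]: given an observed apparent score and
#' the new-MAC fraction `rho`, solves for the retention probability and clips
#' to `[0, 1]`. When the read geometry is supplied, the per-IES catchment
#' ratio from [vote_catchment()] corrects for the IES+ over-representation;
#' otherwise the symmetric-limit estimator `min(1, irs / rho)` is used.
#'
#' @param irs observed apparent retention scores (NA propagates).
#' @param rho new-MAC fraction (> 0).
#' @param ies_length optional IES lengths matching `irs`.
#' @param read_length,mean_insert,min_overlap read geometry used for the
#'   catchment correction (all required together with `ies_length`).
#' @return estimated retention probabilities in `[0, 1]`.
#' @export
estimate_retention <- function(irs, rho, ies_length = NULL,
                               read_length = NULL, mean_insert = NULL,
                               min_overlap = 10) {
  if (rho <= 0 || rho > 1)
    stop("'rho' must be in (0, 1]", call. = FALSE)
  if (is.null(ies_length))
    return(.clip01(irs / rho))
  stopifnot(!is.null(read_length), !is.null(mean_insert),
            length(ies_length) == length(irs))
  lens <- unique(ies_length)
  cc <- vote_catchment(lens, read_length, mean_insert, min_overlap)
  k <- setNames(cc$ratio, lens)[as.character(ies_length)]
  x <- irs / (k - irs * (k - 1))
  .clip01(x / rho)
}

#' Call significantly retained IESs against a control condition
#'
#' Per IES, a one-sided Fisher exact test of whether the IES+ proportion in
#' the case condition exceeds the control's, on the 2x2 table of
#' `(ies_plus, ies_minus)` counts, Benjamini-Hochberg corrected across all
#' tested IESs. IESs with fewer than `min_reads` junction-spanning pairs in
#' either condition are not tested (`tested = FALSE`, `NA` p/q-values).
#'
#' @param case,control per-IES count tables from [count_and_score()]; must
#'   cover the same IES set.
#' @param alpha significance level on the adjusted q-values.
#' @param min_reads minimum `ies_plus + ies_minus` in both conditions.
#' @return the merged table with columns `ies_id`, `replicon`, `position`,
#'   case/control counts and scores, `p_value`, `q_value`, `tested`, and
#'   `significant` (`NA` for untested IESs).
#' @export
test_retention <- function(case, control, alpha = 0.05, min_reads = 10) {
  miss_case <- setdiff(control$ies_id, case$ies_id)
  miss_ctrl <- setdiff(case$ies_id, control$ies_id)
  if (length(miss_case) || length(miss_ctrl))
    stop("case and control cover different IES sets; only in case: ",
         paste(head(miss_ctrl, 5), collapse = ", "),
         "; only in control: ", paste(head(miss_case, 5), collapse = ", "),
         call. = FALSE)
  ctrl <- control[match(case$ies_id, control$ies_id), , drop = FALSE]
  out <- data.frame(
    ies_id = case$ies_id, replicon = case$replicon, position = case$position,
    case_plus = case$ies_plus, case_minus = case$ies_minus,
    case_irs = case$irs,
    control_plus = ctrl$ies_plus, control_minus = ctrl$ies_minus,
    control_irs = ctrl$irs,
    stringsAsFactors = FALSE)
  out$tested <- (out$case_plus + out$case_minus >= min_reads) &
    (out$control_plus + out$control_minus >= min_reads)
  out$p_value <- NA_real_
  idx <- which(out$tested)
  out$p_value[idx] <- vapply(idx, function(i) {
    tab <- matrix(c(out$case_plus[i], out$control_plus[i],
                    out$case_minus[i], out$control_minus[i]), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  out$q_value <- NA_real_
  out$q_value[idx] <- stats::p.adjust(out$p_value[idx], method = "BH")
  out$significant <- ifelse(out$tested, out$q_value <= alpha, NA)
  attr(out, "alpha") <- alpha
  attr(out, "min_reads") <- min_reads
  out
}
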