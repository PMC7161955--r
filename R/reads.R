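#' Simulate paired-end reads from an old/new MAC mixture
#'
#' Whole-cell DNA at late autogamy is a mixture: a fraction `rho` of
#' junction-covering material comes from the new developing MAC, in which
#' each IES locus is independently retained with its own probability `r_i`,
#' and the remaining `1 - rho` comes from old-MAC fragments that always carry
#' the excised (IES-) form. Each sequenced fragment picks a template class,
#' realizes the retention state of every IES locus on its replicon (new-MAC
#' templates only), starts uniformly on the realized molecule, and yields an
#' error-free read pair: `read1` from the left fragment end and `read2` as
#' the reverse complement of the right end. Fragment length is fixed at
#' `mean_insert`; the fragment count is set so that mean depth
#' `n_fragments * 2 * read_length / mac_genome_length` matches `coverage`.
#'
#' @param genome an `ies_genome_pair` from [generate_genome_pair()].
#' @param truth an `ies_truth` from [simulation_truth()] (per-IES retention
#'   probabilities plus the new-MAC fraction `rho`).
#' @param coverage target mean sequencing depth (fold).
#' @param read_length read length in nt.
#' @param mean_insert fragment length in bp (must be >= `read_length`).
#' @param rng_seed integer seed; identical inputs + seed reproduce the read
#'   set byte for byte.
#' @return a list of class `ies_read_set`: `read1`, `read2`
#'   ([Biostrings::DNAStringSet]), `provenance` (factor with levels
#'   `old_mac`, `new_excised`, `new_retained`), `replicon`, and the
#'   simulation parameters.
#' @export
simulate_read_pairs <- function(genome, truth, coverage,
                                read_length = genome$config$read_length,
                                mean_insert = genome$config$mean_insert,
                                rng_seed = 1) {
  stopifnot(inherits(genome, "ies_genome_pair"), inherits(truth, "ies_truth"))
  if (!is.numeric(coverage) || coverage <= 0)
    stop("'coverage' must be positive", call. = FALSE)
  if (read_length > mean_insert)
    stop("'read_length' must be <= 'mean_insert'", call. = FALSE)
  ann <- genome$annotations
  if (!all(ann$ies_id %in% names(truth$retention)))
    stop("truth does not cover every annotated IES", call. = FALSE)

  mac_chr <- as.character(genome$mac)
  rep_len <- nchar(mac_chr)
  genome_len <- sum(rep_len)
  n_frag <- round(coverage * genome_len / (2 * read_length))
  if (n_frag < 1) {
    warning("coverage too low: zero fragments simulated")
    empty <- Biostrings::DNAStringSet()
    return(structure(list(read1 = empty, read2 = empty,
                          provenance = factor(character(0),
                                              levels = .prov_levels),
                          replicon = character(0), n_fragments = 0L,
                          read_length = read_length,
                          mean_insert = mean_insert,
                          coverage_target = coverage, rho = truth$rho),
                     class = "ies_read_set"))
  }

  withr::with_seed(rng_seed, {
    rep_idx <- sample.int(length(rep_len), n_frag, replace = TRUE,
                          prob = rep_len)
    is_new <- runif(n_frag) < truth$rho

    frags <- character(n_frag)
    prov <- character(n_frag)
    F <- as.integer(mean_insert)

    for (ri in seq_along(rep_len)) {
      rn <- names(genome$mac)[ri]
      a <- ann[ann$replicon == rn, , drop = FALSE]
      a <- a[order(a$mac_position), , drop = FALSE]
      r_vec <- unname(truth$retention[a$ies_id])

      sel_old <- which(rep_idx == ri & !is_new)
      if (length(sel_old)) {
        starts <- sample.int(rep_len[ri] - F + 1L, length(sel_old),
                             replace = TRUE) - 1L
        frags[sel_old] <- substring(mac_chr[ri], starts + 1L, starts + F)
        prov[sel_old] <- "old_mac"
      }
      sel_new <- which(rep_idx == ri & is_new)
      if (length(sel_new)) {
        res <- .cpp_new_mac_fragments(mac_chr[ri],
                                      as.integer(a$mac_position),
                                      a$sequence, r_vec,
                                      length(sel_new), F)
        frags[sel_new] <- res$fragment
        prov[sel_new] <- ifelse(res$retained_any, "new_retained",
                                "new_excised")
      }
    }

    ids <- sprintf("frag%08d", seq_len(n_frag))
    read1 <- Biostrings::DNAStringSet(setNames(substring(frags, 1L,
                                                         read_length), ids))
    read2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(
      setNames(substring(frags, F - read_length + 1L, F), ids)))
    structure(list(read1 = read1, read2 = read2,
                   provenance = factor(prov, levels = .prov_levels),
                   replicon = names(genome$mac)[rep_idx],
                   n_fragments = as.integer(n_frag),
                   read_length = as.integer(read_length),
                   mean_insert = as.integer(mean_insert),
                   coverage_target = coverage, rho = truth$rho),
              class = "ies_read_set")
  })
}

.prov_levels <- c("old_mac", "new_excised", "new_retained")

#' @export
print.ies_read_set <- function(x, ...) {
  cat(sprintf(
    "ies_read_set: %d pairs of 2x%d nt (insert %d bp), provenance: %s\n",
    x$n_fragments, x$read_length, x$mean_insert,
    paste(sprintf("%s=%d", levels(x$provenance), table(x$provenance)),
          collapse = ", ")))
  invisible(x)
}
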