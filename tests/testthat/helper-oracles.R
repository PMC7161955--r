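# Independent oracles used across the suite. They deliberately avoid the
# package's matching code paths: classification by plain fixed-string grepl,
# density by O(n^2) pairwise distances, catchments by enumerating every
# fragment position on explicitly built template molecules.

.rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Brute-force read-pair classification by substring scan. Mirrors the
# documented vote-resolution contract: one vote per pair per IES, IES+
# boundaries pooled, sign conflict at an IES discards it as ambiguous.
brute_classify <- function(read1, read2, windows) {
  r1 <- as.character(read1)
  r2 <- as.character(read2)
  n <- length(r1)
  votes <- matrix(FALSE, nrow = n, ncol = nrow(windows))
  for (j in seq_len(nrow(windows))) {
    w <- windows$seq[j]
    wrc <- .rc(w)
    votes[, j] <- grepl(w, r1, fixed = TRUE) | grepl(wrc, r1, fixed = TRUE) |
      grepl(w, r2, fixed = TRUE) | grepl(wrc, r2, fixed = TRUE)
  }
  out <- data.frame(pair = integer(0), ies_id = character(0),
                    call = character(0), stringsAsFactors = FALSE)
  amb <- out[, c("pair", "ies_id")]
  for (i in which(rowSums(votes) > 0)) {
    hit <- unique(data.frame(ies_id = windows$ies_id[votes[i, ]],
                             call = windows$call[votes[i, ]],
                             stringsAsFactors = FALSE))
    conflict <- hit$ies_id[duplicated(hit$ies_id)]
    if (length(conflict))
      amb <- rbind(amb, data.frame(pair = i, ies_id = unique(conflict)))
    keep <- hit[!hit$ies_id %in% conflict, , drop = FALSE]
    if (nrow(keep))
      out <- rbind(out, data.frame(pair = i, ies_id = keep$ies_id,
                                   call = keep$call))
  }
  list(votes = out, ambiguous = amb)
}

brute_counts <- function(read1, read2, library) {
  bc <- brute_classify(read1, read2, library$windows)
  ids <- library$annotations$ies_id
  fct <- function(x) factor(x, levels = ids)
  data.frame(
    ies_id = ids,
    ies_plus = as.integer(table(fct(bc$votes$ies_id[bc$votes$call == "IES+"]))),
    ies_minus = as.integer(table(fct(bc$votes$ies_id[bc$votes$call == "IES-"]))),
    ambiguous = as.integer(table(fct(bc$ambiguous$ies_id))),
    stringsAsFactors = FALSE)
}

# O(n^2) neighbor-density oracle
brute_density <- function(annotations, window = 1000) {
  n <- nrow(annotations)
  d <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          annotations$replicon[i] == annotations$replicon[j] &&
          abs(annotations$mac_position[i] - annotations$mac_position[j]) <
            window)
        d[i] <- d[i] + 1L
    }
  }
  setNames(d, annotations$ies_id)
}

# Count template start positions whose read pair votes IES+ / IES- by
# substring scan over explicitly extracted mates.
scan_template_votes <- function(template, windows, read_length, insert) {
  n <- nchar(template)
  starts <- seq_len(n - insert + 1L)
  r1 <- substring(template, starts, starts + read_length - 1L)
  r2 <- substring(template, starts + insert - read_length,
                  starts + insert - 1L)
  plus <- minus <- logical(length(starts))
  for (j in seq_len(nrow(windows))) {
    w <- windows$seq[j]
    wrc <- .rc(w)
    hit <- grepl(w, r1, fixed = TRUE) | grepl(wrc, r1, fixed = TRUE) |
      grepl(w, r2, fixed = TRUE) | grepl(wrc, r2, fixed = TRUE)
    if (windows$call[j] == "IES+") plus <- plus | hit else minus <- minus | hit
  }
  c(plus = sum(plus), minus = sum(minus))
}

# Exhaustive fragment-position enumeration on explicit template molecules of
# a single-IES genome: counts template start positions whose read pair votes
# IES+ (retained template) / IES- (excised template) by substring scan.
enum_catchment <- function(genome, library, read_length, insert) {
  stopifnot(nrow(genome$annotations) == 1L)
  win <- library$windows
  retained <- scan_template_votes(as.character(genome$germline[[1]]), win,
                                  read_length, insert)
  excised <- scan_template_votes(as.character(genome$mac[[1]]), win,
                                 read_length, insert)
  stopifnot(retained["minus"] == 0L, excised["plus"] == 0L)
  list(c_plus = unname(retained["plus"]), c_minus = unname(excised["minus"]))
}

# Same enumeration on synthetic interior templates built from scratch, one
# per IES length: returns the per-copy IES+ and IES- vote catchments.
template_catchments <- function(lengths, read_length, insert,
                                min_overlap = 10, seed = 999) {
  withr::with_seed(seed, {
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                     prob = c(0.36, 0.14, 0.14, 0.36)),
                              collapse = "")
    out <- t(vapply(lengths, function(L) {
      pad <- insert + read_length + 20L
      left <- rand(pad)
      right <- rand(pad)
      ies <- paste0("TA", rand(L - 2L))
      mac <- paste0(left, "TA", right)
      germ <- paste0(left, ies, "TA", right)
      p <- nchar(left)
      m <- min_overlap
      win <- data.frame(
        call = c("IES-", "IES+", "IES+"),
        seq = c(substr(mac, p - m + 1L, p + 2L + m),
                substr(germ, p - m + 1L, p + m),
                substr(germ, p + L - m + 1L, p + L + m)),
        stringsAsFactors = FALSE)
      ret <- scan_template_votes(germ, win, read_length, insert)
      exc <- scan_template_votes(mac, win, read_length, insert)
      c(c_plus = unname(ret["plus"]), c_minus = unname(exc["minus"]))
    }, c(c_plus = 0L, c_minus = 0L)))
    data.frame(ies_length = lengths, c_plus = out[, "c_plus"],
               c_minus = out[, "c_minus"])
  })
}

# expected apparent IRS from enumerated catchments and the mixture weights
enum_expected_irs <- function(r, rho, c_plus, c_minus) {
  p <- rho * r * c_plus
  m <- (1 - rho * r) * c_minus
  p / (p + m)
}

# small genome configurations used across tests
tiny_config <- function(seed, n_ies = 6, replicon_length = 5000,
                        read_length = 50, mean_insert = 140, ...) {
  simulation_config(n_replicons = 1, replicon_length = replicon_length,
                    n_ies = n_ies, dense_region_count = 1,
                    dense_region_span = 800, cluster_fraction = 0.3,
                    read_length = read_length, mean_insert = mean_insert,
                    rng_seed = seed, ...)
}

one_ies_genome <- function(seed, read_length = 100, mean_insert = 300,
                           replicon_length = 4000) {
  cfg <- simulation_config(n_replicons = 1,
                           replicon_length = replicon_length, n_ies = 1,
                           dense_region_count = 0, cluster_fraction = 0,
                           read_length = read_length,
                           mean_insert = mean_insert, rng_seed = seed)
  generate_genome_pair(cfg)
}
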