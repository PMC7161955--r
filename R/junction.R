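#' Build junction probes for IES+/IES- read classification
#'
#' For an IES inserted at MAC offset `p` (0-based, the MAC carrying `TA` at
#' `[p, p+2)`) with germline left boundary `g` and length `L`, the library
#' holds three probes: the excised-junction (IES-) probe
#' `MAC[p - flank_k : p + 2 + flank_k]`, and the two germline boundary (IES+)
#' probes `germline[g - flank_k : g + flank_k]` and
#' `germline[g + L - flank_k : g + L + flank_k]` (0-based half-open,
#' truncated at replicon ends). Classification uses the central core of each
#' probe: `min_overlap` bases on each side of the junction TA or boundary, so
#' a match is a contiguous exact match covering at least `min_overlap` bases
#' on both sides. Core sequences shared by several probes are flagged as
#' collisions.
#'
#' @param mac,germline [Biostrings::DNAStringSet] genomes.
#' @param annotations IES annotation data.frame; validated against both
#'   genomes (an annotation violating the TA convention is an error naming
#'   the IES).
#' @param flank_k probe flank width, bp (default: one read length).
#' @param min_overlap minimum exact overlap on each side of the
#'   junction/boundary, bp.
#' @return a list of class `ies_junction_library` with `probes` (one row per
#'   IES: `minus_probe`, `plus_left_probe`, `plus_right_probe`), the window
#'   (core) table used for matching, flagged `collisions`, and the
#'   annotations.
#' @export
build_junction_library <- function(mac, germline, annotations, flank_k = 100,
                                   min_overlap = 10) {
  if (flank_k < min_overlap)
    stop("'flank_k' must be >= 'min_overlap'", call. = FALSE)
  .validate_annotations(mac, germline, annotations,
                        min_ies_length = min(annotations$length))
  mac_chr <- as.character(mac)
  germ_chr <- as.character(germline)
  a <- annotations
  p <- a$mac_position
  g <- a$germline_start
  L <- a$length
  m <- as.integer(min_overlap)
  k <- as.integer(flank_k)
  mlen <- nchar(mac_chr)[a$replicon]
  glen <- nchar(germ_chr)[a$replicon]

  slice <- function(seqs, from0, to0, maxlen) {
    # 0-based half-open [from0, to0), truncated to the replicon
    substring(seqs, pmax(from0, 0L) + 1L, pmin(to0, maxlen))
  }
  probes <- data.frame(
    ies_id = a$ies_id,
    minus_probe = slice(mac_chr[a$replicon], p - k, p + 2L + k, mlen),
    plus_left_probe = slice(germ_chr[a$replicon], g - k, g + k, glen),
    plus_right_probe = slice(germ_chr[a$replicon], g + L - k, g + L + k, glen),
    stringsAsFactors = FALSE)

  # matching cores; NA when replicon-end truncation cuts into the core
  core <- function(seqs, from0, to0, maxlen) {
    ifelse(from0 >= 0L & to0 <= maxlen,
           substring(seqs, from0 + 1L, to0), NA_character_)
  }
  win <- rbind(
    data.frame(ies_id = a$ies_id, call = "IES-", probe = "minus",
               seq = core(mac_chr[a$replicon], p - m, p + 2L + m, mlen),
               stringsAsFactors = FALSE),
    data.frame(ies_id = a$ies_id, call = "IES+", probe = "plus_left",
               seq = core(germ_chr[a$replicon], g - m, g + m, glen),
               stringsAsFactors = FALSE),
    data.frame(ies_id = a$ies_id, call = "IES+", probe = "plus_right",
               seq = core(germ_chr[a$replicon], g + L - m, g + L + m, glen),
               stringsAsFactors = FALSE))
  truncated <- is.na(win$seq)
  if (any(truncated))
    warning(sprintf("%d probe core(s) truncated at replicon ends are unusable",
                    sum(truncated)))
  win <- win[!truncated, , drop = FALSE]
  collisions <- unique(win$seq[duplicated(win$seq)])
  if (length(collisions))
    warning(sprintf("%d probe core sequence(s) collide between IESs",
                    length(collisions)))

  structure(list(probes = probes, windows = win, collisions = collisions,
                 flank_k = k, min_overlap = m, annotations = a),
            class = "ies_junction_library")
}

#' @export
print.ies_junction_library <- function(x, ...) {
  cat(sprintf(
    "ies_junction_library: %d IESs, flank_k = %d, min_overlap = %d, %d collision(s)\n",
    nrow(x$probes), x$flank_k, x$min_overlap, length(x$collisions)))
  invisible(x)
}

# Match all probe cores (and their reverse complements) against a read set.
# Returns a data.frame(pair, window_row) of raw hits.
.match_windows <- function(reads, win_seqs, chunk = 50000L) {
  n <- length(reads)
  fwd <- Biostrings::DNAStringSet(win_seqs)
  rev <- Biostrings::reverseComplement(fwd)
  all_pat <- c(fwd, rev)
  owner <- rep(seq_along(win_seqs), 2L)
  widths <- Biostrings::width(all_pat)

  hits_pair <- integer(0)
  hits_win <- integer(0)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    pd <- Biostrings::PDict(all_pat[sel])
    for (off in seq.int(0L, n - 1L, by = chunk)) {
      idx <- seq.int(off + 1L, min(off + chunk, n))
      hv <- Biostrings::vwhichPDict(pd, reads[idx])
      ln <- lengths(hv)
      if (any(ln > 0L)) {
        hits_pair <- c(hits_pair, rep(idx, ln))
        hits_win <- c(hits_win, owner[sel][unlist(hv, use.names = FALSE)])
      }
    }
  }
  data.frame(pair = hits_pair, window_row = hits_win)
}

#' Classify read pairs against a junction library
#'
#' A pair votes `IES-` for IES *i* when either mate (or its reverse
#' complement) contains a contiguous exact match spanning the excised
#' junction TA with at least `min_overlap` bases on each side, and `IES+`
#' likewise across either germline boundary. Votes are resolved per pair:
#' at most one vote per pair per IES (the two IES+ boundary probes pool into
#' a single vote), votes for distinct IESs are all kept, and a sign conflict
#' at the same IES (both `IES+` and `IES-`) discards that IES's votes as
#' ambiguous.
#'
#' @param read1,read2 [Biostrings::DNAStringSet] mates (same length, same
#'   order), or an `ies_read_set` passed as `read1`.
#' @param library an `ies_junction_library`.
#' @return a list with `votes` (data.frame `pair`, `ies_id`, `call`),
#'   `ambiguous` (data.frame `pair`, `ies_id` of sign conflicts), `n_pairs`,
#'   and `label`, a per-pair factor in `unassigned` / `unique` / `multi` /
#'   `ambiguous`.
#' @export
classify_read_pairs <- function(read1, read2 = NULL, library) {
  if (inherits(read1, "ies_read_set")) {
    read2 <- read1$read2
    read1 <- read1$read1
  }
  stopifnot(inherits(library, "ies_junction_library"),
            length(read1) == length(read2))
  n <- length(read1)
  win <- library$windows

  hits <- rbind(.match_windows(read1, win$seq),
                .match_windows(read2, win$seq))
  votes <- unique(data.frame(pair = hits$pair,
                             ies_id = win$ies_id[hits$window_row],
                             call = win$call[hits$window_row],
                             stringsAsFactors = FALSE))
  key <- paste(votes$pair, votes$ies_id)
  conflict_keys <- unique(key[duplicated(key)])
  is_conflict <- key %in% conflict_keys
  ambiguous <- unique(votes[is_conflict, c("pair", "ies_id")])
  votes <- votes[!is_conflict, , drop = FALSE]

  label <- rep("unassigned", n)
  vt <- table(factor(votes$pair, levels = seq_len(n)))
  label[vt == 1L] <- "unique"
  label[vt > 1L] <- "multi"
  if (nrow(ambiguous)) label[unique(ambiguous$pair)] <- "ambiguous"

  list(votes = votes, ambiguous = ambiguous, n_pairs = n,
       label = factor(label,
                      levels = c("unassigned", "unique", "multi", "ambiguous")))
}

#' Classify a single read pair
#'
#' Single-pair convenience wrapper around [classify_read_pairs()]. An empty
#' read yields `unassigned`.
#'
#' @param read1,read2 character or [Biostrings::DNAString] mates.
#' @param library an `ies_junction_library`.
#' @return a list with `label` (`"IES+"`/`"IES-"` with `ies_id` when the pair
#'   resolves to a single IES, else `"unassigned"`, `"multi"` or
#'   `"ambiguous"`), `ies_id` and the full `votes` table.
#' @export
classify_read_pair <- function(read1, read2, library) {
  r1 <- Biostrings::DNAStringSet(as.character(read1))
  r2 <- Biostrings::DNAStringSet(as.character(read2))
  res <- classify_read_pairs(r1, r2, library)
  lab <- as.character(res$label[1L])
  if (lab == "unique")
    list(label = res$votes$call[1L], ies_id = res$votes$ies_id[1L],
         votes = res$votes)
  else
    list(label = lab,
         ies_id = if (nrow(res$votes)) res$votes$ies_id else NA_character_,
         votes = res$votes)
}

#' Count IES+/IES- support and compute retention scores
#'
#' Aggregates [classify_read_pairs()] votes over a read set into per-IES
#' counts and apparent retention scores
#' `irs = ies_plus / (ies_plus + ies_minus)` (undefined, `NA`, when no
#' junction-spanning pair was observed).
#'
#' @param reads an `ies_read_set`, or a list with `read1`/`read2`
#'   [Biostrings::DNAStringSet] mates.
#' @param library an `ies_junction_library`.
#' @param condition optional condition label stored with the records.
#' @return data.frame with one row per IES: `ies_id`, `replicon`, `position`
#'   (1-based MAC coordinate of the junction TA), `ies_plus`, `ies_minus`,
#'   `ambiguous`, `irs`.
#' @export
count_and_score <- function(reads, library, condition = NA_character_) {
  res <- classify_read_pairs(reads$read1, reads$read2, library)
  ids <- library$annotations$ies_id
  fct <- function(x) factor(x, levels = ids)
  plus <- as.integer(table(fct(res$votes$ies_id[res$votes$call == "IES+"])))
  minus <- as.integer(table(fct(res$votes$ies_id[res$votes$call == "IES-"])))
  amb <- as.integer(table(fct(res$ambiguous$ies_id)))
  out <- data.frame(
    ies_id = ids,
    replicon = library$annotations$replicon,
    position = library$annotations$mac_position + 1L,
    ies_plus = plus,
    ies_minus = minus,
    ambiguous = amb,
    irs = compute_irs(plus, minus),
    stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  out
}

#' Apparent IES retention score from boundary counts
#'
#' @param ies_plus,ies_minus non-negative read-pair counts.
#' @return `ies_plus / (ies_plus + ies_minus)`, `NA` where the denominator is
#'   zero.
#' @export
compute_irs <- function(ies_plus, ies_minus) {
  if (any(ies_plus < 0 | ies_minus < 0))
    stop("counts must be non-negative", call. = FALSE)
  tot <- ies_plus + ies_minus
  ifelse(tot > 0, ies_plus / tot, NA_real_)
}
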