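#' Normalized identity between two sequences
#'
#' Global (Needleman-Wunsch) alignment with affine gaps; the normalized
#' identity is the number of identically aligned residues divided by the
#' length of the longer input sequence, so trailing unaligned sequence in
#' the longer partner counts against the score. Proteins are scored with
#' BLOSUM62, nucleotides with a +2/-3 match/mismatch matrix.
#'
#' @param seq_a,seq_b Non-empty sequences (strings).
#' @param type `"protein"` or `"dna"`.
#' @return Normalized identity in \[0, 1\].
#' @export
normalized_identity <- function(seq_a, seq_b, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stop("sequences must be non-empty")
  if (type == "protein") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
      type = "global", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5)
  }
  Biostrings::nmatch(aln) / max(nchar(seq_a), nchar(seq_b))
}

#' Mutual best hits between two sequence sets
#'
#' A pair (a, b) is a mutual best hit (MBH) when b is a's unique
#' highest-identity partner and vice versa. Exact ties are broken toward the
#' lexicographically smaller identifier and flagged in the output.
#'
#' @param set_a,set_b Named character vectors of sequences.
#' @param type Passed to [normalized_identity()].
#' @return data.frame with `a`, `b`, `identity`, `tie_broken`.
#' @export
mutual_best_hits <- function(set_a, set_b, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (length(set_a) == 0 || length(set_b) == 0)
    return(data.frame(a = character(), b = character(), identity = numeric(),
                      tie_broken = logical(), stringsAsFactors = FALSE))
  idm <- matrix(0, length(set_a), length(set_b),
                dimnames = list(names(set_a), names(set_b)))
  for (i in seq_along(set_a))
    for (j in seq_along(set_b))
      idm[i, j] <- normalized_identity(set_a[[i]], set_b[[j]], type)
  best_of <- function(scores, ids) {
    mx <- max(scores)
    cand <- ids[scores == mx]
    list(id = sort(cand)[1], tie = length(cand) > 1)
  }
  rows <- list()
  for (i in seq_along(set_a)) {
    ba <- best_of(idm[i, ], colnames(idm))
    bb <- best_of(idm[, ba$id], rownames(idm))
    if (bb$id == rownames(idm)[i]) {
      tie <- ba$tie || bb$tie
      if (tie)
        message("mutual_best_hits: tie broken lexicographically for ",
                rownames(idm)[i], " ~ ", ba$id)
      rows[[length(rows) + 1]] <-
        data.frame(a = rownames(idm)[i], b = ba$id,
                   identity = idm[i, ba$id], tie_broken = tie,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(a = character(), b = character(), identity = numeric(),
                  tie_broken = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Construct an annotation set for name mapping
#'
#' @param loci data.frame with `locus`, `chrom`, `start`, `end`, `strand`
#'   (intervals 1-based inclusive, shared coordinate frame across versions).
#' @param proteins Named list mapping each locus id to a named character
#'   vector of its translated transcript sequences.
#' @param transcripts Optional named list of transcript nucleotide sequences
#'   with the same transcript names as `proteins` (needed for the
#'   UTR-tolerant transcript rule).
#' @return List of class `annotation_set`.
#' @export
annotation_set <- function(loci, proteins, transcripts = NULL) {
  need <- c("locus", "chrom", "start", "end", "strand")
  if (!all(need %in% names(loci)))
    stop("loci must have columns: ", paste(need, collapse = ", "))
  if (!all(loci$locus %in% names(proteins)))
    stop("every locus needs protein sequences")
  structure(list(loci = loci, proteins = proteins,
                 transcripts = transcripts), class = "annotation_set")
}

# Unique same-strand >=1 bp overlaps between two locus tables. A pair
# qualifies only when each partner overlaps exactly one locus of the other
# set (uniqueness in both directions).
.unique_overlaps <- function(old_loci, new_loci) {
  cand <- list()
  for (i in seq_len(nrow(old_loci))) {
    for (j in seq_len(nrow(new_loci))) {
      if (old_loci$chrom[i] == new_loci$chrom[j] &&
          old_loci$strand[i] == new_loci$strand[j] &&
          old_loci$start[i] <= new_loci$end[j] &&
          new_loci$start[j] <= old_loci$end[i]) {
        cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  }
  if (length(cand) == 0)
    return(data.frame(old = character(), new = character(),
                      stringsAsFactors = FALSE))
  ov <- do.call(rbind, cand)
  keep <- !(duplicated(ov[, 1]) | duplicated(ov[, 1], fromLast = TRUE) |
              duplicated(ov[, 2]) | duplicated(ov[, 2], fromLast = TRUE))
  data.frame(old = old_loci$locus[ov[keep, 1]],
             new = new_loci$locus[ov[keep, 2]],
             stringsAsFactors = FALSE)
}

#' Carry locus names forward between annotation versions
#'
#' A new locus inherits an old locus's name when (1) the two loci overlap
#' uniquely (each overlapping exactly one locus of the other version) on the
#' same strand, and (2) at least one pair of their translated transcripts are
#' mutual best hits with normalized identity of at least `min_identity`.
#' New loci that inherit no name receive fresh names from `name_generator`.
#'
#' @param old,new [annotation_set()] objects in a shared coordinate frame.
#' @param min_identity MBH protein identity threshold (inclusive).
#' @param name_generator Function of an index returning a fresh name.
#' @return data.frame with `new_locus`, `name`, `mapped`, `old_locus`,
#'   `identity`.
#' @export
map_locus_names <- function(old, new, min_identity = 0.70,
                            name_generator = function(i)
                              sprintf("novel%04d", i)) {
  ov <- .unique_overlaps(old$loci, new$loci)
  mapped <- stats::setNames(rep(NA_character_, nrow(new$loci)),
                            new$loci$locus)
  ident <- stats::setNames(rep(NA_real_, nrow(new$loci)), new$loci$locus)
  for (r in seq_len(nrow(ov))) {
    mbh <- mutual_best_hits(old$proteins[[ov$old[r]]],
                            new$proteins[[ov$new[r]]], type = "protein")
    if (nrow(mbh) && max(mbh$identity) >= min_identity) {
      mapped[ov$new[r]] <- ov$old[r]
      ident[ov$new[r]] <- max(mbh$identity)
    }
  }
  fresh_i <- 0L
  name <- character(length(mapped))
  for (k in seq_along(mapped)) {
    if (is.na(mapped[k])) {
      fresh_i <- fresh_i + 1L
      name[k] <- name_generator(fresh_i)
    } else {
      name[k] <- mapped[k]
    }
  }
  data.frame(new_locus = names(mapped), name = name,
             mapped = !is.na(mapped), old_locus = unname(mapped),
             identity = unname(ident), stringsAsFactors = FALSE)
}

#' Carry transcript names forward at mapped loci
#'
#' For each mapped locus pair, a new transcript inherits an old transcript's
#' name when either (rule 1) the two proteins are mutual best hits with at
#' least `min_identity` normalized identity, or (rule 2) the proteins reach
#' `min_identity` without being MBHs but the corresponding transcript
#' nucleotide sequences are MBHs at `min_identity` — the case where models
#' differ mainly by UTR addition or extension.
#'
#' @param old,new [annotation_set()] objects (with `transcripts` for rule 2).
#' @param locus_map Output of [map_locus_names()].
#' @param min_identity Identity threshold (default 0.90).
#' @return data.frame with `new_tx`, `old_tx`, `rule` (1, 2 or `NA`).
#' @export
map_transcript_names <- function(old, new, locus_map, min_identity = 0.90) {
  pairs <- locus_map[locus_map$mapped, , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    old_prot <- old$proteins[[pairs$old_locus[r]]]
    new_prot <- new$proteins[[pairs$new_locus[r]]]
    mbh <- mutual_best_hits(old_prot, new_prot, type = "protein")
    used_old <- character(0)
    for (tx in names(new_prot)) {
      hit <- mbh[mbh$b == tx, , drop = FALSE]
      old_tx <- NA_character_
      rule <- NA_integer_
      if (nrow(hit) == 1 && hit$identity >= min_identity) {
        old_tx <- hit$a
        rule <- 1L
      } else if (!is.null(old$transcripts) && !is.null(new$transcripts)) {
        # rule 2: high protein identity without protein MBH, transcript MBH
        prot_id <- vapply(old_prot, normalized_identity, 0, new_prot[[tx]],
                          type = "protein")
        cand <- names(old_prot)[prot_id >= min_identity]
        cand <- setdiff(cand, mbh$a[mbh$b == tx])
        if (length(cand)) {
          tx_mbh <- mutual_best_hits(
            old$transcripts[[pairs$old_locus[r]]],
            new$transcripts[[pairs$new_locus[r]]], type = "dna")
          tx_hit <- tx_mbh[tx_mbh$b == tx & tx_mbh$a %in% cand &
                             tx_mbh$identity >= min_identity, , drop = FALSE]
          if (nrow(tx_hit) == 1) {
            old_tx <- tx_hit$a
            rule <- 2L
          }
        }
      }
      if (!is.na(old_tx) && old_tx %in% used_old) {
        old_tx <- NA_character_  # keep the mapping injective
        rule <- NA_integer_
      }
      if (!is.na(old_tx)) used_old <- c(used_old, old_tx)
      rows[[length(rows) + 1]] <- data.frame(
        new_tx = tx, old_tx = old_tx, rule = rule,
        new_locus = pairs$new_locus[r], old_locus = pairs$old_locus[r],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(new_tx = character(), old_tx = character(),
                  rule = integer(), new_locus = character(),
                  old_locus = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
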