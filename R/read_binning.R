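#' Alignment identity
#'
#' `identity = 1 - mismatched / aln_len`, the per-alignment identity used
#' throughout binning. `aln_len` is the alignment block length (gap columns
#' included).
#'
#' @param mismatched count of mismatching bases (gaps included).
#' @param aln_len alignment length in bases; must be positive.
#' @return identity fraction in \[0, 1\].
#' @export
alignment_identity <- function(mismatched, aln_len) {
  if (any(aln_len <= 0)) stop("'aln_len' must be positive")
  if (any(mismatched < 0 | mismatched > aln_len))
    stop("'mismatched' must lie in [0, aln_len]")
  1 - mismatched / aln_len
}

#' Distance between two alignment intervals on a read
#'
#' `max(0, s2 - e1, s1 - e2)`: the gap between the two mapped intervals,
#' 0 when they overlap. Symmetric in its arguments.
#'
#' @param int1,int2 numeric length-2 vectors `c(start, end)`, 0-based
#'   half-open, on the same read.
#' @return distance in bases.
#' @export
read_pair_distance <- function(int1, int2) {
  max(0, int2[1] - int1[2], int1[1] - int2[2])
}

#' Two-locus assignment rule for a spanning read
#'
#' A read whose alignments to two loci are separated on the read by
#' `D_reads > 0`, with `|D_reads - D_ref| < theta`, is assigned to both loci;
#' otherwise only to the higher-identity locus. Unlinked loci (different
#' chromosomes, `dref = NA`) always resolve to a single locus.
#'
#' @param cand data.frame with two rows and columns `locus`, `read_start`,
#'   `read_end`, `identity` -- the two top loci for the read.
#' @param dref reference distance between the two loci in bases (`NA` if
#'   unlinked).
#' @param theta distance-agreement tolerance in bases (default 2000).
#' @return character vector of one or two locus identifiers.
#' @export
multi_locus_assign <- function(cand, dref, theta = 2000) {
  stopifnot(nrow(cand) == 2L)
  best <- cand$locus[order(-cand$identity, cand$locus)][1L]
  if (is.na(dref)) return(best)
  dreads <- read_pair_distance(c(cand$read_start[1], cand$read_end[1]),
                               c(cand$read_start[2], cand$read_end[2]))
  if (dreads > 0 && abs(dreads - dref) < theta) sort(cand$locus) else best
}

#' Bin reads to gene loci
#'
#' Per read, the identity for each locus is the highest identity over that
#' locus's alleles; the read goes to the argmax locus (lexicographic locus
#' order on exact ties). Reads whose best identity falls below
#' `min_identity` are discarded. When locus reference geometry is available,
#' a read spanning two loci consistent with their reference distance
#' (see [multi_locus_assign()]) is assigned to both.
#'
#' @param alignments alignment data.frame (multiple records per read allowed).
#' @param min_identity identity threshold below which reads are discarded
#'   (default 0.85).
#' @param loci optional locus-definition data.frame with `locus`, `chrom`,
#'   `start`, `end` enabling the two-locus rule.
#' @param theta two-locus distance tolerance in bases (default 2000).
#' @return an object of class `binning_result`: list with `assignments`
#'   (data.frame `read_id`, `locus`, `identity`) and `discarded` (read ids).
#' @export
bin_reads <- function(alignments, min_identity = 0.85, loci = NULL,
                      theta = 2000) {
  if (is.null(alignments) || nrow(alignments) == 0L) {
    return(structure(list(assignments = data.frame(read_id = character(0),
                                                   locus = character(0),
                                                   identity = numeric(0)),
                          discarded = character(0)),
                     class = "binning_result"))
  }
  alignments <- alignments[!is.na(alignments$locus), , drop = FALSE]
  # per (read, locus): best identity and its alignment interval on the read
  key <- paste(alignments$read_id, alignments$locus, sep = "\r")
  ord <- order(key, -alignments$identity, alignments$allele)
  a <- alignments[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$read_id, a$locus, sep = "\r")), , drop = FALSE]
  out <- list(); disc <- character(0)
  for (rid in sort(unique(a$read_id))) {
    ar <- a[a$read_id == rid, , drop = FALSE]
    ar <- ar[order(-ar$identity, ar$locus), , drop = FALSE]
    if (ar$identity[1L] < min_identity) { disc <- c(disc, rid); next }
    assigned <- ar$locus[1L]
    if (!is.null(loci) && nrow(ar) >= 2L && ar$identity[2L] >= min_identity) {
      top2 <- ar[1:2, , drop = FALSE]
      la <- loci[match(top2$locus[1], loci$locus), ]
      lb <- loci[match(top2$locus[2], loci$locus), ]
      if (nrow(la) == 1L && nrow(lb) == 1L) {
        dref <- reference_locus_distance(la, lb)
        assigned <- multi_locus_assign(top2, dref, theta)
      }
    }
    out[[rid]] <- data.frame(read_id = rid, locus = assigned,
                             identity = ar$identity[match(assigned, ar$locus)],
                             stringsAsFactors = FALSE)
  }
  structure(list(assignments = if (length(out)) do.call(rbind, out) else
                   data.frame(read_id = character(0), locus = character(0),
                              identity = numeric(0)),
                 discarded = disc),
            class = "binning_result")
}

#' @export
print.binning_result <- function(x, ...) {
  n_reads <- length(unique(x$assignments$read_id))
  cat(sprintf("Read binning: %d reads assigned over %d loci, %d discarded\n",
              n_reads, length(unique(x$assignments$locus)), length(x$discarded)))
  multi <- sum(table(x$assignments$read_id) > 1L)
  if (multi > 0) cat(sprintf("  %d read(s) assigned to two loci\n", multi))
  invisible(x)
}
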