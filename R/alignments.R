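#' Alignment record dialect
#'
#' All modules exchange alignments as a data.frame with one row per
#' read-vs-allele alignment and columns:
#' `read_id`, `allele`, `locus`, `matched` (matching bases), `mismatched`
#' (mismatching bases, gap columns included), `aln_len` (alignment block
#' length, gaps included), `read_start`/`read_end` and `ref_start`/`ref_end`
#' (0-based half-open), `identity` (`1 - mismatched / aln_len`), `strand`
#' (`"+"`/`"-"`), `cigar` (query-vs-target, on the aligned strand).
#'
#' The identity convention treats gap columns as mismatch bases, matching the
#' alignment-block-length reading of long-read aligner output.
#'
#' @name alignment_records
NULL

new_alignment_record <- function(read_id, allele, locus, matched, mismatched,
                                 aln_len, read_start, read_end, ref_start,
                                 ref_end, strand = "+", cigar = NA_character_) {
  data.frame(read_id = read_id, allele = allele, locus = locus,
             matched = matched, mismatched = mismatched, aln_len = aln_len,
             read_start = read_start, read_end = read_end,
             ref_start = ref_start, ref_end = ref_end,
             identity = ifelse(aln_len > 0, 1 - mismatched / aln_len, NA_real_),
             strand = strand, cigar = cigar, stringsAsFactors = FALSE)
}

#' Local alignment of a read against a target sequence
#'
#' Affine-gap Smith-Waterman (match +2, mismatch -4, gap open -4, gap extend
#' -2; fixed, documented costs). Both strands are tried and the higher-scoring
#' one reported. Returns an alignment record in the package dialect
#' (see [alignment_records]): `aln_len` is the alignment block length
#' including gap columns and `mismatched = aln_len - matched`.
#'
#' @param read read sequence (character scalar).
#' @param target target sequence.
#' @param read_id,allele,locus identifiers copied into the record.
#' @param both_strands also try the reverse complement (default TRUE).
#' @return one-row alignment data.frame.
#' @export
naive_align <- function(read, target, read_id = "read", allele = "allele",
                        locus = NA_character_, both_strands = TRUE) {
  if (!nzchar(read) || !nzchar(target)) stop("empty sequence")
  fwd <- .sw_align_cpp(read, target)
  hit <- fwd; strand <- "+"
  if (both_strands) {
    rc <- revcomp(read)
    rev <- .sw_align_cpp(rc, target)
    if (rev$score > fwd$score) { hit <- rev; strand <- "-" }
  }
  aln_len <- hit$n_match + hit$n_mismatch + hit$n_ins + hit$n_del
  rs <- hit$query_start; re <- hit$query_end
  if (strand == "-") { # report the interval on the original read orientation
    L <- nchar(read)
    tmp <- rs; rs <- L - re; re <- L - tmp
  }
  new_alignment_record(read_id, allele, locus,
                       matched = hit$n_match,
                       mismatched = aln_len - hit$n_match,
                       aln_len = aln_len,
                       read_start = rs, read_end = re,
                       ref_start = hit$target_start, ref_end = hit$target_end,
                       strand = strand, cigar = hit$cigar)
}

#' Align many reads against many alleles
#'
#' Batch alignment with k-mer seeding: the strand of each (read, allele) pair
#' is chosen by shared k-mer count, the alignment diagonal estimated from
#' k-mer hit positions, and a banded Smith-Waterman run around it; pairs with
#' too few seed k-mers fall back to the full dynamic program on both strands.
#' Optionally prescreens allele candidates per read by shared k-mer count to
#' avoid the full cross product.
#'
#' @param reads named character vector of read sequences.
#' @param db `allele_db` or named character vector of allele sequences.
#' @param alleles optional subset of allele names to align against.
#' @param max_candidates when set, each read is aligned only against the
#'   `max_candidates` alleles sharing most k-mers with it.
#' @param k k-mer size for seeding (default 13).
#' @param band banded-alignment half-width in bases (default 150; `NULL`
#'   forces the full dynamic program).
#' @param min_seeds minimum seed k-mers to trust the banded path (default 5).
#' @return alignment data.frame, one row per computed (read, allele) pair.
#' @export
align_reads <- function(reads, db, alleles = NULL, max_candidates = NULL,
                        k = 13L, band = 150L, min_seeds = 5L) {
  if (inherits(db, "allele_db")) {
    seqs <- setNames(db$alleles$sequence, db$alleles$name)
    loci <- setNames(db$alleles$locus, db$alleles$name)
  } else {
    seqs <- db
    loci <- setNames(rep(NA_character_, length(db)), names(db))
  }
  if (!is.null(alleles)) seqs <- seqs[alleles]
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  rc <- revcomp(unname(reads))
  hits_f <- .kmer_share_cpp(unname(reads), unname(seqs), k)
  hits_r <- .kmer_share_cpp(rc, unname(seqs), k)
  hits <- pmax(hits_f, hits_r)
  cand <- NULL
  if (!is.null(max_candidates) && length(seqs) > max_candidates) {
    cand <- lapply(seq_along(reads), function(i)
      order(-hits[i, ])[seq_len(max_candidates)])
  }
  out <- vector("list", length(reads) * 4L)
  n <- 0L
  for (i in seq_along(reads)) {
    targets <- if (is.null(cand)) seq_along(seqs) else cand[[i]]
    for (ti in targets) {
      a <- names(seqs)[ti]
      n <- n + 1L
      if (is.null(band) || hits[i, ti] < min_seeds) {
        out[[n]] <- naive_align(reads[[i]], seqs[[ti]],
                                read_id = names(reads)[i], allele = a,
                                locus = unname(loci[a]))
        next
      }
      strand <- if (hits_f[i, ti] >= hits_r[i, ti]) "+" else "-"
      q <- if (strand == "+") reads[[i]] else rc[[i]]
      dg <- .kmer_diag_cpp(q, seqs[[ti]], k)
      hit <- .sw_align_banded_cpp(q, seqs[[ti]], dg[2], band)
      aln_len <- hit$n_match + hit$n_mismatch + hit$n_ins + hit$n_del
      rs <- hit$query_start; re <- hit$query_end
      if (strand == "-") {
        L <- nchar(reads[[i]])
        tmp <- rs; rs <- L - re; re <- L - tmp
      }
      out[[n]] <- new_alignment_record(
        names(reads)[i], a, unname(loci[a]),
        matched = hit$n_match, mismatched = aln_len - hit$n_match,
        aln_len = aln_len, read_start = rs, read_end = re,
        ref_start = hit$target_start, ref_end = hit$target_end,
        strand = strand, cigar = hit$cigar)
    }
  }
  do.call(rbind, out[seq_len(n)])
}

#' Read alignment records from a PAF file
#'
#' Column mapping (documented dialect): PAF residue matches -> `matched`,
#' alignment block length -> `aln_len`, `mismatched = aln_len - matched`
#' (gap columns counted as mismatch bases).
#'
#' @param path PAF file.
#' @inheritParams parse_allele_name
#' @return alignment data.frame.
#' @export
read_paf <- function(path, family = "HLA") {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   fill = TRUE)[, 1:12]
  names(df) <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
                 "tstart", "tend", "nmatch", "alnlen", "mapq")
  parsed <- parse_allele_name(df$tname, family)
  locus <- vapply(parsed, function(p) if (is.null(p)) NA_character_ else p$locus,
                  character(1))
  new_alignment_record(df$qname, df$tname, locus,
                       matched = df$nmatch,
                       mismatched = df$alnlen - df$nmatch,
                       aln_len = df$alnlen,
                       read_start = df$qstart, read_end = df$qend,
                       ref_start = df$tstart, ref_end = df$tend,
                       strand = df$strand)
}

#' Read alignment records from a SAM file
#'
#' Uses Rsamtools to parse the file; per record, `aln_len` is the CIGAR
#' M+I+D span, `matched = aln_len - NM` (the NM tag counts mismatches plus
#' gap bases, so gaps are treated as mismatch bases, consistent with the PAF
#' dialect).
#'
#' @param path SAM or BAM file.
#' @inheritParams parse_allele_name
#' @return alignment data.frame.
#' @export
read_sam_alignments <- function(path, family = "HLA") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_sam_alignments() requires the Rsamtools package")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar"), tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(x$pos)
  cig <- x$cigar[keep]
  ops <- lapply(cig, cigar_ops)
  span <- function(o, which) sum(o$len[o$op %in% which])
  aln_len <- vapply(ops, span, numeric(1), c("M", "=", "X", "I", "D"))
  ref_len <- vapply(ops, span, numeric(1), c("M", "=", "X", "D", "N"))
  qclip <- vapply(ops, function(o) {
    if (length(o$op) && o$op[1] %in% c("S", "H")) o$len[1] else 0L
  }, numeric(1))
  qlen_aln <- vapply(ops, span, numeric(1), c("M", "=", "X", "I"))
  nm <- x$tag$NM[keep]
  nm[is.na(nm)] <- 0L
  tname <- as.character(x$rname[keep])
  parsed <- parse_allele_name(tname, family)
  locus <- vapply(parsed, function(pp) if (is.null(pp)) NA_character_ else pp$locus,
                  character(1))
  new_alignment_record(x$qname[keep], tname, locus,
                       matched = aln_len - nm,
                       mismatched = nm,
                       aln_len = aln_len,
                       read_start = qclip, read_end = qclip + qlen_aln,
                       ref_start = x$pos[keep] - 1L,
                       ref_end = x$pos[keep] - 1L + ref_len,
                       strand = as.character(x$strand[keep]),
                       cigar = cig)
}

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(list(op = character(0), len = integer(0)))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  list(op = op, len = len)
}
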