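#' Gap-weighted mismatch penalty of a database hit
#'
#' `iota = (m + g * w) / L`: mismatches plus down-weighted gap length per
#' mapped base. Despite the field's habit of calling this an "identity", it
#' is a penalty -- lower is better; `w` (default 0.4) softens the influence of
#' the indel errors that dominate long reads.
#'
#' @param m mismatch count.
#' @param g total gap length in bases.
#' @param L mapped length in bases (positive).
#' @param w gap weight (default 0.4).
#' @return numeric penalty (vectorized).
#' @export
gap_weighted_identity <- function(m, g, L, w = 0.4) {
  if (any(L <= 0)) stop("'L' must be positive")
  if (any(m < 0) || any(g < 0)) stop("'m' and 'g' must be non-negative")
  (m + g * w) / L
}

#' Compute database hits for a reconstructed haplotype
#'
#' Locally aligns the haplotype against every allele of the locus and reports
#' the (m, g, L) triple per allele -- the same tabular interface an external
#' aligner's output can be substituted into bit-exactly.
#'
#' @param sequence haplotype sequence (N runs allowed; N never matches).
#' @param db `allele_db` or named character vector of allele sequences.
#' @param alleles optional subset of allele names.
#' @param w gap weight for [gap_weighted_identity()].
#' @return data.frame with `allele`, `m`, `g`, `L`, `iota`.
#' @export
match_hits <- function(sequence, db, alleles = NULL, w = 0.4) {
  seqs <- if (inherits(db, "allele_db"))
    setNames(db$alleles$sequence, db$alleles$name) else db
  if (!is.null(alleles)) seqs <- seqs[alleles]
  out <- lapply(names(seqs), function(a) {
    aln <- naive_align(sequence, seqs[[a]], allele = a, both_strands = FALSE)
    # the record's `mismatched` counts gap columns too; recover pure
    # mismatches and total gap length from the block decomposition
    # aln_len = matches + mismatches + ins + del
    n_ins <- aln$aln_len - (aln$ref_end - aln$ref_start)
    n_del <- aln$aln_len - (aln$read_end - aln$read_start)
    m <- aln$mismatched - n_ins - n_del
    # mapped length is measured on the query so gap columns cannot inflate a
    # divergent hit past the exact match under the relative length cutoff
    data.frame(allele = a, m = m, g = n_ins + n_del,
               L = aln$read_end - aln$read_start)
  })
  hits <- do.call(rbind, out)
  hits$iota <- gap_weighted_identity(hits$m, hits$g, hits$L, w)
  hits
}

#' Select best-matched alleles from database hits
#'
#' Candidate set: hits whose mapped length is within a fraction
#' `length_cutoff` of the longest (`L >= (1 - length_cutoff) * L_max`), so
#' short high-identity local alignments cannot win. Among candidates, every
#' allele whose penalty `iota` lies within `iota_cutoff` (absolute) of the
#' best (minimal) penalty is returned -- ties yield an ambiguity set.
#'
#' @param hits data.frame from [match_hits()] (columns `allele`, `L`, `iota`).
#' @param length_cutoff fractional mapped-length tolerance (default 0.02).
#' @param iota_cutoff absolute penalty tolerance (default 4e-4).
#' @return character vector of allele names (ambiguity set, best first).
#' @export
select_best_match <- function(hits, length_cutoff = 0.02, iota_cutoff = 4e-4) {
  if (is.null(hits) || nrow(hits) == 0L) stop("no hits to select from")
  cand <- hits[hits$L >= (1 - length_cutoff) * max(hits$L), , drop = FALSE]
  best <- min(cand$iota)
  sel <- cand[cand$iota <= best + iota_cutoff, , drop = FALSE]
  sel$allele[order(sel$iota, -sel$L, sel$allele)]
}

#' Compatible-accuracy count for one locus
#'
#' The compatible indicator F(R, I) is 1 exactly when truth set R and
#' inferred set I intersect. A locus scores
#' `max(F(R1,I1) + F(R2,I2), F(R1,I2) + F(R2,I1))` -- the haplotype pairing is
#' chosen in the caller's favor. Empty sets never intersect.
#'
#' @param R1,R2 truth ambiguity sets (character vectors).
#' @param I1,I2 inferred ambiguity sets.
#' @return integer in 0, 1, 2.
#' @export
compatible_accuracy <- function(R1, R2, I1, I2) {
  f <- function(r, i) as.integer(length(intersect(r, i)) > 0L)
  max(f(R1, I1) + f(R2, I2), f(R1, I2) + f(R2, I1))
}

#' Truth-annotation configuration
#' @param min_align_ratio minimum alignment ratio eta (default 0.95).
#' @param length_cutoff fractional alignment-length tolerance (default 0.02).
#' @param identity_cutoff absolute identity tolerance (default 4e-4).
#' @return list of thresholds.
#' @export
truth_annotation_config <- function(min_align_ratio = 0.95,
                                    length_cutoff = 0.02,
                                    identity_cutoff = 4e-4) {
  stopifnot(min_align_ratio > 0, min_align_ratio <= 1)
  list(min_align_ratio = min_align_ratio, length_cutoff = length_cutoff,
       identity_cutoff = identity_cutoff)
}

#' Annotate truth alleles from a phased assembly
#'
#' From per-allele alignment statistics against one assembly haplotype:
#' alleles with alignment ratio `eta < min_align_ratio` are excluded; the
#' candidate set keeps alignment lengths within `length_cutoff` (fraction) of
#' the longest; alleles with identity within `identity_cutoff` of the best
#' are retained as the truth ambiguity set.
#'
#' @param assembly_hits data.frame with `allele`, `eta` (alignment length /
#'   allele length), `aln_len`, `identity`.
#' @param cfg a [truth_annotation_config()].
#' @return character vector of truth alleles, or `NULL` (unannotatable) when
#'   no hit passes the eta filter.
#' @export
annotate_truth_from_assembly <- function(assembly_hits,
                                         cfg = truth_annotation_config()) {
  h <- assembly_hits[assembly_hits$eta >= cfg$min_align_ratio, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h <- h[h$aln_len >= (1 - cfg$length_cutoff) * max(h$aln_len), , drop = FALSE]
  best <- max(h$identity)
  sel <- h[h$identity >= best - cfg$identity_cutoff, , drop = FALSE]
  sel$allele[order(-sel$identity, sel$allele)]
}

#' Map a CYP activity score to a metabolizer phenotype
#'
#' Named classes: poor (score 0), intermediate (0.5), normal (1 to 2),
#' ultrarapid (above 2). Scores falling in the gaps between named classes
#' snap to the nearest class (ties toward the lower class) and are flagged
#' out-of-table.
#'
#' @param score activity score(s), non-negative.
#' @return data.frame with `score`, `phenotype`, `in_table`.
#' @export
cyp_activity_phenotype <- function(score) {
  if (any(score < 0)) stop("activity score must be non-negative")
  classify <- function(s) {
    if (s == 0) return(c("poor", TRUE))
    if (s == 0.5) return(c("intermediate", TRUE))
    if (s >= 1 && s <= 2) return(c("normal", TRUE))
    if (s > 2) return(c("ultrarapid", TRUE))
    # gaps: (0, 0.5) and (0.5, 1)
    anchors <- c(poor = 0, intermediate = 0.5, normal = 1)
    d <- abs(anchors - s)
    c(names(anchors)[which(d == min(d))[1L]], FALSE)
  }
  out <- t(vapply(score, classify, character(2)))
  data.frame(score = score, phenotype = out[, 1L],
             in_table = as.logical(out[, 2L]), stringsAsFactors = FALSE)
}

#' Typing accuracy at a field resolution
#'
#' Truncates every truth and inferred allele name to `k` fields, applies the
#' compatible-accuracy count per locus, and aggregates. The denominator is
#' two alleles per evaluated locus.
#'
#' @param calls named list (by locus) of `list(I1 =, I2 =)` inferred sets.
#' @param truth named list (by locus) of `list(R1 =, R2 =)` truth sets.
#' @param k field level.
#' @inheritParams parse_allele_name
#' @return list with `correct`, `total`, `accuracy`, `per_locus`.
#' @export
field_accuracy <- function(calls, truth, k = 4L, family = "HLA") {
  loci <- intersect(names(calls), names(truth))
  trunc_set <- function(x) if (length(x)) unique(truncate_name(x, k, family)) else character(0)
  per <- vapply(loci, function(l) {
    compatible_accuracy(trunc_set(truth[[l]]$R1), trunc_set(truth[[l]]$R2),
                        trunc_set(calls[[l]]$I1), trunc_set(calls[[l]]$I2))
  }, integer(1))
  correct <- sum(per); total <- 2L * length(loci)
  list(correct = correct, total = total,
       accuracy = if (total > 0) correct / total else NA_real_,
       per_locus = per)
}
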