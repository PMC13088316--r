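#' Build read-by-allele alignment matrices
#'
#' Three matrices over the reads and candidate alleles of one locus: matched
#' bases `M`, mismatched bases `S`, and identity `D`. Absent alignments are
#' `NA` (excluded from all downstream sums, distinct from zero). Duplicate
#' records for the same (read, allele) keep the highest-identity alignment.
#'
#' @param alignments alignment data.frame restricted to one locus's candidate
#'   alleles.
#' @return object of class `alignment_matrices`: list with matrices `M`, `S`,
#'   `D` (reads x alleles), `reads`, `alleles`.
#' @export
build_matrices <- function(alignments) {
  stopifnot(is.data.frame(alignments))
  if (nrow(alignments) > 0L) {
    ord <- order(alignments$read_id, alignments$allele, -alignments$identity)
    a <- alignments[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$read_id, a$allele, sep = "\r")), , drop = FALSE]
  } else a <- alignments
  reads <- sort(unique(a$read_id)); alleles <- sort(unique(a$allele))
  M <- S <- D <- matrix(NA_real_, length(reads), length(alleles),
                        dimnames = list(reads, alleles))
  if (nrow(a) > 0L) {
    idx <- cbind(match(a$read_id, reads), match(a$allele, alleles))
    M[idx] <- a$matched; S[idx] <- a$mismatched; D[idx] <- a$identity
  }
  structure(list(M = M, S = S, D = D, reads = reads, alleles = alleles),
            class = "alignment_matrices")
}

#' Assign each read to one member of a candidate allele pair
#'
#' A read goes to the allele to which it aligns with higher identity; exact
#' identity ties are broken by a seeded fair coin. Reads aligned to neither
#' allele are unassigned (`NA`).
#'
#' @param mat `alignment_matrices`.
#' @param i,j allele identifiers (the homozygous candidate `i == j` is
#'   allowed; every aligned read is then assigned to `i`).
#' @param seed integer seed for tie randomization (recorded in the result).
#' @return integer vector along `mat$reads`: `1` for allele `i`, `2` for
#'   allele `j`, `NA` unassigned; attributes `seed`, `i`, `j`.
#' @export
assign_reads_to_pair <- function(mat, i, j, seed = 1L) {
  stopifnot(inherits(mat, "alignment_matrices"))
  di <- mat$D[, i]; dj <- mat$D[, j]
  xi <- rep(NA_integer_, length(di))
  if (i == j) {
    xi[!is.na(di)] <- 1L
  } else {
    xi[!is.na(di) & is.na(dj)] <- 1L
    xi[is.na(di) & !is.na(dj)] <- 2L
    both <- !is.na(di) & !is.na(dj)
    xi[both & di > dj] <- 1L
    xi[both & di < dj] <- 2L
    tie <- both & di == dj
    if (any(tie)) {
      coin <- with_seed(seed, runif(length(di)))
      xi[tie] <- ifelse(coin[tie] < 0.5, 1L, 2L)
    }
  }
  structure(xi, seed = seed, i = i, j = j, names = mat$reads)
}

#' Score one candidate allele pair
#'
#' Aggregates, over reads assigned to each member of the pair, the matched
#' bases `alpha`, mismatched bases `beta_mm`, and the pair identity
#' `gamma = alpha / (alpha + beta_mm)`.
#'
#' @param mat `alignment_matrices`.
#' @param xi assignment vector from [assign_reads_to_pair()].
#' @param i,j allele identifiers.
#' @return object of class `pair_score`: list with `allele_i`, `allele_j`,
#'   `alpha`, `beta_mm`, `gamma`, `assignment`.
#' @export
score_pair <- function(mat, xi, i, j) {
  mi <- mat$M[, i]; mj <- mat$M[, j]
  si <- mat$S[, i]; sj <- mat$S[, j]
  sel_i <- which(!is.na(xi) & xi == 1L)
  sel_j <- which(!is.na(xi) & xi == 2L)
  alpha <- sum(mi[sel_i], na.rm = TRUE) + sum(mj[sel_j], na.rm = TRUE)
  beta_mm <- sum(si[sel_i], na.rm = TRUE) + sum(sj[sel_j], na.rm = TRUE)
  gamma <- if (alpha + beta_mm > 0) alpha / (alpha + beta_mm) else NA_real_
  structure(list(allele_i = i, allele_j = j, alpha = alpha, beta_mm = beta_mm,
                 gamma = gamma, assignment = xi),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("Allele pair (%s, %s): alpha=%g, beta=%g, gamma=%s\n",
              x$allele_i, x$allele_j, x$alpha, x$beta_mm,
              ifelse(is.na(x$gamma), "NA", format(x$gamma, digits = 6))))
  invisible(x)
}

#' Select the best-matched diploid allele pair
#'
#' Evaluates every unordered allele pair, including homozygous candidates
#' `(i, i)`. Pairs with `alpha >= (1 - tau) * alpha_max` form a candidate set
#' (`tau` is a relative tolerance); the retained pair with maximal `gamma`
#' wins. Ties break by higher `alpha`, then lexicographic pair.
#'
#' @param mat `alignment_matrices`.
#' @param alleles candidate allele subset (default: all in `mat`).
#' @param tau relative alpha tolerance (default 0.02).
#' @param seed seed for read-assignment tie coins.
#' @return the winning `pair_score`; attribute `pair_table` holds the
#'   per-pair (alpha, gamma) table.
#' @export
select_best_pair <- function(mat, alleles = NULL, tau = 0.02, seed = 1L) {
  stopifnot(inherits(mat, "alignment_matrices"))
  alleles <- sort(alleles %||% mat$alleles)
  if (length(alleles) == 0L) stop("empty candidate allele set")
  if (!all(alleles %in% mat$alleles)) stop("unknown candidate alleles")
  pairs <- cbind(rep(seq_along(alleles), times = seq_along(alleles)),
                 unlist(lapply(seq_along(alleles), seq_len)))
  # rows: (i >= j) -> use (j, i) ordered lexicographically
  tab <- data.frame(allele_i = alleles[pairs[, 2]],
                    allele_j = alleles[pairs[, 1]],
                    alpha = NA_real_, gamma = NA_real_,
                    stringsAsFactors = FALSE)
  scores <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    xi <- assign_reads_to_pair(mat, tab$allele_i[r], tab$allele_j[r], seed)
    sc <- score_pair(mat, xi, tab$allele_i[r], tab$allele_j[r])
    scores[[r]] <- sc
    tab$alpha[r] <- sc$alpha; tab$gamma[r] <- sc$gamma
  }
  ok <- !is.na(tab$gamma)
  if (!any(ok)) stop("no pair with any aligned bases")
  alpha_max <- max(tab$alpha[ok])
  retained <- ok & tab$alpha >= (1 - tau) * alpha_max
  cand <- which(retained)
  ord <- cand[order(-tab$gamma[cand], -tab$alpha[cand],
                    tab$allele_i[cand], tab$allele_j[cand])]
  best <- scores[[ord[1L]]]
  attr(best, "pair_table") <- tab
  attr(best, "seed") <- seed
  best
}

#' Per-allele depths of the selected pair
#'
#' `d_i` is the total aligned bases (matched + mismatched) of reads assigned
#' to allele `i`, divided by the allele length; analogously `d_j`.
#'
#' @param mat `alignment_matrices`.
#' @param xi assignment vector.
#' @param i,j allele identifiers.
#' @param len_i,len_j allele lengths in bases.
#' @return named numeric vector `c(d_i =, d_j =)`.
#' @export
allele_depths <- function(mat, xi, i, j, len_i, len_j) {
  stopifnot(len_i > 0, len_j > 0)
  sel_i <- which(!is.na(xi) & xi == 1L)
  sel_j <- which(!is.na(xi) & xi == 2L)
  d_i <- (sum(mat$M[sel_i, i], na.rm = TRUE) +
            sum(mat$S[sel_i, i], na.rm = TRUE)) / len_i
  d_j <- (sum(mat$M[sel_j, j], na.rm = TRUE) +
            sum(mat$S[sel_j, j], na.rm = TRUE)) / len_j
  c(d_i = d_i, d_j = d_j)
}

#' Zygosity call from beta-posterior allele frequencies
#'
#' With beta prior `(a, b)`, the posterior frequency of allele i is
#' `kappa_i = (a + d_i) / (a + b + d_i + d_j)`; the locus is homozygous when
#' the minor allele frequency `min(kappa_i, kappa_j)` falls below `chi`.
#'
#' @param d_i,d_j per-allele depths.
#' @param a,b beta prior parameters (default 1 and 1).
#' @param chi MAF threshold (default 0.3).
#' @return object of class `zygosity_call`: list with `kappa_i`, `kappa_j`,
#'   `maf`, `state` (`"heterozygous"`/`"homozygous"`), `d_i`, `d_j`,
#'   `priors`, `chi`.
#' @export
call_zygosity <- function(d_i, d_j, a = 1, b = 1, chi = 0.3) {
  stopifnot(d_i >= 0, d_j >= 0)
  kappa_i <- (a + d_i) / (a + b + d_i + d_j)
  kappa_j <- (a + d_j) / (a + b + d_i + d_j)
  maf <- min(kappa_i, kappa_j)
  structure(list(kappa_i = kappa_i, kappa_j = kappa_j, maf = maf,
                 state = if (maf < chi) "homozygous" else "heterozygous",
                 d_i = d_i, d_j = d_j, priors = c(a = a, b = b), chi = chi),
            class = "zygosity_call")
}

#' @export
print.zygosity_call <- function(x, ...) {
  cat(sprintf("Zygosity: %s (kappa = %.3f / %.3f, MAF = %.3f, chi = %g)\n",
              x$state, x$kappa_i, x$kappa_j, x$maf, x$chi))
  invisible(x)
}
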