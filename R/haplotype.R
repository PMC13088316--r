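#' Apply phased variants to a reference to form a haplotype consensus
#'
#' Substitutes, for the requested haplotype, the alternate allele of every
#' variant whose phased genotype carries it. Indels shift downstream
#' coordinates; the returned coordinate map records the cumulative shift.
#'
#' @param reference reference sequence (character scalar).
#' @param variants data.frame with columns `pos` (1-based), `ref`, `alt`,
#'   `hap1`, `hap2` (0/1 phased genotype columns). May be empty.
#' @param hap_index which haplotype column to apply (1 or 2).
#' @return list with `sequence` (consensus) and `coord_map`, a data.frame
#'   (`ref_pos`, `shift`) giving, after each applied edit, the offset to add
#'   to reference coordinates beyond `ref_pos`.
#' @export
apply_consensus <- function(reference, variants, hap_index = 1L) {
  stopifnot(hap_index %in% c(1L, 2L))
  if (is.null(variants) || nrow(variants) == 0L)
    return(list(sequence = reference, coord_map = data.frame(ref_pos = integer(0),
                                                             shift = integer(0))))
  col <- if (hap_index == 1L) variants$hap1 else variants$hap2
  v <- variants[col == 1L, , drop = FALSE]
  if (nrow(v) == 0L)
    return(list(sequence = reference, coord_map = data.frame(ref_pos = integer(0),
                                                             shift = integer(0))))
  if (any(v$pos < 1L | v$pos + nchar(v$ref) - 1L > nchar(reference)))
    stop("variant position out of range")
  v <- v[order(v$pos), , drop = FALSE]
  if (any(substr(rep(reference, nrow(v)), v$pos, v$pos + nchar(v$ref) - 1L) != v$ref))
    stop("variant ref allele does not match the reference sequence")
  # apply right-to-left so earlier coordinates stay valid
  seq <- reference
  for (r in rev(seq_len(nrow(v)))) {
    seq <- paste0(substr(seq, 1L, v$pos[r] - 1L), v$alt[r],
                  substr(seq, v$pos[r] + nchar(v$ref[r]), nchar(seq)))
  }
  shift <- cumsum(nchar(v$alt) - nchar(v$ref))
  list(sequence = seq,
       coord_map = data.frame(ref_pos = v$pos + nchar(v$ref) - 1L, shift = shift))
}

#' Segment a reference at structural-variant breakpoints
#'
#' `n` distinct breakpoints produce `n + 1` segments tiling the reference.
#' Duplicate breakpoints are collapsed with a warning.
#'
#' @param reference sequence to segment.
#' @param breakpoints integer positions strictly inside `(0, len)`, 0-based:
#'   a breakpoint `b` splits between positions `b` and `b + 1`.
#' @return object of class `segments`: data.frame with `id`, `start`, `end`
#'   (0-based half-open) and `sequence`.
#' @export
segment_reference <- function(reference, breakpoints = integer(0)) {
  L <- nchar(reference)
  if (length(breakpoints)) {
    if (anyDuplicated(breakpoints)) {
      warning("duplicate breakpoints collapsed")
      breakpoints <- unique(breakpoints)
    }
    if (any(breakpoints <= 0 | breakpoints >= L))
      stop("breakpoints must lie strictly inside (0, length)")
    breakpoints <- sort(breakpoints)
  }
  bounds <- c(0L, as.integer(breakpoints), L)
  out <- data.frame(id = seq_len(length(bounds) - 1L),
                    start = bounds[-length(bounds)], end = bounds[-1L])
  out$sequence <- substring(reference, out$start + 1L, out$end)
  structure(out, class = c("segments", "data.frame"))
}

#' Estimate per-segment copy numbers from depths
#'
#' The mean depth over segments is the one-copy baseline; each segment's copy
#' number is `floor(d_i / dbar)` in the default `"floor"` mode. The `"round"`
#' mode (`max(0, round(d_i / dbar))`) is available because flooring assigns
#' copy number 0 to any segment below mean depth under uneven coverage.
#'
#' @param depths numeric vector of per-segment mean depths.
#' @param mode `"floor"` (default) or `"round"`.
#' @return integer vector of copy numbers.
#' @export
estimate_copy_numbers <- function(depths, mode = c("floor", "round")) {
  mode <- match.arg(mode)
  if (length(depths) == 0L) stop("at least one segment required")
  if (all(depths == 0)) stop("all segment depths are zero")
  dbar <- mean(depths)
  cn <- switch(mode,
               floor = floor(depths / dbar),
               round = pmax(0, round(depths / dbar)))
  as.integer(cn)
}

#' Count reads spanning a segment junction
#'
#' A read spans the junction between segments `a` and `b` when its alignment
#' covers at least `min_anchor` bases on each side: from `a`'s end backwards
#' and from `b`'s start forwards (for adjacent segments these coincide at the
#' junction point).
#'
#' @param read_intervals data.frame with `start`, `end` (0-based half-open)
#'   reference intervals of read alignments.
#' @param seg_a,seg_b segment rows (with `start`, `end`).
#' @param min_anchor minimum anchored bases on each side (default 50).
#' @return integer count.
#' @export
count_spanning_reads <- function(read_intervals, seg_a, seg_b, min_anchor = 50L) {
  lo <- seg_a$end - min_anchor
  hi <- seg_b$start + min_anchor
  sum(read_intervals$start <= lo & read_intervals$end >= hi)
}

#' Build a segment graph
#'
#' @param segments `segments` data.frame.
#' @param copy_numbers integer copy number per segment.
#' @param edges data.frame with `from`, `to` (segment ids) and `weight`
#'   (spanning-read counts, non-negative).
#' @return object of class `segment_graph`.
#' @export
segment_graph <- function(segments, copy_numbers, edges) {
  stopifnot(inherits(segments, "segments"),
            length(copy_numbers) == nrow(segments))
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- data.frame(from = integer(0), to = integer(0), weight = numeric(0))
  stopifnot(all(c("from", "to", "weight") %in% names(edges)),
            all(edges$weight >= 0),
            all(edges$from %in% segments$id), all(edges$to %in% segments$id))
  structure(list(segments = segments, copy_numbers = as.integer(copy_numbers),
                 edges = edges),
            class = "segment_graph")
}

walk_weight <- function(walk, edges) {
  if (length(walk) < 2L) return(0)
  key <- paste(edges$from, edges$to)
  w <- edges$weight[match(paste(walk[-length(walk)], walk[-1L]), key)]
  sum(w, na.rm = TRUE)
}

multiset_permutations <- function(items) {
  # unique permutations of an integer multiset
  recurse <- function(remaining) {
    if (length(remaining) == 0L) return(list(integer(0)))
    out <- list()
    for (v in unique(remaining)) {
      rest <- remaining[-match(v, remaining)]
      for (tail in recurse(rest)) out[[length(out) + 1L]] <- c(v, tail)
    }
    out
  }
  recurse(sort(items))
}

#' Reconstruct a linear haplotype walk through the segment graph
#'
#' Orders segment copies (each segment used exactly its copy number of times)
#' to maximize the total weight of traversed spanning-read edges. When the
#' total copy count is at most `exact_limit`, the optimum is found by
#' exhaustive multiset enumeration; larger instances use a greedy walk with
#' one-step look-ahead. Among equal-weight optima the walk closest to
#' reference segment order (lexicographically smallest id sequence) wins.
#'
#' @param graph a `segment_graph`.
#' @param exact_limit maximum total copies for exhaustive search (default 8).
#' @return list with `walk` (segment ids in order), `sequence`, `weight`,
#'   `method` (`"exact"`/`"greedy"`), and `fallback` (TRUE when no segment
#'   had positive copy number and reference order was emitted with warning).
#' @export
reconstruct_haplotype_path <- function(graph, exact_limit = 8L) {
  stopifnot(inherits(graph, "segment_graph"))
  cn <- graph$copy_numbers
  items <- rep(graph$segments$id, times = pmax(cn, 0L))
  fallback <- FALSE
  if (length(items) == 0L) {
    warning("no segment with positive copy number; falling back to reference order")
    items <- graph$segments$id
    fallback <- TRUE
  }
  if (length(items) <= exact_limit) {
    perms <- multiset_permutations(items)
    ws <- vapply(perms, walk_weight, numeric(1), edges = graph$edges)
    best_w <- max(ws)
    cand <- perms[ws == best_w]
    keys <- vapply(cand, function(p) paste(sprintf("%09d", p), collapse = ","),
                   character(1))
    walk <- cand[[order(keys)[1L]]]
    method <- "exact"
  } else {
    # greedy with one-step look-ahead; reference-order tie-break
    remaining <- items
    walk <- remaining[1L]; remaining <- remaining[-1L]
    key <- paste(graph$edges$from, graph$edges$to)
    wt <- function(a, b) {
      w <- graph$edges$weight[match(paste(a, b), key)]
      if (is.na(w)) 0 else w
    }
    while (length(remaining)) {
      cands <- sort(unique(remaining))
      score <- vapply(cands, function(b) {
        rest <- remaining[-match(b, remaining)]
        ahead <- if (length(rest)) max(vapply(unique(rest), function(cc)
          wt(b, cc), numeric(1))) else 0
        wt(walk[length(walk)], b) + ahead
      }, numeric(1))
      nxt <- cands[order(-score, cands)][1L]
      walk <- c(walk, nxt)
      remaining <- remaining[-match(nxt, remaining)]
    }
    best_w <- walk_weight(walk, graph$edges)
    method <- "greedy"
  }
  seqs <- graph$segments$sequence[match(walk, graph$segments$id)]
  list(walk = walk, sequence = paste(seqs, collapse = ""), weight = best_w,
       method = method, fallback = fallback)
}

#' Masking configuration
#' @param window window size in bases (default 20).
#' @param min_depth minimum mean window depth (default 5).
#' @return list with `window` and `min_depth`.
#' @export
masking_config <- function(window = 20L, min_depth = 5) {
  stopifnot(window >= 1L, min_depth >= 0)
  list(window = as.integer(window), min_depth = min_depth)
}

#' Mask low-depth windows with N
#'
#' Slides a `window`-base window (stride 1) along the sequence; every window
#' whose mean depth falls below `min_depth` is fully masked with `N`.
#' Unmasked bases are never altered. Sequences shorter than the window are
#' treated as a single window.
#'
#' @param sequence nucleotide string.
#' @param depth per-base depth track, same length as `sequence`.
#' @param cfg a [masking_config()].
#' @return object of class `haplotype_sequence`: list with `sequence` (masked),
#'   `masked_intervals` (data.frame `start`, `end`, 0-based half-open),
#'   `masked_fraction`.
#' @export
mask_low_depth <- function(sequence, depth, cfg = masking_config()) {
  L <- nchar(sequence)
  if (length(depth) != L) stop("depth track length must equal sequence length")
  w <- min(cfg$window, L)
  cs <- cumsum(c(0, depth))
  means <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  fail <- which(means < cfg$min_depth)
  mask <- rep(FALSE, L)
  for (s in fail) mask[s:(s + w - 1L)] <- TRUE
  chars <- strsplit(sequence, "")[[1L]]
  chars[mask] <- "N"
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  structure(list(sequence = paste(chars, collapse = ""),
                 masked_intervals = iv,
                 masked_fraction = mean(mask)),
            class = "haplotype_sequence")
}

#' @export
print.haplotype_sequence <- function(x, ...) {
  cat(sprintf("Haplotype sequence: %d bases, %.1f%% masked (%d interval(s))\n",
              nchar(x$sequence), 100 * x$masked_fraction,
              nrow(x$masked_intervals)))
  invisible(x)
}

#' Naive pileup variant caller
#'
#' Desk-scale SNV caller used for tests and the iterative reconstruction
#' loop: reads are locally aligned to the reference, a pileup is built, and a
#' substitution is called at every position where the most frequent
#' non-reference base reaches `min_frac` of the aligned depth with depth at
#' least `min_depth`. External phased VCFs can replace it in real runs.
#'
#' @param reads named character vector of read sequences.
#' @param reference reference sequence.
#' @param min_frac minimum alternate-base fraction (default 0.2).
#' @param min_depth minimum aligned depth (default 4).
#' @param alignments optional precomputed alignments of `reads` against
#'   `reference` (skips re-alignment).
#' @return list with `variants` (data.frame `pos`, `ref`, `alt`, `af`,
#'   `depth`), `depth` (per-base track), `alignments`.
#' @export
naive_caller <- function(reads, reference, min_frac = 0.2, min_depth = 4L,
                         alignments = NULL) {
  if (is.null(alignments))
    alignments <- align_reads(reads, setNames(reference, "ref"))
  if (nrow(alignments) == 0L)
    return(list(variants = data.frame(), depth = rep(0, nchar(reference)),
                alignments = alignments))
  oriented <- ifelse(alignments$strand == "-", revcomp(unname(reads[alignments$read_id])),
                     unname(reads[alignments$read_id]))
  qstart <- ifelse(alignments$strand == "-",
                   nchar(oriented) - alignments$read_end,
                   alignments$read_start)
  pile <- .cigar_pileup_cpp(oriented, alignments$cigar,
                            as.integer(alignments$ref_start),
                            as.integer(qstart), nchar(reference))
  rownames(pile) <- c("A", "C", "G", "T", "other", "del")
  base_depth <- colSums(pile[1:4, , drop = FALSE])
  depth <- base_depth + pile["del", ]
  refc <- strsplit(toupper(reference), "")[[1L]]
  vars <- list()
  for (p in which(base_depth >= min_depth)) {
    counts <- pile[1:4, p]
    alt <- names(counts)[counts > 0 & names(counts) != refc[p]]
    if (!length(alt)) next
    alt <- alt[which.max(counts[alt])]
    af <- counts[[alt]] / base_depth[p]
    if (af >= min_frac)
      vars[[length(vars) + 1L]] <- data.frame(pos = p, ref = refc[p], alt = alt,
                                              af = af, depth = base_depth[p])
  }
  list(variants = if (length(vars)) do.call(rbind, vars) else
         data.frame(pos = integer(0), ref = character(0), alt = character(0),
                    af = numeric(0), depth = numeric(0)),
       depth = depth, alignments = alignments,
       oriented_reads = oriented, query_start = qstart)
}

#' Phase called variants by read co-occurrence
#'
#' Greedy 2-coloring: each read votes for variants it covers; variants whose
#' alternate alleles co-occur on reads are placed on the same haplotype,
#' alt/ref co-occurrence places them on opposite haplotypes.
#'
#' @param call result of [naive_caller()].
#' @return the variant data.frame with phased `hap1`/`hap2` columns
#'   (heterozygous variants split across haplotypes; variants with
#'   `af >= hom_threshold` are set on both).
#' @param hom_threshold alternate fraction at and above which a variant is
#'   treated as homozygous (default 0.8).
#' @export
phase_variants <- function(call, hom_threshold = 0.8) {
  v <- call$variants
  if (nrow(v) == 0L) {
    v$hap1 <- integer(0); v$hap2 <- integer(0)
    return(v)
  }
  v$hap1 <- 1L; v$hap2 <- 1L
  het <- which(v$af < hom_threshold)
  if (length(het) >= 1L) {
    bases <- .read_bases_at_cpp(call$oriented_reads, call$alignments$cigar,
                                as.integer(call$alignments$ref_start),
                                as.integer(call$query_start),
                                as.integer(v$pos[het] - 1L))
    # orientation: +1 same phase as anchor, -1 opposite
    phase <- rep(NA_integer_, length(het))
    phase[1L] <- 1L
    for (idx in seq_along(het)[-1L]) {
      same <- 0; opp <- 0
      for (prev in which(!is.na(phase))) {
        cov <- !is.na(bases[, idx]) & !is.na(bases[, prev])
        if (!any(cov)) next
        alt_i <- bases[cov, idx] == v$alt[het[idx]]
        alt_p <- bases[cov, prev] == v$alt[het[prev]]
        agree <- sum(alt_i == alt_p); dis <- sum(alt_i != alt_p)
        if (agree >= dis) same <- same + phase[prev] * (agree - dis)
        else opp <- opp + phase[prev] * (dis - agree)
      }
      phase[idx] <- if (same >= opp) 1L else -1L
    }
    v$hap1[het] <- ifelse(phase == 1L, 1L, 0L)
    v$hap2[het] <- ifelse(phase == 1L, 0L, 1L)
  }
  v
}

#' Iterative haplotype reconstruction
#'
#' Repeats align -> call -> (phase) -> consensus against the personalized
#' reference until the caller reports no variants or `max_iter` is reached.
#' With two initial references (heterozygous locus) each haplotype is refined
#' separately from its assigned reads; with one (homozygous locus) variants
#' are phased by read co-occurrence and two consensus haplotypes built.
#' Final sequences are masked for low depth.
#'
#' @param reads named character vector of locus reads.
#' @param initial_refs character vector of one or two personalized reference
#'   allele sequences.
#' @param read_groups optional list of read-id vectors, one per reference
#'   (the xi assignment); defaults to all reads for each.
#' @param caller variant-calling function with the signature of
#'   [naive_caller()].
#' @param max_iter maximum refinement rounds (default 5).
#' @param mask a [masking_config()].
#' @param min_frac,min_depth forwarded to the caller.
#' @return list of two `haplotype_sequence` objects, with `iterations` and
#'   `converged` attributes per haplotype.
#' @export
iterate_reconstruction <- function(reads, initial_refs, read_groups = NULL,
                                   caller = naive_caller, max_iter = 5L,
                                   mask = masking_config(), min_frac = 0.2,
                                   min_depth = 4L) {
  stopifnot(length(initial_refs) %in% c(1L, 2L))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  refine_one <- function(ref, ids) {
    its <- 0L; converged <- FALSE; last <- NULL
    while (its < max_iter) {
      its <- its + 1L
      last <- caller(reads[ids], ref, min_frac = max(min_frac, 0.5),
                     min_depth = min_depth)
      if (nrow(last$variants) == 0L) { converged <- TRUE; break }
      v <- last$variants; v$hap1 <- 1L; v$hap2 <- 1L
      ref <- apply_consensus(ref, v, 1L)$sequence
    }
    if (!converged && its == max_iter)
      warning("haplotype refinement did not converge within max_iter")
    if (is.null(last) || nrow(last$variants) > 0L)
      last <- caller(reads[ids], ref, min_frac = max(min_frac, 0.5),
                     min_depth = min_depth)
    hs <- mask_low_depth(ref, last$depth, mask)
    attr(hs, "iterations") <- its
    attr(hs, "converged") <- converged
    hs
  }
  if (length(initial_refs) == 2L) {
    groups <- read_groups %||% list(names(reads), names(reads))
    out <- list(refine_one(initial_refs[1L], groups[[1L]]),
                refine_one(initial_refs[2L], groups[[2L]]))
  } else {
    # homozygous call may hide true heterozygosity: call, phase, then split
    first <- caller(reads, initial_refs, min_frac = min_frac,
                    min_depth = min_depth)
    phased <- phase_variants(first)
    if (nrow(phased) == 0L) {
      hs <- mask_low_depth(initial_refs, first$depth, mask)
      attr(hs, "iterations") <- 1L; attr(hs, "converged") <- TRUE
      out <- list(hs, hs)
    } else {
      h1 <- apply_consensus(initial_refs, phased, 1L)$sequence
      h2 <- apply_consensus(initial_refs, phased, 2L)$sequence
      out <- list(refine_one(h1, names(reads)), refine_one(h2, names(reads)))
    }
  }
  names(out) <- c("hap1", "hap2")
  out
}
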