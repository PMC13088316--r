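#' Pipeline configuration
#'
#' Aggregates every tunable of the typing loop with its stated default:
#' binning identity threshold 0.85 and two-locus distance tolerance 2000 bp;
#' condensed candidate set of 200 alleles; pair-selection alpha tolerance
#' tau = 0.02; beta priors (1, 1) and MAF threshold chi = 0.3; 20 bp masking
#' window at minimum depth 5; nomenclature gap weight 0.4, mapped-length
#' cutoff 0.02 and penalty cutoff 4e-4; truth-annotation alignment ratio
#' 0.95. Population-statistics defaults ride along: binary entropy 0.15
#' bits, top-5 PCs, 1000 bootstrap replicates, 10000 permutations,
#' replication chance probability 0.5 * 0.1, precision cutoff 0.02 with
#' stability 0.75 over 100 resamples of 80%.
#'
#' @param min_identity binning identity threshold.
#' @param theta two-locus distance tolerance (bases).
#' @param top_k condensed candidate set size.
#' @param tau relative alpha tolerance in pair selection.
#' @param prior_a,prior_b beta prior parameters.
#' @param chi MAF threshold for the homozygosity call.
#' @param mask_window,mask_min_depth masking window (bp) and depth floor.
#' @param gap_weight w in the nomenclature penalty.
#' @param length_cutoff,iota_cutoff nomenclature candidate-set cutoffs.
#' @param eta_min truth-annotation alignment-ratio threshold.
#' @param entropy_min_bits binary-entropy allele filter (bits).
#' @param n_pcs principal components removed in popstats adjustments.
#' @param n_bootstrap,n_permutations,n_splits resampling replicates.
#' @param replication_p0 chance replication probability.
#' @param precision_cutoff,stability_min,n_stability,stability_frac
#'   precision-network stability selection parameters.
#' @param max_iter reconstruction iteration cap.
#' @param reconstruct run iterative haplotype reconstruction in
#'   [run_typing()] (default TRUE).
#' @param seed integer seed.
#' @param family gene family naming scheme.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_identity = 0.85, theta = 2000, top_k = 200L,
                            tau = 0.02, prior_a = 1, prior_b = 1, chi = 0.3,
                            mask_window = 20L, mask_min_depth = 5,
                            gap_weight = 0.4, length_cutoff = 0.02,
                            iota_cutoff = 4e-4, eta_min = 0.95,
                            entropy_min_bits = 0.15, n_pcs = 5L,
                            n_bootstrap = 1000L, n_permutations = 10000L,
                            n_splits = 100L, replication_p0 = 0.5 * 0.1,
                            precision_cutoff = 0.02, stability_min = 0.75,
                            n_stability = 100L, stability_frac = 0.8,
                            max_iter = 5L, reconstruct = TRUE, seed = 1L,
                            family = "HLA") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Typing pipeline configuration:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Run the full typing loop on a read set
#'
#' Per locus: bin reads by best alignment identity over the allele database
#' (k-mer prescreen shortlists alignment candidates), build the condensed
#' candidate set and the M/S/D matrices, select the best-matched diploid
#' allele pair, call zygosity from beta-posterior depths, optionally refine
#' personalized haplotypes iteratively, and assign nomenclature to the
#' result. Loci with no surviving reads are reported untyped; loci below 10x
#' mean depth carry a low-depth flag (reported, not dropped).
#'
#' @param reads named character vector of read sequences (or a FASTQ path).
#' @param db an `allele_db`.
#' @param cfg a [pipeline_config()].
#' @param prescreen_candidates alleles shortlisted per read in the binning
#'   alignment (default 12).
#' @return object of class `typing_result`: list with `report` (one row per
#'   locus), `haplotypes` (per locus, list of two `haplotype_sequence`),
#'   `binning`, `config`.
#' @export
run_typing <- function(reads, db, cfg = pipeline_config(),
                       prescreen_candidates = 12L) {
  stopifnot(inherits(db, "allele_db"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  empty_report <- data.frame(
    locus = character(0), status = character(0), n_reads = integer(0),
    allele_1 = character(0), allele_2 = character(0), zygosity = character(0),
    depth = numeric(0), identity = numeric(0), iterations = integer(0),
    warnings = character(0))
  if (length(reads) == 0L) {
    warning("empty read set")
    return(structure(list(report = empty_report, haplotypes = list(),
                          binning = NULL, config = cfg),
                     class = "typing_result"))
  }
  alns <- align_reads(reads, db, max_candidates = prescreen_candidates)
  binning <- bin_reads(alns, min_identity = cfg$min_identity, loci = db$loci,
                       theta = cfg$theta)
  lens <- setNames(db$alleles$length, db$alleles$name)
  report <- list(); haps <- list()
  for (locus in db$loci$locus) {
    rids <- binning$assignments$read_id[binning$assignments$locus == locus]
    if (length(rids) == 0L) {
      report[[locus]] <- data.frame(
        locus = locus, status = "untyped", n_reads = 0L,
        allele_1 = NA_character_, allele_2 = NA_character_,
        zygosity = NA_character_, depth = NA_real_, identity = NA_real_,
        iterations = 0L, warnings = "no reads", stringsAsFactors = FALSE)
      next
    }
    locus_alleles <- db$alleles$name[db$alleles$locus == locus]
    la <- align_reads(reads[rids], db, alleles = locus_alleles)
    cand <- condensed_candidate_set(la, lens, cfg$top_k)
    la <- la[la$allele %in% cand, , drop = FALSE]
    mat <- build_matrices(la)
    best <- select_best_pair(mat, tau = cfg$tau, seed = cfg$seed)
    i <- best$allele_i; j <- best$allele_j
    d <- allele_depths(mat, best$assignment, i, j, lens[[i]], lens[[j]])
    zyg <- call_zygosity(d[["d_i"]], d[["d_j"]], cfg$prior_a, cfg$prior_b,
                         cfg$chi)
    state <- if (i == j) "homozygous" else zyg$state
    # a homozygous call collapses to the major allele (the one the reads
    # support), irrelevant of which partner the tie-break happened to keep
    major <- if (zyg$kappa_i >= zyg$kappa_j) i else j
    if (state == "homozygous") i <- j <- major
    warn <- character(0)
    total_depth <- d[["d_i"]] + d[["d_j"]]
    if (total_depth < 10) warn <- c(warn, "depth below 10x")
    iterations <- 0L
    pair_seqs <- NULL
    if (isTRUE(cfg$reconstruct)) {
      xi <- best$assignment
      if (state == "heterozygous" && i != j) {
        groups <- list(names(xi)[!is.na(xi) & xi == 1L],
                       names(xi)[!is.na(xi) & xi == 2L])
        hs <- iterate_reconstruction(
          reads[rids], c(db$alleles[i, "sequence"], db$alleles[j, "sequence"]),
          read_groups = groups, max_iter = cfg$max_iter,
          mask = masking_config(cfg$mask_window, cfg$mask_min_depth))
      } else {
        hs <- iterate_reconstruction(
          reads[rids], db$alleles[i, "sequence"], max_iter = cfg$max_iter,
          mask = masking_config(cfg$mask_window, cfg$mask_min_depth))
      }
      iterations <- max(attr(hs[[1]], "iterations"), attr(hs[[2]], "iterations"))
      if (!attr(hs[[1]], "converged") || !attr(hs[[2]], "converged"))
        warn <- c(warn, "reconstruction not converged")
      mask_frac <- max(hs[[1]]$masked_fraction, hs[[2]]$masked_fraction)
      if (mask_frac > 0.5) warn <- c(warn, "majority of haplotype masked")
      haps[[locus]] <- hs
      # re-derive nomenclature from the reconstructed sequences
      call_set <- lapply(hs, function(h) {
        unmasked <- gsub("N", "", h$sequence)
        if (nchar(unmasked) < 50) return(NA_character_)
        hits <- match_hits(h$sequence, db, alleles = locus_alleles,
                           w = cfg$gap_weight)
        select_best_match(hits, cfg$length_cutoff, cfg$iota_cutoff)[1L]
      })
      a1 <- call_set[[1]]; a2 <- call_set[[2]]
      if (is.na(a1)) a1 <- i
      if (is.na(a2)) a2 <- j
    } else {
      a1 <- i; a2 <- if (state == "homozygous") i else j
    }
    if (state == "homozygous") { a2 <- a1 }
    report[[locus]] <- data.frame(
      locus = locus, status = "typed", n_reads = length(rids),
      allele_1 = a1, allele_2 = a2, zygosity = state,
      depth = total_depth, identity = best$gamma, iterations = iterations,
      warnings = if (length(warn)) paste(warn, collapse = "; ") else "",
      stringsAsFactors = FALSE)
  }
  structure(list(report = do.call(rbind, c(report, list(make.row.names = FALSE))),
                 haplotypes = haps, binning = binning, config = cfg),
            class = "typing_result")
}

#' @export
print.typing_result <- function(x, ...) {
  cat(sprintf("Typing result: %d locus/loci (%d typed, %d untyped)\n",
              nrow(x$report), sum(x$report$status == "typed"),
              sum(x$report$status == "untyped")))
  print(x$report[, c("locus", "status", "allele_1", "allele_2", "zygosity",
                     "depth")], row.names = FALSE)
  invisible(x)
}

#' Evaluate typing calls against truth at a field resolution
#'
#' Joins calls and truth by locus, truncates names to `k` fields, and scores
#' with the compatible-accuracy pairing. Loci present in only one input are
#' listed and excluded from the denominator with a warning.
#'
#' @param calls data.frame with `locus`, `allele_1`, `allele_2` (e.g. the
#'   report of [run_typing()]).
#' @param truth data.frame with `locus`, `allele_1`, `allele_2`.
#' @param k field level (default 4).
#' @inheritParams parse_allele_name
#' @return list as [field_accuracy()], plus `unmatched_loci`.
#' @export
run_eval <- function(calls, truth, k = 4L, family = "HLA") {
  common <- intersect(calls$locus, truth$locus)
  unmatched <- setdiff(union(calls$locus, truth$locus), common)
  if (length(unmatched))
    warning(sprintf("loci without counterpart excluded: %s",
                    paste(unmatched, collapse = ", ")))
  calls <- calls[!is.na(calls$allele_1) & !is.na(calls$allele_2), , drop = FALSE]
  common <- intersect(calls$locus, truth$locus)
  cl <- setNames(lapply(common, function(l) {
    r <- calls[calls$locus == l, ][1, ]
    list(I1 = r$allele_1, I2 = r$allele_2)
  }), common)
  tr <- setNames(lapply(common, function(l) {
    r <- truth[truth$locus == l, ][1, ]
    list(R1 = r$allele_1, R2 = r$allele_2)
  }), common)
  out <- field_accuracy(cl, tr, k, family)
  out$unmatched_loci <- unmatched
  out
}
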