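#' Synthetic allele-database configuration
#'
#' Divergences are substitution fractions between sequences: two alleles of
#' one locus differ at about `inter_allele_divergence` of their bases, two
#' loci at about `inter_locus_divergence` (the homology hierarchy requires
#' inter-locus > inter-allele). A fraction `indel_fraction` of planted edits
#' are 1-10 bp indels instead of substitutions. Loci are laid out on a
#' synthetic chromosome `locus_spacing` bases apart, providing the reference
#' geometry for the two-locus binning rule.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus alleles per locus.
#' @param allele_length ancestral allele length in bases.
#' @param inter_locus_divergence substitution fraction between loci (default 0.10).
#' @param inter_allele_divergence substitution fraction within a locus
#'   (default 0.02).
#' @param indel_fraction fraction of edits that are short indels (default 0.1).
#' @param locus_spacing reference gap between consecutive loci (default 5000).
#' @param family naming scheme (default "HLA").
#' @param seed integer seed.
#' @return list of class `sim_db_config`.
#' @export
sim_db_config <- function(n_loci = 10L, alleles_per_locus = 20L,
                          allele_length = 1000L,
                          inter_locus_divergence = 0.10,
                          inter_allele_divergence = 0.02,
                          indel_fraction = 0.1, locus_spacing = 5000L,
                          family = "HLA", seed = 1L) {
  stopifnot(inter_locus_divergence > inter_allele_divergence,
            inter_locus_divergence > 0, inter_locus_divergence < 1,
            inter_allele_divergence >= 0, inter_allele_divergence < 1)
  structure(list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 allele_length = allele_length,
                 inter_locus_divergence = inter_locus_divergence,
                 inter_allele_divergence = inter_allele_divergence,
                 indel_fraction = indel_fraction,
                 locus_spacing = locus_spacing, family = family, seed = seed),
            class = "sim_db_config")
}

random_sequence <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                     collapse = "")

#' Mutate a sequence at a target divergence
#'
#' Plants `round(rate * length)` edits at distinct positions; a fraction
#' `indel_fraction` are 1-10 bp insertions or deletions, the rest
#' substitutions. Returns the mutated sequence and the edit manifest.
#'
#' @param seq input sequence.
#' @param rate target edit fraction.
#' @param indel_fraction fraction of edits that are indels.
#' @return list with `sequence` and `edits` (data.frame pos, type, ref, alt).
#' @keywords internal
mutate_sequence <- function(seq, rate, indel_fraction = 0) {
  L <- nchar(seq)
  n_edit <- round(rate * L)
  if (n_edit == 0L) return(list(sequence = seq, edits = data.frame()))
  pos <- sort(sample(L, n_edit))
  type <- sample(c("sub", "indel"), n_edit, replace = TRUE,
                 prob = c(1 - indel_fraction, indel_fraction))
  chars <- strsplit(seq, "")[[1L]]
  edits <- data.frame(pos = pos, type = type, ref = chars[pos],
                      alt = NA_character_, stringsAsFactors = FALSE)
  # apply right-to-left so positions stay valid
  for (k in rev(seq_len(n_edit))) {
    p <- pos[k]
    if (type[k] == "sub") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      chars[p] <- alt
      edits$alt[k] <- alt
    } else {
      len <- sample(10L, 1)
      if (runif(1) < 0.5 && p + len <= length(chars)) { # deletion
        edits$alt[k] <- ""
        edits$ref[k] <- paste(chars[p:(p + len - 1)], collapse = "")
        chars <- chars[-(p:(p + len - 1))]
      } else { # insertion after p
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        edits$alt[k] <- ins
        chars <- append(chars, strsplit(ins, "")[[1L]], after = p)
      }
    }
  }
  list(sequence = paste(chars, collapse = ""), edits = edits)
}

#' Simulate a multi-locus allele database
#'
#' A root sequence is mutated into one ancestral sequence per locus (at half
#' the inter-locus divergence each, so locus pairs differ at about the
#' target), and each ancestor into alleles (at half the inter-allele
#' divergence). Allele names follow the family scheme with four resolution
#' fields. Deterministic under the config seed.
#'
#' @param cfg a [sim_db_config()].
#' @return list with `db` (an `allele_db`) and `manifest` (data.frame of
#'   planted per-allele edits relative to the locus ancestor).
#' @export
simulate_allele_db <- function(cfg = sim_db_config()) {
  stopifnot(inherits(cfg, "sim_db_config"))
  with_seed(cfg$seed, {
    root <- random_sequence(cfg$allele_length)
    loci <- sprintf("SY%s", LETTERS[seq_len(cfg$n_loci)])
    rows <- list(); manifest <- list()
    for (li in seq_along(loci)) {
      anc <- mutate_sequence(root, cfg$inter_locus_divergence / 2, 0)$sequence
      for (ai in seq_len(cfg$alleles_per_locus)) {
        mut <- if (ai == 1L) list(sequence = anc, edits = data.frame())
               else mutate_sequence(anc, cfg$inter_allele_divergence / 2,
                                    cfg$indel_fraction)
        name <- format_allele_name(
          loci[li], c(sprintf("%02d", ai), "01", "01", "01"), cfg$family)
        rows[[length(rows) + 1L]] <- data.frame(
          name = name, locus = loci[li], family = cfg$family,
          sequence = mut$sequence, stringsAsFactors = FALSE)
        if (nrow(mut$edits)) {
          mut$edits$allele <- name
          manifest[[length(manifest) + 1L]] <- mut$edits
        }
      }
    }
    locus_tab <- data.frame(
      locus = loci, family = cfg$family, chrom = "chrSim",
      start = (seq_along(loci) - 1L) * (cfg$allele_length + cfg$locus_spacing),
      end = (seq_along(loci) - 1L) * (cfg$allele_length + cfg$locus_spacing) +
        cfg$allele_length,
      gene_class = "synthetic", stringsAsFactors = FALSE)
    list(db = allele_database(do.call(rbind, rows), locus_tab),
         manifest = if (length(manifest)) do.call(rbind, manifest) else
           data.frame())
  })
}

#' Synthetic long-read configuration
#'
#' @param depth per-haplotype fold coverage (default 30).
#' @param accuracy per-base correct probability (default 0.90).
#' @param read_length mean read length; lengths are log-normal with
#'   `read_sd_log` spread and are capped at the source allele length.
#' @param read_sd_log log-scale standard deviation (default 0.25).
#' @param error_profile substitution:insertion:deletion weights
#'   (default balanced `c(1, 1, 1)`).
#' @param seed integer seed.
#' @return list of class `sim_read_config`.
#' @export
sim_read_config <- function(depth = 30, accuracy = 0.90, read_length = 800L,
                            read_sd_log = 0.25, error_profile = c(1, 1, 1),
                            seed = 1L) {
  stopifnot(accuracy > 0.5, accuracy <= 1, depth > 0)
  structure(list(depth = depth, accuracy = accuracy,
                 read_length = read_length, read_sd_log = read_sd_log,
                 error_profile = error_profile / sum(error_profile),
                 seed = seed),
            class = "sim_read_config")
}

inject_errors <- function(seq, accuracy, profile) {
  if (accuracy >= 1) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  err <- which(runif(length(chars)) > accuracy)
  if (!length(err)) return(seq)
  kind <- sample(c("sub", "ins", "del"), length(err), replace = TRUE,
                 prob = profile)
  for (k in rev(seq_along(err))) {
    p <- err[k]
    if (kind[k] == "sub") {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    } else if (kind[k] == "ins") {
      chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = p)
    } else {
      chars <- chars[-p]
    }
  }
  paste(chars, collapse = "")
}

#' Simulate diploid long reads for a genotype
#'
#' Reads alternate between the two haplotype alleles until each reaches the
#' target depth. Read lengths are log-normal (capped at the allele length),
#' start positions uniform, per-base errors injected at `1 - accuracy` with
#' the configured substitution:insertion:deletion profile. Half the reads are
#' reverse-complemented. The truth table maps every read to its source allele
#' and interval.
#'
#' @param db `allele_db`.
#' @param genotype character vector of two allele names (equal for a
#'   homozygous genotype).
#' @param cfg a [sim_read_config()].
#' @return list with `reads` (named character vector) and `truth` (data.frame
#'   `read_id`, `allele`, `locus`, `start`, `end`, `strand`).
#' @export
simulate_diploid_reads <- function(db, genotype, cfg = sim_read_config()) {
  stopifnot(inherits(db, "allele_db"), length(genotype) == 2L,
            all(genotype %in% db$alleles$name))
  with_seed(cfg$seed, {
    reads <- character(0); truth <- list()
    for (h in 1:2) {
      src <- db$alleles[genotype[h], ]
      L <- src$length
      total <- 0; target <- cfg$depth * L
      while (total < target) {
        rl <- min(L, max(50L, round(rlnorm(1, log(cfg$read_length),
                                           cfg$read_sd_log))))
        s <- sample.int(L - rl + 1L, 1L) - 1L
        raw <- substr(src$sequence, s + 1L, s + rl)
        obs <- inject_errors(raw, cfg$accuracy, cfg$error_profile)
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") obs <- revcomp(obs)
        rid <- sprintf("r%04d_h%d", length(reads) + 1L, h)
        reads[rid] <- obs
        truth[[rid]] <- data.frame(read_id = rid, allele = src$name,
                                   locus = src$locus, start = s, end = s + rl,
                                   strand = strand, stringsAsFactors = FALSE)
        total <- total + rl
      }
    }
    list(reads = reads, truth = do.call(rbind, truth))
  })
}

#' Write reads to FASTQ
#' @param reads named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read FASTQ into a named character vector
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), vapply(strsplit(names(x), "\\s+"), `[`,
                                   character(1), 1L))
}

#' Synthetic population-frequency configuration
#'
#' @param n_populations number of populations (default 26).
#' @param families named list: per family, a list with `genes` (count) and
#'   `alleles_per_gene`.
#' @param planted_pairs data.frame with `allele_a`, `allele_b`, `target_r`
#'   (allele names as produced: FAMILY_G<g>_A<a>).
#' @param pc_confound strength of a shared latent gradient loaded on all
#'   alleles (0 disables; confounds raw correlations, removable by PC
#'   adjustment).
#' @param confound_pairs data.frame with `allele_a`, `allele_b`: pairs driven
#'   only by the shared gradient.
#' @param count_depth gene copies sampled per population for the count
#'   matrix (default 1000).
#' @param seed integer seed.
#' @return list of class `sim_pop_config`.
#' @export
sim_pop_config <- function(n_populations = 26L,
                           families = list(HLA = list(genes = 3L, alleles_per_gene = 5L),
                                           KIR = list(genes = 3L, alleles_per_gene = 5L)),
                           planted_pairs = NULL, pc_confound = 0,
                           confound_pairs = NULL, count_depth = 1000L,
                           seed = 1L) {
  structure(list(n_populations = n_populations, families = families,
                 planted_pairs = planted_pairs, pc_confound = pc_confound,
                 confound_pairs = confound_pairs, count_depth = count_depth,
                 seed = seed),
            class = "sim_pop_config")
}

#' Simulate a population allele-frequency table
#'
#' Per gene and population, frequencies are Dirichlet(1) draws. Planted
#' correlated pairs share a latent standard-normal gradient passed through a
#' logistic map and renormalized within gene; the latent loading is tuned by
#' rejection until the realized cross-population correlation is within 0.1
#' of `target_r`. An optional shared gradient (`pc_confound`) loads on every
#' allele, creating population structure that PC adjustment removes. A count
#' matrix is drawn multinomially at `count_depth` per gene and population.
#'
#' @param cfg a [sim_pop_config()].
#' @return list with `table` (a `freq_table`) and `truth` (realized planted
#'   correlations).
#' @export
simulate_population_frequencies <- function(cfg = sim_pop_config()) {
  stopifnot(inherits(cfg, "sim_pop_config"))
  with_seed(cfg$seed, {
    pops <- sprintf("POP%02d", seq_len(cfg$n_populations))
    meta <- do.call(rbind, lapply(names(cfg$families), function(f) {
      spec <- cfg$families[[f]]
      expand.grid(a = seq_len(spec$alleles_per_gene), g = seq_len(spec$genes),
                  stringsAsFactors = FALSE) |>
        (\(d) data.frame(allele = sprintf("%s_G%d_A%d", f, d$g, d$a),
                         family = f, gene = sprintf("%s_G%d", f, d$g),
                         stringsAsFactors = FALSE))()
    }))
    n <- cfg$n_populations
    # Dirichlet(1) per gene/population via normalized exponentials
    f <- matrix(0, n, nrow(meta), dimnames = list(pops, meta$allele))
    for (g in unique(meta$gene)) {
      cols <- which(meta$gene == g)
      draws <- matrix(rgamma(n * length(cols), 1), n)
      f[, cols] <- draws / rowSums(draws)
    }
    gradients <- NULL
    if (cfg$pc_confound > 0) {
      # five population-structure gradients loaded (with allele-specific
      # weights) on every allele: the top principal components are then
      # structure axes rather than any individual allele pair
      gradients <- matrix(rnorm(n * 5L), n, 5L)
      loadings <- matrix(rnorm(5L * ncol(f), sd = cfg$pc_confound), 5L)
      f <- plogis(qlogis(pmin(pmax(f, 1e-4), 1 - 1e-4)) + gradients %*% loadings)
    }
    plant <- function(a, b, target) {
      # the correlation is carried by the ratio of shared-latent to private
      # noise, at a modest logit amplitude so the pair never dominates the
      # matrix's principal components; rejection-tuned until the correlation
      # measured on the final (within-gene renormalized) frequencies lands
      # within 0.1 of the target, boosting the latent ratio as needed to
      # offset renormalization attenuation
      ia <- match(a, meta$allele); ib <- match(b, meta$allele)
      rest_a <- rowSums(f[, setdiff(which(meta$gene == meta$gene[ia]), ia),
                          drop = FALSE])
      rest_b <- rowSums(f[, setdiff(which(meta$gene == meta$gene[ib]), ib),
                          drop = FALSE])
      rho_try <- abs(target)
      for (try in seq_len(100L)) {
        if (try %% 10L == 0L) rho_try <- min(0.98, rho_try + 0.03)
        lam <- sqrt(rho_try / max(1e-6, 1 - rho_try))
        amp <- 1.2 / sqrt(lam^2 + 1)
        z <- rnorm(n)
        xa <- plogis(-1.6 + amp * (lam * z + rnorm(n)))
        xb <- plogis(-1.6 + amp * (sign(target) * lam * z + rnorm(n)))
        realized <- cor(xa / (xa + rest_a), xb / (xb + rest_b))
        if (abs(realized - target) <= 0.1) {
          f[, a] <<- xa; f[, b] <<- xb
          return(realized)
        }
      }
      stop(sprintf("could not realize target correlation %.2f for (%s, %s)",
                   target, a, b))
    }
    truth <- data.frame()
    if (!is.null(cfg$planted_pairs) && nrow(cfg$planted_pairs)) {
      for (k in seq_len(nrow(cfg$planted_pairs))) {
        pp <- cfg$planted_pairs[k, ]
        r <- plant(pp$allele_a, pp$allele_b, pp$target_r)
        truth <- rbind(truth, data.frame(allele_a = pp$allele_a,
                                         allele_b = pp$allele_b,
                                         target_r = pp$target_r, realized_r = r))
      }
    }
    if (!is.null(cfg$confound_pairs) && nrow(cfg$confound_pairs)) {
      stopifnot(cfg$pc_confound > 0)
      for (k in seq_len(nrow(cfg$confound_pairs))) {
        cp <- cfg$confound_pairs[k, ]
        # their only shared driver is the first structure gradient: the raw
        # correlation is strong, the PC-adjusted one vanishes
        f[, cp$allele_a] <- plogis(-1 + 2 * gradients[, 1L] + 0.3 * rnorm(n))
        f[, cp$allele_b] <- plogis(-1 + 2 * gradients[, 1L] + 0.3 * rnorm(n))
      }
    }
    # renormalize per gene so each (population, gene) block sums to 1
    for (g in unique(meta$gene)) {
      cols <- which(meta$gene == g)
      f[, cols] <- f[, cols, drop = FALSE] / rowSums(f[, cols, drop = FALSE])
    }
    counts <- f * 0
    for (g in unique(meta$gene)) {
      cols <- which(meta$gene == g)
      for (i in seq_len(n))
        counts[i, cols] <- as.integer(rmultinom(1, cfg$count_depth, f[i, cols]))
    }
    list(table = freq_table(f, meta, counts),
         truth = truth)
  })
}
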