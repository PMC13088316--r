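#' Shannon diversity (maximum-likelihood estimator)
#'
#' `H = -sum p_i log(p_i)` with `0 log 0 = 0`. The plug-in estimator is
#' negatively biased at small sample sizes; see [shannon_jackknife()] and
#' [shannon_nonparametric()] for bias-reduced alternatives.
#'
#' @param freqs probability vector (non-negative, sums to 1).
#' @param base logarithm base; `exp(1)` (nats, default) or `2` (bits).
#' @return entropy.
#' @export
shannon_mle <- function(freqs, base = exp(1)) {
  if (any(freqs < 0)) stop("negative frequencies")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  p <- freqs[freqs > 0]
  -sum(p * log(p, base = base))
}

#' First-order jackknife estimator of Shannon diversity
#'
#' Leave-one-observation-out jackknife of the plug-in estimator over a
#' multinomial sample: `H_J = n * H - (n - 1)/n * sum_obs H_(-obs)`, where
#' the sum runs over the `n` observations (all observations of a category
#' share the same leave-one-out value).
#'
#' @param counts integer category counts, total `n >= 2`.
#' @inheritParams shannon_mle
#' @return jackknife-corrected entropy.
#' @export
shannon_jackknife <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need a total count of at least 2")
  H <- shannon_mle(counts / n, base)
  loo <- vapply(seq_along(counts), function(k) {
    ck <- counts; ck[k] <- ck[k] - 1L
    shannon_mle(ck[ck > 0] / (n - 1), base)
  }, numeric(1))
  n * H - (n - 1) / n * sum(counts * loo)
}

#' Coverage-adjusted (Chao-Shen) estimator of Shannon diversity
#'
#' Horvitz-Thompson sum over coverage-adjusted frequencies: with sample
#' coverage `C = 1 - f1/n` (`f1` singletons), `p~_i = C p^_i` and
#' `H_CS = -sum p~ log(p~) / (1 - (1 - p~)^n)`. Approaches the plug-in
#' estimator when coverage is complete and corrects upward under heavy
#' singleton load.
#'
#' @inheritParams shannon_jackknife
#' @return coverage-adjusted entropy.
#' @export
shannon_nonparametric <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) stop("empty sample")
  if (length(counts) == 1L) return(0)
  f1 <- sum(counts == 1L)
  C <- 1 - f1 / n
  if (C == 0) C <- 1 / n # all-singleton guard: minimal positive coverage
  pt <- C * counts / n
  -sum(pt * log(pt, base = base) / (1 - (1 - pt)^n))
}

#' Jensen-Shannon distance between two frequency vectors
#'
#' Computes the JS divergence `0.5 KL(p||m) + 0.5 KL(q||m)` with `m` the
#' pointwise mean, and by default returns its square root -- the distance
#' convention of the standard library function the divergence is usually
#' computed with. Natural log by default; with base 2 the distance is bounded
#' by 1, with natural log by `sqrt(log 2)`.
#'
#' @param p,q probability vectors of equal length.
#' @param base logarithm base (default natural).
#' @param distance return the square root (default TRUE); `FALSE` returns the
#'   divergence itself.
#' @return JS distance (or divergence).
#' @export
jensen_shannon_distance <- function(p, q, base = exp(1), distance = TRUE) {
  if (length(p) != length(q)) stop("length mismatch")
  if (any(p < 0) || any(q < 0)) stop("negative frequencies")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz], base = base))
  }
  js <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  js <- max(js, 0) # guard tiny negative rounding
  if (distance) sqrt(js) else js
}

#' Population allele-frequency table
#'
#' @param freq populations x alleles matrix of relative frequencies (row and
#'   column names required).
#' @param meta data.frame with one row per allele: `allele`, `family`, `gene`.
#' @param counts optional integer count matrix, same shape as `freq`.
#' @return object of class `freq_table`.
#' @export
freq_table <- function(freq, meta, counts = NULL) {
  stopifnot(is.matrix(freq), !is.null(rownames(freq)), !is.null(colnames(freq)),
            nrow(meta) == ncol(freq), all(meta$allele == colnames(freq)))
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  if (!is.null(counts)) stopifnot(identical(dim(counts), dim(freq)))
  structure(list(freq = freq, meta = meta, counts = counts),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("Allele frequency table: %d populations x %d alleles (%d famil%s, %d gene%s)\n",
              nrow(x$freq), ncol(x$freq),
              length(unique(x$meta$family)),
              ifelse(length(unique(x$meta$family)) == 1, "y", "ies"),
              length(unique(x$meta$gene)),
              ifelse(length(unique(x$meta$gene)) == 1, "", "s")))
  invisible(x)
}

#' Read a frequency table from TSV
#'
#' Long format with header: population, family, gene, allele, frequency and
#' optionally count.
#'
#' @param path TSV file.
#' @return `freq_table`.
#' @export
read_freq_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  pops <- sort(unique(df$population))
  alleles <- unique(df[, c("family", "gene", "allele")])
  alleles <- alleles[order(alleles$family, alleles$gene, alleles$allele), ]
  f <- matrix(0, length(pops), nrow(alleles),
              dimnames = list(pops, alleles$allele))
  f[cbind(match(df$population, pops), match(df$allele, alleles$allele))] <- df$frequency
  cnt <- NULL
  if ("count" %in% names(df)) {
    cnt <- matrix(0L, length(pops), nrow(alleles),
                  dimnames = list(pops, alleles$allele))
    cnt[cbind(match(df$population, pops), match(df$allele, alleles$allele))] <- df$count
  }
  freq_table(f, data.frame(allele = alleles$allele, family = alleles$family,
                           gene = alleles$gene, stringsAsFactors = FALSE), cnt)
}

#' Intra- versus inter-superpopulation Jensen-Shannon distances
#'
#' Computes the JSD between every pair of populations over the full allele
#' frequency vector, labels each pair intra or inter according to the
#' superpopulation map, and compares the two groups with a Mann-Whitney U
#' test.
#'
#' @param table `freq_table`.
#' @param superpop named character vector mapping population -> superpopulation.
#' @return list with `pairs` (data.frame pop_a, pop_b, jsd, type), `p_value`
#'   (Mann-Whitney, `NA` when a group is empty or degenerate).
#' @export
intra_inter_jsd <- function(table, superpop) {
  pops <- rownames(table$freq)
  if (!all(pops %in% names(superpop))) stop("superpopulation map incomplete")
  sizes <- table(superpop[pops])
  if (any(sizes < 2))
    warning("superpopulation(s) with a single population: no intra pairs there")
  cmb <- combn(pops, 2)
  jsd <- apply(cmb, 2, function(pr)
    jensen_shannon_distance(table$freq[pr[1], ], table$freq[pr[2], ]))
  type <- ifelse(superpop[cmb[1, ]] == superpop[cmb[2, ]], "intra", "inter")
  pairs <- data.frame(pop_a = cmb[1, ], pop_b = cmb[2, ], jsd = jsd,
                      type = type, stringsAsFactors = FALSE)
  p <- NA_real_
  if (all(c("intra", "inter") %in% type) &&
      (sd(jsd) > 0))
    p <- wilcox.test(jsd ~ factor(type, c("intra", "inter")))$p.value
  list(pairs = pairs, p_value = p)
}

#' Differential heterozygosity across loci
#'
#' Per locus, a two-sample t-test on heterozygous-variant counts between the
#' two groups; Bonferroni correction over loci; loci with adjusted p below
#' `alpha` are significant, with direction given by the group-mean
#' difference. Loci with zero variance in both groups are excluded with a
#' note.
#'
#' @param het samples x loci matrix of heterozygous-variant counts.
#' @param groups factor/character of length `nrow(het)` with two levels.
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @return data.frame per locus: `locus`, `mean_a`, `mean_b`, `direction`,
#'   `p`, `p_adj`, `significant`, `note`.
#' @export
differential_het_loci <- function(het, groups, alpha = 0.01) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  lv <- levels(groups)
  res <- lapply(colnames(het), function(l) {
    a <- het[groups == lv[1], l]; b <- het[groups == lv[2], l]
    if (length(a) < 2 || length(b) < 2)
      stop("need >= 2 samples per group per locus")
    if (sd(a) == 0 && sd(b) == 0)
      return(data.frame(locus = l, mean_a = mean(a), mean_b = mean(b),
                        direction = NA_character_, p = NA_real_,
                        note = "constant counts; excluded"))
    tt <- t.test(a, b)
    data.frame(locus = l, mean_a = mean(a), mean_b = mean(b),
               direction = ifelse(mean(a) > mean(b), "enriched", "depleted"),
               p = tt$p.value, note = NA_character_)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(out$p * sum(!is.na(out$p)), 1)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Residual heterozygosity comparison after covariate regression
#'
#' Ordinary least squares of per-sample heterozygosity on technical
#' covariates (log depth, read length, mapping quality, basecaller mode,
#' ...), then a two-sample t-test of the residuals between the two groups --
#' does a biological difference persist after technical variation is removed?
#'
#' @param het numeric vector of per-sample locus-summed heterozygous counts.
#' @param covariates data.frame of technical covariates (numeric or factor).
#' @param group two-level factor/character (e.g. AFR vs non-AFR).
#' @return list with `fit` (the lm), `p_value` (residual t-test),
#'   `group_means` (residual means).
#' @export
het_covariate_regression <- function(het, covariates, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  df <- data.frame(het = het, covariates)
  fit <- lm(het ~ ., data = df)
  al <- alias(fit)$Complete
  if (!is.null(al))
    stop(sprintf("collinear covariates: %s", paste(rownames(al), collapse = ", ")))
  r <- resid(fit)
  tt <- t.test(r ~ group)
  list(fit = fit, p_value = tt$p.value,
       group_means = tapply(r, group, mean))
}

#' Filter alleles by mean binary entropy across populations
#'
#' Per allele, the mean over populations of the binary entropy (base 2) of
#' its frequency; alleles with mean entropy below `min_H` bits are
#' uninformative and removed.
#'
#' @param table `freq_table`.
#' @param min_H minimum mean binary entropy in bits (default 0.15).
#' @return character vector of retained allele names.
#' @export
binary_entropy_filter <- function(table, min_H = 0.15) {
  h2 <- function(p) {
    out <- numeric(length(p))
    nz <- p > 0 & p < 1
    out[nz] <- -p[nz] * log2(p[nz]) - (1 - p[nz]) * log2(1 - p[nz])
    out
  }
  mean_h <- colMeans(apply(table$freq, 2, h2))
  colnames(table$freq)[mean_h >= min_H]
}
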