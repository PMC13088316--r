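#' Ledoit-Wolf shrinkage covariance estimator
#'
#' Well-conditioned covariance: optimal convex combination of the sample
#' covariance `S` (1/n convention) and the scaled identity `m I`, with the
#' shrinkage intensity estimated from the data (the squared-Frobenius
#' oracle-approximation formula). Guarantees an invertible estimate even when
#' variables outnumber observations.
#'
#' @param X observations x variables matrix.
#' @return list with `sigma` (shrunk covariance), `lambda` (intensity),
#'   `mu` (target scale).
#' @export
ledoit_wolf <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least two observations")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 <= .Machine$double.eps)
    return(list(sigma = diag(mu, p), lambda = 1, mu = mu))
  q <- rowSums(Xc^2)
  t2 <- rowSums((Xc %*% S) * Xc)
  bbar2 <- (sum(q^2) - 2 * sum(t2) + n * sum(S^2)) / n^2
  b2 <- min(bbar2, d2)
  lambda <- b2 / d2
  sigma <- lambda * diag(mu, p) + (1 - lambda) * S
  dimnames(sigma) <- list(colnames(X), colnames(X))
  list(sigma = sigma, lambda = lambda, mu = mu)
}

#' Regress out leading principal components
#'
#' Removes the projection onto the top `n_pcs` principal-component scores of
#' the matrix from every column; the standard population-structure adjustment
#' before correlation or precision estimation. Each allele's cross-population
#' vector is residualized against the population-level PC scores.
#'
#' @param X populations x alleles matrix.
#' @param n_pcs number of components to remove (default 5; 0 is a no-op).
#' @return residual matrix of the same shape.
#' @export
remove_top_pcs <- function(X, n_pcs = 5L) {
  if (n_pcs <= 0L) return(X)
  n_pcs <- min(n_pcs, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  fit <- lm.fit(cbind(1, scores), X)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(X)
  res
}

#' Simulated background correlation distribution
#'
#' Null distribution of Pearson correlations between independent frequency
#' vectors over `n_pops` populations; a synthetic stand-in for an external
#' inter-chromosomal background panel, usable as the `background` argument of
#' [crossfamily_correlations()].
#'
#' @param n_pops number of populations.
#' @param n_draws number of null correlations (default 10000).
#' @param seed integer seed.
#' @return numeric vector of correlations.
#' @export
simulate_background_correlations <- function(n_pops, n_draws = 10000L, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(n_draws), function(i)
      cor(rnorm(n_pops), rnorm(n_pops)), numeric(1))
  })
}

#' Cross-family allele-frequency correlation screen
#'
#' For every allele pair drawn from two different gene families: Pearson
#' correlation across populations, recomputed after regressing out the top
#' `n_pcs` principal components of the frequency matrix; permutation p-value
#' against `n_perm` random allele pairings within the same family pair
#' (computed on the PC-adjusted residuals); empirical p-value against a
#' background correlation distribution; population-bootstrap support;
#' split-sample replication with an upper-tail binomial test under chance
#' replication probability `p0 = 0.5 * replication_alpha`; and
#' Benjamini-Hochberg correction. A pair is retained only when every filter
#' passes.
#'
#' Bootstrap, replication (which requires a count matrix) and the binomial
#' test are evaluated only for pairs that survive the raw and PC-adjusted
#' p-value filters, since failing pairs are already rejected.
#'
#' @param table `freq_table`, already entropy-filtered
#'   (see [binary_entropy_filter()]).
#' @param alpha two-sided significance level for raw/PC-adjusted/permutation/
#'   empirical tests and the BH threshold (default 0.05).
#' @param n_pcs principal components removed (default 5).
#' @param n_perm permutations per family pair (default 10000).
#' @param n_boot bootstrap replicates (default 1000).
#' @param boot_support_min minimal fraction of bootstrap resamples with a
#'   same-sign nominally significant correlation (default 0.8).
#' @param n_splits split-sample replications (default 100).
#' @param replication_alpha per-half significance in replication (default 0.1).
#' @param background numeric vector of background correlations; defaults to
#'   [simulate_background_correlations()].
#' @param seed integer seed for all resampling.
#' @return data.frame of `CorrelationRecord`s, one row per cross-family pair.
#' @export
crossfamily_correlations <- function(table, alpha = 0.05, n_pcs = 5L,
                                     n_perm = 10000L, n_boot = 1000L,
                                     boot_support_min = 0.8,
                                     n_splits = 100L, replication_alpha = 0.1,
                                     background = NULL, seed = 1L) {
  stopifnot(inherits(table, "freq_table"))
  F0 <- table$freq
  if (nrow(F0) < 3L) stop("need at least 3 populations")
  fam <- table$meta$family
  if (length(unique(fam)) < 2L) stop("need alleles from at least two families")
  R <- remove_top_pcs(F0, n_pcs)
  if (is.null(background))
    background <- simulate_background_correlations(nrow(F0), seed = seed + 1L)

  fams <- sort(unique(fam))
  fpairs <- combn(fams, 2)
  cor_p <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(x, y))
    c(ct$estimate, ct$p.value)
  }
  rec <- list()
  perm_null <- list()
  with_seed(seed, {
    for (fp in seq_len(ncol(fpairs))) {
      ia <- which(fam == fpairs[1, fp]); ib <- which(fam == fpairs[2, fp])
      # shared permutation null per family pair: random allele pairings
      pa <- sample(ia, n_perm, replace = TRUE)
      pb <- sample(ib, n_perm, replace = TRUE)
      # a random population scramble breaks the true pairing structure
      null_r <- vapply(seq_len(n_perm), function(k) {
        sh <- sample(nrow(R))
        suppressWarnings(cor(R[, pa[k]], R[sh, pb[k]]))
      }, numeric(1))
      null_r <- null_r[!is.na(null_r)]
      perm_null[[paste(fpairs[, fp], collapse = "|")]] <- null_r
      for (a in ia) for (b in ib) {
        raw <- cor_p(F0[, a], F0[, b])
        adj <- cor_p(R[, a], R[, b])
        rec[[length(rec) + 1L]] <- data.frame(
          allele_a = colnames(F0)[a], allele_b = colnames(F0)[b],
          family_a = fpairs[1, fp], family_b = fpairs[2, fp],
          gene_a = table$meta$gene[a], gene_b = table$meta$gene[b],
          r_raw = raw[1], p_raw = raw[2],
          r_pc_adjusted = adj[1], p_pc = adj[2],
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rec)
  out$p_perm <- NA_real_; out$p_empirical <- NA_real_
  for (i in seq_len(nrow(out))) {
    nr <- perm_null[[paste(sort(c(out$family_a[i], out$family_b[i])), collapse = "|")]]
    if (!is.na(out$r_pc_adjusted[i])) {
      out$p_perm[i] <- (1 + sum(abs(nr) >= abs(out$r_pc_adjusted[i]))) /
        (1 + length(nr))
      out$p_empirical[i] <- (1 + sum(abs(background) >= abs(out$r_raw[i]))) /
        (1 + length(background))
    }
  }
  out$p_adj <- p.adjust(out$p_pc, method = "BH")
  cand <- which(!is.na(out$p_raw) & out$p_raw < alpha &
                  !is.na(out$p_pc) & out$p_pc < alpha)
  out$bootstrap_support <- NA_real_
  out$p_replication <- NA_real_
  out$replication_pass <- NA
  n_pop <- nrow(F0)
  crit <- abs(stats::qt(alpha / 2, df = n_pop - 2))
  for (i in cand) {
    a <- out$allele_a[i]; b <- out$allele_b[i]
    sgn <- sign(out$r_pc_adjusted[i])
    with_seed(seed + i, {
      # population-level bootstrap on the PC-adjusted residuals
      supp <- 0L
      for (k in seq_len(n_boot)) {
        idx <- sample(n_pop, n_pop, replace = TRUE)
        rb <- suppressWarnings(cor(R[idx, a], R[idx, b]))
        if (!is.na(rb) && sign(rb) == sgn) {
          tb <- abs(rb) * sqrt((n_pop - 2) / (1 - rb^2))
          if (tb > crit) supp <- supp + 1L
        }
      }
      out$bootstrap_support[i] <- supp / n_boot
      # split-sample replication over the count matrix
      if (!is.null(table$counts)) {
        succ <- 0L; valid <- 0L; tries <- 0L
        while (valid < n_splits && tries < 4L * n_splits) {
          tries <- tries + 1L
          h1 <- matrix(rbinom(length(table$counts), table$counts, 0.5),
                       nrow = n_pop, dimnames = dimnames(table$counts))
          h2 <- table$counts - h1
          f1 <- half_freqs(h1, table$meta)
          f2 <- half_freqs(h2, table$meta)
          x1 <- f1[, a]; y1 <- f1[, b]; x2 <- f2[, a]; y2 <- f2[, b]
          if (sd(x1) == 0 || sd(y1) == 0 || sd(x2) == 0 || sd(y2) == 0) next
          valid <- valid + 1L
          p1 <- suppressWarnings(cor.test(x1, y1))
          p2 <- suppressWarnings(cor.test(x2, y2))
          if (p1$p.value < replication_alpha && p2$p.value < replication_alpha &&
              sign(p1$estimate) == sgn && sign(p2$estimate) == sgn)
            succ <- succ + 1L
        }
        if (valid > 0L) {
          bt <- binom.test(succ, valid, p = 0.5 * replication_alpha,
                           alternative = "greater")
          out$p_replication[i] <- bt$p.value
          out$replication_pass[i] <- bt$p.value < alpha
        }
      }
    })
  }
  out$retained <- !is.na(out$p_raw) & out$p_raw < alpha &
    !is.na(out$p_pc) & out$p_pc < alpha &
    !is.na(out$p_perm) & out$p_perm < alpha &
    !is.na(out$p_empirical) & out$p_empirical < alpha &
    !is.na(out$bootstrap_support) & out$bootstrap_support >= boot_support_min &
    !is.na(out$p_adj) & out$p_adj <= alpha
  if (!is.null(table$counts))
    out$retained <- out$retained & !is.na(out$replication_pass) & out$replication_pass
  rownames(out) <- NULL
  out
}

half_freqs <- function(counts, meta) {
  f <- counts * 0
  for (g in unique(meta$gene)) {
    cols <- which(meta$gene == g)
    tot <- rowSums(counts[, cols, drop = FALSE])
    tot[tot == 0] <- 1
    f[, cols] <- counts[, cols, drop = FALSE] / tot
  }
  f
}

#' Gene-level association graph from retained correlation records
#'
#' Nodes are genes with at least one retained cross-family record; the edge
#' weight between two genes is the highest absolute pairwise correlation over
#' their retained allele pairs.
#'
#' @param records output of [crossfamily_correlations()].
#' @return list with `graph` (igraph object), `edges` (data.frame),
#'   `components` (membership vector), `density`.
#' @export
build_association_graph <- function(records) {
  r <- records[records$retained %in% TRUE, , drop = FALSE]
  if (nrow(r) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(list(graph = g, edges = data.frame(), components = integer(0),
                density = NA_real_))
  }
  key <- paste(pmin(r$gene_a, r$gene_b), pmax(r$gene_a, r$gene_b), sep = "\r")
  w <- tapply(abs(r$r_pc_adjusted), key, max)
  parts <- do.call(rbind, strsplit(names(w), "\r"))
  edges <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                      weight = as.numeric(w), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  list(graph = g, edges = edges,
       components = igraph::components(g)$membership,
       density = igraph::edge_density(g))
}

#' Precision-matrix co-evolution network with stability selection
#'
#' Adjusts the frequency matrix for population structure (top `n_pcs`
#' principal components regressed out), standardizes columns, estimates the
#' precision matrix by inverting the Ledoit-Wolf shrinkage covariance, and
#' evaluates edge robustness by stability selection: `n_boot` resamples of
#' populations (`frac` of them, drawn with replacement), an edge counting in
#' a resample when its absolute precision value exceeds `cutoff`. Edges with
#' stability at least `stability_min` are retained, carrying the mean
#' precision value over the resamples that selected them.
#'
#' @param x `freq_table` or populations x alleles numeric matrix.
#' @param cutoff absolute precision threshold (default 0.02).
#' @param stability_min minimal selection fraction (default 0.75).
#' @param n_boot number of resamples (default 100).
#' @param frac fraction of populations per resample (default 0.8).
#' @param n_pcs principal components removed first (default 5; use 0 when no
#'   population structure is present).
#' @param seed integer seed.
#' @return object of class `precision_network`: list with `edges` (data.frame
#'   `allele_a`, `allele_b`, `theta`, `stability`), `stability` (full
#'   matrix), `theta` (full-data precision), `lambda` (full-data shrinkage).
#' @export
precision_network <- function(x, cutoff = 0.02, stability_min = 0.75,
                              n_boot = 100L, frac = 0.8, n_pcs = 5L,
                              seed = 1L) {
  X <- if (inherits(x, "freq_table")) x$freq else as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("a", seq_len(ncol(X)))
  Xr <- remove_top_pcs(X, n_pcs)
  sds <- apply(Xr, 2, sd)
  if (any(sds == 0)) stop("constant allele column(s) after adjustment")
  Xs <- scale(Xr)
  p <- ncol(Xs); n <- nrow(Xs)
  theta_of <- function(M) {
    lw <- ledoit_wolf(M)
    solve(lw$sigma)
  }
  theta_full <- theta_of(Xs)
  lambda <- ledoit_wolf(Xs)$lambda
  cnt <- matrix(0, p, p); acc <- matrix(0, p, p)
  m <- max(2L, floor(frac * n))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample(n, m, replace = TRUE)
      Mb <- Xs[idx, , drop = FALSE]
      if (any(apply(Mb, 2, sd) == 0)) next
      tb <- theta_of(scale(Mb))
      hit <- abs(tb) > cutoff
      cnt <- cnt + hit
      acc <- acc + ifelse(hit, tb, 0)
    }
  })
  stab <- cnt / n_boot
  dimnames(stab) <- dimnames(theta_full) <- list(colnames(Xs), colnames(Xs))
  ut <- which(upper.tri(stab) & stab >= stability_min, arr.ind = TRUE)
  edges <- data.frame(
    allele_a = colnames(Xs)[ut[, 1]], allele_b = colnames(Xs)[ut[, 2]],
    theta = ifelse(cnt[ut] > 0, acc[ut] / cnt[ut], NA_real_),
    stability = stab[ut], stringsAsFactors = FALSE)
  structure(list(edges = edges, stability = stab, theta = theta_full,
                 lambda = lambda, cutoff = cutoff,
                 stability_min = stability_min),
            class = "precision_network")
}

#' @export
print.precision_network <- function(x, ...) {
  cat(sprintf("Precision network: %d edge(s) at |theta| > %g, stability >= %g (LW lambda = %.3f)\n",
              nrow(x$edges), x$cutoff, x$stability_min, x$lambda))
  invisible(x)
}
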