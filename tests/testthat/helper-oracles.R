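# Independent oracles and instance generators used across the suite.
# They deliberately recompute everything from the raw alignment records,
# never through the package's matrix/scoring path.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# random alignment instance: reads x alleles with continuous identities so
# per-read argmax assignments are tie-free (generic position)
random_pair_instance <- function(n_reads, n_alleles, missing_frac = 0.2) {
  reads <- sprintf("r%02d", seq_len(n_reads))
  alleles <- sprintf("al%02d", seq_len(n_alleles))
  recs <- list()
  for (r in reads) for (a in alleles) {
    if (runif(1) < missing_frac) next
    aln_len <- sample(200:1000, 1)
    mism <- rbinom(1, aln_len, runif(1, 0.01, 0.2))
    recs[[length(recs) + 1L]] <- data.frame(
      read_id = r, allele = a, locus = "L", matched = aln_len - mism,
      mismatched = mism, aln_len = aln_len, read_start = 0L,
      read_end = aln_len, ref_start = 0L, ref_end = aln_len,
      identity = 1 - mism / aln_len, strand = "+", cigar = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  # enforce tie-free identities within each read (generic position) so the
  # oracle's deterministic argmax matches the package's
  for (r in unique(out$read_id)) {
    idx <- which(out$read_id == r)
    while (anyDuplicated(out$identity[idx])) {
      d <- idx[duplicated(out$identity[idx])][1L]
      out$mismatched[d] <- out$mismatched[d] + 1L
      out$matched[d] <- out$aln_len[d] - out$mismatched[d]
      out$identity[d] <- 1 - out$mismatched[d] / out$aln_len[d]
    }
  }
  out
}

# exhaustive best-pair oracle over raw records; returns the set of optimal
# pairs (ties included) together with the winning alpha/gamma
oracle_best_pair <- function(recs, tau) {
  alleles <- sort(unique(recs$allele))
  per_read <- split(recs, recs$read_id)
  score1 <- function(i, j) {
    alpha <- 0; beta <- 0
    for (rr in per_read) {
      di <- rr$identity[rr$allele == i]
      dj <- rr$identity[rr$allele == j]
      has_i <- length(di) == 1L; has_j <- length(dj) == 1L
      if (!has_i && !has_j) next
      pick <- if (has_i && (!has_j || di > dj || i == j)) "i"
              else if (has_j && (!has_i || dj > di)) "j"
              else "i" # exact tie cannot occur in generic instances
      if (pick == "i") {
        alpha <- alpha + rr$matched[rr$allele == i]
        beta <- beta + rr$mismatched[rr$allele == i]
      } else {
        alpha <- alpha + rr$matched[rr$allele == j]
        beta <- beta + rr$mismatched[rr$allele == j]
      }
    }
    c(alpha = alpha, gamma = if (alpha + beta > 0) alpha / (alpha + beta) else NA)
  }
  grid <- expand.grid(i = seq_along(alleles), j = seq_along(alleles))
  grid <- grid[grid$i <= grid$j, ]
  sc <- t(apply(grid, 1, function(g) score1(alleles[g[1]], alleles[g[2]])))
  ok <- !is.na(sc[, "gamma"])
  amax <- max(sc[ok, "alpha"])
  keep <- ok & sc[, "alpha"] >= (1 - tau) * amax
  gbest <- max(sc[keep, "gamma"])
  sel <- which(keep & abs(sc[, "gamma"] - gbest) < 1e-12)
  list(pairs = lapply(sel, function(s)
         c(alleles[grid$i[s]], alleles[grid$j[s]])),
       alpha = sc[sel, "alpha"], gamma = gbest)
}

# independent multiset-walk oracle: full enumeration via recursive expansion
oracle_best_walk <- function(ids, copy_numbers, edges) {
  items <- rep(ids, times = copy_numbers)
  ekey <- paste(edges$from, edges$to)
  wt <- function(a, b) {
    w <- edges$weight[match(paste(a, b), ekey)]
    if (is.na(w)) 0 else w
  }
  best <- list(weight = -Inf, walks = list())
  expand <- function(prefix, remaining, w) {
    if (!length(remaining)) {
      if (w > best$weight + 1e-9) best <<- list(weight = w, walks = list(prefix))
      else if (abs(w - best$weight) <= 1e-9)
        best$walks[[length(best$walks) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      nxt <- remaining[-match(v, remaining)]
      dw <- if (length(prefix)) wt(prefix[length(prefix)], v) else 0
      expand(c(prefix, v), nxt, w + dw)
    }
  }
  expand(integer(0), items, 0)
  best
}

# brute-force compatible-accuracy: maximum over both explicit pairings
oracle_compatible <- function(R1, R2, I1, I2) {
  f <- function(r, i) as.integer(length(intersect(r, i)) > 0)
  max(f(R1, I1) + f(R2, I2), f(R1, I2) + f(R2, I1))
}

small_db <- function(seed = 2, n_loci = 2, alleles = 6, len = 500) {
  simulate_allele_db(sim_db_config(n_loci = n_loci, alleles_per_locus = alleles,
                                   allele_length = len, seed = seed))
}
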