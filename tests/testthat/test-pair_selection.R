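test_that("matrices hold one best alignment per read-allele pair", {
  recs <- rbind(
    data.frame(read_id = "r1", allele = "a", matched = 95, mismatched = 5,
               identity = 0.95),
    data.frame(read_id = "r1", allele = "a", matched = 90, mismatched = 10,
               identity = 0.90), # duplicate, lower identity: dropped
    data.frame(read_id = "r1", allele = "b", matched = 80, mismatched = 20,
               identity = 0.80),
    data.frame(read_id = "r2", allele = "a", matched = 99, mismatched = 1,
               identity = 0.99))
  m <- build_matrices(recs)
  expect_equal(dim(m$M), c(2L, 2L))
  expect_equal(m$M["r1", "a"], 95)
  expect_equal(m$D["r1", "a"], 0.95)
  expect_true(is.na(m$M["r2", "b"]))   # absent, not zero
})

test_that("reads go to the higher-identity allele, coin-flipping exact ties", {
  recs <- data.frame(read_id = c("r1", "r1", "r2", "r3", "r3"),
                     allele = c("a", "b", "a", "a", "b"),
                     matched = c(99, 95, 90, 50, 50),
                     mismatched = c(1, 5, 10, 50, 50),
                     identity = c(0.99, 0.95, 0.90, 0.5, 0.5))
  m <- build_matrices(recs)
  xi <- assign_reads_to_pair(m, "a", "b", seed = 7)
  expect_equal(unname(xi[c("r1", "r2")]), c(1L, 1L)) # r2 aligned only to a
  expect_true(xi["r3"] %in% c(1L, 2L))
  # the tie coin is fair across seeds
  draws <- vapply(1:4000, function(s)
    assign_reads_to_pair(m, "a", "b", seed = s)[["r3"]], integer(1))
  frac_i <- mean(draws == 1L)
  expect_lt(abs(frac_i - 0.5), 3 * sqrt(0.25 / 4000))
  # unassigned read: aligned to neither member
  m2 <- build_matrices(rbind(recs, data.frame(read_id = "r4", allele = "c",
                                              matched = 10, mismatched = 0,
                                              identity = 1)))
  xi2 <- assign_reads_to_pair(m2, "a", "b", seed = 1)
  expect_true(is.na(xi2[["r4"]]))
})

test_that("pair scores aggregate matched and mismatched bases additively", {
  recs <- data.frame(read_id = c("r1", "r2", "r2"),
                     allele = c("a", "a", "b"),
                     matched = c(95, 40, 60), mismatched = c(5, 60, 40),
                     identity = c(0.95, 0.40, 0.60))
  m <- build_matrices(recs)
  xi <- assign_reads_to_pair(m, "a", "b", seed = 1)
  sc <- score_pair(m, xi, "a", "b")
  # r1 -> a (only), r2 -> b (0.60 > 0.40)
  expect_equal(sc$alpha, 95 + 60)
  expect_equal(sc$beta_mm, 5 + 40)
  expect_equal(sc$gamma, 155 / 200)
  # single read case
  xi1 <- assign_reads_to_pair(m, "a", "a", seed = 1)
  sc1 <- score_pair(m, xi1, "a", "a")
  expect_equal(sc1$alpha, 95 + 40)
})

test_that("pair scoring equals per-read brute force on random instances", {
  set.seed(99)
  for (rep in 1:10) {
    recs <- random_pair_instance(5, 4, missing_frac = 0.25)
    m <- build_matrices(recs)
    alleles <- m$alleles
    i <- sample(alleles, 1); j <- sample(alleles, 1)
    xi <- assign_reads_to_pair(m, i, j, seed = rep)
    sc <- score_pair(m, xi, i, j)
    # brute force from the raw records
    alpha <- 0; beta <- 0
    for (r in m$reads) {
      k <- xi[[r]]
      if (is.na(k)) next
      a <- if (k == 1L) i else j
      row <- recs[recs$read_id == r & recs$allele == a, ]
      alpha <- alpha + row$matched; beta <- beta + row$mismatched
    }
    expect_equal(sc$alpha, alpha)
    expect_equal(sc$beta_mm, beta)
  }
})

test_that("best-pair selection matches the exhaustive oracle", {
  set.seed(7)
  for (rep in 1:30) {
    recs <- random_pair_instance(sample(5:20, 1), sample(3:8, 1))
    tau <- sample(c(0, 0.02, 0.1), 1)
    m <- build_matrices(recs)
    got <- select_best_pair(m, tau = tau, seed = rep)
    orc <- oracle_best_pair(recs, tau)
    keys <- vapply(orc$pairs, function(p) paste(sort(p), collapse = "|"),
                   character(1))
    expect_true(paste(sort(c(got$allele_i, got$allele_j)), collapse = "|") %in% keys)
    expect_equal(got$gamma, orc$gamma, tolerance = 1e-12)
  }
})

test_that("degenerate candidate sets behave as limits", {
  recs <- data.frame(read_id = "r1", allele = "only", matched = 90,
                     mismatched = 10, identity = 0.9)
  m <- build_matrices(recs)
  best <- select_best_pair(m, seed = 1)
  expect_equal(c(best$allele_i, best$allele_j), c("only", "only"))
  expect_error(select_best_pair(m, alleles = character(0)), "empty")
  expect_error(select_best_pair(m, alleles = "unknown"), "unknown")
})

test_that("allele depths normalize assigned bases by allele length", {
  recs <- data.frame(read_id = c("r1", "r2"), allele = c("a", "a"),
                     matched = c(950, 900), mismatched = c(50, 100),
                     identity = c(0.95, 0.90))
  m <- build_matrices(recs)
  # all reads assigned to the homozygous pair member
  xi <- assign_reads_to_pair(m, "a", "a", seed = 1)
  d <- allele_depths(m, xi, "a", "a", len_i = 1000, len_j = 1000)
  expect_equal(unname(d["d_i"]), 2.0)
  # one full-length read on a 1000-base allele
  m1 <- build_matrices(recs[1, ])
  xi1 <- assign_reads_to_pair(m1, "a", "a", seed = 1)
  expect_equal(unname(allele_depths(m1, xi1, "a", "a", 1000, 1000)["d_i"]), 1.0)
})

test_that("zygosity follows the beta-posterior MAF rule", {
  z <- call_zygosity(10, 10)
  expect_equal(z$kappa_i, 11 / 22)
  expect_equal(z$state, "heterozygous")
  z2 <- call_zygosity(30, 2)
  expect_equal(z2$kappa_j, 3 / 34)
  expect_equal(z2$state, "homozygous")
  z0 <- call_zygosity(0, 0)
  expect_equal(z0$kappa_i, 0.5)
  expect_equal(z0$state, "heterozygous")
  # kappa_i + kappa_j == 1 exactly when priors are equal
  for (d in list(c(3, 9), c(0, 5), c(12.5, 12.5))) {
    z <- call_zygosity(d[1], d[2], a = 2, b = 2)
    expect_equal(z$kappa_i + z$kappa_j, 1)
  }
  # state is homozygous exactly when maf < chi
  set.seed(3)
  for (k in 1:20) {
    z <- call_zygosity(runif(1, 0, 40), runif(1, 0, 40), chi = 0.3)
    expect_identical(z$state == "homozygous", z$maf < 0.3)
  }
})

test_that("gamma is order-invariant and alpha scales under read duplication", {
  set.seed(5)
  recs <- random_pair_instance(8, 4, missing_frac = 0.1)
  m <- build_matrices(recs)
  best <- select_best_pair(m, seed = 1)
  perm <- recs[sample(nrow(recs)), ]
  best2 <- select_best_pair(build_matrices(perm), seed = 1)
  expect_equal(best$gamma, best2$gamma)
  expect_equal(sort(c(best$allele_i, best$allele_j)),
               sort(c(best2$allele_i, best2$allele_j)))
  # duplicating every read doubles alpha at the same gamma
  dup <- recs
  dup$read_id <- paste0(dup$read_id, "_dup")
  both <- build_matrices(rbind(recs, dup))
  i <- best$allele_i; j <- best$allele_j
  sc <- score_pair(both, assign_reads_to_pair(both, i, j, seed = 1), i, j)
  expect_equal(sc$alpha, 2 * best$alpha)
  expect_equal(sc$gamma, best$gamma)
})
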