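test_that("Shannon MLE matches closed forms", {
  expect_equal(shannon_mle(rep(0.25, 4)), log(4))
  expect_equal(shannon_mle(1), 0)
  expect_equal(shannon_mle(c(0.5, 0.25, 0.25), base = 2), 1.5)
  expect_equal(shannon_mle(c(0.5, 0.5, 0)), log(2)) # 0 log 0 = 0
  expect_error(shannon_mle(c(-0.1, 1.1)), "negative")
  expect_error(shannon_mle(c(0.2, 0.2)), "sum to 1")
})

test_that("the jackknife reduces small-sample entropy bias", {
  expect_equal(shannon_jackknife(c(20)), 0)
  expect_error(shannon_jackknife(c(1)), "at least 2")
  set.seed(3)
  n <- 20; true_H <- log(4)
  mle <- jk <- numeric(400)
  for (r in 1:400) {
    counts <- tabulate(sample(4, n, replace = TRUE), 4)
    mle[r] <- shannon_mle(counts / n)
    jk[r] <- shannon_jackknife(counts)
  }
  expect_lt(abs(mean(jk) - true_H), abs(mean(mle) - true_H))
  # large-sample consistency: jackknife converges to the MLE
  big <- tabulate(sample(4, 1e5, replace = TRUE), 4)
  expect_lt(abs(shannon_jackknife(big) - shannon_mle(big / 1e5)), 1e-3)
})

test_that("the coverage-adjusted estimator corrects the singleton regime", {
  expect_equal(shannon_nonparametric(c(50)), 0)
  # no singletons, large n: close to the plug-in value
  counts <- c(400, 300, 200, 100)
  expect_lt(abs(shannon_nonparametric(counts) - shannon_mle(counts / 1000)),
            5e-3)
  # heavy singleton load: corrects upward
  heavy <- c(5, rep(1, 15))
  expect_gt(shannon_nonparametric(heavy), shannon_mle(heavy / sum(heavy)))
  # all estimators agree in the full-coverage large-n limit
  set.seed(5)
  big <- tabulate(sample(6, 1e5, replace = TRUE), 6)
  h <- c(shannon_mle(big / 1e5), shannon_jackknife(big),
         shannon_nonparametric(big))
  expect_lt(max(h) - min(h), 1e-3)
})

test_that("Jensen-Shannon distance hits its closed forms and bounds", {
  expect_equal(jensen_shannon_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), sqrt(log(2)),
               tolerance = 1e-9)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1), base = 2), 1,
               tolerance = 1e-9)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1), distance = FALSE),
               log(2), tolerance = 1e-9)
  expect_error(jensen_shannon_distance(c(1, 0), c(0.5, 0.25, 0.25)), "length")
  set.seed(7)
  for (k in 1:25) {
    p <- rgamma(6, 1); p <- p / sum(p)
    q <- rgamma(6, 1); q <- q / sum(q)
    d <- jensen_shannon_distance(p, q)
    expect_equal(d, jensen_shannon_distance(q, p))
    expect_gte(d, 0)
    expect_lte(d, sqrt(log(2)) + 1e-12)
  }
})

test_that("intra-superpopulation JSD is below inter under planted structure", {
  set.seed(9)
  pops <- sprintf("P%02d", 1:12)
  superpop <- setNames(rep(c("S1", "S2", "S3"), each = 4), pops)
  base <- matrix(rgamma(12 * 8, 5), 12, 8)
  shift <- matrix(0, 12, 8)
  for (s in 1:3) shift[(4 * s - 3):(4 * s), ] <-
    matrix(rep(rgamma(8, 2), each = 4), 4, 8)
  f <- base + 3 * shift
  f <- f / rowSums(f)
  dimnames(f) <- list(pops, sprintf("HLA_G1_A%d", 1:8))
  tab <- freq_table(f, data.frame(allele = colnames(f), family = "HLA",
                                  gene = "HLA_G1"))
  res <- intra_inter_jsd(tab, superpop)
  expect_lt(mean(res$pairs$jsd[res$pairs$type == "intra"]),
            mean(res$pairs$jsd[res$pairs$type == "inter"]))
  expect_lt(res$p_value, 0.01)
  # identical frequencies: all distances zero, no test
  f0 <- matrix(rep(f[1, ], each = 12), 12, dimnames = dimnames(f))
  res0 <- intra_inter_jsd(freq_table(f0, tab$meta), superpop)
  expect_true(all(res0$pairs$jsd == 0))
  expect_true(is.na(res0$p_value))
  # single-population superpopulation warns
  sp1 <- superpop; sp1[1] <- "LONE"
  expect_warning(intra_inter_jsd(tab, sp1), "single population")
})

test_that("differential heterozygosity flags the planted locus only", {
  set.seed(11)
  n <- 100
  het <- cbind(L1 = c(rpois(n, 3), rpois(n, 1)),   # planted enrichment
               L2 = rpois(2 * n, 2),
               L3 = rpois(2 * n, 2),
               L4 = rep(0L, 2 * n))                 # constant: excluded
  groups <- rep(c("g1", "g2"), each = n)
  res <- differential_het_loci(het, groups)
  expect_true(res$significant[res$locus == "L1"])
  expect_equal(res$direction[res$locus == "L1"], "enriched")
  expect_false(any(res$significant[res$locus %in% c("L2", "L3")]))
  expect_true(is.na(res$p[res$locus == "L4"]))
  expect_match(res$note[res$locus == "L4"], "constant")
  # Bonferroni: raw p times the number of tested loci, capped at 1
  tested <- sum(!is.na(res$p))
  expect_equal(res$p_adj[!is.na(res$p)],
               pmin(res$p[!is.na(res$p)] * tested, 1))
  # identical groups: nothing significant
  het0 <- cbind(L1 = rpois(2 * n, 2), L2 = rpois(2 * n, 2))
  expect_false(any(differential_het_loci(het0, groups)$significant))
})

test_that("residual heterozygosity tests control for technical covariates", {
  set.seed(13)
  n <- 120
  run_one <- function(group_effect) {
    depth <- runif(n, 10, 60)
    rl <- runif(n, 5, 15)
    grp <- rep(c("AFR", "nonAFR"), each = n / 2)
    het <- 5 + 2 * log(depth) + 0.5 * rl +
      group_effect * (grp == "AFR") + rnorm(n)
    het_covariate_regression(het, data.frame(log_depth = log(depth),
                                             read_len = rl), grp)$p_value
  }
  # null: type-I error near nominal over replicates
  p0 <- vapply(1:200, function(i) run_one(0), numeric(1))
  expect_lt(mean(p0 < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  # a planted group shift survives covariate adjustment
  expect_lt(run_one(2), 1e-6)
  # degenerate inputs fail loudly
  expect_error(het_covariate_regression(rnorm(10), data.frame(x = rnorm(10)),
                                        rep("one", 10)), "two groups")
  x <- rnorm(20)
  expect_error(het_covariate_regression(rnorm(20),
                                        data.frame(a = x, b = 2 * x),
                                        rep(c("u", "v"), 10)), "collinear")
})

test_that("binary entropy filtering removes uninformative alleles", {
  f <- cbind(common = rep(0.5, 5), rare = rep(0.01, 5), absent = rep(0, 5))
  rownames(f) <- sprintf("P%d", 1:5)
  tab <- freq_table(f, data.frame(allele = colnames(f), family = "HLA",
                                  gene = "HLA_G1"))
  kept <- binary_entropy_filter(tab)
  expect_true("common" %in% kept)
  expect_false("rare" %in% kept)   # H(0.01) ~ 0.081 bits < 0.15
  expect_false("absent" %in% kept)
})

test_that("frequency tables round-trip through the TSV interface", {
  pop <- simulate_population_frequencies(sim_pop_config(seed = 15))
  tab <- pop$table
  path <- tempfile(fileext = ".tsv")
  long <- data.frame(population = rep(rownames(tab$freq), ncol(tab$freq)),
                     family = rep(tab$meta$family, each = nrow(tab$freq)),
                     gene = rep(tab$meta$gene, each = nrow(tab$freq)),
                     allele = rep(tab$meta$allele, each = nrow(tab$freq)),
                     frequency = as.vector(tab$freq),
                     count = as.vector(tab$counts))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tab2 <- read_freq_table(path)
  expect_equal(tab2$freq[rownames(tab$freq), colnames(tab$freq)], tab$freq)
  expect_equal(tab2$counts[rownames(tab$freq), colnames(tab$freq)],
               tab$counts)
})
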