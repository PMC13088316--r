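test_that("consensus substitutes phased variants and maps coordinates", {
  ref <- "ACGTACGTACGTACGTACGT"
  expect_equal(apply_consensus(ref, NULL, 1)$sequence, ref)
  v <- data.frame(pos = 10, ref = "C", alt = "G", hap1 = 1, hap2 = 0)
  out <- apply_consensus(ref, v, 1)
  expect_equal(substr(out$sequence, 10, 10), "G")
  expect_equal(nchar(out$sequence), nchar(ref))
  expect_equal(apply_consensus(ref, v, 2)$sequence, ref)
  # two phased SNVs: haplotype consensus differ at exactly those sites
  v2 <- rbind(data.frame(pos = 3, ref = "G", alt = "A", hap1 = 1, hap2 = 0),
              data.frame(pos = 13, ref = "A", alt = "T", hap1 = 0, hap2 = 1))
  h1 <- apply_consensus(ref, v2, 1)$sequence
  h2 <- apply_consensus(ref, v2, 2)$sequence
  diffs <- which(strsplit(h1, "")[[1]] != strsplit(h2, "")[[1]])
  expect_equal(diffs, c(3L, 13L))
  # indel shifts downstream coordinates
  vi <- data.frame(pos = 5, ref = "A", alt = "ATT", hap1 = 1, hap2 = 1)
  oi <- apply_consensus(ref, vi, 1)
  expect_equal(nchar(oi$sequence), nchar(ref) + 2)
  expect_equal(oi$coord_map$shift, 2)
  expect_error(apply_consensus(ref, data.frame(pos = 99, ref = "A", alt = "T",
                                               hap1 = 1, hap2 = 1), 1),
               "out of range")
  expect_error(apply_consensus(ref, data.frame(pos = 2, ref = "T", alt = "A",
                                               hap1 = 1, hap2 = 1), 1),
               "does not match")
})

test_that("segmentation tiles the reference and reassembles exactly", {
  ref <- random_dna(300)
  s0 <- segment_reference(ref)
  expect_equal(nrow(s0), 1L)
  expect_equal(s0$sequence, ref)
  s1 <- segment_reference(ref, 100)
  expect_equal(s1$start, c(0L, 100L))
  expect_equal(s1$end, c(100L, 300L))
  set.seed(8)
  bp <- sort(sample(1:299, 3))
  s3 <- segment_reference(ref, bp)
  expect_equal(paste(s3$sequence, collapse = ""), ref)
  expect_warning(segment_reference(ref, c(100, 100)), "duplicate")
  expect_error(segment_reference(ref, 300), "inside")
})

test_that("copy numbers floor the depth ratio, with a round alternative", {
  expect_equal(estimate_copy_numbers(c(40, 40, 40)), c(1L, 1L, 1L))
  expect_equal(estimate_copy_numbers(c(100, 0))[1], 2L)
  expect_equal(estimate_copy_numbers(c(20, 40, 60)), c(0L, 1L, 1L))
  expect_equal(estimate_copy_numbers(c(20, 40, 60), mode = "round"),
               c(0L, 1L, 2L))
  expect_error(estimate_copy_numbers(numeric(0)))
  expect_error(estimate_copy_numbers(c(0, 0)), "zero")
})

test_that("spanning reads must anchor both sides of the junction", {
  segs <- segment_reference(random_dna(200), 100)
  reads <- data.frame(start = c(80, 95, 100, 0), end = c(120, 105, 150, 100))
  expect_equal(count_spanning_reads(reads, segs[1, ], segs[2, ],
                                    min_anchor = 10), 1L)
  # read ending exactly at the junction never spans
  expect_equal(count_spanning_reads(reads[4, , drop = FALSE], segs[1, ],
                                    segs[2, ], min_anchor = 10), 0L)
  # simulated junction coverage stays within binomial bounds
  set.seed(11)
  L <- 400; rl <- 100; n <- 120 # ~30x
  starts <- sample(0:(L - rl), n, replace = TRUE)
  rd <- data.frame(start = starts, end = starts + rl)
  segs2 <- segment_reference(random_dna(L), 200)
  cnt <- count_spanning_reads(rd, segs2[1, ], segs2[2, ], min_anchor = 20)
  p <- (rl - 2 * 20 + 1) / (L - rl + 1) # admissible starts / all starts
  expect_gt(cnt, n * p - 3 * sqrt(n * p * (1 - p)))
  expect_lt(cnt, n * p + 3 * sqrt(n * p * (1 - p)))
})

test_that("the walk maximizes spanning-read weight over segment multisets", {
  segs <- segment_reference(random_dna(300), c(100, 200))
  # all copy number 1, reference-adjacent edges only: identity walk
  g1 <- segment_graph(segs, c(1, 1, 1),
                      data.frame(from = c(1, 2), to = c(2, 3), weight = c(5, 5)))
  w1 <- reconstruct_haplotype_path(g1)
  expect_equal(w1$walk, c(1, 2, 3))
  expect_equal(w1$sequence, paste(segs$sequence, collapse = ""))
  # tandem duplication of the middle segment
  g2 <- segment_graph(segs, c(1, 2, 1),
                      data.frame(from = c(1, 2, 2), to = c(2, 2, 3),
                                 weight = c(10, 8, 9)))
  w2 <- reconstruct_haplotype_path(g2)
  orc2 <- oracle_best_walk(segs$id, c(1, 2, 1), g2$edges)
  expect_equal(w2$walk, c(1, 2, 2, 3))
  expect_equal(w2$weight, orc2$weight)
  # deletion: zero-copy segment excluded
  g3 <- segment_graph(segs, c(1, 0, 1), data.frame(from = 1, to = 3, weight = 7))
  expect_equal(reconstruct_haplotype_path(g3)$walk, c(1, 3))
  # random instances: enumeration optimum and baseline dominance
  set.seed(13)
  for (rep in 1:8) {
    cn <- sample(0:2, 3, replace = TRUE)
    if (sum(cn) == 0) cn <- c(1, 1, 1)
    ed <- expand.grid(from = 1:3, to = 1:3)
    ed$weight <- rpois(nrow(ed), 3)
    g <- segment_graph(segs, cn, ed)
    w <- reconstruct_haplotype_path(g)
    orc <- oracle_best_walk(segs$id, cn, ed)
    expect_equal(w$weight, orc$weight)
    keys <- vapply(orc$walks, paste, character(1), collapse = ",")
    expect_true(paste(w$walk, collapse = ",") %in% keys)
    # optimum weight dominates the reference-order walk
    ref_walk <- rep(segs$id, times = cn)
    expect_gte(w$weight, polytypeR:::walk_weight(ref_walk, ed))
  }
  # no positive copy number: reference-order fallback with warning
  expect_warning(wf <- reconstruct_haplotype_path(
    segment_graph(segs, c(0, 0, 0), NULL)), "falling back")
  expect_true(wf$fallback)
  expect_equal(wf$walk, c(1, 2, 3))
})

test_that("low-depth windows are masked and nothing else changes", {
  seqc <- random_dna(300)
  flat <- mask_low_depth(seqc, rep(30, 300))
  expect_equal(flat$sequence, seqc)
  expect_equal(flat$masked_fraction, 0)
  allN <- mask_low_depth(seqc, rep(0, 300))
  expect_equal(allN$sequence, paste(rep("N", 300), collapse = ""))
  # windowed-mean oracle for a depth-2 stretch at positions [100, 150)
  depth <- c(rep(30, 100), rep(2, 50), rep(30, 150))
  out <- mask_low_depth(seqc, depth, masking_config(window = 20, min_depth = 5))
  w <- 20
  fail_windows <- which(vapply(1:(300 - w + 1), function(s)
    mean(depth[s:(s + w - 1)]) < 5, logical(1)))
  expected <- rep(FALSE, 300)
  for (s in fail_windows) expected[s:(s + w - 1)] <- TRUE
  got <- strsplit(out$sequence, "")[[1]] == "N"
  orig_N <- strsplit(seqc, "")[[1]] == "N"
  expect_equal(got & !orig_N, expected)
  # unmasked positions identical to input
  expect_equal(strsplit(out$sequence, "")[[1]][!expected],
               strsplit(seqc, "")[[1]][!expected])
  # monotone: a lower depth floor masks no more
  m_lo <- mask_low_depth(seqc, depth, masking_config(20, 3))
  expect_lte(m_lo$masked_fraction, out$masked_fraction)
  expect_error(mask_low_depth(seqc, rep(5, 10)), "length")
})

test_that("the naive caller finds planted substitutions", {
  set.seed(23)
  ref <- random_dna(300)
  mut <- ref
  pos <- c(40, 120, 260)
  for (p in pos) substr(mut, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[substr(mut, p, p)]
  reads <- unlist(lapply(1:30, function(i) {
    s <- sample(1:100, 1); substr(mut, s, s + 199)
  }))
  names(reads) <- paste0("r", seq_along(reads))
  cc <- naive_caller(reads, ref)
  expect_setequal(cc$variants$pos, pos)
  expect_true(all(cc$variants$af > 0.9))
})

test_that("iterative reconstruction is a fixed point on error-free reads", {
  set.seed(31)
  ref <- random_dna(250)
  reads <- setNames(rep(ref, 8), paste0("r", 1:8)) # uniform full coverage
  out <- iterate_reconstruction(reads, ref, max_iter = 5)
  expect_equal(attr(out$hap1, "iterations"), 1L)
  expect_true(attr(out$hap1, "converged"))
  expect_equal(out$hap1$sequence, ref)
  expect_equal(out$hap2$sequence, ref)
})

test_that("iteration converges onto planted substitutions", {
  set.seed(37)
  ref <- random_dna(300)
  mut <- ref
  pos <- c(30, 90, 150, 210, 270)
  for (p in pos) substr(mut, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[substr(mut, p, p)]
  reads <- unlist(lapply(1:40, function(i) {
    s <- sample(1:100, 1); substr(mut, s, s + 199)
  }))
  names(reads) <- paste0("r", seq_along(reads))
  out <- iterate_reconstruction(reads, ref, max_iter = 5)
  h <- strsplit(out$hap1$sequence, "")[[1]]
  m <- strsplit(mut, "")[[1]]
  unmasked <- h != "N"
  expect_gt(mean(unmasked), 0.7)
  expect_equal(sum(h[unmasked] != m[unmasked]), 0L)
})

test_that("a heterozygous planted pair is reconstructed to high identity", {
  sim <- small_db(seed = 41, n_loci = 1, alleles = 6, len = 600)
  db <- sim$db
  g <- db$alleles$name[c(2, 5)]
  rd <- simulate_diploid_reads(db, g, sim_read_config(depth = 30, accuracy = 0.95,
                                                      read_length = 450, seed = 42))
  al <- align_reads(rd$reads, db)
  mat <- build_matrices(al)
  best <- select_best_pair(mat, seed = 1)
  xi <- best$assignment
  groups <- list(names(xi)[!is.na(xi) & xi == 1L], names(xi)[!is.na(xi) & xi == 2L])
  hs <- iterate_reconstruction(rd$reads,
                               db$alleles[c(best$allele_i, best$allele_j), "sequence"],
                               read_groups = groups, max_iter = 4)
  ident_to <- function(hap, truth_allele) {
    a <- naive_align(gsub("N", "", hap$sequence),
                     db$alleles[truth_allele, "sequence"], both_strands = FALSE)
    a$identity
  }
  ids <- c(max(ident_to(hs$hap1, g[1]), ident_to(hs$hap1, g[2])),
           max(ident_to(hs$hap2, g[1]), ident_to(hs$hap2, g[2])))
  expect_true(all(ids >= 0.995))
})
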