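toy_model <- function(ori, ter, N, id = "toy") {
  build_replichores(ori, N = N, ter = ter, genome_id = id)
}

gene_at <- function(mid0, strand, N, id = "toy") {
  # single-base gene whose continuous midpoint is mid0 + 0.5
  data.frame(genome_id = id, start = mid0 + 1L, end = mid0 + 1L,
             strand = strand, label = "g", wraps = FALSE,
             stringsAsFactors = FALSE)
}

test_that("ori/ter are recovered on synthetic genomes with known truth", {
  set.seed(71)
  hits <- 0L
  for (i in 1:5) {
    true_ori <- sample.int(200000L, 1L) - 1L
    sp <- skew_spec(N = 200000L, ori = true_ori, seed = 700 + i)
    g <- generate_genome(sp)
    m <- estimate_ori_ter(disparity_curves(g$seq))
    expect_identical(m$source, "extrema")
    expect_true(m$confidence > 0)
    if (circ_dist(m$ori, sp$ori, sp$N) <= 0.01 * sp$N &&
        circ_dist(m$ter, sp$ter, sp$N) <= 0.01 * sp$N) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("ori estimation is rotation-equivariant", {
  sp <- skew_spec(N = 100000L, ori = 0L, seed = 72)
  g <- generate_genome(sp)
  m0 <- estimate_ori_ter(disparity_curves(g$seq))
  k <- 31234L
  rot <- rotate_to_ori(g$seq, k)  # rotation by k: old position k -> index 0
  mk <- estimate_ori_ter(disparity_curves(rot))
  expect_lte(circ_dist(mk$ori, (m0$ori - k) %% sp$N, sp$N), 0.01 * sp$N)
})

test_that("flat disparity tracks give a no-signal error", {
  # AT-alternating genome: the G-C track is identically zero
  curves <- disparity_curves(genome_seq("flat", strrep("AT", 600)))
  expect_error(estimate_ori_ter(curves), "no signal")
})

test_that("build_replichores uses the interval midpoint, ties broken down", {
  oric <- data.frame(genome_id = "g1", oric_start = 1L, oric_end = 300L)
  m <- build_replichores(oric, N = 1000L, ter = 600L)
  expect_identical(m$ori, 149L)  # 1-based midpoint 150
  expect_identical(m$source, "table")
  m2 <- build_replichores(0L, N = 1000L, ter = 500L)
  expect_identical(c(m2$ori, m2$ter), c(0L, 500L))
  expect_error(build_replichores(0L, N = 1000L, ter = 0L), "collides")
})

test_that("ter can be estimated from curves when only ori is known", {
  sp <- skew_spec(N = 100000L, ori = 20000L, seed = 73)
  g <- generate_genome(sp)
  m <- build_replichores(sp$ori, N = sp$N,
                         curves = disparity_curves(g$seq),
                         genome_id = "synth_1")
  expect_lte(circ_dist(m$ter, sp$ter, sp$N), 0.01 * sp$N)
})

test_that("strand assignment follows the arc convention on both arcs", {
  m <- toy_model(0L, 50L, 100L)
  expect_identical(assign_strand(gene_at(10L, "+", 100L), m), "leading")
  expect_identical(assign_strand(gene_at(10L, "-", 100L), m), "lagging")
  expect_identical(assign_strand(gene_at(60L, "+", 100L), m), "lagging")
  expect_identical(assign_strand(gene_at(60L, "-", 100L), m), "leading")
  # wrapping arc: ori = 80, ter = 30
  m2 <- toy_model(80L, 30L, 100L)
  expect_identical(assign_strand(gene_at(10L, "+", 100L), m2), "leading")
  expect_identical(assign_strand(gene_at(50L, "+", 100L), m2), "lagging")
})

test_that("strand flip always flips the assignment; arcs partition the circle", {
  m <- toy_model(80L, 30L, 100L)
  for (mid in 0:99) {
    plus <- assign_strand(gene_at(mid, "+", 100L), m)
    minus <- assign_strand(gene_at(mid, "-", 100L), m)
    expect_true(plus != minus)
  }
  # exhaustive half-open partition check (integer midpoints via in-arc test)
  pos <- 0:99
  arc1 <- (pos - 80) %% 100 < (30 - 80) %% 100
  arc2 <- (pos - 30) %% 100 < (80 - 30) %% 100
  expect_true(all(xor(arc1, arc2)))
})

test_that("SGD counts and fraction follow the toy enumeration", {
  m <- toy_model(0L, 50L, 100L)
  genes <- rbind(gene_at(10L, "+", 100L), gene_at(10L, "-", 100L),
                 gene_at(60L, "+", 100L), gene_at(60L, "-", 100L))
  s <- sgd_fraction(genes, m)
  expect_identical(s$n_leading, 2L)
  expect_identical(s$n_lagging, 2L)
  expect_equal(s$fraction_leading, 0.5)

  all_lead <- rbind(gene_at(10L, "+", 100L), gene_at(60L, "-", 100L))
  expect_equal(sgd_fraction(all_lead, m)$fraction_leading, 1.0)

  other <- gene_at(10L, "+", 100L, id = "elsewhere")
  expect_warning(s2 <- sgd_fraction(rbind(genes, other), m), "other replicons")
  expect_identical(s2$n_leading + s2$n_lagging, 4L)
  expect_error(sgd_fraction(genes[0, ], m), "no assignable")
})

test_that("SGD recovers the designed leading-placement probability", {
  sp <- skew_spec(N = 500000L, ori = 0L, n_genes = 1000L,
                  p_leading = 0.78, mean_gene_len = 300L, seed = 74)
  g <- generate_genome(sp)
  ann <- generate_genes(sp, g$truth)
  m <- toy_model(sp$ori, sp$ter, sp$N, id = "synth_1")
  s <- sgd_fraction(ann$genes, m)
  ci <- binom_ci(1000L, 0.78)
  expect_gte(s$fraction_leading, ci[["lower"]])
  expect_lte(s$fraction_leading, ci[["upper"]])
  # assignment agrees with the generator's intended classes exactly
  expect_identical(assign_strand(ann$genes, m), ann$true_class)
})

test_that("rotation to ori moves sequence and genes consistently", {
  s <- genome_seq("t", "ACGT")
  expect_identical(rotate_to_ori(s, 2L)$residues, "GTAC")
  expect_identical(rotate_to_ori(s, 4L)$residues, "ACGT")
  expect_error(rotate_to_ori(genome_seq("t", "ACGT", "linear"), 1L), "linear")

  genes <- data.frame(genome_id = "t", start = 3L, end = 4L, strand = "+",
                      label = "g", wraps = FALSE, stringsAsFactors = FALSE)
  rot <- rotate_genes(genes, 2L, N = 4L)
  expect_identical(c(rot$start, rot$end), c(1L, 2L))
  # rotation can push a gene across the deposited start
  rot2 <- rotate_genes(genes, 3L, N = 4L)
  expect_true(rot2$wraps)
})

test_that("replichore arcs export as valid BED intervals covering the circle", {
  bed <- replichore_bed(toy_model(80L, 30L, 100L))
  expect_true(all(bed$chromStart < bed$chromEnd))
  expect_identical(sum(bed$chromEnd - bed$chromStart), 100L)
})
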