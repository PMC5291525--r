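fake_records <- function(phylum, zcc, gc = NULL, sgd = NULL, prefix = phylum) {
  n <- length(zcc)
  data.frame(genome_id = sprintf("%s_%02d", prefix, seq_len(n)),
             N = 1000L, gc_content = if (is.null(gc)) 0.5 else gc,
             zcc = zcc, rymk = 0, degenerate = is.na(zcc),
             ori = NA_integer_, ter = NA_integer_, ori_source = NA_character_,
             sgd_fraction = if (is.null(sgd)) NA_real_ else sgd,
             phylum = phylum, stringsAsFactors = FALSE)
}

test_that("phylum summaries reproduce direct arithmetic", {
  rec <- fake_records("PhyA", c(0.9, 0.8, -0.1))
  s <- summarize_phylum(rec, min_n = 1L)
  expect_identical(s$n_positive, 2L)
  expect_identical(s$n_negative, 1L)
  expect_equal(s$pct_positive, 66.7)
  expect_equal(s$mean_zcc, mean(c(0.9, 0.8, -0.1)))
  expect_equal(s$sd_zcc, sd(c(0.9, 0.8, -0.1)))
  expect_identical(s$group, "P-ZCC")
})

test_that("majority-sign grouping matches the canonical cohort patterns", {
  # strongly positive-dominated phylum (92.7% positive)
  rec <- fake_records("FirmLike", c(rep(0.9, 433), rep(-0.5, 34)))
  s <- summarize_phylum(rec)
  expect_identical(s$group, "P-ZCC")
  expect_equal(s$pct_positive, 92.7)
  expect_equal(s$pct_negative, 7.3)
  # entirely negative phylum
  rec <- fake_records("ChlaLike", rep(-0.94, 52))
  s <- summarize_phylum(rec)
  expect_identical(s$group, "N-ZCC")
  expect_equal(s$pct_negative, 100.0)
  # small majority (9 of 15 positive)
  expect_identical(classify_group(9L, 6L), "P-ZCC")
  expect_identical(classify_group(0L, 57L), "N-ZCC")
  expect_warning(g <- classify_group(3L, 3L), "tie")
  expect_true(is.na(g))
  expect_error(classify_group(0L, 0L), "cannot classify")
})

test_that("phyla at or below min_n are dropped; percentages account for everyone", {
  rec <- rbind(fake_records("Big", rnorm(20)),
               fake_records("Edge", rnorm(15)),
               fake_records("Tiny", rnorm(3)))
  s <- summarize_phylum(rec, min_n = 15L)
  expect_identical(s$phylum, "Big")  # strictly more than 15
  s2 <- summarize_phylum(rec, min_n = 2L)
  expect_identical(sort(s2$phylum), c("Big", "Edge", "Tiny"))
  tot <- s2$pct_positive + s2$pct_negative +
    round(100 * (s2$n_zero + s2$n_degenerate) / s2$n_total, 1)
  expect_true(all(abs(tot - 100) <= 0.1))
})

test_that("degenerate and exactly-zero indexes are reported separately", {
  rec <- fake_records("PhyA", c(0.5, -0.5, 0, NA))
  s <- suppressWarnings(summarize_phylum(rec, min_n = 1L))
  expect_identical(s$n_zero, 1L)
  expect_identical(s$n_degenerate, 1L)
  expect_identical(s$n_total, 4L)
  expect_warning(summarize_phylum(rec, min_n = 1L), "tie")
})

test_that("Tukey fences match hand computation and exhaustive checks", {
  tf <- tukey_outliers(c(1:9, 100), ids = c(letters[1:9], "big"))
  expect_equal(tf$q1, 3.25)
  expect_equal(tf$q3, 7.75)
  expect_identical(tf$outlier_ids, "big")
  expect_identical(tf$outlier_values, 100)

  same <- tukey_outliers(rep(2.5, 8))
  expect_equal(same$iqr, 0)
  expect_identical(length(same$outlier_ids), 0L)

  sym <- tukey_outliers(c(-3, -2, -1, 0, 1, 2, 3))
  expect_identical(length(sym$outlier_ids), 0L)

  expect_error(tukey_outliers(c(1, 2, 3)), "at least 4")

  set.seed(81)
  for (i in 1:25) {
    v <- rnorm(sample(4:60, 1)) * 10^sample(-1:2, 1)
    tf <- tukey_outliers(v)
    expect_identical(tf$is_outlier, v < tf$lower | v > tf$upper)
    expect_true(tf$lower <= tf$q1 && tf$q1 <= tf$q3 && tf$q3 <= tf$upper)
  }
})

test_that("polymerase cross-tab counts PC/DE per phylum in both variants", {
  rec <- rbind(fake_records("PhyA", c(0.9, 0.8, -0.7)),
               fake_records("PhyB", c(-0.9, -0.8)))
  meta <- data.frame(genome_id = c(rec$genome_id, "unseen"),
                     phylum = c(rec$phylum, "PhyC"),
                     has_polc = c(TRUE, FALSE, FALSE, FALSE, NA, TRUE),
                     dnae_types = "DnaE", stringsAsFactors = FALSE)
  expect_warning(xt <- polymerase_crosstab(rec, meta), "unknown PolC")
  expect_identical(xt$all["DE", "PhyA"], 2L)
  expect_identical(xt$all["PC", "PhyA"], 1L)
  expect_identical(xt$all["DE", "PhyB"], 1L)
  expect_identical(xt$all["PC", "PhyB"], 0L)
  expect_identical(sum(xt$all), xt$n_matched)

  # removing one flagged genome decrements exactly one cell
  xt2 <- suppressWarnings(
    polymerase_crosstab(rec, meta, outlier_ids = "PhyA_03"))
  expect_identical(sum(xt2$all) - sum(xt2$no_outliers), 1L)
  expect_identical(xt2$no_outliers["DE", "PhyA"], 1L)

  rec2 <- rbind(rec, fake_records("PhyZ", 0.1, prefix = "nometa"))
  w <- capture_warnings(polymerase_crosstab(rec2, meta))
  expect_match(w, "without polymerase", all = FALSE)
})

test_that("cross-tab column sums conserve genome counts on randomized metadata", {
  set.seed(82)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    rec <- fake_records("Mix", rnorm(n))
    rec$phylum <- sample(c("P1", "P2", "P3"), n, replace = TRUE)
    meta <- data.frame(genome_id = rec$genome_id, phylum = rec$phylum,
                       has_polc = sample(c(TRUE, FALSE), n, replace = TRUE),
                       dnae_types = "DnaE", stringsAsFactors = FALSE)
    xt <- polymerase_crosstab(rec, meta)
    expected <- table(rec$phylum)
    got <- colSums(xt$all)
    expect_equal(got[names(expected)], c(expected)[names(expected)],
                 ignore_attr = TRUE)
  }
})

test_that("SGD means split by ZCC sign, absent class reported as NA", {
  rec <- rbind(
    fake_records("PhyA", c(0.9, 0.8, -0.5), sgd = c(0.8, 0.9, 0.6)),
    fake_records("NegOnly", c(-0.9, -0.7), sgd = c(0.55, 0.65)))
  out <- sgd_by_sign(rec)
  a <- out[out$phylum == "PhyA", ]
  expect_equal(a$mean_sgd_positive, 0.85)
  expect_equal(a$mean_sgd_negative, 0.6)
  b <- out[out$phylum == "NegOnly", ]
  expect_true(is.na(b$mean_sgd_positive))
  expect_equal(b$mean_sgd_negative, 0.6)
})
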