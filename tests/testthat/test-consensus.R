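test_that("binomial tail matches hand-derived values and is monotone", {
  expect_equal(binomial_tail(5, 5), 0.03125)
  expect_equal(binomial_tail(4, 4), 0.0625)
  expect_equal(binomial_tail(10, 9), 11 / 1024)
  expect_equal(binomial_tail(7, 0), 1)
  expect_equal(binomial_tail(0, 0), 1)
  expect_error(binomial_tail(3, 4), "k <= n")
  for (n in c(5, 9, 16))
    expect_true(all(diff(binomial_tail(rep(n, n + 1), 0:n)) < 0))
})

test_that("column test rejects only when the tail reaches alpha", {
  expect_equal(column_test(5, 5), list(rejected = TRUE, E_hat = 5))
  expect_equal(column_test(4, 4), list(rejected = FALSE, E_hat = 0))
  expect_equal(column_test(10, 9), list(rejected = TRUE, E_hat = 9))
  expect_error(column_test(5, 5, alpha = 0), "alpha")
  expect_error(column_test(5, 5, alpha = 1), "alpha")
})

test_that("no depth at or below 4 can ever be rejected at alpha = 0.05", {
  for (n in 0:4)
    for (k in 0:n)
      expect_false(column_test(n, k)$rejected)
})

test_that("column probability floors at epsilon and caps at 1", {
  expect_equal(column_probability(5, 5), 1)
  expect_equal(column_probability(0, 8), 1e-4)
  expect_equal(column_probability(9, 10), 0.9)
  expect_error(column_probability(0, 0), "n = 0")
})

test_that("column log probability sums predictor logs", {
  expect_equal(column_log_probability(rep(1, 5)), 0)
  expect_equal(column_log_probability(rep(1e-4, 5)), 5 * log(1e-4))
  expect_equal(column_log_probability(c(1, 0.5)), log(0.5))
  expect_error(column_log_probability(numeric(0)), "empty")
})

test_that("segment delineation returns maximal runs", {
  pos <- rep(FALSE, 25)
  pos[3:9] <- TRUE; pos[15:20] <- TRUE
  segs <- delineate_segments(pos)
  expect_equal(segs, data.frame(start = c(3L, 15L), end = c(9L, 20L)))
  expect_equal(nrow(delineate_segments(rep(FALSE, 10))), 0L)
  one <- rep(FALSE, 10); one[4] <- TRUE
  expect_equal(delineate_segments(one), data.frame(start = 4L, end = 4L))
})

test_that("fragments bridged by one composite run become one segment", {
  # all predictors union-positive over 8..32 -> composite run 8..32
  k <- matrix(0L, 3, 40)
  k[, 8:32] <- 1L
  proj <- list(n = rep(5L, 40), k = k, category = "TM")
  raw <- data.frame(start = c(10L, 22L), end = c(18L, 30L))
  merged <- merge_tm_fragments(raw, proj)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$start, 10L)
  expect_equal(merged[[1]]$end, 30L)
  expect_equal(nrow(merged[[1]]$fragments), 2L)
})

test_that("fragments in distinct composite runs stay separate", {
  k <- matrix(0L, 3, 40)
  k[, 5:15] <- 1L; k[, 25:35] <- 1L
  proj <- list(n = rep(5L, 40), k = k, category = "TM")
  raw <- data.frame(start = c(7L, 27L), end = c(12L, 33L))
  merged <- merge_tm_fragments(raw, proj)
  expect_length(merged, 2L)
  # a single unfragmented run passes through unchanged
  single <- merge_tm_fragments(data.frame(start = 7L, end = 12L), proj)
  expect_length(single, 1L)
  expect_equal(nrow(single[[1]]$fragments), 1L)
})

test_that("a predictor splitting two helices keeps them separate", {
  # predictor 1 unions across 5..35; predictor 2 sees two helices
  k <- matrix(0L, 2, 40)
  k[1, 5:35] <- 1L
  k[2, c(5:15, 25:35)] <- 1L
  proj <- list(n = rep(5L, 40), k = k, category = "TM")
  raw <- data.frame(start = c(6L, 26L), end = c(14L, 34L))
  merged <- merge_tm_fragments(raw, proj)   # composite = intersection
  expect_length(merged, 2L)
})

test_that("segment scores are (weighted) means of column log probabilities", {
  L <- c(-2, -4, -6)
  expect_equal(score_segment(data.frame(start = 1L, end = 3L), L), -4)
  # fragments of 2 and 6 predicted columns with psi -3 and -7
  L2 <- c(rep(-3, 2), rep(0, 4), rep(-7, 6))
  fr <- data.frame(start = c(1L, 7L), end = c(2L, 12L))
  expect_equal(score_segment(fr, L2), (2 * -3 + 6 * -7) / 8)
  expect_equal(score_segment(data.frame(start = 1L, end = 3L), rep(0, 3)), 0)
  expect_error(score_segment(data.frame(start = integer(0),
                                        end = integer(0)), L),
               "zero predicted")
})

test_that("SP span runs from column 1 to the most C-terminal boundary", {
  L <- rep(-1, 25)
  seg <- sp_segment_span(data.frame(start = c(2L, 12L), end = c(8L, 19L)), L)
  expect_equal(seg$start_col, 1L)
  expect_equal(seg$end_col, 19L)
  expect_equal(seg$n_pred_columns, 7L + 8L)
  # psi is the mean over the WHOLE span, not only predicted columns
  L2 <- rep(2 * log(1e-4), 19)
  L2[c(2:8, 12:19)] <- 0
  seg2 <- sp_segment_span(data.frame(start = c(2L, 12L), end = c(8L, 19L)), L2)
  expect_equal(seg2$score, mean(L2[1:19]))
  single <- sp_segment_span(data.frame(start = 1L, end = 20L), L)
  expect_equal(c(single$start_col, single$end_col), c(1L, 20L))
})

test_that("TM regions concatenate under the strict 40-column linker rule", {
  s1 <- structure(list(category = "TM", start_col = 30L, end_col = 50L,
                       fragments = data.frame(start = 30L, end = 50L),
                       n_pred_columns = 21L, score = -1, retained = TRUE),
                  class = "detected_segment")
  s2 <- s1; s2$start_col <- 89L; s2$end_col <- 100L   # gap 38 < 40
  expect_length(concatenate_tm_regions(list(s1, s2)), 1L)
  s3 <- s1; s3$start_col <- 91L; s3$end_col <- 100L   # gap exactly 40
  expect_length(concatenate_tm_regions(list(s1, s3)), 2L)
  expect_length(concatenate_tm_regions(list(s1)), 1L)
})

test_that("cutoffs retain at the boundary (ties kept)", {
  mk <- function(category, score)
    structure(list(category = category, start_col = 1L, end_col = 5L,
                   fragments = data.frame(start = 1L, end = 5L),
                   n_pred_columns = 5L, score = score, retained = NA),
              class = "detected_segment")
  out <- apply_cutoffs(list(mk("TM", -11), mk("TM", -12.5), mk("SP", -1)))
  expect_equal(vapply(out, `[[`, NA, "retained"), c(TRUE, FALSE, TRUE))
})

test_that("audit recovers a planted block with perfect masks", {
  spec <- synth_spec(n_sequences = 10, n_columns = 80, gap_rate = 0,
                     segments = data.frame(category = "TM",
                                           start = 30L, end = 50L),
                     seed = 21)
  m <- make_alignment(spec)
  ms <- perfect_masks(m, c(30, 50), D = 5)
  audit <- audit_domain(m, ms)
  expect_true(audit$tm_problematic)
  retained <- Filter(function(s) s$retained, audit$segments)
  expect_length(retained, 1L)
  expect_equal(c(retained[[1]]$start_col, retained[[1]]$end_col), c(30, 50))
  expect_equal(retained[[1]]$score, 0)     # all p_hat = 1
})

test_that("all-zero masks yield no segments; depth <= 4 never flags", {
  spec <- synth_spec(n_sequences = 10, n_columns = 60, gap_rate = 0,
                     segments = NULL, sensitivity = 0, fp_rate = 0,
                     seed = 3)
  m <- make_alignment(spec)
  ms <- make_masks(m, spec)
  audit <- audit_domain(m, ms)
  expect_length(audit$segments, 0L)
  expect_false(audit$tm_problematic || audit$sp_problematic)
  # 4 rows with PERFECT masks: the test has no power
  spec4 <- synth_spec(n_sequences = 4, n_columns = 60, gap_rate = 0,
                      segments = data.frame(category = "TM",
                                            start = 20L, end = 40L),
                      seed = 5)
  m4 <- make_alignment(spec4)
  ms4 <- perfect_masks(m4, c(20, 40), D = 5)
  expect_length(audit_domain(m4, ms4)$segments, 0L)
})

test_that("audit matches the direct column-state reference on small cases", {
  set.seed(17)
  for (rep in 1:15) {
    nc <- sample(4:8, 1)
    nr <- sample(5:8, 1)
    spec <- synth_spec(n_sequences = nr, n_columns = nc,
                       segments = data.frame(category = "TM",
                                             start = 2L,
                                             end = min(nc, 4L)),
                       gap_rate = 0.15, sensitivity = 0.8, fp_rate = 0.2,
                       n_tm_predictors = 3, n_sp_predictors = 1,
                       seed = 1000 + rep)
    m <- make_alignment(spec)
    ms <- make_masks(m, spec)
    ref <- reference_positive_columns(m, ms, "TM")
    proj <- project_to_columns(m, ms, "TM")
    st <- column_stats(proj)
    expect_equal(st$positive, ref$positive)
    expect_equal(st$L, ref$L, tolerance = 1e-12)
    expect_equal(delineate_segments(st), delineate_segments(ref$positive))
  }
})

test_that("column statistics are invariant under row permutation", {
  spec <- synth_spec(n_sequences = 12, n_columns = 50,
                     segments = data.frame(category = "TM",
                                           start = 15L, end = 30L),
                     seed = 77)
  m <- make_alignment(spec)
  ms <- make_masks(m, spec)
  st1 <- column_stats(project_to_columns(m, ms, "TM"))
  set.seed(1)
  perm <- sample(seq_along(m$ids))
  m2 <- msa(m$ids[perm], m$seqs[perm])
  st2 <- column_stats(project_to_columns(m2, ms, "TM"))
  expect_equal(st1$L, st2$L)
  expect_equal(st1$positive, st2$positive)
})

test_that("segment scores stay within [D log(eps), 0]", {
  spec <- synth_spec(seed = 13,
                     segments = data.frame(category = c("TM", "SP"),
                                           start = c(41L, 1L),
                                           end = c(61L, 15L)))
  m <- make_alignment(spec)
  ms <- make_masks(m, spec)
  audit <- audit_domain(m, ms)
  for (s in audit$segments) {
    D <- if (s$category == "TM") 5 else 2
    expect_gte(s$score, D * log(1e-4))
    expect_lte(s$score, 0)
  }
})
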