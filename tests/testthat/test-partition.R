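test_that("degenerate masks send everything to one side", {
  set.seed(61)
  hmm <- random_hmm(4)
  sq <- random_aa_string(7)
  aln <- viterbi_hmmls(hmm, sq)
  empty <- model_region_mask(4)
  p0 <- partition_score(aln, hmm, empty)
  expect_equal(p0$S_TM, 0)
  expect_equal(p0$S_NG + p0$S_const, p0$S_total)
  full <- model_region_mask(4, ranges = data.frame(start = 1, end = 4))
  p1 <- partition_score(aln, hmm, full)
  expect_equal(p1$S_NG, 0)
  expect_equal(p1$S_TM + p1$S_const, p1$S_total)
  expect_error(model_region_mask(4, ranges = data.frame(start = 3, end = 5)),
               "outside")
})

test_that("partition equals a hand-summed decomposition on a fixed path", {
  # deterministic 4-node model: node s strongly favours residue s of "ACDE"
  emit <- matrix(-6, 4, 20)
  for (s in 1:4) emit[s, s] <- s          # A=1, C=2, D=3, E=4 bits
  tr <- matrix(rep(c(-0.5, -3, -3, -1, -1, -1, -1, -Inf, -Inf), each = 4),
               nrow = 4)
  colnames(tr) <- domaudit:::TRANSITION_NAMES
  tr[1, "bm"] <- -0.25; tr[4, "me"] <- -0.125
  hmm <- profile_hmm(emit, matrix(0, 4, 20), tr)
  aln <- viterbi_hmmls(hmm, "ACDE")
  expect_true(all(aln$path$state == "M"))
  expect_equal(aln$score, -0.25 + (1 + 2 + 3 + 4) + 3 * -0.5 - 0.125)
  mask <- model_region_mask(4, ranges = data.frame(start = 3, end = 4))
  p <- partition_score(aln, hmm, mask)
  # flagged nodes 3,4: emissions 3+4 plus the mm transition leaving node 3
  expect_equal(p$S_TM, 3 + 4 - 0.5)
  # unflagged nodes 1,2: emissions 1+2 plus mm leaving nodes 1 and 2
  expect_equal(p$S_NG, 1 + 2 - 1)
  expect_equal(p$S_const, -0.25 - 0.125)
  expect_equal(p$S_NG + p$S_TM + p$S_const, p$S_total, tolerance = 1e-12)
})

test_that("partition additivity holds on fuzzed models and masks", {
  set.seed(97)
  for (rep in 1:50) {
    M <- sample(2:6, 1)
    hmm <- random_hmm(M, extra_ports = rep %% 4 == 0)
    sq <- random_aa_string(sample(M:12, 1))
    aln <- viterbi_hmmls(hmm, sq)
    nodes <- sample(M, sample(0:M, 1))
    p <- partition_score(aln, hmm, model_region_mask(M, nodes = nodes))
    expect_lt(abs(p$S_NG + p$S_TM + p$S_const - p$S_total), 1e-9)
  }
})

test_that("gathering partition follows the per-seed scaling arithmetic", {
  # single seed with S_const = 0, S_NG = 30, S_TM = 10, GA = 20:
  # c = 0.5, G_TM = 5, G_NG = 15 -- engineered via a deterministic model
  emit <- matrix(-20, 4, 20)
  emit[1, 1] <- 15; emit[2, 1] <- 15      # unflagged nodes: 30 bits on 'A'
  emit[3, 1] <- 5; emit[4, 1] <- 5        # flagged nodes: 10 bits on 'A'
  tr <- matrix(rep(c(0, -9, -9, -9, -9, -9, -9, -Inf, -Inf), each = 4),
               nrow = 4)
  colnames(tr) <- domaudit:::TRANSITION_NAMES
  tr[1, "bm"] <- 0; tr[4, "me"] <- 0
  hmm <- profile_hmm(emit, matrix(0, 4, 20), tr, GA = 20)
  mask <- model_region_mask(4, ranges = data.frame(start = 3, end = 4))
  gp <- gathering_partition(hmm, c(seed1 = "AAAA"), mask)
  expect_equal(gp$seed_table$c, 0.5)
  expect_equal(gp$G_TM, 5)
  expect_equal(gp$G_NG, 15)
  # two identical seeds: unchanged (mean idempotence)
  gp2 <- gathering_partition(hmm, c(a = "AAAA", b = "AAAA"), mask)
  expect_equal(gp2$G_NG, gp$G_NG)
  # empty mask: G_TM = 0 and G_NG = GA exactly
  gp3 <- gathering_partition(hmm, c(a = "AAAA"), model_region_mask(4))
  expect_equal(gp3$G_TM, 0)
  expect_identical(gp3$G_NG, gp3$GA)
})

test_that("per-seed scaling reproduces GA identically on fixtures", {
  fx <- make_profile(profile_spec(seed = 5, n_members = 12))
  gp <- gathering_partition(fx$hmm, fx$members, fx$mask)
  tab <- gp$seed_table
  expect_true(all(abs(tab$c * (tab$S_NG + tab$S_TM) + tab$S_const -
                        gp$GA) < 1e-9))
})

test_that("hit classification covers the four quadrants exactly once", {
  mk <- function(S_total, S_NG)
    structure(list(S_total = S_total, S_NG = S_NG,
                   S_TM = S_total - S_NG, S_const = 0),
              class = "score_partition")
  expect_equal(classify_hit(mk(25, 18), 20, 15)$verdict, "true_positive")
  expect_equal(classify_hit(mk(25, 10), 20, 15)$verdict, "unjustified")
  expect_equal(classify_hit(mk(12, 18), 20, 15)$verdict, "false_negative")
  expect_equal(classify_hit(mk(12, 10), 20, 15)$verdict, "no_call")
  # boundaries are inclusive
  expect_equal(classify_hit(mk(20, 15), 20, 15)$verdict, "true_positive")
})

test_that("rescore with an empty mask is the identity", {
  set.seed(43)
  hmm <- random_hmm(4)
  sq <- random_aa_string(8)
  r <- rescore_without_region(hmm, model_region_mask(4), sq)
  expect_equal(r$score, viterbi_hmmls(hmm, sq)$score)
  expect_error(rescore_without_region(
    hmm, model_region_mask(4, ranges = data.frame(start = 1, end = 4)), sq),
    "every node")
})

test_that("rescore equals Viterbi on the manually spliced sub-model", {
  set.seed(53)
  for (rep in 1:10) {
    M <- 5
    hmm <- random_hmm(M)
    sq <- random_aa_string(9)
    drop <- sort(sample(2:(M - 1), 2))
    mask <- model_region_mask(M, nodes = drop)
    keep <- setdiff(1:M, drop)
    manual <- hmm
    manual$M <- length(keep)
    manual$match_emit <- hmm$match_emit[keep, , drop = FALSE]
    manual$insert_emit <- hmm$insert_emit[keep, , drop = FALSE]
    manual$transitions <- hmm$transitions[keep, , drop = FALSE]
    expect_equal(rescore_without_region(hmm, mask, sq)$score,
                 viterbi_hmmls(manual, sq)$score)
  }
})

test_that("removing a net-negative block raises the score", {
  fx <- make_profile(profile_spec(seed = 3, n_decoys = 5))
  # a globular-only sequence: the flagged hydrophobic block only penalises
  set.seed(10)
  glob_part <- substring(fx$members[[1]], 11 + fx$pspec$n_flagged,
                         nchar(fx$members[[1]]))
  original <- viterbi_hmmls(fx$hmm, glob_part)$score
  rescored <- rescore_without_region(fx$hmm, fx$mask, glob_part)$score
  expect_gt(rescored, original)
  # E-values use the ORIGINAL model's EVD parameters
  r <- rescore_without_region(fx$hmm, fx$mask, glob_part, db_size = 1e6)
  expect_equal(r$evalue,
               evalue(r$score, 1e6, fx$hmm$evd_mu, fx$hmm$evd_lambda))
})

test_that("region mask files read back into per-domain masks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain_id\tcategory\tstart_node\tend_node",
               "domA\tTM\t3\t5", "domA\tTM\t9\t9", "domB\tSP\t1\t4"), f)
  masks <- read_region_masks(f, c(domA = 10L, domB = 6L))
  expect_equal(masks$domA$nodes, c(3L, 4L, 5L, 9L))
  expect_equal(masks$domB$nodes, 1:4)
  expect_equal(masks$domB$category, "SP")
})
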