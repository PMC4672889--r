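test_that("consensus classes map to pseudocounted PWM columns", {
  m <- consensus_to_pwm(yrs_consensus())
  expect_equal(m$width, 7)
  expect_equal(colSums(m$prob), rep(1, 7), tolerance = 1e-9)
  eps <- 1e-4
  # position 3 is the singleton class {C}
  expect_equal(unname(m$prob["C", 3]), (1 + eps) / (1 + 4 * eps), tolerance = 1e-12)
  expect_equal(unname(m$prob["A", 3]), eps / (1 + 4 * eps), tolerance = 1e-12)
  # position 1 is {T, A, C}
  expect_equal(unname(m$prob[c("T", "A", "C"), 1]),
               rep((1 / 3 + eps) / (1 + 4 * eps), 3), tolerance = 1e-12)
  expect_equal(unname(m$prob["G", 1]), eps / (1 + 4 * eps), tolerance = 1e-12)
  # single-letter consensus, and RNA alphabet accepted
  m1 <- consensus_to_pwm("A")
  expect_equal(unname(m1$prob["A", 1]), (1 + eps) / (1 + 4 * eps), tolerance = 1e-12)
  expect_equal(consensus_to_pwm("[UAC][CA]CA[UC]C[ACU]")$prob, m$prob)
  expect_error(consensus_to_pwm("[TAC][]CA"), class = "fracseq_validation_error")
  expect_error(consensus_to_pwm("AXC"), class = "fracseq_validation_error")
})

test_that("exact p-value table has the YRS tail anchors and tail shape", {
  m <- consensus_to_pwm(yrs_consensus())
  tab <- exact_pvalue_table(m, uniform_background())
  # 3*2*1*1*2*1*3 = 36 consensus-compatible 7-mers of 4^7 = 16384
  max_attained <- max(which(tab$tail > 0))
  expect_equal(tab$tail[max_attained], 36 / 16384, tolerance = 1e-12)
  expect_equal(tab$tail[1], 1)
  expect_true(all(diff(tab$tail) <= 1e-15))
})

test_that("DP p-values equal exhaustive enumeration on random PWMs", {
  set.seed(404)
  for (i in 1:6) {
    w <- sample(3:8, 1)
    m <- random_pwm(w)
    bg <- random_background()
    tab <- exact_pvalue_table(m, bg, n_bins = 1e4)
    oracle <- oracle_pwm_tail(tab)
    attained <- oracle > 0 | tab$tail > 0
    expect_lt(max(abs(tab$tail[attained][-1] - oracle[attained][-1])), 1e-12)
    expect_equal(tab$tail[1], 1)
  }
})

test_that("scanning finds consensus windows at their exact p-value", {
  m <- consensus_to_pwm(yrs_consensus())
  bg <- uniform_background()
  hits <- scan_utrs(utr_set(c(t1 = "GGGACCATCAGGG")), m, bg)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 4)
  expect_equal(hits$end, 10)
  expect_identical(hits$matched, "ACCATCA")
  expect_equal(hits$p, 36 / 16384, tolerance = 1e-12)

  # U-containing input normalized before scanning
  hits_u <- scan_utrs(utr_set(c(t1 = "ACCAUCA")), m, bg)
  expect_equal(hits_u$start, 1)

  # G-only sequence yields nothing at the default threshold
  expect_equal(nrow(scan_utrs(utr_set(c(t1 = strrep("G", 50))), m, bg)), 0)

  # windows containing N are skipped, flanking windows still scanned
  hits_n <- scan_utrs(utr_set(c(t1 = "ACCATCANACCATCA")), m, bg)
  expect_equal(hits_n$start, c(1, 9))

  # sequences shorter than the motif yield zero hits with a log note
  expect_message(h0 <- scan_utrs(utr_set(c(t1 = "ACG")), m, bg), "shorter")
  expect_equal(nrow(h0), 0)
})

test_that("BH q-values match the step-up oracle and rejection rule", {
  expect_equal(bh_qvalues(c(0.001, 0.01, 0.04, 0.5)),
               c(0.004, 0.02, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_equal(bh_qvalues(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_qvalues(0.3), 0.3)
  expect_error(bh_qvalues(c(0.1, 1.2)), class = "fracseq_validation_error")

  set.seed(77)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_qvalues(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    for (alpha in c(0.05, 0.2))
      expect_identical(q <= alpha, oracle_bh_reject(p, alpha))
  }
})

test_that("canonical counting matches a window-membership oracle", {
  expect_equal(count_canonical("ACCATCA"), 1L)
  expect_equal(count_canonical("ACCATCACCATCA"), 2L)  # overlapping starts 1 and 7
  expect_equal(count_canonical("GGGGGGG"), 0L)

  classes <- fracseq:::parse_consensus(yrs_consensus())
  set.seed(55)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                      prob = c(.3, .3, .1, .3)), collapse = "")
    expect_identical(count_canonical(s), oracle_count_canonical(s, classes))
  }
})

test_that("every planted consensus instance is reported at the maximal score", {
  g <- generate_utr_set(30, lengths = 120, planted_per_utr = 2, seed = 12)
  m <- consensus_to_pwm(yrs_consensus())
  bg <- uniform_background()
  hits <- scan_utrs(g$utrs, m, bg)
  max_score <- max(hits$score_bits)
  planted_key <- paste(g$truth$transcript_id, g$truth$start)
  hit_key <- paste(hits$transcript_id, hits$start)
  found <- match(planted_key, hit_key)
  expect_false(any(is.na(found)))
  expect_equal(hits$score_bits[found], rep(max_score, length(found)), tolerance = 1e-9)
})

test_that("UTR-set comparison summarizes hit fractions and canonical content", {
  planted <- generate_utr_set(25, lengths = 60, planted_per_utr = 1, seed = 3)$utrs
  gonly <- generate_utr_set(25, lengths = 60, planted_per_utr = 0,
                            base_composition = c(A = 0, C = 0, G = 1, T = 0),
                            seed = 4)$utrs
  two <- generate_utr_set(25, lengths = 80, planted_per_utr = 2,
                          base_composition = c(A = 0, C = 0, G = 1, T = 0),
                          seed = 5)$utrs
  summ <- compare_utr_sets(list(planted = planted, gonly = gonly, two = two),
                           bg = uniform_background())
  expect_equal(summ$frac_with_hit[summ$set == "planted"], 1)
  expect_equal(summ$frac_with_hit[summ$set == "gonly"], 0)
  expect_equal(summ$mean_canonical[summ$set == "two"], 2)
  expect_error(compare_utr_sets(list()), class = "fracseq_config_error")
})

test_that("hits export as GFF3 with transcript-relative coordinates", {
  g <- generate_utr_set(3, lengths = 40, planted_per_utr = 1, seed = 9)
  hits <- scan_utrs(g$utrs, bg = uniform_background())
  path <- withr::local_tempfile(fileext = ".gff3")
  write_hits_gff3(hits, path)
  lines <- readLines(path)
  expect_identical(lines[1], "##gff-version 3")
  body <- read.delim(path, header = FALSE, comment.char = "#")
  expect_equal(nrow(body), nrow(hits))
  expect_equal(body$V4, hits$start)
})
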