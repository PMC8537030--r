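test_that("maturation rates are pooled-count ratios ignoring not-read states", {
  cat <- event_catalogue(data.frame(
    event_id = c("e1", "e2"), kind = "editing", chrom = "chr", strand = "+",
    position = c(10L, 20L), intron_start = NA, intron_end = NA,
    transcript_group = "tx", stringsAsFactors = FALSE))
  s1 <- cbind(rep(c("M", "I"), c(50, 5)), rep("N", 55))
  s2 <- cbind(rep(c("M", "I"), c(39, 6)), rep("N", 45))
  mats <- list(matrix_from_states(s1, cat, "rep1"),
               matrix_from_states(s2, cat, "rep2"))
  r <- maturation_rates(mats)
  expect_equal(r$rate[r$event_id == "e1"], 89 / 100)   # 89 M, 11 I pooled
  expect_true(r$flagged[r$event_id == "e2"])
  expect_true(is.na(r$rate[r$event_id == "e2"]))

  # invariant under replicate order
  expect_equal(maturation_rates(rev(mats))$rate, r$rate)
})

test_that("planted marginal rates are recovered within binomial tolerance", {
  cfg <- sim_scenario_null(seed = 401, n_reads = 1000, n_replicates = 2,
                           err_sub = 0, err_ins = 0, err_del = 0)
  sim <- simulate_dataset(cfg)
  r <- maturation_rates(annotate_dataset(sim))
  expected <- 1 - exp(-cfg$events$base_rate)   # fixed unit sampling age
  for (i in seq_len(nrow(r))) {
    n <- r$n_mature[i] + r$n_immature[i]
    se <- sqrt(expected[i] * (1 - expected[i]) / n)
    expect_lt(abs(r$rate[i] - expected[i]), 3 * se)
  }
})

test_that("virtual Northern normalization pins the modal length to 100", {
  sam <- tempfile(fileext = ".sam")
  recs <- c(lapply(1:4, function(i) list(qname = paste0("a", i), pos = 50L,
                                         cigar = "200M",
                                         seq = strrep("A", 200))),
            lapply(1:2, function(i) list(qname = paste0("b", i), pos = 50L,
                                         cigar = "400M",
                                         seq = strrep("A", 400))))
  write_test_sam(recs, sam, len = 1000L)
  bp <- virtual_northern(sam, "chr", 100, 150, "+")
  h <- bp$histogram
  expect_equal(h$normalized[h$length == 200], 100)
  expect_equal(h$normalized[h$length == 400], 50)

  # single read: its full length carries intensity 100
  sam2 <- tempfile(fileext = ".sam")
  write_test_sam(list(list(qname = "solo", pos = 10L, cigar = "852M",
                           seq = strrep("A", 852))), sam2, len = 2000L)
  bp2 <- virtual_northern(sam2, "chr", 500, 600, "+")
  expect_equal(bp2$histogram$length, 852L)
  expect_equal(bp2$histogram$normalized, 100)

  # strand and overlap filters
  expect_warning(empty <- virtual_northern(sam, "chr", 100, 150, "-"),
                 "no read")
  expect_equal(nrow(empty$histogram), 0L)
})

test_that("blot rendering writes an image and a deterministic histogram TSV", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(list(
    list(qname = "a", pos = 50L, cigar = "200M", seq = strrep("A", 200)),
    list(qname = "b", pos = 50L, cigar = "450M", seq = strrep("A", 450)),
    list(qname = "c", pos = 50L, cigar = "450M", seq = strrep("A", 450))),
    sam, len = 1000L)
  bp <- virtual_northern(sam, "chr", 100, 150, "+")
  img <- tempfile(fileext = ".png")
  tsv1 <- tempfile(fileext = ".tsv")
  tsv2 <- tempfile(fileext = ".tsv")
  render_blot(bp, img, tsv1)
  render_blot(bp, tempfile(fileext = ".png"), tsv2)
  expect_true(file.exists(img) && file.size(img) > 0)
  expect_identical(readLines(tsv1), readLines(tsv2))
  empty_bp <- suppressWarnings(virtual_northern(sam, "chr", 100, 150, "-"))
  expect_error(render_blot(empty_bp, img), "empty")
})

test_that("strand coverage equals the naive per-base counting oracle", {
  set.seed(11)
  recs <- list()
  pos <- integer(0); cig <- character(0)
  for (i in 1:60) {
    p <- sample(1:300, 1)
    blocks <- sample(1:3, 1)
    parts <- c()
    total <- 0L
    for (b in seq_len(blocks)) {
      m <- sample(20:80, 1); parts <- c(parts, paste0(m, "M")); total <- total + m
      if (b < blocks) {
        op <- sample(c("N", "D", "I"), 1)
        l <- sample(5:30, 1)
        parts <- c(parts, paste0(l, op))
        if (op != "I") total <- total + 0L
      }
    }
    cigar <- paste(parts, collapse = "")
    qlen <- sum(as.integer(sub("[MI]", "",
      regmatches(cigar, gregexpr("\\d+[MI]", cigar))[[1]])))
    recs[[i]] <- list(qname = paste0("r", i), pos = p, cigar = cigar,
                      seq = strrep("A", qlen))
    pos <- c(pos, p); cig <- c(cig, cigar)
  }
  sam <- tempfile(fileext = ".sam")
  write_test_sam(recs, sam, len = 1000L)
  cp <- strand_coverage(sam, "chr", 50, 450, "+")
  expect_equal(cp$profile$depth, oracle_coverage(pos, cig, 50, 450))

  # a read on the opposite strand does not contribute
  recs2 <- c(recs, list(list(qname = "rev", pos = 60L, cigar = "100M",
                             seq = strrep("A", 100), flag = 16L)))
  sam2 <- tempfile(fileext = ".sam")
  write_test_sam(recs2, sam2, len = 1000L)
  cp2 <- strand_coverage(sam2, "chr", 50, 450, "+")
  expect_equal(cp2$profile$depth, cp$profile$depth)
})

test_that("single reads produce unit depth exactly over their aligned span", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(list(list(qname = "r1", pos = 10L, cigar = "11M",
                           seq = strrep("A", 11))), sam, len = 100L)
  cp <- strand_coverage(sam, "chr", 1, 50, "+")
  expect_equal(cp$profile$depth, as.integer(c(rep(0, 9), rep(1, 11),
                                              rep(0, 30))))
})
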