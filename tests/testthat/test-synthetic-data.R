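test_that("the toy genome is deterministic and plants editable cytidines", {
  cfg <- sim_scenario_null(seed = 501)
  g1 <- build_toy_genome(cfg)
  g2 <- build_toy_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))

  ed <- g1$catalogue[g1$catalogue$kind == "editing", ]
  bases <- as.character(Biostrings::extractAt(
    g1$genome[[1]], IRanges::IRanges(ed$position, ed$position)))
  expect_true(all(bases == ifelse(ed$strand == "+", "C", "G")))
  expect_true(check_reference_base(g1$genome, g1$catalogue))

  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_dataset(cfg, dir = d1)
  s2 <- simulate_dataset(cfg, dir = d2)
  expect_identical(readLines(s1$sam[[1]]), readLines(s2$sam[[1]]))
  expect_identical(readLines(s1$fasta), readLines(s2$fasta))
})

test_that("invalid configurations are rejected", {
  tr <- data.frame(transcript = "t", start = 100L, end = 400L, strand = "+")
  mk <- function(events) sim_config(tr, events, seed = 1)
  # event outside the transcript span
  expect_error(build_toy_genome(mk(data.frame(
    event_id = "e", kind = "editing", transcript = "t", position = 500L,
    base_rate = 1))), "outside")
  # editing position inside an intron interval
  expect_error(build_toy_genome(mk(data.frame(
    event_id = c("e", "i"), kind = c("editing", "splicing"),
    transcript = "t", position = c(250L, NA),
    intron_start = c(NA, 200L), intron_end = c(NA, 300L),
    base_rate = 1))), "collides")
  # seed is mandatory; error rates bounded
  ev <- data.frame(event_id = "e", kind = "editing", transcript = "t",
                   position = 200L, base_rate = 1)
  expect_error(sim_config(tr, ev), "seed")
  expect_error(sim_config(tr, ev, err_sub = 1.2, seed = 1), "error rates")
  expect_error(sim_config(tr, ev, seed = 1,
                          enhancement = data.frame(from = "e", to = "x",
                                                   multiplier = 2)),
               "unknown event")
})

test_that("independent events obey the product law in the truth table", {
  tr <- data.frame(transcript = "t", start = 1L, end = 400L, strand = "+")
  ev <- data.frame(event_id = c("a", "b"), kind = "editing",
                   transcript = "t", position = c(100L, 300L),
                   base_rate = c(0.9, 0.6))
  cfg <- sim_config(tr, ev, n_reads = 20000L, n_replicates = 1L, seed = 502)
  truth <- simulate_molecules(cfg)
  tab <- table(truth$states[, "a"], truth$states[, "b"])
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("an overwhelming enhancement forbids the gated intermediate", {
  tr <- data.frame(transcript = "t", start = 1L, end = 400L, strand = "+")
  ev <- data.frame(event_id = c("a", "b"), kind = "editing",
                   transcript = "t", position = c(100L, 300L),
                   base_rate = c(0.8, 1e-9))
  enh <- data.frame(from = "a", to = "b", multiplier = 1e9)
  cfg <- sim_config(tr, ev, enhancement = enh, n_reads = 5000L,
                    n_replicates = 1L, seed = 503)
  truth <- simulate_molecules(cfg)
  # b cannot mature while a is immature: the FT intermediate is absent
  expect_equal(sum(!truth$states[, "a"] & truth$states[, "b"]), 0L)
})

test_that("a strong sequential chain produces only prefix intermediates", {
  cfg <- sim_scenario_chain(seed = 504, n_reads = 3000, n_replicates = 1)
  truth <- simulate_molecules(cfg)
  st <- truth$states
  n_mature <- rowSums(st)
  # every molecule's mature set must be a prefix of (c1, ..., c5)
  for (k in 0:5) {
    rows <- which(n_mature == k)
    if (k > 0)
      expect_true(all(st[rows, seq_len(k), drop = FALSE]))
    if (k < 5)
      expect_true(!any(st[rows, (k + 1):5, drop = FALSE]))
  }
})

test_that("spliced molecules round-trip through exact skip CIGARs", {
  cfg <- sim_scenario_null(seed = 505, n_reads = 200, n_replicates = 1,
                           err_sub = 0, err_ins = 0, err_del = 0)
  sim <- simulate_dataset(cfg)
  spliced <- sim$truth$molecules$molecule_id[sim$truth$states[, "int_A"]]
  reads <- sim$reads
  hit <- reads$read_id %in% spliced & !reads$truncated
  expect_true(any(hit))
  expect_true(all(grepl("101N", reads$cigar[hit])))   # intron [150,250]
  m <- annotate_alignments(sim$sam[[1]], sim$catalogue, "rep1")
  called <- setNames(m$int_A, m$read_id)[reads$read_id[hit]]
  expect_true(all(called == "M"))
})

test_that("the observed mismatch rate tracks the substitution parameter", {
  eps <- 0.04
  tr <- data.frame(transcript = "t", start = 1L, end = 1000L, strand = "+")
  ev <- data.frame(event_id = "e", kind = "editing", transcript = "t",
                   position = 500L, base_rate = 1)
  cfg <- sim_config(tr, ev, err_sub = eps, err_ins = 0, err_del = 0,
                    n_reads = 2000L, n_replicates = 1L, seed = 506)
  sim <- simulate_dataset(cfg)
  aln <- read_alignments(sim$sam[[1]])
  ref <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(aln)$seq, GenomicAlignments::cigar(aln),
    from = "query", to = "reference")
  gseq <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  mm <- 0L; tot <- 0L
  refchar <- as.character(ref)
  starts <- BiocGenerics::start(aln)
  for (i in seq_along(refchar)) {
    rc <- strsplit(refchar[i], "")[[1]]
    gpos <- starts[i] + seq_along(rc) - 1L
    use <- gpos != 500L                # exclude the edited site
    mm <- mm + sum(rc[use] != gseq[gpos[use]])
    tot <- tot + sum(use)
  }
  se <- sqrt(eps * (1 - eps) / tot)
  expect_lt(abs(mm / tot - eps), 3 * se)
})

test_that("capture bias under-represents transcripts beyond the cutoff", {
  tr <- data.frame(transcript = c("long", "short"),
                   start = c(1L, 3101L), end = c(3000L, 4100L),
                   strand = "+", weight = 1)
  ev <- data.frame(event_id = c("el", "es"), kind = "editing",
                   transcript = c("long", "short"),
                   position = c(1500L, 3600L), base_rate = 1)
  cfg <- sim_config(tr, ev, capture_L0 = 2000, n_reads = 2000L,
                    n_replicates = 1L, err_sub = 0, err_ins = 0,
                    err_del = 0, seed = 507)
  sim <- simulate_dataset(cfg)
  full <- sim$reads[!sim$reads$truncated, ]
  n_long <- sum(full$transcript == "long")
  n_short <- sum(full$transcript == "short")
  # equal molarity in, strong depletion of full-length long reads out
  expect_lt(n_long, 0.5 * n_short)
  # truncated survivors keep their 3' (right) end
  tr_reads <- sim$reads[sim$reads$truncated &
                          sim$reads$transcript == "long", ]
  if (nrow(tr_reads) > 0) {
    ends <- tr_reads$pos + vapply(tr_reads$cigar, function(cg) {
      ops <- regmatches(cg, gregexpr("\\d+[MDN]", cg))[[1]]
      sum(as.integer(sub("[MDN]", "", ops)))
    }, numeric(1), USE.NAMES = FALSE) - 1L
    expect_true(all(ends == 3000L))
  }
})

test_that("FASTQ export carries the same sequences as the SAM", {
  cfg <- sim_scenario_null(seed = 508, n_reads = 50, n_replicates = 1)
  sim <- simulate_dataset(cfg, fastq = TRUE)
  fq <- readLines(sim$fastq[[1]])
  ids <- sub("^@", "", fq[seq(1, length(fq), 4)])
  seqs <- fq[seq(2, length(fq), 4)]
  expect_equal(ids, sim$reads$read_id)
  expect_equal(seqs, sim$reads$seq)
})
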