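test_that("editing calls follow the three-modality rule on the plus strand", {
  cat <- editing_catalogue(position = 30L)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(list(
    list(qname = "mat",  pos = 11L, cigar = "40M",
         seq = seq_with(40, at = 20, base = "T")),
    list(qname = "imm",  pos = 11L, cigar = "40M",
         seq = seq_with(40, at = 20, base = "C")),
    list(qname = "othr", pos = 11L, cigar = "40M",
         seq = seq_with(40, at = 20, base = "G")),
    list(qname = "del",  pos = 11L, cigar = "15M5D20M",
         seq = seq_with(35, at = 5, base = "T")),
    list(qname = "edge", pos = 26L, cigar = "40M",
         seq = seq_with(40, at = 5, base = "T")),
    list(qname = "anti", pos = 11L, cigar = "40M", flag = 16L,
         seq = seq_with(40, at = 20, base = "T"))), sam)
  m <- annotate_alignments(sam, cat, "r1")
  state_of <- function(id)
    if (id %in% m$read_id) m$ed1[m$read_id == id] else "N"
  expect_equal(state_of("mat"), "M")
  expect_equal(state_of("imm"), "I")
  expect_equal(state_of("othr"), "N")   # non-C/T base: conservative
  expect_equal(state_of("del"), "N")    # deletion spans the site
  expect_equal(state_of("edge"), "N")   # within end_margin of read start
  expect_equal(state_of("anti"), "N")   # antisense read informs nothing

  # single-read wrapper agrees on the deletion case
  aln <- read_alignments(sam)
  del_rec <- aln[S4Vectors::mcols(aln)$qname == "del"]
  expect_equal(call_editing_state(del_rec, cat[1, ]), "NOT_READ")
  mat_rec <- aln[S4Vectors::mcols(aln)$qname == "mat"]
  expect_equal(call_editing_state(mat_rec, cat[1, ]), "MATURE")
})

test_that("editing calls on a minus-strand site use plus-reference G/A", {
  cat <- editing_catalogue(position = 30L, strand = "-")
  sam <- tempfile(fileext = ".sam")
  write_test_sam(list(
    list(qname = "mat", pos = 11L, cigar = "40M", flag = 16L,
         seq = seq_with(40, at = 20, base = "A")),
    list(qname = "imm", pos = 11L, cigar = "40M", flag = 16L,
         seq = seq_with(40, at = 20, base = "G")),
    list(qname = "plus", pos = 11L, cigar = "40M", flag = 0L,
         seq = seq_with(40, at = 20, base = "A"))), sam)
  m <- annotate_alignments(sam, cat, "r1")
  states <- setNames(m$ed1, m$read_id)
  expect_equal(states[["mat"]], "M")
  expect_equal(states[["imm"]], "I")
  expect_false("plus" %in% m$read_id)
})

test_that("splicing calls distinguish spliced, retained and uninformative reads", {
  cat <- splicing_catalogue(40L, 80L)   # 41-nt intron
  sam <- tempfile(fileext = ".sam")
  write_test_sam(list(
    list(qname = "exact",  pos = 20L, cigar = "20M41N30M",
         seq = strrep("A", 50)),
    list(qname = "retain", pos = 20L, cigar = "91M",
         seq = strrep("A", 91)),
    list(qname = "short",  pos = 20L, cigar = "15M",
         seq = strrep("A", 15)),            # ends upstream of the intron
    list(qname = "wobble", pos = 20L, cigar = "25M39N47M",
         seq = strrep("A", 72)),            # skip [45,83]: within tolerance
    list(qname = "offjxn", pos = 20L, cigar = "40M21N31M",
         seq = strrep("A", 71))), sam)     # skip [60,80]: misses 5' junction
  m <- annotate_alignments(sam, cat, "r1")
  state_of <- function(id)
    if (id %in% m$read_id) m$int1[m$read_id == id] else "N"
  expect_equal(state_of("exact"), "M")
  expect_equal(state_of("retain"), "I")
  expect_equal(state_of("short"), "N")    # does not span the intron
  expect_equal(state_of("wobble"), "M")
  expect_equal(state_of("offjxn"), "N")   # neither clean skip nor retention

  aln <- read_alignments(sam)
  ret_rec <- aln[S4Vectors::mcols(aln)$qname == "retain"]
  expect_equal(call_splicing_state(ret_rec, cat[1, ]), "IMMATURE")
})

test_that("reference-base validation flags catalogue/reference mismatches", {
  genome <- Biostrings::DNAStringSet(c(chr = strrep("A", 100)))
  expect_error(check_reference_base(genome, editing_catalogue(30L)),
               "expected C")
  ok <- Biostrings::DNAStringSet(c(chr = seq_with(100, 30, "C")))
  expect_true(check_reference_base(ok, editing_catalogue(30L)))
})

test_that("empty or uninformative input yields an empty matrix with warning", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(list(), sam)
  expect_warning(m <- annotate_alignments(sam, editing_catalogue(30L), "r1"),
                 "empty matrix")
  expect_equal(nrow(m), 0L)
})

test_that("error-free simulation annotates every read exactly as the truth", {
  cfg <- sim_scenario_null(seed = 301, n_reads = 400, n_replicates = 1,
                           err_sub = 0, err_ins = 0, err_del = 0)
  sim <- simulate_dataset(cfg)
  m <- annotate_alignments(sim$sam[[1]], sim$catalogue, "rep1")
  truth_states <- sim$truth$states[match(m$read_id,
                                         sim$truth$molecules$molecule_id), ]
  for (ev in sim$catalogue$event_id) {
    called <- m[[ev]]
    informative <- called != "N"
    expect_true(all((called[informative] == "M") ==
                      truth_states[informative, ev]))
    # full-length reads inform every event
    expect_true(all(informative[!m$read_id %in%
                                  sim$reads$read_id[sim$reads$truncated]]))
  }
})

test_that("states are invariant under SAM vs BAM container and read order", {
  cfg <- sim_scenario_null(seed = 302, n_reads = 150, n_replicates = 1)
  sim <- simulate_dataset(cfg)
  m_sam <- annotate_alignments(sim$sam[[1]], sim$catalogue, "r")
  bam <- Rsamtools::asBam(sim$sam[[1]], tempfile(), overwrite = TRUE)
  m_bam <- annotate_alignments(bam, sim$catalogue, "r")
  o1 <- order(m_sam$read_id)
  o2 <- order(m_bam$read_id)
  expect_equal(as.data.frame(m_sam)[o1, ], as.data.frame(m_bam)[o2, ],
               ignore_attr = TRUE)

  # shuffle record order in the SAM text: same annotation
  lines <- readLines(sim$sam[[1]])
  hdr <- grepl("^@", lines)
  set.seed(1)
  shuf <- c(lines[hdr], sample(lines[!hdr]))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(shuf, sam2)
  m_shuf <- annotate_alignments(sam2, sim$catalogue, "r")
  expect_equal(as.data.frame(m_sam)[o1, ],
               as.data.frame(m_shuf)[order(m_shuf$read_id), ],
               ignore_attr = TRUE)
})

test_that("substitution errors flip editing calls at close to the expected rate", {
  eps <- 0.04
  cfg <- sim_scenario_null(seed = 303, n_reads = 1500, n_replicates = 1,
                           err_sub = eps, err_ins = 0, err_del = 0)
  sim <- simulate_dataset(cfg)
  m <- annotate_alignments(sim$sam[[1]], sim$catalogue, "rep1")
  truth_states <- sim$truth$states[match(m$read_id,
                                         sim$truth$molecules$molecule_id), ]
  ed <- sim$catalogue$event_id[sim$catalogue$kind == "editing"]
  flips <- 0L; informative <- 0L
  for (ev in ed) {
    called <- m[[ev]]
    ok <- called != "N"
    flips <- flips + sum((called[ok] == "M") != truth_states[ok, ev])
    informative <- informative + sum(ok)
  }
  # a C/T (or G/A) site miscalls as its counterpart for 1 of the 3
  # substitution targets: flip rate = eps / 3
  expected <- eps / 3
  se <- sqrt(expected * (1 - expected) / informative)
  expect_gt(informative, 10000)
  expect_lt(abs(flips / informative - expected), 3 * se + 1e-6)
})
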