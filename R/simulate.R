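#' Configuration of the maturation/read simulator
#'
#' The simulator draws, for each molecule, a transcript and a sampling age,
#' runs a continuous-time maturation process over the transcript's events,
#' and then turns the molecule into one pre-aligned SAM read with
#' nanopore-like errors. Maturation of event i proceeds at rate
#' `base_rate_i * prod(multiplier_ji)` over all already-mature events j, so
#' with all multipliers at 1 the events of a molecule mature independently
#' (product of exponentials), while a multiplier above 1 plants
#' co-maturation of the pair (both intermediate classes depleted) and a
#' j-before-i preferred order.
#'
#' @param transcripts data.frame: `transcript`, `start`, `end` (1-based
#'   inclusive genomic span), `strand`, optional `weight` (relative
#'   molarity, default 1).
#' @param events data.frame: `event_id`, `kind` (`editing`/`splicing`),
#'   `transcript`, `position` (editing), `intron_start`/`intron_end`
#'   (splicing), `base_rate` (maturation rate constant, 1/time).
#' @param enhancement optional data.frame `from`, `to`, `multiplier`:
#'   event `from`, once mature, multiplies the rate of event `to`.
#' @param genome_length toy genome length (nt).
#' @param chrom contig name of the toy genome.
#' @param mean_age sampling age of the molecules (time units of the rate
#'   constants). With the default `age_distribution = "fixed"` every
#'   molecule is sampled at exactly this age, which makes the independence
#'   contract exact: states are a product of independent exponential-clock
#'   outcomes. `"exponential"` draws per-molecule ages with this mean
#'   (steady-state population under constant transcription and first-order
#'   decay) - note that a shared random age is a kinetic confounder that
#'   induces positive association between all event pairs even at unit
#'   multipliers.
#' @param age_distribution `"fixed"` (default) or `"exponential"`.
#' @param err_sub,err_ins,err_del per-base substitution / insertion /
#'   deletion probabilities. Defaults total ~4%, the typical nanopore cDNA
#'   error rate.
#' @param capture_L0,capture_steepness logistic capture bias: a molecule of
#'   pre-error length L is captured with probability
#'   `1/(1 + exp((L - L0)/steepness))`; non-captured molecules are either
#'   dropped or truncated to a 3'-anchored fragment (cDNA synthesis starts
#'   at the 3' end). Defaults penalize transcripts beyond ~2 kb.
#' @param n_reads molecules per replicate.
#' @param n_replicates number of biological replicates.
#' @param seed mandatory integer; all randomness derives from it, with a
#'   fixed offset per stage (genome, kinetics, errors) so stages are
#'   independently reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(transcripts, events, enhancement = NULL,
                       genome_length = NULL, chrom = "toyplastome",
                       mean_age = 1, age_distribution = c("fixed",
                                                          "exponential"),
                       err_sub = 0.03, err_ins = 0.003, err_del = 0.007,
                       capture_L0 = 2000, capture_steepness = 200,
                       n_reads = 2000L, n_replicates = 3L, seed) {
  age_distribution <- match.arg(age_distribution)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is mandatory")
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  if (is.null(transcripts$weight)) transcripts$weight <- 1
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (is.null(events$base_rate))
    stop("events need a base_rate column")
  if (any(events$base_rate < 0)) stop("base rates must be >= 0")
  for (e in c(err_sub, err_ins, err_del))
    if (e < 0 || e >= 1) stop("error rates must lie in [0, 1)")
  if (!is.null(enhancement)) {
    enhancement <- as.data.frame(enhancement, stringsAsFactors = FALSE)
    if (any(enhancement$multiplier < 0)) stop("multipliers must be >= 0")
    bad <- !enhancement$from %in% events$event_id |
      !enhancement$to %in% events$event_id
    if (any(bad)) stop("enhancement refers to unknown event(s)")
    tr_of <- events$transcript[match(enhancement$from, events$event_id)]
    tr_to <- events$transcript[match(enhancement$to, events$event_id)]
    if (any(tr_of != tr_to))
      stop("enhancement pairs must live on the same transcript")
  }
  if (is.null(genome_length)) genome_length <- max(transcripts$end) + 50L
  if (genome_length < max(transcripts$end))
    stop("genome_length shorter than the last transcript")
  bad <- !events$transcript %in% transcripts$transcript
  if (any(bad))
    stop("event(s) placed on unknown transcript: ",
         paste(events$event_id[bad], collapse = ", "))

  structure(list(transcripts = transcripts, events = events,
                 enhancement = enhancement,
                 genome_length = as.integer(genome_length), chrom = chrom,
                 mean_age = mean_age, age_distribution = age_distribution,
                 err_sub = err_sub, err_ins = err_ins,
                 err_del = err_del, capture_L0 = capture_L0,
                 capture_steepness = capture_steepness,
                 n_reads = as.integer(n_reads),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

config_catalogue <- function(config) {
  tr <- config$transcripts
  ev <- config$events
  strand <- tr$strand[match(ev$transcript, tr$transcript)]
  event_catalogue(data.frame(
    event_id = ev$event_id, kind = ev$kind, chrom = config$chrom,
    strand = strand,
    position = if ("position" %in% names(ev)) ev$position else NA,
    intron_start = if ("intron_start" %in% names(ev)) ev$intron_start else NA,
    intron_end = if ("intron_end" %in% names(ev)) ev$intron_end else NA,
    transcript_group = ev$transcript, stringsAsFactors = FALSE))
}

#' Build a toy plastome-like genome matching a simulator configuration
#'
#' Generates a seeded random genome with the edited cytidine guaranteed at
#' every editing position (`C` on plus-strand genes, `G` on minus-strand
#' ones in plus-reference coordinates) and returns the matching event
#' catalogue. Event placements are validated: every event must lie inside
#' its transcript span (with a few nt of margin at the ends) and editing
#' positions must not fall within an intron interval.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named `DNAStringSet`) and `catalogue`.
#' @export
build_toy_genome <- function(config) {
  catalogue <- config_catalogue(config)
  tr <- config$transcripts
  span <- tr[match(catalogue$transcript_group, tr$transcript), ]
  ev_start <- ifelse(catalogue$kind == "editing", catalogue$position,
                     catalogue$intron_start)
  ev_end <- ifelse(catalogue$kind == "editing", catalogue$position,
                   catalogue$intron_end)
  bad <- ev_start < span$start + 5L | ev_end > span$end - 5L
  if (any(bad))
    stop("event(s) outside (or too close to the edge of) their transcript ",
         "span: ", paste(catalogue$event_id[bad], collapse = ", "))
  ed <- catalogue$kind == "editing"
  sp <- which(!ed)
  for (i in which(ed)) {
    same <- sp[catalogue$transcript_group[sp] == catalogue$transcript_group[i]]
    hit <- catalogue$position[i] >= catalogue$intron_start[same] &
      catalogue$position[i] <= catalogue$intron_end[same]
    if (any(hit))
      stop("editing position of ", catalogue$event_id[i],
           " collides with intron ", catalogue$event_id[same[hit][1L]])
  }

  set.seed(config$seed + 11L)   # genome stage
  bases <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)
  plus <- ed & catalogue$strand == "+"
  minus <- ed & catalogue$strand == "-"
  bases[catalogue$position[plus]] <- "C"
  bases[catalogue$position[minus]] <- "G"
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- config$chrom
  list(genome = genome, catalogue = catalogue)
}

#' Simulate ground-truth maturation states for every molecule
#'
#' Runs, per molecule, a Gillespie jump process over the events of its
#' transcript: each immature event i matures at rate
#' `base_rate_i * prod(multiplier_ji over mature j)`, simulated up to an
#' exponential sampling age. Returns per-molecule states and maturation
#' times - the ground truth against which annotation and dependency
#' recovery are checked.
#'
#' @param config a [sim_config()].
#' @return a `sim_truth` list: `molecules` (data.frame `replicate`,
#'   `molecule_id`, `transcript`, `age`), `states` (logical matrix molecule
#'   x event, NA for events on other transcripts), `times` (numeric matrix,
#'   `Inf` for never-matured).
#' @export
simulate_molecules <- function(config) {
  set.seed(config$seed + 22L)   # kinetics stage
  tr <- config$transcripts
  ev <- config$events
  ids <- ev$event_id
  nev <- length(ids)

  n <- config$n_reads
  total <- n * config$n_replicates
  tri <- sample.int(nrow(tr), total, replace = TRUE,
                    prob = tr$weight / sum(tr$weight))
  ages <- if (config$age_distribution == "exponential")
    stats::rexp(total, rate = 1 / config$mean_age)
  else rep(config$mean_age, total)
  states <- matrix(NA, nrow = total, ncol = nev, dimnames = list(NULL, ids))
  times <- matrix(NA_real_, nrow = total, ncol = nev,
                  dimnames = list(NULL, ids))

  enh <- config$enhancement
  enh_ids <- if (is.null(enh)) character(0) else union(enh$from, enh$to)
  mol_tr <- tr$transcript[tri]

  for (tname in unique(ev$transcript)) {
    idx <- which(ev$transcript == tname)
    rows <- which(mol_tr == tname)
    if (length(rows) == 0L) next

    # events untouched by any enhancement: independent exponential clocks
    indep <- idx[!ids[idx] %in% enh_ids]
    for (j in indep) {
      tj <- if (ev$base_rate[j] > 0)
        stats::rexp(length(rows), ev$base_rate[j]) else rep(Inf, length(rows))
      mat <- tj <= ages[rows]
      states[rows, j] <- mat
      times[rows, j] <- ifelse(mat, tj, Inf)
    }

    # events in the enhancement subgraph: per-molecule Gillespie
    dep <- idx[ids[idx] %in% enh_ids]
    if (length(dep) > 0L) {
      ne <- length(dep)
      k <- ev$base_rate[dep]
      M <- matrix(1, ne, ne, dimnames = list(ids[dep], ids[dep]))
      keep <- enh$from %in% ids[dep] & enh$to %in% ids[dep]
      for (i in which(keep)) M[enh$from[i], enh$to[i]] <- enh$multiplier[i]
      for (mi in rows) {
        st <- rep(FALSE, ne)
        tm <- rep(Inf, ne)
        mult <- rep(1, ne)   # running product of multipliers from mature js
        t <- 0
        age <- ages[mi]
        repeat {
          rates <- k * mult
          rates[st] <- 0
          tot <- sum(rates)
          if (tot <= 0) break
          t <- t + stats::rexp(1L, tot)
          if (t > age) break
          pick <- sample.int(ne, 1L, prob = rates)
          st[pick] <- TRUE
          tm[pick] <- t
          mult <- mult * M[pick, ]
        }
        states[mi, dep] <- st
        times[mi, dep] <- tm
      }
    }
  }

  rep_lab <- rep(paste0("rep", seq_len(config$n_replicates)), each = n)
  molecules <- data.frame(
    replicate = rep_lab,
    molecule_id = sprintf("%s_m%06d", rep_lab,
                          rep(seq_len(n), config$n_replicates)),
    transcript = tr$transcript[tri],
    age = ages, stringsAsFactors = FALSE)
  structure(list(molecules = molecules, states = states, times = times,
                 config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d molecules, %d events, %d replicates\n",
              nrow(x$molecules), ncol(x$states),
              length(unique(x$molecules$replicate))))
  invisible(x)
}

#' Turn simulated molecules into error-bearing aligned SAM reads
#'
#' Each captured molecule becomes one read: the transcript span of the
#' genome with edited bases applied (C->T on plus-strand genes, G->A in
#' plus-reference coordinates on minus-strand genes) and introns removed
#' when spliced. The capture bias may drop long molecules or truncate them
#' to a 3'-anchored fragment; per-base substitutions and indels are then
#' applied. Because the full transform from the reference is known, the
#' CIGAR is constructed directly (`N` skips for spliced introns, edits and
#' substitutions as `M` mismatches, simulated indels as `I`/`D`) and the
#' read is emitted as a pre-aligned SAM record, bypassing any aligner.
#'
#' @param truth a `sim_truth` from [simulate_molecules()].
#' @param genome the matching `DNAStringSet` from [build_toy_genome()].
#' @param dir output directory for the per-replicate SAM files.
#' @param fastq also write plain FASTQ (for users wanting a real aligner).
#' @return list: `sam` (named per-replicate SAM paths), `reads` (data.frame
#'   of emitted reads: `replicate`, `read_id`, `transcript`, `length`,
#'   `truncated`), `kept` (logical vector over truth molecules), `fastq`
#'   (paths or NULL).
#' @export
sequence_reads <- function(truth, genome, dir = tempfile("simreads"),
                           fastq = FALSE) {
  config <- truth$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- config$transcripts
  ev <- config$events
  chrom <- config$chrom
  graw <- charToRaw(as.character(genome[[1L]]))
  rawACGT <- charToRaw("ACGT")

  set.seed(config$seed + 33L)   # sequencing stage
  mol <- truth$molecules
  ntot <- nrow(mol)
  tr_row <- match(mol$transcript, tr$transcript)
  t0v <- tr$start[tr_row]
  t1v <- tr$end[tr_row]
  strandv <- tr$strand[tr_row]
  spanv <- t1v - t0v + 1L
  ev_tr_strand <- tr$strand[match(ev$transcript, tr$transcript)]

  # pre-error read length: span minus spliced intron widths
  L <- spanv
  for (j in which(ev$kind == "splicing")) {
    m <- which(!is.na(truth$states[, j]) & truth$states[, j])
    L[m] <- L[m] - (ev$intron_end[j] - ev$intron_start[j] + 1L)
  }

  # capture bias: drop or 3'-truncate molecules failing the logistic keep
  p_keep <- 1 / (1 + exp((L - config$capture_L0) / config$capture_steepness))
  fail <- stats::runif(ntot) > p_keep
  dropm <- fail & stats::runif(ntot) < 0.5
  truncm <- fail & !dropm
  lt <- integer(ntot)
  if (any(truncm)) {
    i <- which(truncm)
    lt[i] <- round(stats::runif(length(i), pmin(200, L[i]),
                                pmin(L[i], config$capture_L0)))
  }
  kept <- !dropm
  ki <- which(kept)
  nk <- length(ki)

  # one concatenated ops/base vector over all captured molecules
  spank <- spanv[ki]
  offs <- cumsum(c(0L, spank))[seq_len(nk)]
  gpos <- sequence(spank, from = t0v[ki])
  mid <- rep.int(seq_len(nk), spank)
  base <- graw[gpos]
  ops <- rep.int(1L, sum(spank))   # op codes: 1=M, 2=D, 3=N, 4=I

  st_k <- truth$states[ki, , drop = FALSE]
  for (j in seq_len(nrow(ev))) {
    rows <- which(!is.na(st_k[, j]) & st_k[, j])   # mature carriers
    if (length(rows) == 0L) next
    if (ev$kind[j] == "splicing") {
      iw <- ev$intron_end[j] - ev$intron_start[j] + 1L
      from <- offs[rows] + (ev$intron_start[j] - t0v[ki][rows]) + 1L
      ops[sequence(rep.int(iw, length(rows)), from = from)] <- 3L
    } else {
      idx <- offs[rows] + (ev$position[j] - t0v[ki][rows]) + 1L
      base[idx] <- charToRaw(if (ev_tr_strand[j] == "+") "T" else "A")
    }
  }

  # 3'-anchored truncation (cDNA synthesis starts at the 3' end): delete the
  # 5' part of the block; for plus-strand transcripts the 3' end is the
  # right end in plus coordinates, for minus-strand ones the left end
  del_mask <- logical(length(ops))
  for (i in which(truncm[ki])) {
    block <- (offs[i] + 1L):(offs[i] + spank[i])
    mpos <- block[ops[block] == 1L]
    keep_m <- if (strandv[ki][i] == "+") utils::tail(mpos, lt[ki[i]]) else
      utils::head(mpos, lt[ki[i]])
    del_mask[block[block < min(keep_m) | block > max(keep_m)]] <- TRUE
  }
  if (any(del_mask)) {
    keep2 <- !del_mask
    ops <- ops[keep2]; base <- base[keep2]
    gpos <- gpos[keep2]; mid <- mid[keep2]
  }

  # sequencing errors on aligned bases: one uniform draw per base decides
  # between deletion, substitution, insertion-after, or no error
  midx <- which(ops == 1L)
  u <- stats::runif(length(midx))
  if (config$err_del > 0) {
    rdel <- u < config$err_del
    ops[midx[rdel]] <- 2L
    midx <- midx[!rdel]
    u <- u[!rdel]
  }
  u <- u - config$err_del
  if (config$err_sub > 0) {
    s <- midx[u >= 0 & u < config$err_sub]
    if (length(s) > 0L) base[s] <- other_base(base[s])
  }
  u <- u - config$err_sub
  if (config$err_ins > 0) {
    ins <- midx[u >= 0 & u < config$err_ins]
    if (length(ins) > 0L) {
      # splice each insertion in right after its carrier base; carriers are
      # strictly increasing so the merged order is computed directly
      N <- length(ops)
      K <- length(ins)
      pos_orig <- seq_len(N) + findInterval(seq_len(N) - 1L, ins)
      pos_ins <- ins + seq_len(K)
      splice <- function(x, xi) {
        out <- vector(typeof(x), N + K)
        out[pos_orig] <- x
        out[pos_ins] <- xi
        out
      }
      newbase <- rawACGT[sample.int(4L, K, replace = TRUE)]
      base <- splice(base, newbase)
      gposi <- gpos[ins]
      midi <- mid[ins]
      ops <- splice(ops, rep.int(4L, K))
      gpos <- splice(gpos, gposi)
      mid <- splice(mid, midi)
    }
  }

  # trim each molecule to its first/last emitted (M or I) entry
  emit <- ops == 1L | ops == 4L
  ei <- which(emit)
  em <- mid[ei]
  d1 <- !duplicated(em)
  d2 <- !duplicated(em, fromLast = TRUE)
  firstv <- rep(NA_integer_, nk)
  lastv <- rep(NA_integer_, nk)
  firstv[em[d1]] <- ei[d1]
  lastv[em[d2]] <- ei[d2]
  idx <- seq_along(ops)
  keep3 <- !is.na(firstv[mid]) & idx >= firstv[mid] & idx <= lastv[mid]
  ops <- ops[keep3]; base <- base[keep3]
  gpos <- gpos[keep3]; mid <- mid[keep3]
  kept[ki[is.na(firstv)]] <- FALSE

  # per-molecule CIGAR: runs break where the op or the molecule changes
  nL <- length(ops)
  reads <- data.frame(replicate = character(0), read_id = character(0),
                      transcript = character(0), flag = integer(0),
                      pos = integer(0), cigar = character(0),
                      seq = character(0), truncated = logical(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (nL > 0L) {
    brk <- ops[-1L] != ops[-nL] | mid[-1L] != mid[-nL]
    ends <- c(which(brk), nL)
    lens <- diff(c(0L, ends))
    cigs <- vapply(split(paste0(lens, c("M", "D", "N", "I")[ops[ends]]),
                         mid[ends]),
                   paste, character(1), collapse = "")
    emit2 <- ops == 1L | ops == 4L
    seqs <- vapply(split(base[emit2], mid[emit2]),
                   rawToChar, character(1))
    fi <- which(!duplicated(mid))
    molv <- mid[fi]                       # molecule (index into ki) per read
    stopifnot(identical(as.character(molv), names(cigs)))
    orig <- ki[molv]
    reads <- data.frame(
      replicate = mol$replicate[orig],
      read_id = mol$molecule_id[orig],
      transcript = mol$transcript[orig],
      flag = ifelse(strandv[orig] == "+", 0L, 16L),
      pos = gpos[fi],
      cigar = unname(cigs),
      seq = unname(seqs),
      truncated = truncm[orig],
      stringsAsFactors = FALSE)
    reads$length <- nchar(reads$seq)
  }

  sam_paths <- character(0)
  fq_paths <- if (fastq) character(0) else NULL
  for (r in unique(mol$replicate)) {
    rr <- reads[reads$replicate == r, , drop = FALSE]
    path <- file.path(dir, paste0(r, ".sam"))
    write_sam(rr, chrom, length(genome[[1L]]), path)
    sam_paths[r] <- path
    if (fastq) {
      fp <- file.path(dir, paste0(r, ".fastq"))
      writeLines(as.vector(rbind(paste0("@", rr$read_id), rr$seq, "+",
                                 strrep("I", nchar(rr$seq)))), fp)
      fq_paths[r] <- fp
    }
  }
  list(sam = sam_paths, reads = reads, kept = kept, fastq = fq_paths)
}

# uniform substitution to one of the three other bases, vectorized over
# raw bytes
other_base <- function(b) {
  bases <- charToRaw("ACGT")
  bi <- match(as.integer(b), as.integer(bases))
  shift <- sample.int(3L, length(b), replace = TRUE)
  bases[((bi - 1L + shift) %% 4L) + 1L]
}

write_sam <- function(reads, chrom, genome_length, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, genome_length))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                 reads$read_id, reads$flag, chrom, reads$pos, reads$cigar,
                 reads$seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Run the whole simulator: genome, molecules, reads, truth files
#'
#' Convenience wrapper producing everything the downstream modules need:
#' FASTA + catalogue TSV, per-replicate SAM, and ground-truth tables.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created; default a fresh temporary one).
#' @param fastq also emit FASTQ.
#' @return list: `genome`, `catalogue`, `truth` (`sim_truth`), `reads`,
#'   `sam` (per-replicate paths), `kept`, plus `fasta`, `catalogue_path`,
#'   `truth_path` file paths.
#' @export
simulate_dataset <- function(config, dir = tempfile("simdata"),
                             fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- build_toy_genome(config)
  truth <- simulate_molecules(config)
  sq <- sequence_reads(truth, g$genome, dir = dir, fastq = fastq)

  fasta <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(g$genome, fasta)
  cat_path <- file.path(dir, "events.tsv")
  write_catalogue(g$catalogue, cat_path)
  truth_path <- file.path(dir, "truth.tsv")
  tt <- cbind(truth$molecules,
              as.data.frame(ifelse(is.na(truth$states), "NA",
                                   ifelse(truth$states, "mature",
                                          "immature"))),
              stringsAsFactors = FALSE)
  utils::write.table(tt, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  c(list(genome = g$genome, catalogue = g$catalogue, truth = truth,
         fasta = fasta, catalogue_path = cat_path, truth_path = truth_path),
    sq)
}

#' Annotate every replicate of a simulated dataset
#'
#' @param sim result of [simulate_dataset()].
#' @param ... passed to [annotate_alignments()].
#' @return named list of per-replicate `annotation_matrix` objects.
#' @export
annotate_dataset <- function(sim, ...) {
  out <- list()
  for (r in names(sim$sam))
    out[[r]] <- annotate_alignments(sim$sam[[r]], sim$catalogue,
                                    replicate = r, ...)
  out
}

#' Ground-truth contingency counts for a pair of events
#'
#' Cross-tabulates the simulator's true maturation states (restricted to
#' the emitted reads) for one event pair - the oracle against which
#' [joint_table()] output is compared in round-trip checks.
#'
#' @param truth a `sim_truth`.
#' @param event_a,event_b event ids.
#' @param kept optional logical vector (from [sequence_reads()]) selecting
#'   the molecules that became reads.
#' @param replicate optional replicate label filter.
#' @return named integer vector `TT`, `TF`, `FT`, `FF`.
#' @export
truth_pair_counts <- function(truth, event_a, event_b, kept = NULL,
                              replicate = NULL) {
  sel <- rep(TRUE, nrow(truth$molecules))
  if (!is.null(kept)) sel <- sel & kept
  if (!is.null(replicate)) sel <- sel & truth$molecules$replicate %in% replicate
  a <- truth$states[sel, event_a]
  b <- truth$states[sel, event_b]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  c(TT = sum(a & b), TF = sum(a & !b), FT = sum(!a & b), FF = sum(!a & !b))
}
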