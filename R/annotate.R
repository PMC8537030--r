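#' Read aligned long reads from SAM or BAM
#'
#' Loads primary alignments (secondary, supplementary and unmapped records
#' are dropped) together with read name, MAPQ and query sequence. SAM input
#' is converted to a temporary coordinate-sorted BAM on the fly, so plain
#' text SAM from the simulator and indexed BAM behave identically.
#'
#' @param path SAM or BAM file.
#' @return a `GAlignments` object with `qname`, `mapq` and `seq` metadata
#'   columns.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "mapq", "seq"))
  GenomicAlignments::readGAlignments(path, param = param)
}

state_codes <- c(MATURE = "M", IMMATURE = "I", NOT_READ = "N")

#' Annotate aligned reads for every catalogued maturation event
#'
#' Every primary alignment is scored against every event of the catalogue
#' with three modalities: `"M"` (mature: edited base observed / intron
#' spliced out), `"I"` (immature: genomic base / intron retained) or `"N"`
#' (not read: site deleted, outside the aligned span, near an alignment end,
#' ambiguous base, or event on the opposite strand or another contig).
#' Reads informing no event at all are dropped from the matrix.
#'
#' The library is assumed strand-oriented upstream, so a read informs only
#' events on its own mapped strand. For a plus-strand editing site the
#' edited state is a `T` at the position and the immature state a `C`; for a
#' minus-strand site the plus-reference bases are `A` (mature) and `G`
#' (immature). Any other aligned base is conservatively `"N"`. Insertions
#' adjacent to a site do not affect the call. A spliced intron is recognised
#' as a single reference skip (or deletion) whose boundaries fall within
#' `junction_tol` nt of the annotated intron ends and which removes at least
#' `intron_cover_min` of the intron; intron retention requires aligned
#' blocks covering at least `intron_cover_min` of the intron with no such
#' skip, and the read must span both exon flanks either way.
#'
#' @param alignments a `GAlignments` from [read_alignments()], or a SAM/BAM
#'   path.
#' @param catalogue an [event_catalogue()].
#' @param replicate replicate label stored with every row.
#' @param junction_tol tolerance (nt) on splice-junction boundaries.
#' @param intron_cover_min minimum fraction of the intron that must be
#'   skipped (mature) or covered by aligned blocks (immature).
#' @param end_margin sites closer than this to either end of the aligned
#'   span are called `"N"` (alignment edges are unreliable).
#' @param min_mapq drop alignments below this MAPQ.
#' @return an `annotation_matrix`: a data.frame with columns `read_id`,
#'   `replicate`, `strand`, `length` and one `"M"/"I"/"N"` column per event,
#'   carrying the catalogue as attribute `"catalogue"`.
#' @export
annotate_alignments <- function(alignments, catalogue, replicate = "rep1",
                                junction_tol = 10L, intron_cover_min = 0.5,
                                end_margin = 5L, min_mapq = 0L) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  aln <- alignments
  mq <- S4Vectors::mcols(aln)$mapq
  keep <- is.na(mq) | mq == 255L | mq >= min_mapq
  aln <- aln[keep]

  n <- length(aln)
  ev_ids <- catalogue$event_id
  states <- matrix("N", nrow = n, ncol = length(ev_ids),
                   dimnames = list(NULL, ev_ids))
  if (n > 0L) {
    chrom <- as.character(GenomicAlignments::seqnames(aln))
    strand <- as.character(BiocGenerics::strand(aln))
    astart <- GenomicAlignments::start(aln)
    aend <- GenomicAlignments::end(aln)
    cig <- GenomicAlignments::cigar(aln)

    has_editing <- any(catalogue$kind == "editing")
    if (has_editing) {
      refseq <- GenomicAlignments::sequenceLayer(
        S4Vectors::mcols(aln)$seq, cig, from = "query", to = "reference",
        D.letter = "-", N.letter = ".")
      refchar <- as.character(refseq)
    }
    has_splicing <- any(catalogue$kind == "splicing")
    if (has_splicing) {
      gap_list <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig, pos = astart, ops = c("N", "D"))
      m_list <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig, pos = astart, ops = c("M", "=", "X"), reduce.ranges = TRUE)
    }

    for (j in seq_along(ev_ids)) {
      ev <- catalogue[j, ]
      on_target <- chrom == ev$chrom & strand == ev$strand
      if (!any(on_target)) next
      if (ev$kind == "editing") {
        pos <- ev$position
        idx <- which(on_target &
                       astart + end_margin <= pos &
                       aend - end_margin >= pos)
        if (length(idx) == 0L) next
        base <- substr(refchar[idx], pos - astart[idx] + 1L,
                       pos - astart[idx] + 1L)
        call <- rep("N", length(idx))
        if (ev$strand == "+") {
          call[base == "T"] <- "M"
          call[base == "C"] <- "I"
        } else {
          call[base == "A"] <- "M"
          call[base == "G"] <- "I"
        }
        states[idx, j] <- call
      } else {
        is <- ev$intron_start; ie <- ev$intron_end
        iw <- ie - is + 1L
        idx <- which(on_target & astart <= is - 1L & aend >= ie + 1L)
        if (length(idx) == 0L) next
        gaps <- gap_list[idx]
        gs <- BiocGenerics::unlist(gaps)
        grid <- rep(seq_along(idx), S4Vectors::elementNROWS(gaps))
        olap <- pmin(BiocGenerics::end(gs), ie) -
          pmax(BiocGenerics::start(gs), is) + 1L
        match_gap <- abs(BiocGenerics::start(gs) - is) <= junction_tol &
          abs(BiocGenerics::end(gs) - ie) <= junction_tol &
          olap >= intron_cover_min * iw
        mature <- unique(grid[match_gap])

        mb <- m_list[idx]
        ms <- BiocGenerics::unlist(mb)
        mrid <- rep(seq_along(idx), S4Vectors::elementNROWS(mb))
        mcov <- pmax(0L, pmin(BiocGenerics::end(ms), ie) -
                       pmax(BiocGenerics::start(ms), is) + 1L)
        covered <- rowsum(as.numeric(mcov), mrid)
        cov_frac <- numeric(length(idx))
        cov_frac[as.integer(rownames(covered))] <- covered[, 1L]
        cov_frac <- cov_frac / iw

        call <- rep("N", length(idx))
        call[cov_frac >= intron_cover_min] <- "I"
        call[mature] <- "M"
        states[idx, j] <- call
      }
    }
  }

  df <- data.frame(
    read_id = if (n > 0L) S4Vectors::mcols(aln)$qname else character(0),
    replicate = rep(replicate, n),
    strand = if (n > 0L) as.character(BiocGenerics::strand(aln)) else character(0),
    length = if (n > 0L) BiocGenerics::width(S4Vectors::mcols(aln)$seq) else integer(0),
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(states, stringsAsFactors = FALSE))

  informative <- rowSums(states != "N") > 0L
  df <- df[informative, , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L)
    warning("no alignment informs any catalogued event; empty matrix")
  annotation_matrix(df, catalogue)
}

#' Construct an annotation matrix
#'
#' Mostly internal; [annotate_alignments()] and the pooling helpers return
#' objects of this class. `read_id`s must be unique within a replicate and
#' the state columns must exactly match the catalogue.
#'
#' @param df data.frame with `read_id`, `replicate`, `strand`, `length` and
#'   one M/I/N column per catalogue event.
#' @param catalogue the [event_catalogue()] the states refer to.
#' @return an `annotation_matrix`.
#' @export
annotation_matrix <- function(df, catalogue) {
  miss <- setdiff(catalogue$event_id, names(df))
  if (length(miss) > 0L)
    stop("annotation matrix lacks state column(s): ",
         paste(miss, collapse = ", "))
  dup <- duplicated(df[, c("replicate", "read_id")])
  if (any(dup))
    stop("duplicated read_id within replicate: ",
         paste(unique(df$read_id[dup]), collapse = ", "))
  attr(df, "catalogue") <- catalogue
  class(df) <- c("annotation_matrix", "data.frame")
  df
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation_matrix: %d reads x %d events (replicates: %s)\n",
              nrow(x), nrow(attr(x, "catalogue")),
              paste(unique(x$replicate), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Pool annotation matrices across replicates
#'
#' Concatenates the rows of several annotation matrices (typically the three
#' biological replicates) before rate quantification or pooled dependency
#' testing.
#'
#' @param matrices list of `annotation_matrix` objects sharing a catalogue.
#' @return a pooled `annotation_matrix`.
#' @export
pool_matrices <- function(matrices) {
  if (inherits(matrices, "annotation_matrix")) return(matrices)
  stopifnot(length(matrices) >= 1L)
  catalogue <- attr(matrices[[1L]], "catalogue")
  df <- do.call(rbind, lapply(matrices, as.data.frame))
  rownames(df) <- NULL
  annotation_matrix(df, catalogue)
}

#' Write / read an annotation matrix TSV
#'
#' @param matrix an `annotation_matrix`.
#' @param path TSV path.
#' @return `path` (write) or the `annotation_matrix` (read).
#' @export
write_annotation <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @param catalogue the [event_catalogue()] the file was written against.
#' @export
read_annotation <- function(path, catalogue) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  df$length <- as.integer(df$length)
  annotation_matrix(df, catalogue)
}

#' Call the editing state of one aligned read at one site
#'
#' Single-read convenience wrapper around the vectorised annotation; useful
#' for spot checks. See [annotate_alignments()] for the calling rules.
#'
#' @param alignment a length-1 `GAlignments` (with `seq` metadata).
#' @param event one-row [event_catalogue()] slice of kind `"editing"`.
#' @param reference optional `DNAStringSet`; when given, the reference base
#'   at the site is checked to be `C` (plus strand) or `G` (minus strand)
#'   and a mismatch raises an error.
#' @inheritParams annotate_alignments
#' @return `"MATURE"`, `"IMMATURE"` or `"NOT_READ"`.
#' @export
call_editing_state <- function(alignment, event, reference = NULL,
                               end_margin = 5L) {
  stopifnot(event$kind == "editing", length(alignment) == 1L)
  if (!is.null(reference)) check_reference_base(reference, event)
  m <- suppressWarnings(
    annotate_alignments(alignment, event_catalogue(as.data.frame(event)),
                        end_margin = end_margin))
  if (nrow(m) == 0L) return("NOT_READ")
  names(state_codes)[match(m[[event$event_id]], state_codes)]
}

#' Call the splicing state of one aligned read at one intron
#'
#' @param event one-row [event_catalogue()] slice of kind `"splicing"`.
#' @inheritParams call_editing_state
#' @inheritParams annotate_alignments
#' @return `"MATURE"`, `"IMMATURE"` or `"NOT_READ"`.
#' @export
call_splicing_state <- function(alignment, event, junction_tol = 10L,
                                intron_cover_min = 0.5) {
  stopifnot(event$kind == "splicing", length(alignment) == 1L)
  m <- suppressWarnings(
    annotate_alignments(alignment, event_catalogue(as.data.frame(event)),
                        junction_tol = junction_tol,
                        intron_cover_min = intron_cover_min))
  if (nrow(m) == 0L) return("NOT_READ")
  names(state_codes)[match(m[[event$event_id]], state_codes)]
}

#' Check that catalogue editing sites match the reference sequence
#'
#' Editing converts a cytidine, so the plus-strand reference base must be
#' `C` for a plus-strand site and `G` for a minus-strand site. A mismatch
#' indicates a catalogue/reference disagreement and raises an error.
#'
#' @param reference a `DNAStringSet` (names = contigs) or FASTA path.
#' @param catalogue an [event_catalogue()] (or one-row slice).
#' @return `TRUE`, invisibly, when all sites check out.
#' @export
check_reference_base <- function(reference, catalogue) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  ed <- catalogue[catalogue$kind == "editing", , drop = FALSE]
  for (i in seq_len(nrow(ed))) {
    base <- as.character(Biostrings::subseq(reference[[ed$chrom[i]]],
                                            ed$position[i], ed$position[i]))
    want <- if (ed$strand[i] == "+") "C" else "G"
    if (base != want)
      stop(sprintf("reference base at %s (%s:%d%s) is %s, expected %s",
                   ed$event_id[i], ed$chrom[i], ed$position[i], ed$strand[i],
                   base, want))
  }
  invisible(TRUE)
}
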