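#' Maturation-event catalogues
#'
#' A maturation event is a single post-transcriptional processing step on a
#' plastid transcript: either a C-to-U editing site (one genomic position
#' whose sense-strand cytidine is converted to uridine) or a group-II intron
#' (one genomic interval removed by splicing). The catalogue is the fixed
#' list of events a dataset is annotated against; per read, each event is
#' later called mature, immature or not read.
#'
#' Catalogues are plain data frames of class `event_catalogue` with one row
#' per event and columns `event_id`, `kind` (`"editing"` or `"splicing"`),
#' `chrom`, `strand` (`"+"` or `"-"`), `position` (editing only, 1-based),
#' `intron_start`/`intron_end` (splicing only, 1-based inclusive) and
#' `transcript_group` (label joining events carried on the same transcript
#' unit). Coordinates are 1-based inclusive throughout the user-facing
#' interface. tRNA introns are expected to be absent by construction of the
#' catalogue; the loader does not special-case them.
#'
#' @param events data.frame with the columns listed above.
#' @return An `event_catalogue` object (validated data.frame).
#' @examples
#' cat <- event_catalogue(data.frame(
#'   event_id = c("geneA_101", "int_GENEA"),
#'   kind = c("editing", "splicing"),
#'   chrom = "plastome", strand = "+",
#'   position = c(101L, NA),
#'   intron_start = c(NA, 150L), intron_end = c(NA, 400L),
#'   transcript_group = "geneA"))
#' n_events(cat)
#' @export
event_catalogue <- function(events) {
  required <- c("event_id", "kind", "chrom", "strand", "transcript_group")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0L)
    stop("catalogue is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"position" %in% names(events)) events$position <- NA_integer_
  if (!"intron_start" %in% names(events)) events$intron_start <- NA_integer_
  if (!"intron_end" %in% names(events)) events$intron_end <- NA_integer_

  events$event_id <- as.character(events$event_id)
  events$kind <- as.character(events$kind)
  events$chrom <- as.character(events$chrom)
  events$strand <- as.character(events$strand)
  events$transcript_group <- as.character(events$transcript_group)
  events$position <- as.integer(events$position)
  events$intron_start <- as.integer(events$intron_start)
  events$intron_end <- as.integer(events$intron_end)

  validate_catalogue(events)
  events <- events[, c(required[1:4], "position", "intron_start", "intron_end",
                       "transcript_group")]
  rownames(events) <- NULL
  class(events) <- c("event_catalogue", "data.frame")
  events
}

validate_catalogue <- function(events) {
  dup <- unique(events$event_id[duplicated(events$event_id)])
  if (length(dup) > 0L)
    stop("duplicated event_id(s): ", paste(dup, collapse = ", "))
  bad_kind <- unique(events$kind[!events$kind %in% c("editing", "splicing")])
  if (length(bad_kind) > 0L)
    stop("unknown kind(s): ", paste(bad_kind, collapse = ", "))
  bad_strand <- !events$strand %in% c("+", "-")
  if (any(bad_strand))
    stop("invalid strand in row(s): ",
         paste(which(bad_strand), collapse = ", "), " (must be '+' or '-')")

  ed <- events$kind == "editing"
  bad <- ed & (is.na(events$position) | !is.na(events$intron_start) |
                 !is.na(events$intron_end))
  if (any(bad))
    stop("editing event(s) must have a position and no interval: ",
         paste(events$event_id[bad], collapse = ", "))
  sp <- events$kind == "splicing"
  bad <- sp & (is.na(events$intron_start) | is.na(events$intron_end) |
                 !is.na(events$position))
  if (any(bad))
    stop("splicing event(s) must have an interval and no position: ",
         paste(events$event_id[bad], collapse = ", "))
  bad <- sp & !is.na(events$intron_start) & !is.na(events$intron_end) &
    events$intron_end <= events$intron_start
  if (any(bad))
    stop("intron_end must exceed intron_start for: ",
         paste(events$event_id[bad], collapse = ", "))
  invisible(events)
}

#' Read a maturation-event catalogue from a TSV file
#'
#' The file must be tab-separated with a header row carrying at least
#' `event_id`, `kind`, `chrom`, `strand` and `transcript_group`, plus
#' `position` for editing rows and `intron_start`/`intron_end` for splicing
#' rows (empty or NA in the rows of the other kind). Rows violating the
#' catalogue invariants abort the load with a message naming the offending
#' event.
#'
#' @param path path to the TSV file.
#' @return An [event_catalogue()].
#' @export
load_catalogue <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           quote = "", comment.char = "#")
  event_catalogue(tab)
}

#' Write a catalogue to TSV
#'
#' @param catalogue an [event_catalogue()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  utils::write.table(as.data.frame(catalogue), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.event_catalogue <- function(x, ...) {
  cat(sprintf("event_catalogue: %d events (%d editing, %d splicing) on %s\n",
              nrow(x), sum(x$kind == "editing"), sum(x$kind == "splicing"),
              paste(unique(x$chrom), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more events\n")
  invisible(x)
}

#' Event counts
#' @param catalogue an [event_catalogue()].
#' @return `n_events`: total number of events; `n_editing`/`n_splicing`:
#'   counts by kind.
#' @export
n_events <- function(catalogue) nrow(catalogue)

#' @rdname n_events
#' @export
n_editing <- function(catalogue) sum(catalogue$kind == "editing")

#' @rdname n_events
#' @export
n_splicing <- function(catalogue) sum(catalogue$kind == "splicing")

#' Number of theoretically co-observable event pairs
#'
#' With n catalogued events, n(n-1)/2 unordered pairs could in principle be
#' observed co-occurring on single reads. With a typical angiosperm plastid
#' catalogue of 43 editing sites and 14 introns (57 events) this is 1596
#' pairs; in practice far fewer are jointly covered because events sit on
#' different transcripts.
#'
#' @param catalogue an [event_catalogue()], or directly an integer number of
#'   events.
#' @return integer pair count.
#' @export
theoretical_pair_count <- function(catalogue) {
  n <- if (is.numeric(catalogue)) as.integer(catalogue) else n_events(catalogue)
  if (is.na(n) || n < 2L) stop("need at least 2 events to form a pair")
  as.integer(n * (n - 1L) / 2L)
}

#' Number of joint maturation states for k binary events
#'
#' Each event on a read is either mature or immature, so k jointly covered
#' events admit 2^k intermediate configurations (e.g. 4096 for the 12 events
#' of a heavily edited transcript such as ndhB).
#'
#' @param k integer number of events (k >= 1).
#' @return 2^k as a double (exact for k <= 52).
#' @export
n_joint_states <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("k must be a single integer >= 1")
  2^k
}

#' Export event footprints as BED6
#'
#' Editing sites become 1-base features, introns become their interval;
#' scores are 0 and names are the event ids. Coordinates follow the BED
#' convention (0-based half-open), converted internally.
#'
#' @param catalogue an [event_catalogue()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(catalogue, path) {
  start0 <- ifelse(catalogue$kind == "editing",
                   catalogue$position - 1L, catalogue$intron_start - 1L)
  end <- ifelse(catalogue$kind == "editing",
                catalogue$position, catalogue$intron_end)
  bed <- data.frame(chrom = catalogue$chrom, start = start0, end = end,
                    name = catalogue$event_id, score = 0L,
                    strand = catalogue$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Catalogue events as GRanges
#'
#' @param catalogue an [event_catalogue()].
#' @return a `GRanges` with one range per event (width 1 for editing sites).
#' @export
catalogue_ranges <- function(catalogue) {
  start <- ifelse(catalogue$kind == "editing",
                  catalogue$position, catalogue$intron_start)
  end <- ifelse(catalogue$kind == "editing",
                catalogue$position, catalogue$intron_end)
  GenomicRanges::GRanges(
    seqnames = catalogue$chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = catalogue$strand,
    event_id = catalogue$event_id,
    kind = catalogue$kind,
    transcript_group = catalogue$transcript_group)
}
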