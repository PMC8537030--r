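#' Editing and splicing rates from pooled reads
#'
#' For every catalogued event, the maturation rate is the fraction of
#' informative pooled reads calling it mature:
#' `rate = n_mature / (n_mature + n_immature)`. Not-read states never enter
#' the denominator. Replicates are pooled before counting; events with no
#' informative read are flagged and carry `NA`.
#'
#' @param matrices list of per-replicate `annotation_matrix` objects (or a
#'   single, possibly pooled, matrix).
#' @return data.frame with `event_id`, `kind`, `n_mature`, `n_immature`,
#'   `rate`, `flagged`.
#' @export
maturation_rates <- function(matrices) {
  pooled <- pool_matrices(matrices)
  catalogue <- attr(pooled, "catalogue")
  s <- as.matrix(as.data.frame(pooled)[, catalogue$event_id, drop = FALSE])
  n_mature <- colSums(s == "M")
  n_immature <- colSums(s == "I")
  informative <- n_mature + n_immature
  data.frame(event_id = catalogue$event_id,
             kind = catalogue$kind,
             n_mature = as.integer(n_mature),
             n_immature = as.integer(n_immature),
             rate = ifelse(informative > 0, n_mature / informative, NA_real_),
             flagged = informative == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Virtual Northern blot of a probe region
#'
#' Emulates a Northern blot from long reads: every primary read on the
#' probe strand whose alignment overlaps the probe interval by at least
#' `min_overlap` bases contributes its full read length (not clipped to the
#' probe) to a length histogram, which is normalized by setting the most
#' abundant read length to 100.
#'
#' @param alignments a `GAlignments` from [read_alignments()] or a SAM/BAM
#'   path.
#' @param chrom,start,end probe interval (1-based inclusive).
#' @param strand probe strand, `"+"` (Watson) or `"-"` (Crick).
#' @param min_overlap minimum probe overlap in bases (default 1).
#' @param smoothing_sigma Gaussian sigma (nt) used only when rendering.
#' @return a `blot_profile`: data.frame `histogram` (`length`, `count`,
#'   `normalized`) plus the probe description.
#' @export
virtual_northern <- function(alignments, chrom, start, end, strand = "+",
                             min_overlap = 1L, smoothing_sigma = 5) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  aln <- alignments
  olap <- pmin(BiocGenerics::end(aln), end) -
    pmax(BiocGenerics::start(aln), start) + 1L
  keep <- as.character(GenomicAlignments::seqnames(aln)) == chrom &
    as.character(BiocGenerics::strand(aln)) == strand &
    olap >= min_overlap
  lens <- BiocGenerics::width(S4Vectors::mcols(aln)$seq)[keep]
  if (length(lens) == 0L) {
    warning("no read overlaps the probe; empty blot profile")
    hist <- data.frame(length = integer(0), count = integer(0),
                       normalized = numeric(0))
  } else {
    tab <- table(lens)
    hist <- data.frame(length = as.integer(names(tab)),
                       count = as.integer(tab))
    hist$normalized <- 100 * hist$count / max(hist$count)
  }
  structure(list(histogram = hist,
                 probe = list(chrom = chrom, start = start, end = end,
                              strand = strand),
                 n_reads = sum(keep),
                 smoothing_sigma = smoothing_sigma),
            class = "blot_profile")
}

#' @export
print.blot_profile <- function(x, ...) {
  cat(sprintf("blot_profile: %s:%d-%d(%s), %d reads, %d distinct lengths\n",
              x$probe$chrom, x$probe$start, x$probe$end, x$probe$strand,
              x$n_reads, nrow(x$histogram)))
  invisible(x)
}

#' Render a virtual Northern blot as a gel-lane image
#'
#' Draws one gel lane: band intensity proportional to the
#' Gaussian-smoothed normalized histogram, length axis descending downward
#' on a log scale (mimicking gel migration). The companion TSV holds the
#' exact unsmoothed histogram, so the data artifact is deterministic
#' regardless of graphics backend.
#'
#' @param profile a non-empty `blot_profile`.
#' @param image_path output image (`.png` or `.svg` by extension).
#' @param tsv_path optional path for the raw histogram TSV.
#' @param lane_title label drawn above the lane.
#' @return `image_path`, invisibly.
#' @export
render_blot <- function(profile, image_path, tsv_path = NULL,
                        lane_title = "") {
  hist <- profile$histogram
  if (nrow(hist) == 0L) stop("cannot render an empty blot profile")
  if (!is.null(tsv_path))
    utils::write.table(hist, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  sigma <- max(profile$smoothing_sigma, 0.5)
  lo <- max(1, min(hist$length) - 4 * sigma)
  hi <- max(hist$length) + 4 * sigma
  grid <- exp(seq(log(lo), log(hi), length.out = 800))
  intensity <- vapply(grid, function(g)
    sum(hist$normalized * exp(-0.5 * ((g - hist$length) / sigma)^2)),
    numeric(1))
  intensity <- intensity / max(intensity)

  ext <- tolower(tools::file_ext(image_path))
  if (ext == "svg") grDevices::svg(image_path, width = 2.2, height = 6)
  else grDevices::png(image_path, width = 220, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 4, 3, 1))   # device-local; dies with dev.off()
  graphics::plot(NA, xlim = c(0, 1), ylim = rev(log(range(grid))),
                 xlab = "", ylab = "read length (nt)", axes = FALSE,
                 main = lane_title)
  ticks <- pretty(hist$length, n = 6)
  ticks <- ticks[ticks > 0]
  graphics::axis(2, at = log(ticks), labels = ticks, las = 1)
  graphics::rect(0.25, log(grid[-length(grid)]), 0.75, log(grid[-1]),
                 col = grDevices::grey(1 - intensity[-1]), border = NA)
  graphics::box()
  invisible(image_path)
}

#' Strand-specific per-base coverage of an interval
#'
#' Depth counts, at single-nucleotide resolution, the aligned bases of all
#' primary reads on the requested strand that overlap the interval at least
#' partially (reads are not clipped before counting, so their aligned bases
#' inside the window all contribute; reference skips of spliced reads do
#' not).
#'
#' @inheritParams virtual_northern
#' @return a `coverage_profile`: data.frame with `pos` and `depth`, plus
#'   interval metadata.
#' @export
strand_coverage <- function(alignments, chrom, start, end, strand = "+") {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  aln <- alignments
  keep <- as.character(GenomicAlignments::seqnames(aln)) == chrom &
    as.character(BiocGenerics::strand(aln)) == strand &
    BiocGenerics::start(aln) <= end & BiocGenerics::end(aln) >= start
  aln <- aln[keep]
  depth <- integer(end - start + 1L)
  if (length(aln) > 0L) {
    cov <- GenomicAlignments::coverage(aln)[[chrom]]
    cov <- as.integer(cov)
    span <- seq.int(start, min(end, length(cov)))
    if (length(span) > 0 && span[1L] <= length(cov))
      depth[span - start + 1L] <- cov[span]
  }
  structure(list(profile = data.frame(pos = seq.int(start, end),
                                      depth = depth),
                 chrom = chrom, strand = strand),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile %s:%d-%d(%s): mean depth %.1f, max %d\n",
              x$chrom, min(x$profile$pos), max(x$profile$pos), x$strand,
              mean(x$profile$depth), max(x$profile$depth)))
  invisible(x)
}
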