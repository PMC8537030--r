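#' Canned simulation scenarios
#'
#' Fixed study conditions used throughout the test-suite and the
#' reproduction script. Each returns a [sim_config()]; only the seed (and,
#' where stated, the error model) varies between runs.
#'
#' * `sim_scenario_null()`: one 800-nt plus-strand transcript carrying 10
#'   events (8 editing sites, 2 introns) with base rates spreading marginal
#'   maturation between ~0.39 and ~0.86 at the fixed unit sampling age,
#'   all multipliers at 1 (full independence), 3 replicates x 2000 reads.
#'   The negative control for the dependency network.
#' * `sim_scenario_power(multiplier)`: the null scenario plus one planted
#'   enhancement: editing site `e3` (rate log(2), marginal exactly 0.50)
#'   multiplies the rate of `e7` (base rate 0.425, marginal ~0.50 under
#'   the default 4-fold enhancement; rates calibrated by Monte Carlo
#'   integration of the two-state kinetic model).
#' * `sim_scenario_chain(k)`: one transcript with `k` editing sites
#'   maturing strictly sequentially: the first at rate 1.5, each later one
#'   at a negligible base rate (1e-12) boosted 2e12-fold by its
#'   predecessor, so maturation is a monotone chain and every intermediate
#'   is a prefix at any simulated scale.
#' * `sim_scenario_isoforms()`: two co-terminal plus-strand transcripts of
#'   1800 and 1100 nt at equal molarity sharing a probe window - the
#'   two-band virtual-Northern scenario. Capture bias is disabled so band
#'   positions are exact.
#'
#' @param seed integer seed.
#' @param n_reads molecules per replicate.
#' @param n_replicates biological replicates.
#' @param err_sub,err_ins,err_del error model (defaults follow
#'   [sim_config()]: ~4% total, nanopore-like).
#' @param multiplier enhancement factor of the planted pair.
#' @param k chain length (number of sequential editing sites).
#' @return a [sim_config()].
#' @name sim_scenarios
NULL

null_events <- function() {
  data.frame(
    event_id = c("e1", "e2", "e3", "e4", "int_A", "e5", "e6", "int_B",
                 "e7", "e8"),
    kind = c(rep("editing", 4L), "splicing", "editing", "editing",
             "splicing", "editing", "editing"),
    transcript = "tA",
    position = c(20L, 60L, 100L, 130L, NA, 300L, 350L, NA, 560L, 700L),
    intron_start = c(rep(NA, 4L), 150L, NA, NA, 400L, NA, NA),
    intron_end = c(rep(NA, 4L), 250L, NA, NA, 520L, NA, NA),
    base_rate = c(0.5, 0.8, 1.0, 1.5, 0.7, 1.2, 0.6, 1.0, 0.6, 2.0),
    stringsAsFactors = FALSE)
}

#' @rdname sim_scenarios
#' @export
sim_scenario_null <- function(seed, n_reads = 2000L, n_replicates = 3L,
                              err_sub = 0.03, err_ins = 0.003,
                              err_del = 0.007) {
  sim_config(
    transcripts = data.frame(transcript = "tA", start = 1L, end = 800L,
                             strand = "+", stringsAsFactors = FALSE),
    events = null_events(),
    genome_length = 850L,
    n_reads = n_reads, n_replicates = n_replicates,
    err_sub = err_sub, err_ins = err_ins, err_del = err_del,
    seed = seed)
}

#' @rdname sim_scenarios
#' @export
sim_scenario_power <- function(seed, multiplier = 4, n_reads = 2000L,
                               n_replicates = 3L, err_sub = 0.03,
                               err_ins = 0.003, err_del = 0.007) {
  cfg <- sim_scenario_null(seed, n_reads, n_replicates,
                           err_sub, err_ins, err_del)
  # marginals ~0.5/0.5 at the fixed unit sampling age: the enhancer at rate
  # log(2) and the enhanced event at base rate 0.425 under a 4x multiplier
  cfg$events$base_rate[cfg$events$event_id == "e3"] <- log(2)
  cfg$events$base_rate[cfg$events$event_id == "e7"] <- 0.425
  cfg$enhancement <- data.frame(from = "e3", to = "e7",
                                multiplier = multiplier,
                                stringsAsFactors = FALSE)
  cfg
}

#' @rdname sim_scenarios
#' @export
sim_scenario_chain <- function(seed, k = 5L, n_reads = 2000L,
                               n_replicates = 3L, err_sub = 0,
                               err_ins = 0, err_del = 0) {
  ids <- paste0("c", seq_len(k))
  events <- data.frame(
    event_id = ids, kind = "editing", transcript = "tC",
    position = as.integer(seq(30L, 570L, length.out = k)),
    base_rate = c(1.5, rep(1e-12, k - 1L)),
    stringsAsFactors = FALSE)
  enh <- data.frame(from = ids[-k], to = ids[-1L], multiplier = 2e12,
                    stringsAsFactors = FALSE)
  sim_config(
    transcripts = data.frame(transcript = "tC", start = 1L, end = 600L,
                             strand = "+", stringsAsFactors = FALSE),
    events = events, enhancement = enh, genome_length = 650L,
    n_reads = n_reads, n_replicates = n_replicates,
    err_sub = err_sub, err_ins = err_ins, err_del = err_del,
    seed = seed)
}

#' @rdname sim_scenarios
#' @export
sim_scenario_isoforms <- function(seed, n_reads = 2000L,
                                  n_replicates = 1L) {
  sim_config(
    transcripts = data.frame(
      transcript = c("long", "short"),
      start = c(301L, 1001L), end = c(2100L, 2100L),
      strand = "+", weight = 1, stringsAsFactors = FALSE),
    events = data.frame(
      event_id = c("eL", "eS"), kind = "editing",
      transcript = c("long", "short"),
      position = c(500L, 1200L), base_rate = 1,
      stringsAsFactors = FALSE),
    genome_length = 2200L,
    err_sub = 0, err_ins = 0, err_del = 0,
    capture_L0 = 1e6,
    n_reads = n_reads, n_replicates = n_replicates,
    seed = seed)
}
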