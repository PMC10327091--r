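#' Simulate a bloom time series with ASV tables and per-day experiments
#'
#' Amplicon (ASV) tables are multinomial draws from the configured per-day
#' community fractions, with a metazoan pseudo-taxon mixed in at a constant
#' fraction (metazoans are abundant in real amplicon data but are excluded
#' from the relative-abundance analysis downstream). For sampled days a
#' droplet experiment is generated in which the focal taxon is infected by
#' the focal family at that day's configured infected fraction.
#'
#' @param config a \linkS4class{CommunityConfig}; taxa and seed are taken
#'   from it
#' @param days integer vector of day labels
#' @param trajectory data.frame with one row per day: a column per taxon
#'   (per-day community fractions, summing to 1 across taxa) and a column
#'   \code{infected_fraction} for the focal taxon
#' @param focalTaxon,focalFamily the tracked host class and its virus
#' @param nASV amplicon reads drawn per day (default 10000)
#' @param metazoanFraction fraction of amplicons from the metazoan
#'   pseudo-taxon (default 0.15)
#' @param sampledDays days on which single-cell experiments are generated
#'   (default none)
#' @param sampleCells cells per sampled-day experiment (0 = skip)
#' @param focalExprFraction viral expression fraction in infected focal
#'   cells
#' @param refs \linkS4class{ReferenceSet} (required when sampleCells > 0)
#' @return list(asv = long data.frame(day, taxon, count),
#'   infected_fraction = named per-day planted infected fractions,
#'   experiments = named list of \code{simulateExperiment} results)
#' @export
simulateTimeseries <- function(config, days, trajectory, focalTaxon,
                               focalFamily, nASV = 10000L,
                               metazoanFraction = 0.15,
                               sampledDays = integer(0), sampleCells = 0L,
                               focalExprFraction = 0.2, refs = NULL) {
  stopifnot(is(config, "CommunityConfig"))
  if (length(days) != nrow(trajectory))
    stop("days (", length(days), ") and trajectory rows (", nrow(trajectory),
         ") disagree")
  taxa <- config@taxonNames
  if (!all(taxa %in% names(trajectory)))
    stop("trajectory must carry one fraction column per taxon")
  if (!"infected_fraction" %in% names(trajectory))
    stop("trajectory must carry an infected_fraction column")
  stopifnot(focalTaxon %in% taxa, focalFamily %in% config@familyNames)
  set.seed(config@seed + 2L)
  asv <- do.call(rbind, lapply(seq_along(days), function(d) {
    fr <- as.numeric(trajectory[d, taxa])
    if (abs(sum(fr) - 1) > 1e-6)
      stop("trajectory fractions on day ", days[d], " do not sum to 1")
    probs <- c(fr * (1 - metazoanFraction), metazoanFraction)
    cnt <- as.integer(rmultinom(1L, nASV, probs))
    data.frame(day = days[d], taxon = c(taxa, "Metazoa"), count = cnt,
               stringsAsFactors = FALSE)
  }))
  experiments <- list()
  if (sampleCells > 0L && length(sampledDays)) {
    if (is.null(refs)) stop("refs required when sampleCells > 0")
    if (!all(sampledDays %in% days)) stop("sampledDays must be a subset of days")
    for (d in sampledDays) {
      row <- match(d, days)
      dayCfg <- communityConfig(
        taxonNames = taxa,
        taxonCellFractions = as.numeric(trajectory[row, taxa]),
        dominantTaxon = config@dominantTaxon,
        familyNames = config@familyNames,
        markerGenesPerFamily = config@markerGenesPerFamily,
        infectionTable = data.frame(
          taxon = focalTaxon, family = focalFamily,
          frac_infected = trajectory$infected_fraction[row],
          expr_fraction = focalExprFraction, stringsAsFactors = FALSE),
        ambientViralRate = config@ambientViralRate,
        doubletRate = config@doubletRate,
        nCells = sampleCells, readsPerCell = config@readsPerCell,
        seed = config@seed + 100L + row)
      experiments[[as.character(d)]] <- simulateExperiment(refs, dayCfg)
    }
  }
  list(asv = asv,
       infected_fraction = setNames(trajectory$infected_fraction, days),
       experiments = experiments)
}
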