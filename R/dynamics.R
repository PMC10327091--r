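#' Per-day relative abundance from ASV counts
#'
#' Per day, each taxon's fraction of all amplicon counts after excluding
#' the given taxa (metazoans by default). Scale-invariant in the day's
#' counts.
#'
#' @param asv long data.frame(day, taxon, count), counts >= 0
#' @param excludeTaxa taxa excluded from the denominator (default
#'   "Metazoa")
#' @return data.frame(day, taxon, fraction); fractions sum to 1 per day
#' @export
relativeAbundance <- function(asv, excludeTaxa = "Metazoa") {
  stopifnot(all(c("day", "taxon", "count") %in% names(asv)))
  if (any(asv$count < 0)) stop("counts must be non-negative")
  days0 <- unique(asv$day)
  asv <- asv[!asv$taxon %in% excludeTaxa, , drop = FALSE]
  gone <- setdiff(days0, unique(asv$day))
  if (length(gone)) stop("no non-excluded counts on day ", gone[1L])
  out <- do.call(rbind, lapply(split(asv, asv$day), function(d) {
    tot <- sum(d$count)
    if (tot == 0)
      stop("no non-excluded counts on day ", d$day[1L])
    data.frame(day = d$day[1L], taxon = d$taxon, fraction = d$count / tot,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Infected fraction of a focal group in one sample
#'
#' @param calls output of \code{\link{callHighlyInfected}} for the sample
#' @param taxonomy output of \code{\link{assignCellTaxon}} for the sample
#' @param focalGroup the group of interest
#' @return list(fraction, n_infected, n_total); fraction is NA when no
#'   focal cells were observed
#' @export
infectedFraction <- function(calls, taxonomy, focalGroup) {
  focal <- taxonomy$barcode[taxonomy$group == focalGroup]
  nTot <- length(focal)
  inf <- calls$barcode[calls$highly_infected]
  nInf <- length(intersect(focal, inf))
  list(fraction = if (nTot > 0) nInf / nTot else NA_real_,
       n_infected = nInf, n_total = nTot)
}

#' Link the focal taxon's infection peak to its population decline
#'
#' Identifies the focal taxon's peak day (argmax fraction, earliest on
#' ties), the first later day whose fraction falls to at most
#' \code{declineRatio} times the peak, and the sampled day of maximum
#' infected fraction. The demise is flagged as infection-associated when
#' the maximum-infection day lies inside [peak day, decline day]. This is
#' an explicit operationalization of a qualitative observation; the flag is
#' a deterministic function of the series.
#'
#' @param abundance data.frame(day, fraction) for the focal taxon
#' @param infection data.frame(day, infected_fraction) on sampled days
#' @param declineRatio decline threshold relative to the peak (default 0.5)
#' @return list(peak_day, peak_fraction, decline_day, max_infection_day,
#'   infection_associated_demise); decline_day is NA for monotone series
#' @export
demiseReport <- function(abundance, infection, declineRatio = 0.5) {
  stopifnot(all(c("day", "fraction") %in% names(abundance)),
            all(c("day", "infected_fraction") %in% names(infection)))
  if (nrow(abundance) < 3L) stop("need at least 3 days")
  ab <- abundance[order(abundance$day), , drop = FALSE]
  peakIdx <- which.max(ab$fraction)  # earliest on ties
  peakDay <- ab$day[peakIdx]
  peakFrac <- ab$fraction[peakIdx]
  post <- ab[ab$day > peakDay & ab$fraction <= declineRatio * peakFrac, ,
             drop = FALSE]
  declineDay <- if (nrow(post)) post$day[1L] else NA
  maxInfDay <- if (nrow(infection))
    infection$day[which.max(infection$infected_fraction)] else NA
  flag <- !is.na(declineDay) && !is.na(maxInfDay) &&
    maxInfDay >= peakDay && maxInfDay <= declineDay
  list(peak_day = peakDay, peak_fraction = peakFrac,
       decline_day = declineDay, max_infection_day = maxInfDay,
       infection_associated_demise = flag)
}
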