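## Substrate composition accounting: ash-conservation solids loss, final
## composition adjusted to the initial-mass basis, per-component and
## pooled percentage losses.

#' Total dry-solids loss inferred from ash conservation
#'
#' Mineral ash is assumed not to be depleted during incubation, so the
#' rise of the ash fraction measures the loss of total dry solids:
#' loss = 1 - ashInitial / ashFinal.
#'
#' @param ashInitial,ashFinal ash fractions of total dry solids, in (0, 1)
#' @return solids loss as a fraction
#' @examples
#' solidsLoss(0.115, 0.175)  # ~0.343
#' @export
solidsLoss <- function(ashInitial, ashFinal) {
  if (ashFinal <= 0) stop("ashFinal must be > 0")
  if (ashInitial <= 0 || ashInitial >= 1 || ashFinal >= 1)
    stop("ash fractions must lie in (0, 1)")
  if (ashFinal < ashInitial)
    stop("ashFinal < ashInitial implies a mass gain; not a composting",
         " mass balance")
  1 - ashInitial / ashFinal
}

#' Adjust a measured final composition to the initial-mass basis
#'
#' Final compositions are measured per kg of final dry solids; multiplying
#' by (1 - solids loss) = ashInitial/ashFinal expresses them per kg of
#' initial dry mix, so that initial and final columns are directly
#' comparable.
#'
#' @param finalMeasured g per kg final dry solids
#' @param ashInitial,ashFinal ash fractions of total dry solids
#' @return g per kg initial dry mix
#' @export
adjustFinal <- function(finalMeasured, ashInitial, ashFinal) {
  finalMeasured * (1 - solidsLoss(ashInitial, ashFinal))
}

#' Percentage loss of one component
#'
#' 100 * (initial - finalAdjusted) / initial. Negative losses (apparent
#' gains) are allowed but flagged with a warning. Reported values are
#' rounded half-up to integers to match conventional table presentation;
#' set \code{rounded = FALSE} for the exact value.
#'
#' @param initial g per kg initial dry mix (> 0)
#' @param finalAdjusted g per kg initial dry mix
#' @param rounded round half-up to integer percent (default TRUE)
#' @return percentage loss
#' @examples
#' componentLossPercent(314, 260)  # 17
#' @export
componentLossPercent <- function(initial, finalAdjusted, rounded = TRUE) {
  if (any(initial <= 0))
    stop("initial mass must be > 0 (zero-initial components are",
         " not applicable)")
  loss <- 100 * (initial - finalAdjusted) / initial
  if (any(loss < 0))
    warning("negative loss (apparent gain) for some component(s)")
  if (rounded) .roundHalfUp(loss) else loss
}

#' Mass-weighted pooled percentage loss of several components
#'
#' 100 * (sum initial - sum finalAdjusted) / sum initial: the loss of the
#' pooled mass, not the mean of per-component percentages. The two agree
#' only when all initial masses are equal.
#'
#' @param initial,finalAdjusted parallel vectors, g per kg initial dry mix
#' @param rounded round half-up to integer percent (default TRUE)
#' @return pooled percentage loss
#' @export
pooledLossPercent <- function(initial, finalAdjusted, rounded = TRUE) {
  if (!length(initial)) stop("empty component list")
  if (sum(initial) <= 0) stop("total initial mass must be > 0")
  loss <- 100 * (sum(initial) - sum(finalAdjusted)) / sum(initial)
  if (rounded) .roundHalfUp(loss) else loss
}

#' Build a composition loss report
#'
#' Accepts either final compositions already on the initial-mass basis
#' (column \code{final_adjusted_g_per_kg}) or measured finals per kg of
#' final solids (column \code{final_measured_g_per_kg}) together with ash
#' fractions for the conversion.
#'
#' @param comp data.frame with columns \code{name},
#'   \code{initial_g_per_kg} and one of the final columns above
#' @param ashInitial,ashFinal ash fractions, required when finals are
#'   measured per kg final solids
#' @return data.frame: \code{name}, \code{initial}, \code{finalAdjusted},
#'   \code{lossPercent} (exact), \code{lossRounded}; components with zero
#'   initial mass get \code{NA} (not applicable)
#' @export
compositionReport <- function(comp, ashInitial = NULL, ashFinal = NULL) {
  if (!"final_adjusted_g_per_kg" %in% names(comp)) {
    if (!"final_measured_g_per_kg" %in% names(comp))
      stop("need final_adjusted_g_per_kg or final_measured_g_per_kg")
    if (is.null(ashInitial) || is.null(ashFinal))
      stop("ash fractions required to adjust measured finals")
    comp$final_adjusted_g_per_kg <-
      adjustFinal(comp$final_measured_g_per_kg, ashInitial, ashFinal)
  }
  ini <- comp$initial_g_per_kg
  fin <- comp$final_adjusted_g_per_kg
  loss <- rep(NA_real_, length(ini))
  ok <- ini > 0
  loss[ok] <- componentLossPercent(ini[ok], fin[ok], rounded = FALSE)
  data.frame(name = comp$name, initial = ini, finalAdjusted = fin,
             lossPercent = loss, lossRounded = .roundHalfUp(loss),
             stringsAsFactors = FALSE)
}

#' Read a composition CSV
#'
#' @param path CSV with header \code{name, initial_g_per_kg} and a final
#'   column (adjusted or measured)
#' @return data.frame
#' @export
readComposition <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
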