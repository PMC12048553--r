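#' Z-scores of a luminescence screen
#'
#' Per receptor, log10-transforms the raw relative-luminescence (RLU)
#' readouts and standardises them: `Z = (x - mean) / sd`. The log transform
#' is what makes single-point RLU screens approximately Gaussian and hence
#' amenable to Z-score hit calling. The standard-deviation convention
#' defaults to the sample sd (n-1) and is config-exposed. Compounds on an
#' exclusion list (e.g. receptor-independent luminescence dampeners) are
#' dropped first.
#'
#' @param screen data frame with columns `compound_id`, `receptor_id`,
#'   `rlu` (strictly positive)
#' @param sdType `"sample"` (n-1, default) or `"population"` (n)
#' @param exclude compound ids to drop before analysis
#' @return `screen` (minus exclusions) with columns `log_rlu` and `z` added
#' @export
zScore <- function(screen, sdType = c("sample", "population"),
                   exclude = character(0)) {
  sdType <- match.arg(sdType)
  screen <- screen[!screen$compound_id %in% exclude, , drop = FALSE]
  if (any(screen$rlu <= 0)) stop("RLU values must be strictly positive")
  screen$log_rlu <- log10(screen$rlu)
  screen$z <- NA_real_
  for (r in unique(screen$receptor_id)) {
    i <- screen$receptor_id == r
    x <- screen$log_rlu[i]
    if (length(x) < 2) stop("receptor ", r, " has fewer than 2 measurements")
    s <- if (sdType == "sample") stats::sd(x)
         else sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("zero variance for receptor ", r)
    screen$z[i] <- (x - mean(x)) / s
  }
  screen
}

#' Modified (robust) Z-scores of a luminescence screen
#'
#' Per receptor, `Zmod = 0.6745 * (x - m) / MAD` on the log10 RLU values,
#' with `m` the median and `MAD = median(|x - m|)` (unscaled). The 0.6745
#' factor makes the modified score consistent with the ordinary Z-score
#' under normality, while the median/MAD base rescues genuine outliers from
#' inflating the scale estimate.
#'
#' @inheritParams zScore
#' @return `screen` (minus exclusions) with columns `log_rlu` and `z_mod`
#'   added
#' @export
modifiedZScore <- function(screen, exclude = character(0)) {
  screen <- screen[!screen$compound_id %in% exclude, , drop = FALSE]
  if (any(screen$rlu <= 0)) stop("RLU values must be strictly positive")
  screen$log_rlu <- log10(screen$rlu)
  screen$z_mod <- NA_real_
  for (r in unique(screen$receptor_id)) {
    i <- screen$receptor_id == r
    x <- screen$log_rlu[i]
    m <- stats::median(x)
    mad <- stats::median(abs(x - m))
    if (mad == 0) stop("zero MAD for receptor ", r)
    screen$z_mod[i] <- 0.6745 * (x - m) / mad
  }
  screen
}

#' Call hits from Z-scores
#'
#' Strict-threshold hit calling: `two_sided` flags `|Z| > threshold`,
#' `positive` flags `Z > threshold`. A score exactly at the threshold is
#' not a hit.
#'
#' @param z numeric Z-scores (ordinary or modified)
#' @param threshold hit threshold (default 3)
#' @param sign `"two_sided"` or `"positive"`
#' @return logical hit flags
#' @export
callHits <- function(z, threshold = 3, sign = c("two_sided", "positive")) {
  sign <- match.arg(sign)
  if (sign == "two_sided") abs(z) > threshold else z > threshold
}
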