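#' Per-dendrite synapse densities and E/I ratio
#'
#' Excitatory density counts PSD95+ spines plus dually innervated
#' spines (DIS carry PSD95); inhibitory density counts shaft gephyrin
#' puncta plus DIS (they also carry gephyrin). Densities are reported
#' per 100 micrometres; the E/I ratio is their quotient. Set
#' `include_dis = FALSE` for the exclusive definition.
#'
#' @param records a `dendrite_table` / data frame with columns
#'   `length_um`, `psd95_spines`, `dual_innervated_spines`,
#'   `shaft_gephyrin`.
#' @param include_dis count dually innervated spines on both sides
#'   (default TRUE).
#' @return data frame: `excitatory_per100`, `inhibitory_per100`,
#'   `ei_ratio` (`NA` and `flagged` where the inhibitory count is 0).
#' @export
synapse_densities <- function(records, include_dis = TRUE) {
  if (any(records$length_um <= 0)) stop("dendrite lengths must be > 0")
  dis <- if (include_dis) records$dual_innervated_spines else 0
  e <- (records$psd95_spines + dis) / records$length_um * 100
  i <- (records$shaft_gephyrin + dis) / records$length_um * 100
  flagged <- i == 0
  ratio <- ifelse(flagged, NA_real_, e / i)
  data.frame(excitatory_per100 = e, inhibitory_per100 = i,
             ei_ratio = ratio, flagged = flagged)
}

#' Pearson correlation of excitatory and inhibitory densities
#'
#' @param records a dendrite table (>= 3 rows), or a data frame
#'   already holding `excitatory_per100` / `inhibitory_per100`.
#' @param include_dis passed to [synapse_densities()].
#' @return list: `r`, `p` (two-sided), `n`.
#' @export
ei_correlation <- function(records, include_dis = TRUE) {
  if (nrow(records) < 3L) stop("need at least 3 dendrites")
  d <- if (all(c("excitatory_per100", "inhibitory_per100") %in% names(records)))
    records else synapse_densities(records, include_dis)
  if (stats::var(d$excitatory_per100) == 0 || stats::var(d$inhibitory_per100) == 0)
    stop("zero variance in a density: correlation undefined")
  ct <- stats::cor.test(d$excitatory_per100, d$inhibitory_per100,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

#' Compare two Pearson correlations (Fisher r-to-z)
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with the
#' p value from the standard normal distribution.
#'
#' @param r1,r2 sample correlations, |r| < 1.
#' @param n1,n2 sample sizes, >= 4.
#' @param sided "two" (default) or "one".
#' @return list: `z`, `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each sample")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (sided == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' Fractional gain and loss of identity-matched puncta
#'
#' Gain is the fraction of session-2 puncta that are new
#' (|S2 minus S1| / |S2|); loss is the fraction of session-1 puncta
#' that disappeared (|S1 minus S2| / |S1|).
#'
#' @param s1_ids,s2_ids vectors of puncta identities in sessions 1 and
#'   2 (nonempty).
#' @return list: `gain`, `loss`, `ratio` (gain/loss, `NA` when loss is
#'   0), `n_s1`, `n_s2`.
#' @export
fractional_dynamics <- function(s1_ids, s2_ids) {
  s1 <- unique(s1_ids); s2 <- unique(s2_ids)
  if (!length(s1) || !length(s2)) stop("empty session puncta set")
  gain <- length(setdiff(s2, s1)) / length(s2)
  loss <- length(setdiff(s1, s2)) / length(s1)
  list(gain = gain, loss = loss,
       ratio = if (loss > 0) gain / loss else NA_real_,
       n_s1 = length(s1), n_s2 = length(s2))
}
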