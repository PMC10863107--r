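# Internal helpers shared across modules.

.datatable.aware <- TRUE

#' @importFrom stats rpois runif rnorm qnorm pnorm median pchisq p.adjust
#' @importFrom utils packageVersion
NULL

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages draw their own substream seed from the single
#' pipeline seed, so per-individual simulation is independent of call order.
#' Kept below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param index non-negative stream index.
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919 + 1) %%
               2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ltr <- function(...) stop(..., call. = FALSE)

# truncated-normal draws via inverse-CDF (deterministic under set.seed)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# 1-based-with-commas junction label, e.g. "chrB2:55,690,560"
site_label <- function(chrom, junction0) {
  paste0(chrom, ":", formatC(junction0 + 1, big.mark = ",", format = "d"))
}

as_pct1 <- function(x) round(100 * x, 1)
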