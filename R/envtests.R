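#' One-way ANOVA on litter size for an environmental factor
#'
#' Classical fixed-effects one-way ANOVA of weaned litter size on a
#' single environmental factor: `"month"` (calendar month pooled over
#' years, i.e. a seasonality test), `"year_month"` (the 48 distinct
#' batches, a non-seasonal environment test), or `"parity"` (litter
#' order). The month of a record is derived from its batch index, which
#' counts consecutive year-months starting at month 1 of year 1.
#' Restricting to inbred matings only (the diagonal of the diallel) is
#' supported, since those crosses have robust sample sizes throughout a
#' breeding program.
#'
#' @param records a litter-record data frame.
#' @param factor one of `"month"`, `"year_month"`, `"parity"`.
#' @param inbred_only logical; use only records with dam and sire of the
#'   same strain.
#' @return A one-row data frame: `factor`, `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(records,
                         factor = c("month", "year_month", "parity"),
                         inbred_only = FALSE) {
  factor <- match.arg(factor)
  stopifnot(is.data.frame(records))
  if (inbred_only)
    records <- records[records$dam_strain == records$sire_strain, ,
                       drop = FALSE]
  g <- switch(factor,
              month = ((as.integer(records$batch) - 1L) %% 12L) + 1L,
              year_month = as.integer(records$batch),
              parity = as.integer(records$parity))
  g <- base::factor(g)
  y <- as.numeric(records$litter_size)
  tab <- table(g)
  if (sum(tab >= 2L) < 2L || nlevels(g) < 2L)
    stop("need at least 2 factor levels with at least 2 observations each")
  av <- stats::anova(stats::lm(y ~ g))
  data.frame(factor = factor,
             F = av$`F value`[1L],
             df1 = av$Df[1L], df2 = av$Df[2L],
             p = av$`Pr(>F)`[1L],
             stringsAsFactors = FALSE)
}

#' Exact binomial tests of sex-ratio bias with multiplicity correction
#'
#' For each group of litters (either the eight inbred matings, one per
#' strain, or every cross), pools the male and total pup counts and
#' runs the exact two-tailed binomial test of a 0.5 male proportion
#' (the standard two-sided convention: all outcomes at most as probable
#' as the observed one). Unadjusted p-values are then corrected for
#' multiple testing across the groups tested.
#'
#' @param records litter records with `n_male` (and `litter_size`).
#' @param grouping `"strain"` (inbred matings per strain) or `"cross"`
#'   (each dam x sire combination).
#' @param correction a method of [stats::p.adjust()]; default `"holm"`.
#' @return A data frame with one row per non-empty group: `group`,
#'   `males`, `total`, `proportion`, `p`, `p_adj`.
#' @export
sexratio_tests <- function(records, grouping = c("strain", "cross"),
                           correction = "holm") {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(records))
  if (!"n_male" %in% names(records) || anyNA(records$n_male))
    stop("records need complete male counts for sex-ratio tests")
  if (grouping == "strain") {
    records <- records[records$dam_strain == records$sire_strain, ,
                       drop = FALSE]
    key <- records$dam_strain
  } else {
    key <- paste(records$dam_strain, records$sire_strain, sep = "x")
  }
  males <- tapply(as.numeric(records$n_male), key, sum)
  total <- tapply(as.numeric(records$litter_size), key, sum)
  keep <- !is.na(total) & total > 0
  males <- males[keep]; total <- total[keep]
  p <- mapply(function(x, n) stats::binom.test(x, n, p = 0.5)$p.value,
              males, total)
  out <- data.frame(group = names(males),
                    males = as.numeric(males), total = as.numeric(total),
                    proportion = as.numeric(males / total),
                    p = as.numeric(p),
                    p_adj = stats::p.adjust(p, method = correction),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}
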