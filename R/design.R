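#' The eight Collaborative Cross founder strains
#'
#' Returns the canonical ordered strain set used throughout the package:
#' the five classical strains A/J (AJ), C57BL/6J (B6), 129S1/SvImJ (129S1),
#' NOD/ShiLtJ (NOD), NZO/HlLtJ (NZO) and the three wild-derived strains
#' CAST/EiJ (CAST), PWK/PhJ (PWK), WSB/EiJ (WSB). The ordering is fixed:
#' it determines the sign convention of the asymmetric epistatic terms
#' (which cross direction within an unordered strain pair counts as
#' positive), so it is recorded in every fit and must not change between
#' simulation, fitting, and summarization.
#'
#' @param labels optional character vector of 8 distinct strain labels to
#'   use instead of the CC founder names (same positional semantics).
#' @return A character vector of 8 strain labels, class `"strain_set"`.
#' @export
diallel_strains <- function(labels = NULL) {
  if (is.null(labels)) {
    labels <- c("AJ", "B6", "129S1", "NOD", "NZO", "CAST", "PWK", "WSB")
  }
  labels <- as.character(labels)
  if (length(labels) != 8L || anyDuplicated(labels) || any(is.na(labels)) ||
      any(!nzchar(labels))) {
    stop("a strain set must contain exactly 8 distinct non-empty labels")
  }
  structure(labels, class = "strain_set")
}

strain_index <- function(x, strains) {
  idx <- match(as.character(x), strains)
  if (anyNA(idx)) {
    bad <- unique(as.character(x)[is.na(idx)])
    stop("unknown strain label(s): ", paste(bad, collapse = ", "),
         "; known strains are ", paste(strains, collapse = ", "))
  }
  idx
}

#' Unordered strain pairs of a diallel
#'
#' Enumerates the 28 unordered pairs \{j, k\}, j < k, in canonical order
#' (1,2), (1,3), ..., (7,8). These index the symmetric (`v`) and
#' asymmetric (`w`) epistatic effect classes.
#'
#' @param strains a [diallel_strains()] strain set.
#' @return A data frame with columns `j`, `k` (strain indices), and
#'   `label` (e.g. `"AJ:B6"`), 28 rows.
#' @export
strain_pairs <- function(strains = diallel_strains()) {
  jk <- which(upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  jk <- jk[order(jk[, 1], jk[, 2]), , drop = FALSE]
  data.frame(
    j = jk[, 1], k = jk[, 2],
    label = paste(strains[jk[, 1]], strains[jk[, 2]], sep = ":"),
    stringsAsFactors = FALSE
  )
}

pair_index <- function(j, k) {
  # index of unordered pair {j,k} (j != k) in the canonical enumeration
  lo <- pmin(j, k); hi <- pmax(j, k)
  (lo - 1L) * 8L - (lo * (lo - 1L)) %/% 2L + (hi - lo)
}

#' Encode one mating as a diallel design row
#'
#' Builds the covariate encoding of a single dam x sire parentage under
#' the full diallel decomposition: additive strain dosages (0/1/2),
#' signed parental-sex entries (+1 for the dam strain, -1 for the sire
#' strain, so the maternal-vs-paternal difference for a strain is twice
#' its parental-sex effect), overall and strain-specific inbred
#' indicators for selfed matings, the active unordered epistatic pair,
#' and the asymmetric-epistasis sign (+1/2 when the dam strain precedes
#' the sire strain in the canonical order, -1/2 when it follows).
#'
#' @param dam,sire strain labels (or indices 1..8) of the dam and sire.
#' @param strains a [diallel_strains()] strain set.
#' @return A list with elements `additive` (named length-8 dosage),
#'   `parental_sex` (named length-8 signed), `inbred_overall` (0/1),
#'   `inbred_strain` (named length-8 indicator), `epi_pair` (pair index
#'   1..28 or `NA` for inbred matings), `epi_pair_label`, and
#'   `epi_asym_sign` (+0.5, -0.5, or 0).
#' @examples
#' r <- encode_parentage("AJ", "B6")
#' r$epi_asym_sign   # +0.5: AJ precedes B6 in the canonical order
#' @export
encode_parentage <- function(dam, sire, strains = diallel_strains()) {
  j <- strain_index(dam, strains)
  k <- strain_index(sire, strains)
  stopifnot(length(j) == 1L, length(k) == 1L)
  additive <- numeric(8)
  psex <- numeric(8)
  inbred_strain <- numeric(8)
  names(additive) <- names(psex) <- names(inbred_strain) <- strains
  additive[j] <- additive[j] + 1
  additive[k] <- additive[k] + 1
  if (j == k) {
    inbred_strain[j] <- 1
    list(additive = additive, parental_sex = psex, inbred_overall = 1,
         inbred_strain = inbred_strain, epi_pair = NA_integer_,
         epi_pair_label = NA_character_, epi_asym_sign = 0)
  } else {
    psex[j] <- 1
    psex[k] <- -1
    p <- pair_index(j, k)
    list(additive = additive, parental_sex = psex, inbred_overall = 0,
         inbred_strain = inbred_strain, epi_pair = p,
         epi_pair_label = strain_pairs(strains)$label[p],
         epi_asym_sign = if (j < k) 0.5 else -0.5)
  }
}

#' Validate breeding records
#'
#' Screens a litter-record table before analysis. Rows are dropped (never
#' silently altered) when the weaned litter size is missing or below 1
#' (failed litters are unobservable under the zero-truncated model, so a
#' recorded zero is a data error), or when reported male plus female
#' counts disagree with the litter size. Parity values above 12 are
#' clamped to 12 with a warning, since the model declares 12 parity
#' levels while real files occasionally exceed that.
#'
#' @param records a data frame with columns `dam_strain`, `sire_strain`,
#'   `batch`, `parity`, `litter_size`, and optionally `n_male`,
#'   `n_female`, `dam_id`, `sire_id`.
#' @return A list with `records` (the clean rows) and `report` (a data
#'   frame counting dropped rows by reason).
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("dam_strain", "sire_strain", "batch", "parity", "litter_size")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack required column(s): ",
                         paste(miss, collapse = ", "))
  n0 <- nrow(records)
  reasons <- character(0); counts <- integer(0)
  note <- function(reason, k) {
    if (k > 0) { reasons <<- c(reasons, reason); counts <<- c(counts, k) }
  }

  bad_zero <- is.na(records$litter_size) | records$litter_size < 1
  note("zero litter", sum(bad_zero))
  records <- records[!bad_zero, , drop = FALSE]

  if (all(c("n_male", "n_female") %in% names(records))) {
    have_sex <- !is.na(records$n_male) & !is.na(records$n_female)
    bad_sex <- have_sex &
      (records$n_male + records$n_female != records$litter_size |
         records$n_male < 0 | records$n_female < 0)
    note("sex-count mismatch", sum(bad_sex))
    records <- records[!bad_sex, , drop = FALSE]
  }

  bad_batch <- is.na(records$batch) | records$batch < 1 | records$batch > 48
  note("batch out of range", sum(bad_batch))
  records <- records[!bad_batch, , drop = FALSE]

  bad_par <- is.na(records$parity) | records$parity < 1
  note("invalid parity", sum(bad_par))
  records <- records[!bad_par, , drop = FALSE]
  if (any(records$parity > 12)) {
    warning(sum(records$parity > 12),
            " record(s) with parity > 12 clamped to 12")
    records$parity[records$parity > 12] <- 12L
  }

  report <- data.frame(reason = reasons, n_dropped = counts,
                       stringsAsFactors = FALSE)
  attr(report, "n_input") <- n0
  attr(report, "n_kept") <- nrow(records)
  list(records = records, report = report)
}

#' Build the diallel design bundle for a set of litters
#'
#' Encodes every litter record into the index/covariate form consumed by
#' the samplers, the simulator, and the variance projections: strain
#' indices of dam and sire, the unordered epistatic pair index and the
#' asymmetric sign, inbred indicators, and batch/parity level indices.
#' Random-effect classes are exposed with their level counts
#' (additive 8, parental-sex 8, strain-inbred 8, symmetric epistatic 28,
#' asymmetric epistatic 28, parity 12, batch 48).
#'
#' @param records a validated litter-record data frame (see
#'   [validate_records()]).
#' @param strains a [diallel_strains()] strain set.
#' @return A list of parallel vectors (`j`, `k`, `pair`, `asym_sign`,
#'   `inbred`, `batch`, `parity`, `y`, `n_male`) plus `n`, `strains`, and
#'   `n_levels`.
#' @export
build_design <- function(records, strains = diallel_strains()) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n == 0L) {
    return(list(n = 0L, j = integer(0), k = integer(0), pair = integer(0),
                asym_sign = numeric(0), inbred = integer(0),
                batch = integer(0), parity = integer(0), y = numeric(0),
                n_male = numeric(0), strains = strains,
                n_levels = c(a = 8L, m = 8L, b = 8L, v = 28L, w = 28L,
                             order = 12L, batch = 48L)))
  }
  j <- strain_index(records$dam_strain, strains)
  k <- strain_index(records$sire_strain, strains)
  batch <- as.integer(records$batch)
  parity <- as.integer(records$parity)
  if (any(batch < 1 | batch > 48)) stop("batch index out of declared range 1..48")
  if (any(parity < 1 | parity > 12)) stop("parity out of declared range 1..12")
  inbred <- as.integer(j == k)
  pair <- ifelse(j == k, NA_integer_, pair_index(j, k))
  asym <- ifelse(j == k, 0, ifelse(j < k, 0.5, -0.5))
  list(n = n, j = j, k = k, pair = as.integer(pair), asym_sign = asym,
       inbred = inbred, batch = batch, parity = parity,
       y = as.numeric(records$litter_size),
       n_male = if ("n_male" %in% names(records))
         as.numeric(records$n_male) else rep(NA_real_, n),
       strains = strains,
       n_levels = c(a = 8L, m = 8L, b = 8L, v = 28L, w = 28L,
                    order = 12L, batch = 48L))
}
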