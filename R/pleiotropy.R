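# Pleiotropy assessment of candidate editing loci from GWAS summary
# statistics: observed-scale effect conversion, per-phenotype promotion /
# inhibition classification, per-SNP profiling, strength binning, weak-SNP
# screening and QQ diagnostics.

#' Convert an observed-scale GWAS effect to the allelic substitution effect
#'
#' Case-control GWAS run on the observed (linear 0/1) scale attenuate the
#' allelic substitution effect; the conversion rescales `betaObs` using the
#' study's case proportion `phi` and reference allele frequency `theta`:
#'
#' \deqn{\beta = \beta_{obs} \cdot D^{-1}, \quad
#'   D = \phi(1-\phi) + 0.5(1-2\phi)(1-2\theta)\beta_{obs}
#'     - (0.084 + 0.9\phi(1-2\phi))\,\theta(1-\theta)\,\phi(1-\phi)\,
#'       \beta_{obs}^2}
#'
#' In the small-effect limit this reduces to the standard
#' \eqn{\beta \approx \beta_{obs} / (\phi(1-\phi))} rescaling, which is the
#' property that pins down the grouping of the polynomial (`parse =
#' "rational"`, the default). The alternative reading of the formula with
#' the trailing \eqn{-1} taken as a subtraction,
#' \eqn{\beta = \beta_{obs}(D' - 1)} with \eqn{D'} the same bracket, is kept
#' behind `parse = "offset"` for comparison; it does not reproduce the
#' small-effect limit and is not used by the pipeline.
#'
#' @param betaObs observed-scale effect(s).
#' @param phi case proportion(s), in (0, 1).
#' @param theta reference allele frequency(ies), in (0, 1).
#' @param parse `"rational"` (default) or `"offset"`; see Details.
#' @param onNonconvertible what to do when the denominator is <= 0 (the
#'   quadratic has overwhelmed the leading term and the conversion is
#'   undefined): `"error"` (default) or `"na"`.
#' @return converted effect(s) `beta`; zero maps to zero.
#' @examples
#' convertBeta(0.1, phi = 0.5, theta = 0.5)
#' @export
convertBeta <- function(betaObs, phi, theta,
                        parse = c("rational", "offset"),
                        onNonconvertible = c("error", "na")) {
  parse <- match.arg(parse)
  onNonconvertible <- match.arg(onNonconvertible)
  n <- max(length(betaObs), length(phi), length(theta))
  betaObs <- rep_len(betaObs, n)
  phi <- rep_len(phi, n)
  theta <- rep_len(theta, n)
  if (any(!is.finite(phi) | phi <= 0 | phi >= 1))
    stop("domain error: phi must lie in (0, 1)", call. = FALSE)
  if (any(!is.finite(theta) | theta <= 0 | theta >= 1))
    stop("domain error: theta must lie in (0, 1)", call. = FALSE)
  d <- phi * (1 - phi) +
    0.5 * (1 - 2 * phi) * (1 - 2 * theta) * betaObs -
    (0.084 + 0.9 * phi * (1 - 2 * phi)) *
      theta * (1 - theta) * phi * (1 - phi) * betaObs^2
  if (parse == "offset") return(betaObs * (d - 1))
  bad <- d <= 0
  if (any(bad)) {
    if (onNonconvertible == "error")
      stop(sprintf(
        "non-convertible effect: denominator <= 0 at beta_obs=%g, phi=%g, theta=%g",
        betaObs[which(bad)[1]], phi[which(bad)[1]], theta[which(bad)[1]]),
        call. = FALSE)
    d[bad] <- NA_real_
  }
  betaObs / d
}

#' Classify one SNP-phenotype association
#'
#' Promotion means the allele significantly increases disease incidence
#' (`beta > 0`, `p < alpha`); inhibition the reverse; everything else,
#' including an exactly zero effect, is nonsignificant.
#'
#' @param beta converted allelic substitution effect(s).
#' @param pValue association P value(s).
#' @param alpha significance threshold (default 0.05; no multiple-testing
#'   correction, matching the stated threshold convention).
#' @return character vector in `{"promotion", "inhibition",
#'   "nonsignificant"}`.
#' @export
classifyAssociation <- function(beta, pValue, alpha = 0.05) {
  ifelse(pValue < alpha & beta > 0, "promotion",
         ifelse(pValue < alpha & beta < 0, "inhibition", "nonsignificant"))
}

.strengthBin <- function(nSignificant) {
  ifelse(nSignificant < 10, "<10",
         ifelse(nSignificant <= 20, "10-20", ">20"))
}

#' Pleiotropy profile of one SNP across phenotypes
#'
#' Converts each record's observed-scale effect, classifies every
#' association at level `alpha` and counts significant promotions and
#' inhibitions. The strength bin follows the number of significant
#' phenotypes: fewer than 10, 10--20 (inclusive), more than 20.
#' Records whose effect cannot be converted (denominator <= 0) are excluded
#' and counted in `n_nonconvertible`.
#'
#' @param snpId SNP identifier.
#' @param gwas data.frame from [readGwas()].
#' @param alpha significance threshold.
#' @return one-row data.frame: `snp_id`, `n_phenotypes_tested`,
#'   `n_significant`, `n_promote`, `n_inhibit`, `n_nonconvertible`,
#'   `strength_bin`.
#' @export
pleiotropyProfile <- function(snpId, gwas, alpha = 0.05) {
  rec <- gwas[gwas$snp_id == snpId, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no GWAS records for SNP ", sQuote(snpId), call. = FALSE)
  beta <- convertBeta(rec$beta_obs, rec$phi, rec$theta,
                      onNonconvertible = "na")
  dropped <- sum(is.na(beta))
  if (dropped > 0L)
    message(dropped, " non-convertible record(s) excluded for SNP ", snpId)
  cls <- classifyAssociation(beta[!is.na(beta)],
                             rec$p_value[!is.na(beta)], alpha = alpha)
  nPromote <- sum(cls == "promotion")
  nInhibit <- sum(cls == "inhibition")
  data.frame(
    snp_id = snpId,
    n_phenotypes_tested = nrow(rec),
    n_significant = nPromote + nInhibit,
    n_promote = nPromote,
    n_inhibit = nInhibit,
    n_nonconvertible = dropped,
    strength_bin = .strengthBin(nPromote + nInhibit),
    stringsAsFactors = FALSE
  )
}

#' Pleiotropy profiles for all (or selected) SNPs in a GWAS table
#'
#' @param gwas data.frame from [readGwas()].
#' @param snpIds SNPs to profile (default: all present).
#' @param alpha significance threshold.
#' @return data.frame, one row per SNP (see [pleiotropyProfile()]).
#' @export
pleiotropyProfiles <- function(gwas, snpIds = NULL, alpha = 0.05) {
  if (is.null(snpIds)) snpIds <- unique(gwas$snp_id)
  out <- do.call(rbind, lapply(snpIds, pleiotropyProfile, gwas = gwas,
                               alpha = alpha))
  rownames(out) <- NULL
  out
}

#' Bin SNPs by pleiotropy strength
#'
#' @param profiles data.frame from [pleiotropyProfiles()], or a named
#'   numeric vector of counts per bin (names `"<10"`, `"10-20"`, `">20"`).
#' @return data.frame with `strength_bin`, `count`, `percent` (half-up,
#'   1 decimal), plus attribute `total`.
#' @examples
#' binStrength(c("<10" = 577, "10-20" = 121, ">20" = 9))
#' @export
binStrength <- function(profiles) {
  bins <- c("<10", "10-20", ">20")
  if (is.data.frame(profiles)) {
    counts <- vapply(bins, function(b) sum(profiles$strength_bin == b),
                     numeric(1))
  } else {
    if (is.null(names(profiles)) || !all(names(profiles) %in% bins))
      stop("counts must be named with the three strength bins", call. = FALSE)
    counts <- setNames(numeric(3), bins)
    counts[names(profiles)] <- profiles
  }
  total <- sum(counts)
  if (total == 0) stop("no profiles to bin", call. = FALSE)
  out <- data.frame(
    strength_bin = bins,
    count = unname(counts),
    percent = .roundHalfUp(100 * unname(counts) / total, 1L),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  out
}

#' Screen SNPs with weak pleiotropic effects
#'
#' Returns the SNPs whose total number of significant associations does not
#' exceed `maxSignificant` (default 1: at most one phenotype significantly
#' promoted or inhibited), i.e. loci whose editing is least likely to
#' perturb unrelated phenotypes.
#'
#' @param profiles data.frame from [pleiotropyProfiles()].
#' @param maxSignificant inclusive upper bound on `n_significant`.
#' @return character vector of SNP ids.
#' @export
screenWeak <- function(profiles, maxSignificant = 1L) {
  profiles$snp_id[profiles$n_significant <= maxSignificant]
}

#' Expected-vs-observed P value pairs for a QQ plot
#'
#' Observed P values are sorted ascending and paired with the uniform
#' quantiles `(i - 0.5)/n`; both are returned on the -log10 scale. Zero
#' P values are clamped to the smallest positive double with a warning.
#'
#' @param pValues numeric vector of P values in \[0, 1\].
#' @return data.frame with columns `expected` and `observed`.
#' @export
qqPoints <- function(pValues) {
  if (any(!is.finite(pValues)) || any(pValues < 0) || any(pValues > 1))
    stop("P values must lie in [0, 1]", call. = FALSE)
  if (any(pValues == 0)) {
    warning("P value(s) of 0 clamped to the smallest positive double",
            call. = FALSE)
    pValues[pValues == 0] <- .Machine$double.xmin
  }
  n <- length(pValues)
  obs <- sort(pValues)
  expd <- (seq_len(n) - 0.5) / n
  data.frame(expected = -log10(expd), observed = -log10(obs))
}
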