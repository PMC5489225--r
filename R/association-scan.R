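# Marginal and exposure-stratified association scans, the between-strata
# heterogeneity interaction test, and ingestion of external GWAS summary
# tables.

#' Marginal additive association scan
#'
#' Ordinary least squares of the prepared trait on allele dosage (additive
#' coding), one SNP at a time, vectorized across the dosage matrix.
#' Two-sided P-values from the t distribution with n-2 degrees of freedom.
#' Complete-case per SNP. Monomorphic SNPs are flagged with no P-value.
#'
#' @param genotypes n x m dosage matrix (column names = SNP ids).
#' @param prepared `prepared_phenotype` or numeric trait vector.
#' @param min_n minimum non-missing individuals per SNP (default 10).
#' @return data.frame: snp_id, n, beta, se, t, P_m, flag.
#' @export
marginal_scan <- function(genotypes, prepared, min_n = 10) {
  y <- .pheno_values(prepared)
  G <- genotypes
  stopifnot(length(y) == nrow(G))
  if (!anyNA(G) && !anyNA(y)) {
    m <- ncol(G)
    n <- rep(nrow(G), m)
    Sx <- colSums(G)
    Sxx <- colSums(G * G)
    Sxy <- as.vector(crossprod(G, y))
    Sy <- rep(sum(y), m)
    Syy <- rep(sum(y * y), m)
  } else {
    yok <- !is.na(y)
    y0 <- ifelse(yok, y, 0)
    gmiss <- is.na(G)
    if (any(gmiss)) {
      W <- (!gmiss) * as.numeric(yok)
      G0 <- G; G0[gmiss] <- 0
    } else {
      W <- matrix(as.numeric(yok), nrow(G), ncol(G))
      G0 <- G
    }
    n <- colSums(W)
    Sx <- colSums(G0 * W)
    Sy <- colSums(W * y0)
    Sxx <- colSums(G0^2 * W)
    Sxy <- colSums(G0 * (W * y0))
    Syy <- colSums(W * y0^2)
  }
  Sxx_c <- Sxx - Sx^2 / n
  Sxy_c <- Sxy - Sx * Sy / n
  Syy_c <- Syy - Sy^2 / n
  flag <- rep(NA_character_, ncol(G))
  poly <- Sxx_c > 1e-12 & n >= min_n
  flag[n < min_n] <- "LOW_N"
  flag[n >= min_n & Sxx_c <= 1e-12] <- "MONOMORPHIC"
  beta <- ifelse(poly, Sxy_c / Sxx_c, NA)
  rss <- pmax(Syy_c - beta * Sxy_c, 0)
  sigma2 <- rss / (n - 2)
  se <- ifelse(poly, sqrt(sigma2 / Sxx_c), NA)
  tstat <- beta / se
  P <- .floor_p(2 * stats::pt(-abs(tstat), df = n - 2))
  exact_fit <- which(!is.na(se) & se == 0)
  P[exact_fit] <- .P_FLOOR   # exact fit: P underflows to the floor
  tstat[exact_fit] <- Inf * sign(beta[exact_fit])
  data.frame(snp_id = colnames(G), n = n, beta = beta, se = se, t = tstat,
             P_m = ifelse(poly, P, NA), flag = flag, stringsAsFactors = FALSE)
}

#' Between-strata heterogeneity test
#'
#' z = (beta1 - beta2) / sqrt(se1^2 + se2^2), two-sided normal P; identical
#' to Cochran's Q with one degree of freedom. This is the interaction test
#' applied to stratum-specific marginal effect estimates.
#'
#' @param beta1,se1 estimate and SE in stratum 1 (vectorized).
#' @param beta2,se2 estimate and SE in stratum 2.
#' @return data.frame with `z` and `p`.
#' @examples
#' heterogeneity_test(1.0, 0.1, 0.0, 0.1)  # z = 7.071
#' @export
heterogeneity_test <- function(beta1, se1, beta2, se2) {
  if (any(se1 <= 0, na.rm = TRUE) || any(se2 <= 0, na.rm = TRUE))
    stop("data error: standard errors must be positive")
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  data.frame(z = z, p = .floor_p(2 * stats::pnorm(-abs(z))))
}

#' Exposure-stratified scan with interaction test
#'
#' Runs [marginal_scan()] separately within the exposed and unexposed strata
#' and compares the stratum-specific estimates with [heterogeneity_test()]
#' to obtain P_int. SNPs with fewer than `min_n` usable individuals in either
#' stratum are flagged with no P_int.
#'
#' @param genotypes n x m dosage matrix.
#' @param prepared `prepared_phenotype` or numeric trait vector.
#' @param exposure 0/1 vector.
#' @param min_n per-stratum minimum (default 10).
#' @return data.frame: snp_id, beta1/se1/n1 (exposed), beta0/se0/n0
#'   (unexposed), het_z, P_int, flag.
#' @export
stratified_interaction_scan <- function(genotypes, prepared, exposure,
                                        min_n = 10) {
  y <- .pheno_values(prepared)
  stopifnot(length(exposure) == length(y))
  e1 <- which(exposure == 1)
  e0 <- which(exposure == 0)
  empty <- function(m) data.frame(snp_id = colnames(genotypes),
                                  n = 0, beta = NA_real_, se = NA_real_,
                                  t = NA_real_, P_m = NA_real_,
                                  flag = "EMPTY_STRATUM",
                                  stringsAsFactors = FALSE)
  s1 <- if (length(e1)) marginal_scan(genotypes[e1, , drop = FALSE], y[e1], min_n) else empty()
  s0 <- if (length(e0)) marginal_scan(genotypes[e0, , drop = FALSE], y[e0], min_n) else empty()
  ok <- is.na(s1$flag) & is.na(s0$flag) & !is.na(s1$se) & !is.na(s0$se) &
    s1$se > 0 & s0$se > 0
  z <- rep(NA_real_, ncol(genotypes))
  p <- rep(NA_real_, ncol(genotypes))
  if (any(ok)) {
    ht <- heterogeneity_test(s1$beta[ok], s1$se[ok], s0$beta[ok], s0$se[ok])
    z[ok] <- ht$z
    p[ok] <- ht$p
  }
  flag <- ifelse(ok, NA_character_,
                 paste0("exposed:", ifelse(is.na(s1$flag), "SE", s1$flag),
                        ";unexposed:", ifelse(is.na(s0$flag), "SE", s0$flag)))
  data.frame(snp_id = colnames(genotypes),
             beta1 = s1$beta, se1 = s1$se, n1 = s1$n,
             beta0 = s0$beta, se0 = s0$se, n0 = s0$n,
             het_z = z, P_int = p, flag = flag, stringsAsFactors = FALSE)
}

#' Read an external GWAS summary-statistic table
#'
#' Parses a delimited text file of marker-level association results (the
#' format large consortia distribute) into the package's scan-result layout,
#' harmonizing each row's effect allele to a reference: when the alleles are
#' swapped relative to the reference the sign of beta is flipped. Rows with
#' unparseable numeric fields are dropped and counted.
#'
#' @param path file path; tab- or whitespace-delimited with a header row.
#' @param column_map named list mapping the required fields (marker, ea, oa,
#'   beta, se, p; optionally n) to column names in the file.
#' @param reference optional data.frame (snp_id, ea, oa) to harmonize
#'   against; rows whose alleles match neither orientation are dropped.
#' @return data.frame: snp_id, ea, oa, beta, se, P_m, n, with attribute
#'   `n_dropped` (count of malformed rows) and `n_flipped`.
#' @export
read_summary_table <- function(path,
                               column_map = list(marker = "MarkerName",
                                                 ea = "Allele1", oa = "Allele2",
                                                 beta = "b", se = "SE",
                                                 p = "p", n = "N"),
                               reference = NULL) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  req <- c("marker", "ea", "oa", "beta", "se", "p")
  miss <- setdiff(req, names(column_map))
  if (length(miss))
    stop("configuration error: column_map lacks ", paste(miss, collapse = ", "))
  absent <- setdiff(unlist(column_map[req]), names(raw))
  if (length(absent))
    stop("configuration error: column(s) not in file: ",
         paste(absent, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(snp_id = as.character(raw[[column_map$marker]]),
                    ea = toupper(as.character(raw[[column_map$ea]])),
                    oa = toupper(as.character(raw[[column_map$oa]])),
                    beta = num(raw[[column_map$beta]]),
                    se = num(raw[[column_map$se]]),
                    P_m = num(raw[[column_map$p]]),
                    stringsAsFactors = FALSE)
  out$n <- if (!is.null(column_map$n) && column_map$n %in% names(raw))
    num(raw[[column_map$n]]) else NA_real_
  bad <- is.na(out$beta) | is.na(out$se) | is.na(out$P_m) |
    out$se <= 0 | out$P_m <= 0 | out$P_m > 1
  n_dropped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  n_flipped <- 0L
  if (!is.null(reference)) {
    idx <- match(out$snp_id, reference$snp_id)
    known <- !is.na(idx)
    aligned <- known & out$ea == reference$ea[idx] & out$oa == reference$oa[idx]
    swapped <- known & out$ea == reference$oa[idx] & out$oa == reference$ea[idx]
    out$beta[swapped] <- -out$beta[swapped]
    tmp <- out$ea[swapped]
    out$ea[swapped] <- out$oa[swapped]
    out$oa[swapped] <- tmp
    n_flipped <- sum(swapped)
    out <- out[aligned | swapped, , drop = FALSE]
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_flipped") <- n_flipped
  out
}

#' Write a scan-result table
#'
#' Tab-delimited, deterministic formatting; round-trips through
#' [read_summary_table()] with the default column map by using its column
#' names.
#'
#' @param scan data.frame with snp_id, beta, se and a P column.
#' @param path output path.
#' @param p_col name of the P column in `scan` (default "P_m").
#' @param meta optional data.frame (snp_id, ea, oa) supplying alleles.
#' @return invisibly, `path`.
#' @export
write_scan_table <- function(scan, path, p_col = "P_m", meta = NULL) {
  ea <- oa <- NULL
  if (!is.null(meta)) {
    idx <- match(scan$snp_id, meta$snp_id)
    ea <- meta$ea[idx]; oa <- meta$oa[idx]
  }
  out <- data.frame(MarkerName = scan$snp_id,
                    Allele1 = if (is.null(ea)) "A" else ea,
                    Allele2 = if (is.null(oa)) "G" else oa,
                    b = scan$beta, SE = scan$se, p = scan[[p_col]],
                    N = if ("n" %in% names(scan)) scan$n else NA_real_,
                    stringsAsFactors = FALSE)
  write_tsv_stable(out, path)
}
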