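# Trait preparation and per-SNP absolute deviations Z.

#' Prepare a raw trait for variance-heterogeneity analysis
#'
#' Applies, in order: log10 transform (for positive, typically right-skewed
#' traits such as BMI or lipids), z-score standardization (subtract mean,
#' divide by the sample SD, n-1 convention), and Winsorization clamping the
#' z-scores to +/- `winsor_sd` SD. No re-standardization is performed after
#' clamping; the number of clamped values is recorded. Missing values
#' propagate untouched.
#'
#' @param raw numeric trait vector; strictly positive where non-missing when
#'   `log10 = TRUE`.
#' @param winsor_sd clamp bound in SD units (default 4).
#' @param log10 apply the log10 step (default TRUE).
#' @return object of class `prepared_phenotype`: list with `values` and a
#'   `transform_log` recording the log10 flag, the post-log mean and SD used,
#'   the Winsor limit, and the count of clamped values.
#' @examples
#' p <- prepare_trait(c(10, 100, 1000))
#' p$values                      # symmetric around 0
#' @export
prepare_trait <- function(raw, winsor_sd = 4, log10 = TRUE) {
  ok <- !is.na(raw)
  if (sum(ok) < 2L) stop("data error: need at least 2 non-missing values")
  y <- as.numeric(raw)
  if (log10) {
    bad <- which(ok & raw <= 0)
    if (length(bad))
      stop("data error: non-positive trait value(s) with log10 enabled at index ",
           paste(utils::head(bad, 5L), collapse = ", "))
    y[ok] <- log10(y[ok])
  }
  mu <- mean(y[ok])
  sdv <- stats::sd(y[ok])
  if (!is.finite(sdv) || sdv == 0) stop("data error: zero variance in trait")
  z <- (y - mu) / sdv
  n_clamped <- sum(abs(z[ok]) > winsor_sd)
  z <- pmin(pmax(z, -winsor_sd), winsor_sd)
  structure(list(
    values = z,
    transform_log = list(log10 = log10, mean = mu, sd = sdv,
                         winsor_sd = winsor_sd, n_clamped = n_clamped)
  ), class = "prepared_phenotype")
}

#' @export
print.prepared_phenotype <- function(x, ...) {
  tl <- x$transform_log
  cat(sprintf(
    "prepared_phenotype: n=%d (log10=%s, mean=%.4g, sd=%.4g, winsor=%g SD, clamped=%d)\n",
    length(x$values), tl$log10, tl$mean, tl$sd, tl$winsor_sd, tl$n_clamped))
  invisible(x)
}

# Accept either a prepared_phenotype or a bare numeric vector.
.pheno_values <- function(prepared) {
  if (inherits(prepared, "prepared_phenotype")) prepared$values else as.numeric(prepared)
}

#' Absolute deviations from genotype-group means
#'
#' For one SNP, computes Z_i = |Y_i - mean(Y over i's genotype group)|, the
#' quantity Levene's test performs a one-way ANOVA on. Individuals with a
#' missing genotype or phenotype are excluded (Z = NA).
#'
#' @param prepared a `prepared_phenotype` or numeric vector Y.
#' @param genotype_classes integer vector of 0/1/2 (NA allowed).
#' @return list with `values` (Z, NA where excluded) and `group_assignment`.
#' @export
absolute_deviations <- function(prepared, genotype_classes) {
  y <- .pheno_values(prepared)
  g <- genotype_classes
  if (length(g) != length(y)) stop("data error: length mismatch")
  if (!all(g[!is.na(g)] %in% 0:2))
    stop("data error: genotype classes must be 0, 1 or 2")
  use <- !is.na(y) & !is.na(g)
  if (!any(use)) stop("data error: all genotype groups empty")
  z <- rep(NA_real_, length(y))
  for (k in 0:2) {
    sel <- use & g == k
    if (any(sel)) z[sel] <- abs(y[sel] - mean(y[sel]))
  }
  list(values = z, group_assignment = g)
}

#' Read a two-column phenotype file
#'
#' @param path tab-delimited file with columns `iid` and `value` ('.' = NA).
#' @return data.frame with `iid` (character) and `value` (numeric).
#' @export
read_phenotype_file <- function(path) {
  df <- read_tsv_stable(path, numeric_cols = "value")
  if (!all(c("iid", "value") %in% names(df)))
    stop("configuration error: phenotype file must have columns iid, value")
  df
}

#' Write a prepared phenotype with its transform log
#'
#' The sidecar `<path>.log` records the transform as `key=value` lines.
#'
#' @param prepared a `prepared_phenotype`.
#' @param path output path for the two-column values file.
#' @param ids optional individual ids (default sequential).
#' @return invisibly, `path`.
#' @export
write_prepared_phenotype <- function(prepared, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("i%06d", seq_along(prepared$values))
  write_tsv_stable(data.frame(iid = ids, value = prepared$values), path)
  tl <- prepared$transform_log
  writeLines(sprintf("%s=%s", names(tl),
                     vapply(tl, function(v) sprintf("%.10g", as.numeric(v)), "")),
             paste0(path, ".log"))
  invisible(path)
}
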