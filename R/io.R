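# Exchange formats: the cohort genotype-group summary submission, the meta
# result table, and known-locus lists.

#' Write genotype-group summaries in the exchange format
#'
#' Tab-delimited, one row per SNP x cohort, columns snp_id, cohort, ea, oa,
#' eaf, info, callrate, n0, n1, n2, meanZ0..meanZ2, varZ0..varZ2; '.' for
#' undefined; floats at a fixed 10 significant digits so re-writing the same
#' data is byte-stable.
#'
#' @param summaries rows as produced by [summarize_groups()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_group_summaries <- function(summaries, path) {
  cols <- c("snp_id", "cohort", "ea", "oa", "eaf", "info", "callrate",
            "n0", "n1", "n2", "meanZ0", "meanZ1", "meanZ2",
            "varZ0", "varZ1", "varZ2")
  write_tsv_stable(summaries[, cols], path)
}

#' Read genotype-group summaries
#'
#' Validates the invariants of the exchange format: counts non-negative,
#' variances non-negative where defined, group variance only defined where
#' the count is at least 2.
#'
#' @param path file written by [write_group_summaries()].
#' @return summary data.frame.
#' @export
read_group_summaries <- function(path) {
  num <- c("eaf", "info", "callrate", "n0", "n1", "n2",
           "meanZ0", "meanZ1", "meanZ2", "varZ0", "varZ1", "varZ2")
  s <- read_tsv_stable(path, numeric_cols = num)
  need <- c("snp_id", "cohort", "ea", "oa", num)
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("configuration error: summary file lacks column(s) ",
         paste(miss, collapse = ", "))
  for (k in 0:2) {
    nk <- s[[paste0("n", k)]]
    vk <- s[[paste0("varZ", k)]]
    if (any(nk < 0)) stop("data error: negative group count")
    if (any(!is.na(vk) & vk < 0)) stop("data error: negative group variance")
    if (any(!is.na(vk) & nk < 2))
      stop("data error: variance defined for group with n < 2")
  }
  s
}

#' Write meta-analysis Levene results
#'
#' @param meta result of [meta_levene()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_meta_results <- function(meta, path) {
  write_tsv_stable(meta[, c("snp_id", "N", "L", "df2", "P_v", "n_cohorts",
                            "reason")], path)
}

#' Read a known-locus list
#'
#' @param path delimited file with at least columns snp (or snp_id), chrom
#'   and pos.
#' @return data.frame snp_id, chrom, pos.
#' @export
read_known_loci <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  nm <- names(df)
  id_col <- intersect(c("snp_id", "snp", "marker"), nm)[1]
  if (is.na(id_col) || !all(c("chrom", "pos") %in% nm))
    stop("configuration error: known-locus file needs snp, chrom, pos columns")
  data.frame(snp_id = as.character(df[[id_col]]),
             chrom = as.character(df$chrom),
             pos = as.numeric(df$pos), stringsAsFactors = FALSE)
}
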