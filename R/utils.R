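# Internal helpers shared across modules.

# Seed the RNG only when the caller supplied a seed; returns invisibly.
.seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' Derive replicate seeds from one master seed
#'
#' Draws `k` integer seeds after seeding the RNG with `seed`, so replicates
#' can be run in any order (or subset) and still reproduce.
#'
#' @param seed master seed (NULL leaves the RNG state untouched).
#' @param k number of seeds.
#' @return integer vector of length `k`, each below 2^31.
#' @export
derive_seeds <- function(seed, k) {
  .seed_if(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

# Deterministic tab-delimited writer: fixed 10-significant-digit floats,
# '.' for missing, no quoting, so identical inputs give byte-identical files.
write_tsv_stable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.double(x)) {
      s <- sprintf("%.10g", x)
      s[!is.finite(x)] <- "."
      out[[j]] <- s
    } else {
      s <- as.character(x)
      s[is.na(s)] <- "."
      out[[j]] <- s
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

read_tsv_stable <- function(path, numeric_cols = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = ".", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (nm in intersect(numeric_cols, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  df
}

# Moment skewness (used by the generator's shape checks).
.skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

# Floor tiny upper-tail P-values; anything below gets the floor and a flag.
.P_FLOOR <- 1e-300

.floor_p <- function(p) pmax(p, .P_FLOOR)
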