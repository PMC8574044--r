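# Shared fixtures: reference parameter sets, random generators, a designed
# promoter reference with known PAM sites, and brute-force oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

tbl <- list(
  promoterSingle = exampleCircuitParams("promoter_single"),
  promoterSingleAlt = exampleCircuitParams("promoter_single_alt"),
  promoterDual = exampleCircuitParams("promoter_dual"),
  elongationSingle = exampleCircuitParams("elongation_single"),
  elongationDual = exampleCircuitParams("elongation_dual")
)

# random observable-scale parameter draw (log-uniform where natural)
randomSSParams <- function(dual = FALSE) {
  yMin <- stats::runif(1, 0, 100)
  yMax <- stats::runif(1, 1e3, 1e4)
  kap <- 10^stats::runif(1, -3, 0)
  alp <- 10^stats::runif(1, log10(1.3), log10(500))
  if (dual)
    SteadyStateParams(yMin, yMax, kap, alp,
                      kappaD = 10^stats::runif(1, -3, 0),
                      alphaD = 10^stats::runif(1, 0, 1))
  else SteadyStateParams(yMin, yMax, kap, alp)
}

randomKineticParams <- function() {
  KineticParams(betaM = stats::runif(1, 1, 50),
                beta = stats::runif(1, 0, 0.5),
                deltaM = stats::runif(1, 0.05, 1),
                KR = 10^stats::runif(1, -3, 0),
                KD = 10^stats::runif(1, -3, 0),
                alphaR = 10^stats::runif(1, 0, 2.5),
                alphaD = 10^stats::runif(1, 0, 1))
}

randomDnaString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive window-scan PAM oracle, independent of the package scanner
bruteForcePams <- function(s) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  rows <- list()
  for (i in seq_len(L - 2)) {
    if (ch[i + 1] == "G" && ch[i + 2] == "G")
      rows[[length(rows) + 1]] <- data.frame(start = i, end = i + 2L,
                                             strand = "top")
    if (ch[i] == "C" && ch[i + 1] == "C")
      rows[[length(rows) + 1]] <- data.frame(start = i, end = i + 2L,
                                             strand = "bottom")
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Designed 400-nt promoter reference: all-A background with a top-strand PAM
# at 121-123 (sgD; protospacer 101-120, wholly upstream of -60 for a TSS at
# 200) and a bottom-strand PAM at 138-140 (sgR; protospacer 141-160).  The
# footprint gap is exactly 14 bp with the PAMs facing each other.
toyPromoterRef <- function() {
  ch <- rep("A", 400)
  ch[121:123] <- c("A", "G", "G")
  ch[138:140] <- c("C", "C", "T")
  paste(ch, collapse = "")
}
toyTss <- 200L

# construct a GuideSite directly from coordinates (valid by construction)
mkSite <- function(protoStart, strand) {
  protoStart <- as.integer(protoStart)
  if (strand == "top")
    new("GuideSite", spacer = strrep("A", 20), strand = "top",
        protoStart = protoStart, protoEnd = protoStart + 19L,
        pamStart = protoStart + 20L, pamEnd = protoStart + 22L)
  else
    new("GuideSite", spacer = strrep("A", 20), strand = "bottom",
        protoStart = protoStart, protoEnd = protoStart + 19L,
        pamStart = protoStart - 3L, pamEnd = protoStart - 1L)
}
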