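# Independent oracles used across the suite. Each recomputes a quantity by
# a different route than the implementation under test.

# Expected mutant-allele fraction by cell-class allele counting: enumerate
# the three cell classes of the admixture (normal, tumor without the CNA,
# tumor with the CNA), assign each class its mutant and total allele counts
# from first principles, and take the weighted ratio.
oracleMaf <- function(alpha, beta, state, alleleConfig = "none") {
  w <- c(normal = 1 - alpha,
         tumorNoCna = alpha * (1 - beta),
         tumorCna = alpha * beta)
  total <- c(2, 2, switch(state,
    CN2 = 2, CN1 = 1, LOH = 2, CN0 = 0, AMP = 3))
  mutant <- c(0, 1, switch(state,
    CN2 = 1,
    CN1 = if (alleleConfig == "mutant_retained") 1 else 0,
    LOH = if (alleleConfig == "mutant_duplicated") 2 else 0,
    CN0 = 0,
    AMP = if (alleleConfig == "mutant_duplicated") 2 else 1))
  sum(w * mutant) / sum(w * total)
}

# Same quantity by literal enumeration of a large population of cells.
oracleMafEnumerated <- function(alpha, beta, state, alleleConfig = "none",
                                nCells = 1e6) {
  nNormal <- round(nCells * (1 - alpha))
  nCna <- round(nCells * alpha * beta)
  nNoCna <- nCells - nNormal - nCna
  mt <- c(0, 1, switch(state,
    CN2 = 1,
    CN1 = if (alleleConfig == "mutant_retained") 1 else 0,
    LOH = if (alleleConfig == "mutant_duplicated") 2 else 0))
  tt <- c(2, 2, switch(state, CN2 = 2, CN1 = 1, LOH = 2))
  counts <- c(nNormal, nNoCna, nCna)
  sum(rep(mt, counts)) / sum(rep(tt, counts))
}

# Two-sided Fisher exact p by exhaustive enumeration over all tables with
# the observed margins, summing the hypergeometric probabilities of tables
# no more probable than the observed one (probabilities via choose()).
oracleFisher2x2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0) stop("empty table")
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  pObs <- p[xs == a]
  sum(p[p <= pObs * (1 + 1e-7)])
}

# Profile log-likelihood of the symmetric BAF mixture on a grid of peak
# positions, with responsibilities replaced by hard assignment to the
# nearer component; returns the grid argmax.
oracleGridPeak <- function(x, grid = seq(0.01, 0.5, by = 5e-4)) {
  ll <- vapply(grid, function(mu) {
    d <- pmin((x - mu)^2, (x - (1 - mu))^2)
    s2 <- max(mean(d), 1e-8)
    -length(x) / 2 * log(2 * pi * s2) - sum(d) / (2 * s2)
  }, numeric(1))
  grid[which.max(ll)]
}

# All 96 substitution/context combinations on the pyrimidine strand, with
# their labels constructed directly from the definition.
pyrimidineCases <- function() {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (ref in c("C", "T")) {
    alts <- setdiff(bases, ref)
    for (alt in alts) for (b1 in bases) for (b3 in bases) {
      ctx <- paste0(b1, ref, b3)
      label <- if (ref == "C") {
        paste0("C>", alt, if (b3 == "G") "_CpG" else "_nonCpG")
      } else paste0("T>", alt)
      out[[length(out) + 1L]] <- data.frame(
        ref = ref, alt = alt, context = ctx, label = label,
        apobec = (ref == "C") && ctx %in% c("TCA", "TCT") &&
          alt %in% c("T", "G"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

revCompOracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(s, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
}

# All distinct 2x2 tables (up to the symmetries that leave the Fisher p
# unchanged: row swap, column swap, transpose) with grand total <= maxN.
canonicalTables <- function(maxN = 30L) {
  tabs <- list()
  seen <- new.env(hash = TRUE)
  for (a in 0:maxN) for (b in 0:(maxN - a))
    for (c in 0:(maxN - a - b)) for (d in 0:(maxN - a - b - c)) {
      if (a + b + c + d == 0L) next
      forms <- rbind(c(a, b, c, d), c(c, d, a, b), c(b, a, d, c),
                     c(d, c, b, a), c(a, c, b, d), c(b, d, a, c),
                     c(c, a, d, b), c(d, b, c, a))
      key <- min(apply(forms, 1, paste, collapse = ","))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      tabs[[length(tabs) + 1L]] <- c(a, b, c, d)
    }
  do.call(rbind, tabs)
}
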